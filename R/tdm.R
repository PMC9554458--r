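#' Therapeutic drug monitoring dataset
#'
#' Per-subject dosing and sampled concentrations, the input of the
#' validation and estimation modules. `subjects` holds one row per subject
#' (id, subgroup label, body weight, gestational and postnatal age, dose
#' and infusion duration); `obs` holds one row per sample (id, time since
#' first dose, concentration, below-LLOQ flag).
#'
#' @param subjects Data.frame with columns `id`, `group`, `TBW`, `GA`,
#'   `PNA`, `dose_per_kg`, `infusion_h`, `interval`.
#' @param obs Data.frame with columns `id`, `time`, `conc`, `blq`.
#' @param lloq Lower limit of quantification, mg/L (default 0.3).
#' @return An object of class `tdm_dataset`.
#' @export
tdm_dataset <- function(subjects, obs, lloq = 0.3) {
  need_s <- c("id", "group", "TBW", "dose_per_kg", "infusion_h", "interval")
  need_o <- c("id", "time", "conc", "blq")
  if (!all(need_s %in% names(subjects)))
    stop("subjects is missing columns: ",
         paste(setdiff(need_s, names(subjects)), collapse = ", "))
  if (!all(need_o %in% names(obs)))
    stop("obs is missing columns: ",
         paste(setdiff(need_o, names(obs)), collapse = ", "))
  if (any(obs$time < 0)) stop("sampling times must be non-negative")
  quant <- obs[!obs$blq, , drop = FALSE]
  if (any(quant$conc < lloq - 1e-12))
    stop("quantifiable concentrations below the LLOQ must be flagged blq")
  no_obs <- setdiff(subjects$id, quant$id)
  if (length(no_obs))
    warning("subjects without quantifiable observations: ",
            paste(no_obs, collapse = ", "))
  structure(list(subjects = subjects, obs = obs, lloq = lloq),
            class = "tdm_dataset")
}

#' @export
print.tdm_dataset <- function(x, ...) {
  cat(sprintf("TDM dataset: %d subjects, %d observations (%d below LLOQ %.2g mg/L)\n",
              nrow(x$subjects), nrow(x$obs), sum(x$obs$blq), x$lloq))
  invisible(x)
}

#' Read / write the NONMEM-flavoured TDM CSV dialect
#'
#' Columns `ID, TIME, DV, AMT, RATE, WT, GROUP, BLQ`: one dosing row per
#' subject (`AMT` mg and `RATE` mg/h at `TIME` 0, `DV` empty) followed by
#' observation rows (`DV` mg/L, `AMT`/`RATE` empty). An optional `IVL`
#' column carries the dosing interval in hours (default 48 preterm /
#' 36 term). The dialect round-trips through [read_tdm()] and
#' [write_tdm()].
#'
#' @param path CSV file path.
#' @param lloq LLOQ passed to [tdm_dataset()].
#' @return [read_tdm()]: a `tdm_dataset`; [write_tdm()]: `path`,
#'   invisibly.
#' @name tdm_io
#' @export
read_tdm <- function(path, lloq = 0.3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ID", "TIME", "DV", "AMT", "RATE", "WT", "GROUP")
  if (!all(need %in% names(df)))
    stop("malformed TDM CSV, missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"BLQ" %in% names(df)) df$BLQ <- 0L
  dose_rows <- df[!is.na(df$AMT), , drop = FALSE]
  obs_rows <- df[is.na(df$AMT) & (!is.na(df$DV) | df$BLQ > 0), ,
                 drop = FALSE]
  if (anyDuplicated(dose_rows$ID))
    stop("multiple dosing rows per subject are not supported")
  subjects <- data.frame(
    id = dose_rows$ID, group = dose_rows$GROUP, TBW = dose_rows$WT,
    GA = if ("GA" %in% names(df)) dose_rows$GA else NA_real_,
    PNA = if ("PNA" %in% names(df)) dose_rows$PNA else NA_real_,
    dose_per_kg = dose_rows$AMT / dose_rows$WT,
    infusion_h = dose_rows$AMT / dose_rows$RATE,
    interval = if ("IVL" %in% names(df)) dose_rows$IVL else
      ifelse(dose_rows$GROUP == "term", 36, 48))
  obs <- data.frame(id = obs_rows$ID, time = obs_rows$TIME,
                    conc = obs_rows$DV, blq = obs_rows$BLQ > 0)
  tdm_dataset(subjects, obs, lloq = lloq)
}

#' @rdname tdm_io
#' @param tdm A [tdm_dataset()].
#' @export
write_tdm <- function(tdm, path) {
  stopifnot(inherits(tdm, "tdm_dataset"))
  s <- tdm$subjects
  dose_rows <- data.frame(
    ID = s$id, TIME = 0, DV = NA_real_,
    AMT = s$dose_per_kg * s$TBW,
    RATE = s$dose_per_kg * s$TBW / s$infusion_h,
    WT = s$TBW, GROUP = s$group, BLQ = 0L,
    GA = if ("GA" %in% names(s)) s$GA else NA_real_,
    PNA = if ("PNA" %in% names(s)) s$PNA else NA_real_,
    IVL = s$interval)
  o <- merge(tdm$obs, s[, c("id", "TBW", "group", "interval")], by = "id")
  obs_rows <- data.frame(
    ID = o$id, TIME = o$time, DV = o$conc, AMT = NA_real_, RATE = NA_real_,
    WT = o$TBW, GROUP = o$group, BLQ = as.integer(o$blq),
    GA = NA_real_, PNA = NA_real_, IVL = o$interval)
  all_rows <- rbind(dose_rows, obs_rows)
  all_rows <- all_rows[order(all_rows$ID, all_rows$TIME,
                             is.na(all_rows$AMT)), ]
  utils::write.csv(all_rows, path, row.names = FALSE, na = "")
  invisible(path)
}
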