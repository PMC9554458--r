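#' Read and validate a run configuration
#'
#' Configurations are YAML (or JSON) files with blocks `population`
#' (label, n, seed, vd_policy), `regimens` (list of name, dose_per_kg,
#' interval, n_doses, infusion_duration), `criteria` overrides, `mic`
#' (grid bounds/step and reference value), and `solver` (mode, engine,
#' dt). Three presets ship with the package:
#' `system.file("extdata/configs", c("study-preterm.yaml",
#' "study-term.yaml", "toy.yaml"), package = "gentapbpk")`.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return Validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    # YAML 1.1 parses the bare key `n` as a boolean; map it back
    if (is.list(config$population)) {
      nm <- names(config$population)
      names(config$population)[nm %in% c("FALSE", "no")] <- "n"
    }
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  fail <- function(path, msg) stop("config error at ", path, ": ", msg)
  if (is.null(config$population)) fail("$population", "block is required")
  pop <- config$population
  if (is.null(pop$label) || !pop$label %in% c("preterm", "term"))
    fail("$population$label", "must be 'preterm' or 'term'")
  if (is.null(pop$n) || pop$n < 1) fail("$population$n", "must be >= 1")
  if (is.null(pop$seed)) config$population$seed <- 1L
  if (is.null(pop$vd_policy)) config$population$vd_policy <- "fixed"
  if (!is.null(config$regimens)) {
    if (length(config$regimens) == 0)
      fail("$regimens", "must contain at least one regimen")
    for (i in seq_along(config$regimens)) {
      r <- config$regimens[[i]]
      for (f in c("dose_per_kg", "interval"))
        if (is.null(r[[f]]))
          fail(sprintf("$regimens[[%d]]$%s", i, f), "is required")
    }
  }
  if (is.null(config$solver)) config$solver <- list()
  config$solver <- utils::modifyList(
    list(mode = "mass_conserving", engine = "analytic", dt = 0.1),
    config$solver)
  if (!config$solver$mode %in% c("mass_conserving", "as_printed"))
    fail("$solver$mode", "must be 'mass_conserving' or 'as_printed'")
  if (is.null(config$mic)) config$mic <- list()
  config$mic <- utils::modifyList(
    list(min = 0.05, max = 2.0, step = 0.05, reference = 1),
    config$mic)
  structure(config, class = c("run_config", "list"))
}

run_provenance <- function(config, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tf <- tempfile()
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  prov <- list(config_md5 = unname(tools::md5sum(tf)), seed = seed,
               package_version = as.character(
                 utils::packageVersion("gentapbpk")),
               timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tf)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  prov
}

config_cohort <- function(config, seed = NULL) {
  pop <- config$population
  if (!is.null(seed)) pop$seed <- seed
  spec <- population_spec(pop$label, n = pop$n, seed = pop$seed,
                          vd_policy = pop$vd_policy)
  sample_cohort(spec)
}

config_regimens <- function(config) {
  lapply(config$regimens, function(r)
    dosing_regimen(r$dose_per_kg, r$interval,
                   n_doses = if (is.null(r$n_doses)) 1L else r$n_doses,
                   infusion_duration = if (is.null(r$infusion_duration))
                     0.5 else r$infusion_duration))
}

#' Config-driven pipelines
#'
#' End-to-end runners over a [read_run_config()] configuration, each
#' writing plain CSV/JSON outputs plus a provenance sidecar
#' (`provenance.json`: config hash, seed, package version) into
#' `out_dir`. All randomness is controlled by the population seed (or the
#' `seed` override), so a rerun reproduces every output byte-for-byte.
#'
#' * `run_simulate()` -- one concentration profile per virtual subject,
#'   tidy CSV `profiles.csv` (subject_id, time_h, conc_mg_L, compartment).
#' * `run_pta()` -- PTA curves over the MIC grid per regimen
#'   (`pta_curves.csv`) and a summary at the reference MIC
#'   (`pta_summary.csv`) including the toxicity criteria and the
#'   effective/safe classification.
#' * `run_validate()` -- predictive-performance metrics
#'   (`validation_report.csv`) and VPC bands/coverage (`vpc_bands.csv`,
#'   `vpc_coverage.json`) for a TDM CSV against the configured cohort.
#' * `run_estimate()` -- ITS population estimate from a TDM CSV
#'   (`estimate.json` with the convergence trace).
#' * `run_synth()` -- a synthetic TDM dataset (`tdm.csv`) with its
#'   generating truth (`truth.json`).
#'
#' @param config Path or list accepted by [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @param tdm_csv Path to a TDM CSV in the [read_tdm()] dialect.
#' @param regimen_index Which configured regimen to use for simulation/
#'   validation (default 1).
#' @return The main result object of each pipeline, invisibly.
#' @name runners
NULL

#' @rdname runners
#' @export
run_simulate <- function(config, out_dir, seed = NULL, regimen_index = 1) {
  config <- read_run_config(config)
  run_provenance(config, out_dir, seed)
  cohort <- config_cohort(config, seed)
  reg <- config_regimens(config)[[regimen_index]]
  profs <- simulate_cohort(cohort, reg, engine = config$solver$engine,
                           dt = config$solver$dt,
                           mode = config$solver$mode)
  tab <- do.call(rbind, lapply(seq_along(profs), function(i)
    as.data.frame(profs[[i]], subject_id = i)))
  utils::write.csv(tab, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  invisible(profs)
}

#' @rdname runners
#' @export
run_pta <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  if (is.null(config$regimens)) stop("config error at $regimens: required")
  run_provenance(config, out_dir, seed)
  cohort <- config_cohort(config, seed)
  grid <- seq(config$mic$min, config$mic$max, by = config$mic$step)
  crit <- do.call(pkpd_criteria,
                  if (is.null(config$criteria)) list() else config$criteria)
  curves <- NULL; summary <- NULL
  regs <- config_regimens(config)
  results <- list()
  for (i in seq_along(regs)) {
    nm <- config$regimens[[i]]$name
    if (is.null(nm)) nm <- sprintf("regimen%d", i)
    profs <- simulate_cohort(cohort, regs[[i]],
                             engine = config$solver$engine,
                             dt = config$solver$dt,
                             mode = config$solver$mode)
    res <- pta(profs, crit, mic_grid = grid)
    cls <- classify_regimen(res, mic = config$mic$reference)
    results[[nm]] <- res
    curves <- rbind(curves, cbind(population = config$population$label,
                                  regimen = nm, res$pta))
    summary <- rbind(summary, data.frame(
      population = config$population$label, regimen = nm,
      mic = config$mic$reference,
      criterion = names(cls$pta), pta_percent = unname(cls$pta),
      effective = cls$effective, safe = cls$safe))
  }
  utils::write.csv(curves, file.path(out_dir, "pta_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "pta_summary.csv"),
                   row.names = FALSE)
  invisible(results)
}

#' @rdname runners
#' @export
run_validate <- function(config, tdm_csv, out_dir, seed = NULL,
                         regimen_index = 1) {
  config <- read_run_config(config)
  run_provenance(config, out_dir, seed)
  tdm <- read_tdm(tdm_csv)
  grp <- config$population$label
  subjects <- tdm$subjects[tdm$subjects$group == grp, , drop = FALSE]
  if (nrow(subjects) == 0)
    stop("no subjects of group '", grp, "' in ", tdm_csv)
  obs <- tdm$obs[!tdm$obs$blq & tdm$obs$id %in% subjects$id, , drop = FALSE]
  unmatched <- setdiff(tdm$obs$id, tdm$subjects$id)
  if (length(unmatched))
    warning("observations for unknown subjects ignored: ",
            paste(unmatched, collapse = ", "))
  reg <- config_regimens(config)[[regimen_index]]
  cohort <- config_cohort(config, seed)
  profs <- simulate_cohort(cohort, reg, engine = config$solver$engine,
                           dt = config$solver$dt,
                           mode = config$solver$mode)

  # population prediction at the subject's dose for the metric pairs
  base <- pbpk_preset(grp)
  pairs <- do.call(rbind, lapply(seq_len(nrow(obs)), function(j) {
    s <- as.list(subjects[subjects$id == obs$id[j], ])
    pred <- predict_subject(base$GFR, "GFR", s, obs$time[j], base,
                            mode = config$solver$mode)
    data.frame(pred = pred, obs = obs$conc[j],
               endpoint = sprintf("C%gh", obs$time[j]),
               dose_given = s$dose_per_kg)
  }))
  report <- fold_error_metrics(pred_obs_set(
    pairs$pred, pairs$obs, endpoint = pairs$endpoint))
  obs_in <- data.frame(time = obs$time, conc = obs$conc,
                       dose_given = subjects$dose_per_kg[
                         match(obs$id, subjects$id)])
  v <- vpc(obs_in, profs, dose_standard = reg$dose_per_kg)
  utils::write.csv(report, file.path(out_dir, "validation_report.csv"),
                   row.names = FALSE)
  write_vpc_csv(v, file.path(out_dir, "vpc_bands.csv"))
  jsonlite::write_json(
    list(coverage_overall = v$coverage_overall,
         coverage = as.list(v$coverage), adequate = v$adequate),
    file.path(out_dir, "vpc_coverage.json"), auto_unbox = TRUE)
  invisible(list(report = report, vpc = v))
}

#' @rdname runners
#' @export
run_estimate <- function(config, tdm_csv, out_dir, seed = NULL) {
  config <- read_run_config(config)
  run_provenance(config, out_dir, seed)
  tdm <- read_tdm(tdm_csv)
  fit <- its_fit(tdm, group = config$population$label)
  jsonlite::write_json(
    list(group = fit$group, parameter = fit$model$parameter,
         population_mean = fit$population_mean,
         omega = fit$model$omega, sigma = fit$model$sigma,
         converged = fit$converged, iterations = fit$iterations,
         n_subjects = fit$n_subjects,
         n_blq_excluded = fit$n_blq_excluded,
         trace = fit$trace, individuals = fit$individuals),
    file.path(out_dir, "estimate.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' @rdname runners
#' @export
run_synth <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  run_provenance(config, out_dir, seed)
  pop <- config$population
  sy <- config$synthetic
  if (is.null(sy)) sy <- list()
  spec <- synthetic_study_spec(
    n_preterm = if (!is.null(sy$n_preterm)) sy$n_preterm else
      if (pop$label == "preterm") pop$n else 0L,
    n_term = if (!is.null(sy$n_term)) sy$n_term else
      if (pop$label == "term") pop$n else 0L,
    dose_policy = if (!is.null(sy$dose_policy)) sy$dose_policy else "fixed",
    residual_cv = if (!is.null(sy$residual_cv)) sy$residual_cv else 0.10,
    n_missing = if (!is.null(sy$n_missing)) sy$n_missing else 3L,
    seed = if (!is.null(seed)) seed else pop$seed)
  ds <- generate_tdm(spec, vd_policy = pop$vd_policy)
  write_tdm(ds$data, file.path(out_dir, "tdm.csv"))
  jsonlite::write_json(ds$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}
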