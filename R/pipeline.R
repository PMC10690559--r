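# Pipeline orchestration: preprocess -> fit -> optional leave-one-out
# prediction, identifiability diagnostics and alpha report, with JSON/CSV
# artifacts, a human-readable summary, and one seed funneled everywhere.

#' Pipeline run configuration
#'
#' @param model model kind (`"three_step"` default).
#' @param cohort_obs,cohort_covariates input cohort paths (see
#'   [read_cohort()]); `NULL` to simulate a synthetic cohort instead.
#' @param out_dir output directory (created if needed).
#' @param fit a [fit_config()].
#' @param synthetic a [cohort_config()] used when no input paths are given.
#' @param run_loo,run_identifiability,run_alpha_report stage toggles.
#' @param seed master seed; overrides the seeds inside `fit` and
#'   `synthetic`.
#' @return list of class `run_config`.
#' @export
run_config <- function(model = "three_step", cohort_obs = NULL,
                       cohort_covariates = NULL, out_dir = tempfile("ctdnakin_"),
                       fit = fit_config(fast = TRUE),
                       synthetic = clinical_defaults(),
                       run_loo = FALSE, run_identifiability = TRUE,
                       run_alpha_report = TRUE, seed = 1) {
  fit$seed <- as.integer(seed)
  synthetic$seed <- as.integer(seed)
  structure(list(model = model, cohort_obs = cohort_obs,
                 cohort_covariates = cohort_covariates, out_dir = out_dir,
                 fit = fit, synthetic = synthetic, run_loo = run_loo,
                 run_identifiability = run_identifiability,
                 run_alpha_report = run_alpha_report,
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(status, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  status[[name]] <- list(ok = res$ok,
                         seconds = round(proc.time()[["elapsed"]] - t0, 2),
                         error = if (res$ok) NULL else res$value)
  list(status = status, value = if (res$ok) res$value else NULL,
       ok = res$ok)
}

#' Run the full analysis pipeline
#'
#' Stages: load-or-simulate cohort, preprocess, population fit, then the
#' requested analyses. Every artifact (JSON/CSV) plus a `summary.txt` and a
#' config echo land in `out_dir`. Stage failures are recorded and dependent
#' stages are skipped with explicit status.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `out_dir`, per-stage `status`, and an
#'   overall `ok` flag (all requested stages succeeded).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  # stage: cohort
  st <- .stage(status, "cohort", {
    if (!is.null(config$cohort_obs)) {
      read_cohort(config$cohort_obs, config$cohort_covariates)
    } else {
      sim <- simulate_cohort(config$synthetic)
      write_truth(sim$truth, file.path(config$out_dir, "truth.json"))
      write_cohort(sim$cohort, file.path(config$out_dir, "cohort_obs.csv"),
                   file.path(config$out_dir, "cohort_covariates.json"))
      sim$cohort
    }
  })
  status <- st$status; coh <- st$value
  if (st$ok) {
    s <- summarize_cohort(coh)
    say("cohort: ", s$n_patients, " patients (",
        paste(names(s$n_per_mutation), s$n_per_mutation, collapse = ", ",
              sep = ":"), "); ctDNA measurements per patient: mean ",
        round(s$ctdna_measurements$mean, 1))
  }

  # stage: preprocess
  prep <- NULL
  if (st$ok) {
    st <- .stage(status, "preprocess", prepare_cohort(coh))
    status <- st$status; prep <- st$value
  } else status$preprocess <- list(ok = FALSE, error = "skipped")

  # stage: fit
  pop <- NULL
  if (!is.null(prep)) {
    st <- .stage(status, "fit", fit_population(prep, config$model, config$fit))
    status <- st$status; pop <- st$value
    if (st$ok) {
      est <- c(as.list(pop$beta), as.list(pop$delta),
               list(sigma_c = pop$sigma_c))
      say("fit: loglik ", format(pop$loglik), "; ", length(est),
          " estimated population parameters")
      jsonlite::write_json(
        list(model = config$model, loglik = pop$loglik,
             beta_transformed = as.list(pop$beta),
             delta = as.list(pop$delta), sigma_c = pop$sigma_c,
             typical_values = as.list(unclass(pop$typical_values)),
             n_estimated = length(est), seed = pop$seed,
             config = list(n_starts = pop$config$n_starts,
                           ctdna_noise_scale = pop$config$ctdna_noise_scale)),
        file.path(config$out_dir, "population_fit.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write.csv(pop$multistart_table,
                file.path(config$out_dir, "waterfall.csv"),
                row.names = FALSE)
    }
  } else status$fit <- list(ok = FALSE, error = "skipped")

  # stage: identifiability
  if (config$run_identifiability && !is.null(pop)) {
    st <- .stage(status, "identifiability", {
      rep_ <- fim_rank_analysis(config$model, pop$typical_values)
      jsonlite::write_json(
        list(model = rep_$model, observed = rep_$observed,
             fim_rank = rep_$fim_rank, n_parameters = rep_$n_parameters,
             verdict = rep_$verdict,
             null_directions = apply(rep_$null_directions, 2, as.list)),
        file.path(config$out_dir, "identifiability.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rep_
    })
    status <- st$status
    if (st$ok) {
      say("identifiability: rank ", st$value$fim_rank, "/",
          st$value$n_parameters, " -> ", st$value$verdict,
          if (st$value$verdict == "rank_deficient")
            " [WARNING: non-identifiable parameter direction]" else "")
    }
  } else if (config$run_identifiability)
    status$identifiability <- list(ok = FALSE, error = "skipped")

  # stage: single-patient estimates + alpha report
  if (config$run_alpha_report && !is.null(pop)) {
    st <- .stage(status, "alpha_report", {
      ests <- lapply(prep, estimate_single_patient, population = pop)
      rel <- vapply(prep, `[[`, TRUE, "relapse")
      rep_ <- alpha_relapse_report(ests, rel)
      write.csv(rep_$alpha_table,
                file.path(config$out_dir, "alpha_table.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(pair_separation = rep_$pair_separation),
        file.path(config$out_dir, "alpha_summary.json"),
        auto_unbox = TRUE, digits = NA)
      rep_
    })
    status <- st$status
    if (st$ok) say("alpha report: pair separation ",
                   format(st$value$pair_separation))
  } else if (config$run_alpha_report)
    status$alpha_report <- list(ok = FALSE, error = "skipped")

  # stage: leave-one-out blast prediction
  if (config$run_loo && !is.null(pop)) {
    st <- .stage(status, "loo", {
      rep_ <- loo_predict_blasts(prep, config$model, config$fit)
      write.csv(rep_$predictions,
                file.path(config$out_dir, "loo_predictions.csv"),
                row.names = FALSE)
      rep_
    })
    status <- st$status
    if (st$ok) {
      okp <- st$value$predictions
      okp <- okp[okp$fold_ok & !is.na(okp$within_10pct), ]
      say("loo: ", sum(okp$within_10pct), "/", nrow(okp),
          " blast measurements within 10%")
    }
  } else if (config$run_loo) status$loo <- list(ok = FALSE, error = "skipped")

  ok <- all(vapply(status, function(s) isTRUE(s$ok), TRUE))
  cfg_echo <- list(model = config$model, seed = config$seed,
                   n_starts = config$fit$n_starts,
                   ctdna_noise_scale = config$fit$ctdna_noise_scale,
                   stages = names(status))
  jsonlite::write_json(cfg_echo, file.path(config$out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste("ctdnakin pipeline, seed", config$seed), log_lines,
               paste0("stage ", names(status), ": ",
                      vapply(status, function(s)
                        if (isTRUE(s$ok)) "ok" else paste("FAILED:", s$error),
                        ""))),
             file.path(config$out_dir, "summary.txt"))
  invisible(list(out_dir = config$out_dir, status = status, ok = ok))
}
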