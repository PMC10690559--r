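# Single-patient conditional estimation against a population prior,
# leave-one-out blast prediction from ctDNA alone, and the alpha-based
# relapse stratification report.

#' Estimate one patient's parameters given a population prior
#'
#' Maximizes the conditional density of the random effects b given only the
#' selected observables, with the `N(0, D)` population prior, and returns
#' the mode, the natural-scale effects, and predicted trajectories for ALL
#' observables (including unobserved ones). Prediction uncertainty is
#' propagated by linearization: `sd_y(t) = sqrt(S H^{-1} S')` with S the
#' observable sensitivities with respect to b at the mode and H the
#' Gauss-Newton curvature.
#'
#' @param prepared_patient a `prepared_patient`.
#' @param population a [fit_population()] result.
#' @param use_observables non-empty subset of `c("y_ctdna", "y_blast")`.
#' @param predict_times time grid for the predicted trajectory (default:
#'   daily over the observation span, plus the observation times).
#' @return object of class `patient_estimate`: `patient_id`, `b_hat`,
#'   `phi_hat` ([effect_vector()]), `alpha_hat`, `predicted_trajectory`,
#'   `uncertainty` (per-time sd of each observable), `curvature`,
#'   `ll_joint`, `converged`.
#' @export
estimate_single_patient <- function(prepared_patient, population,
                                    use_observables = c("y_ctdna", "y_blast"),
                                    predict_times = NULL) {
  stopifnot(inherits(population, "population_estimate"))
  use_observables <- unique(use_observables)
  if (length(use_observables) == 0 ||
      !all(use_observables %in% c("y_ctdna", "y_blast")))
    stop("use_observables must be a non-empty subset of y_ctdna, y_blast")
  structure_ <- population$structure
  model <- structure_$model
  cfg <- population$config
  cm <- conditional_mode(prepared_patient, structure_, population$beta,
                         population$delta, population$sigma_c,
                         cfg$ctdna_noise_scale, use_observables,
                         cfg$gamma_deg)
  phi_hat <- compose_effects(structure_, population$beta, cm$b_hat,
                             cfg$gamma_deg)
  if (is.null(predict_times)) {
    tmax <- max(prepared_patient$obs$time)
    predict_times <- sort(unique(c(seq(0, max(tmax, 1), by = 0.5),
                                   prepared_patient$obs$time)))
  }
  tr <- solve_analytic(model, phi_hat, predict_times)
  # linearized observable uncertainty: dy/db = dy/dtheta * dtheta/db
  sens <- sensitivities_analytic(model, phi_hat, predict_times)
  q <- .q_of(structure_)
  mix <- structure_$random_effect_names
  dtheta_db <- vapply(seq_len(q), function(j) {
    nm <- mix[j]
    v <- phi_hat[[nm]]
    if (structure_$transform[j] == "shifted_log") v - 1 else v
  }, 0)
  Hinv <- solve(cm$curvature)
  unc <- vapply(model$observable_names, function(o) {
    S <- vapply(seq_len(q), function(j)
      sens$d_observable_d_parameter[, o, mix[j]] * dtheta_db[j],
      numeric(length(predict_times)))
    if (length(predict_times) == 1) S <- matrix(S, 1, q)
    sqrt(pmax(rowSums((S %*% Hinv) * S), 0))
  }, numeric(length(predict_times)))
  structure(list(patient_id = prepared_patient$patient_id,
                 b_hat = cm$b_hat, phi_hat = phi_hat,
                 alpha_hat = phi_hat[["alpha"]],
                 predicted_trajectory = tr,
                 uncertainty = unc,
                 curvature = cm$curvature, ll_joint = cm$ll_joint,
                 converged = cm$converged,
                 use_observables = use_observables),
            class = "patient_estimate")
}

#' @export
print.patient_estimate <- function(x, ...) {
  cat("<patient_estimate>", x$patient_id, "(conditioned on",
      paste(x$use_observables, collapse = ", "), ")\n")
  cat("  alpha_hat:", format(x$alpha_hat), "\n")
  cat("  b_hat:", paste(sprintf("%s=%.3f", names(x$b_hat), x$b_hat),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-out prediction of bone-marrow blasts from ctDNA
#'
#' For each patient k: the population is re-fitted on the cohort without k;
#' patient k is then estimated from ctDNA alone with that population as
#' prior; the blast counts at k's marrow measurement times are predicted
#' and compared with the measurements. A prediction is flagged as a hit
#' when it falls within 10% of the measured blast count; zero-valued
#' measurements are evaluated against their substituted noise-sd band
#' (|prediction - 0| <= 2 sd) instead.
#'
#' The held-out patient's blast data enter neither the population fit nor
#' the conditional estimate.
#'
#' @param prepared a `prepared_cohort` with at least 3 patients.
#' @param model a [kinetic_model()] or kind string.
#' @param config a [fit_config()] for the fold fits.
#' @return object of class `loo_report`: data frame `predictions`
#'   (patient_id, time, observed count, predicted count, predicted sd,
#'   rel_error, within_10pct, fold_ok) plus the per-fold population
#'   estimates in `folds`.
#' @export
loo_predict_blasts <- function(prepared, model, config = fit_config()) {
  stopifnot(inherits(prepared, "prepared_cohort"), length(prepared) >= 3)
  model <- .as_model(model)
  rows <- list(); folds <- list()
  for (id in names(prepared)) {
    rest <- prepared[names(prepared) != id]
    class(rest) <- "prepared_cohort"
    pop <- tryCatch(fit_population(rest, model, config),
                    error = function(e) e)
    if (inherits(pop, "error")) {
      folds[[id]] <- pop
      rows[[id]] <- data.frame(patient_id = id, time = NA_real_,
                               observed = NA_real_, predicted = NA_real_,
                               predicted_sd = NA_real_, rel_error = NA_real_,
                               within_10pct = NA, fold_ok = FALSE)
      next
    }
    folds[[id]] <- pop
    pt <- prepared[[id]]
    bl <- pt$obs[pt$obs$type == "blast", , drop = FALSE]
    est <- estimate_single_patient(pt, pop, use_observables = "y_ctdna",
                                   predict_times = sort(unique(bl$time)))
    idx <- match(bl$time, est$predicted_trajectory$times)
    pred <- est$predicted_trajectory$observables[idx, "y_blast"]
    psd <- est$uncertainty[idx, "y_blast"]
    rel <- ifelse(bl$count > 0, abs(pred - bl$count) / bl$count, NA_real_)
    hit <- ifelse(bl$count > 0, rel <= 0.10, abs(pred) <= 2 * bl$sd)
    rows[[id]] <- data.frame(patient_id = id, time = bl$time,
                             observed = bl$count, predicted = pred,
                             predicted_sd = psd, rel_error = rel,
                             within_10pct = hit, fold_ok = TRUE)
  }
  structure(list(predictions = do.call(rbind, c(rows, make.row.names = FALSE)),
                 folds = folds, model = model$kind),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  ok <- x$predictions[x$predictions$fold_ok & !is.na(x$predictions$within_10pct), ]
  cat("<loo_report>", x$model, "-", length(x$folds), "folds\n")
  cat("  within 10%:", sum(ok$within_10pct), "/", nrow(ok),
      "blast measurements\n")
  invisible(x)
}

#' Alpha-based relapse stratification report
#'
#' Descriptive comparison of the estimated mutation fraction alpha between
#' relapsed and non-relapsed patients: per-patient table, group summaries,
#' and the fraction of (relapsed, non-relapsed) pairs with
#' `alpha_relapsed < alpha_non_relapsed` (ties count 1/2). No hypothesis
#' test is performed.
#'
#' @param patient_estimates list of [estimate_single_patient()] results.
#' @param relapse logical vector (or named by patient id).
#' @return object of class `alpha_report`: data frame `alpha_table`
#'   (patient_id, alpha, relapse), `group_summary`, and
#'   `pair_separation` (fraction in `[0, 1]`, `NA` if a class is empty).
#' @export
alpha_relapse_report <- function(patient_estimates, relapse) {
  stopifnot(length(patient_estimates) >= 2)
  ids <- vapply(patient_estimates, `[[`, "", "patient_id")
  if (!is.null(names(relapse))) relapse <- relapse[ids]
  stopifnot(length(relapse) == length(patient_estimates))
  alpha <- vapply(patient_estimates, `[[`, 0, "alpha_hat")
  tab <- data.frame(patient_id = ids, alpha = alpha,
                    relapse = as.logical(relapse), row.names = NULL)
  grp <- do.call(rbind, lapply(split(tab$alpha, tab$relapse), function(a)
    data.frame(n = length(a), geometric_mean = exp(mean(log(a))),
               min = min(a), max = max(a))))
  a_rel <- tab$alpha[tab$relapse]; a_non <- tab$alpha[!tab$relapse]
  sep <- if (length(a_rel) == 0 || length(a_non) == 0) NA_real_ else {
    cmp <- outer(a_rel, a_non, function(r, s) (r < s) + 0.5 * (r == s))
    mean(cmp)
  }
  structure(list(alpha_table = tab, group_summary = grp,
                 pair_separation = sep),
            class = "alpha_report")
}

#' @export
print.alpha_report <- function(x, ...) {
  cat("<alpha_report>\n")
  print(x$alpha_table, row.names = FALSE)
  if (is.na(x$pair_separation))
    cat("  pair separation: not applicable (single class)\n")
  else
    cat(sprintf("  pair separation (alpha_relapsed < alpha_non-relapsed): %.2f\n",
                x$pair_separation))
  invisible(x)
}
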