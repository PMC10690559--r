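# Mixed-effects assembly and population estimation.
#
# Effects phi = A beta + B b on a transformed scale (log links for
# positivity; shifted log for s_c so that s_c >= 1), random effects
# b ~ N(0, D) with D = exp(diag(delta)) diagonal. The marginal likelihood
# is the first-order conditional (Laplace) approximation with Gauss-Newton
# curvature, evaluated in compiled code; an independent plain-R Laplace
# implementation is provided for validation (see laplace-ref.R).

#' Mixed-effect structure of a model
#'
#' One-step: mixed effects `c0pb, alpha`. Two-step: mixed `B0, c0pb, alpha`,
#' fixed `gamma_t`. Three-step: mixed `B0, c0pb, gamma_d, s_c, alpha`,
#' fixed `gamma_t`. Every effect slot receives exactly one fixed-effect
#' contribution; random contributions exist only for the mixed effects.
#'
#' @param model a [kinetic_model()] or kind string.
#' @return object of class `effect_structure` with `model`,
#'   `fixed_effect_names` (all beta entries, in effect order),
#'   `random_effect_names`, `transform` (per-effect link label), and the
#'   design maps as index vectors.
#' @export
build_effect_structure <- function(model) {
  model <- .as_model(model)
  pn <- model$parameter_names
  q <- unname(count_parameters(model)["patient_specific"])
  structure(list(
    model = model,
    fixed_effect_names = pn,
    random_effect_names = pn[seq_len(q)],
    design_map_A = seq_along(pn),
    design_map_B = seq_len(q),
    transform = ifelse(pn == "s_c", "shifted_log", "log")),
    class = "effect_structure")
}

#' @export
print.effect_structure <- function(x, ...) {
  cat("<effect_structure>", x$model$kind, "\n")
  cat("  fixed effects (beta):", paste(x$fixed_effect_names, collapse = ", "),
      "\n")
  cat("  random effects (b):  ",
      paste(x$random_effect_names, collapse = ", "), "\n")
  invisible(x)
}

.q_of <- function(structure) length(structure$random_effect_names)
.p_of <- function(structure) length(structure$fixed_effect_names)

#' Compose natural-scale effects from fixed and random effects
#'
#' `phi = A beta + B b` on the transformed scale, then the inverse link per
#' effect: `exp` for positive effects, `1 + exp` for `s_c`. The fixed
#' degradation constant `gamma_deg` is appended.
#'
#' @param structure an [build_effect_structure()] result.
#' @param beta fixed-effect vector (transformed scale, length = all effects).
#' @param b_k random-effect vector (length = mixed effects); defaults to 0.
#' @param gamma_deg fixed degradation rate.
#' @return an [effect_vector()] on the natural scale.
#' @export
compose_effects <- function(structure, beta, b_k = NULL,
                            gamma_deg = gamma_deg_default()) {
  p <- .p_of(structure); q <- .q_of(structure)
  if (length(beta) != p) stop("beta must have length ", p)
  if (is.null(b_k)) b_k <- numeric(q)
  if (length(b_k) != q) stop("b_k must have length ", q)
  phi <- beta
  phi[structure$design_map_B] <- phi[structure$design_map_B] + b_k
  nat <- ifelse(structure$transform == "shifted_log", 1 + exp(phi), exp(phi))
  full <- list(B0 = 1, c0pb = 1, gamma_d = 1, s_c = 1, alpha = 1, gamma_t = 1)
  full[structure$fixed_effect_names] <- as.list(nat)
  full$alpha <- min(full$alpha, 1)  # guard: alpha is a fraction
  do.call(effect_vector, c(full, list(gamma_deg = gamma_deg)))
}

#' Extract random effects back from a natural-scale effect vector
#'
#' Inverse of [compose_effects()] for the mixed slots (log-difference on the
#' transformed scale); used in round-trip tests.
#'
#' @inheritParams compose_effects
#' @param effects an [effect_vector()].
#' @return random-effect vector b.
#' @export
extract_random_effects <- function(structure, beta, effects) {
  q <- .q_of(structure)
  nm <- structure$random_effect_names
  phi <- vapply(seq_len(q), function(j) {
    v <- effects[[nm[j]]]
    if (structure$transform[j] == "shifted_log") log(v - 1) else log(v)
  }, 0)
  phi - beta[seq_len(q)]
}

# flatten a prepared_patient into the plain-vector form the C++ side expects
.pdata <- function(prepared_patient, use_observables = c("y_ctdna", "y_blast")) {
  obs <- prepared_patient$obs
  keep <- (obs$type == "ctdna" & "y_ctdna" %in% use_observables) |
          (obs$type == "blast" & "y_blast" %in% use_observables)
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations left for patient ",
                           prepared_patient$patient_id)
  if (any(obs$type == "blast" & !is.finite(obs$sd)))
    stop("blast observations need attached noise sds (see attach_noise)")
  list(time = as.numeric(obs$time),
       type = as.integer(obs$type == "blast"),
       value = as.numeric(obs$count),
       sd = ifelse(is.finite(obs$sd), as.numeric(obs$sd), 0))
}

.scale_code <- function(ctdna_noise_scale) {
  match.arg(ctdna_noise_scale, c("log10", "linear"))
  if (ctdna_noise_scale == "log10") 0L else 1L
}

#' Patient observation log-likelihood at fixed effects
#'
#' Sum of independent Gaussian log-densities: blast counts against
#' `y_blast` with their attached sds; ctDNA counts against `y_ctdna` with
#' sd `sigma_c` on the configured noise scale (`log10` of counts by
#' default, or linear counts).
#'
#' @param prepared_patient a `prepared_patient`.
#' @param effects an [effect_vector()].
#' @param sigma_c ctDNA noise sd on the configured scale.
#' @param model a [kinetic_model()] or kind string (default three-step).
#' @param ctdna_noise_scale `"log10"` (default) or `"linear"`.
#' @return scalar log-likelihood (`-Inf` if the model output is not finite).
#' @export
patient_loglik <- function(prepared_patient, effects, sigma_c,
                           model = "three_step",
                           ctdna_noise_scale = "log10") {
  d <- .pdata(prepared_patient)
  model <- .as_model(model)
  if (model$kind == "one_step" && any(d$type == 1L))
    stop("one-step model has no blast observable")
  tr <- solve_analytic(model, effects, unique(sort(d$time)))
  yfun <- function(tt, o) tr$observables[match(tt, tr$times), o]
  ll <- 0
  for (i in seq_along(d$time)) {
    if (d$type[i] == 0L) {
      ym <- yfun(d$time[i], "y_ctdna")
      if (!is.finite(ym) || ym <= 0) return(-Inf)
      if (ctdna_noise_scale == "log10")
        ll <- ll + dnorm(log10(d$value[i]), log10(ym), sigma_c, log = TRUE)
      else
        ll <- ll + dnorm(d$value[i], ym, sigma_c, log = TRUE)
    } else {
      ym <- yfun(d$time[i], "y_blast")
      if (!is.finite(ym)) return(-Inf)
      ll <- ll + dnorm(d$value[i], ym, d$sd[i], log = TRUE)
    }
  }
  ll
}

#' Conditional mode of a patient's random effects
#'
#' Maximizes `patient_loglik(phi(beta, b)) + log N(b; 0, D)` over b with
#' `D = exp(diag(delta))`, by damped Gauss-Newton in compiled code, and
#' returns the mode together with the Gauss-Newton curvature
#' (`J'WJ + D^{-1}`) used by the Laplace approximation.
#'
#' @param prepared_patient a `prepared_patient` (noise attached).
#' @param structure an [build_effect_structure()] result.
#' @param beta fixed effects (transformed scale).
#' @param delta random-effect log-variances.
#' @param sigma_c ctDNA noise sd.
#' @param ctdna_noise_scale `"log10"` or `"linear"`.
#' @param use_observables observables to condition on.
#' @param gamma_deg fixed degradation rate.
#' @param b_init optional starting point.
#' @return list with `b_hat`, `curvature`, `ll_joint` (joint log density at
#'   the mode), `ll_laplace` (this patient's Laplace marginal contribution),
#'   `converged`, `iterations`.
#' @export
conditional_mode <- function(prepared_patient, structure, beta, delta,
                             sigma_c, ctdna_noise_scale = "log10",
                             use_observables = NULL,
                             gamma_deg = gamma_deg_default(), b_init = NULL) {
  if (is.null(use_observables))
    use_observables <- structure$model$observable_names
  kind <- .kind_code(structure$model$kind)
  q <- .q_of(structure)
  stopifnot(length(beta) == .p_of(structure), length(delta) == q)
  res <- cpp_conditional_mode(kind, gamma_deg, beta, delta, sigma_c,
                              .scale_code(ctdna_noise_scale),
                              .pdata(prepared_patient, use_observables),
                              .RATE_MERGE_TOL, b_init)
  if (!res$converged)
    warning("inner optimization did not fully converge for patient ",
            prepared_patient$patient_id, " (grad ",
            format(res$grad_norm), "); returning best point found")
  names(res$b_hat) <- structure$random_effect_names
  dimnames(res$curvature) <- list(structure$random_effect_names,
                                  structure$random_effect_names)
  res
}

#' First-order conditional (Laplace) marginal log-likelihood
#'
#' Sum over patients of the Laplace approximation to the marginal density
#' of the observations: joint log density at the conditional mode plus
#' `(q/2) log(2 pi) - 0.5 log det H`, with Gauss-Newton curvature H.
#'
#' @param prepared a `prepared_cohort`.
#' @inheritParams conditional_mode
#' @return scalar marginal log-likelihood.
#' @export
marginal_loglik_foce <- function(prepared, structure, beta, delta, sigma_c,
                                 ctdna_noise_scale = "log10",
                                 gamma_deg = gamma_deg_default()) {
  kind <- .kind_code(structure$model$kind)
  stopifnot(length(beta) == .p_of(structure),
            length(delta) == .q_of(structure))
  pats <- lapply(prepared, .pdata,
                 use_observables = structure$model$observable_names)
  out <- cpp_cohort_laplace(kind, gamma_deg, beta, delta, sigma_c,
                            .scale_code(ctdna_noise_scale), unname(pats),
                            .RATE_MERGE_TOL, FALSE)
  out$loglik
}

# ---------------------------------------------------------------------------
# population fit: multi-start bounded quasi-Newton maximization
# ---------------------------------------------------------------------------

#' Default transformed-scale optimization bounds
#'
#' Box bounds spanning several decades around physiologic magnitudes:
#' B0 1e10-1.2e12 cells, c0pb 1e3-1e9 copies, rates 1e-2-1e2 per day,
#' alpha 1e-6-1, s_c - 1 in 1e-3-1e2; random-effect log-variances delta in
#' [-8, 2]; log sigma_c in [log 0.005, log 2] (log10-scale noise) or
#' [log 1e2, log 1e8] (linear scale).
#'
#' @param model a [kinetic_model()] or kind string.
#' @param ctdna_noise_scale `"log10"` or `"linear"`.
#' @return list with matrices `beta` (2 x p), `delta` (2 x q) and vector
#'   `log_sigma_c` (lower/upper).
#' @export
default_bounds <- function(model, ctdna_noise_scale = "log10") {
  model <- .as_model(model)
  rng <- list(B0 = log(c(1e10, 1.2e12)), c0pb = log(c(1e3, 1e9)),
              gamma_d = log(c(1e-2, 1e2)), s_c = log(c(1e-3, 1e2)),
              alpha = log(c(1e-6, 1)), gamma_t = log(c(1e-2, 1e2)))
  beta <- vapply(model$parameter_names, function(nm) rng[[nm]], numeric(2))
  q <- unname(count_parameters(model)["patient_specific"])
  delta <- matrix(rep(c(-8, 2), q), 2, q,
                  dimnames = list(NULL, model$parameter_names[seq_len(q)]))
  lsc <- if (ctdna_noise_scale == "log10") log(c(0.005, 2)) else log(c(1e2, 1e8))
  list(beta = beta, delta = delta, log_sigma_c = lsc)
}

#' Population-fit configuration
#'
#' @param n_starts number of multi-start points (300 by default, matching
#'   the full analysis; use `fast = TRUE` for the 30-start test profile).
#' @param fast logical; shortcut setting `n_starts = 30`.
#' @param bounds as from [default_bounds()]; `NULL` for defaults.
#' @param seed integer seed for the start-point draw.
#' @param ctdna_noise_scale `"log10"` (default) or `"linear"`.
#' @param gamma_deg fixed degradation rate (1/day).
#' @param maxit iteration cap per local optimization.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 300, fast = FALSE, bounds = NULL, seed = 1,
                       ctdna_noise_scale = "log10",
                       gamma_deg = gamma_deg_default(), maxit = 300) {
  if (isTRUE(fast)) n_starts <- 30
  structure(list(n_starts = as.integer(n_starts), bounds = bounds,
                 seed = as.integer(seed),
                 ctdna_noise_scale = match.arg(ctdna_noise_scale,
                                               c("log10", "linear")),
                 gamma_deg = gamma_deg, maxit = as.integer(maxit)),
            class = "fit_config")
}

# Latin hypercube sample of n points within [lower, upper]^d
.latin_hypercube <- function(n, lower, upper) {
  d <- length(lower)
  u <- vapply(seq_len(d), function(j) (sample(n) - runif(n)) / n, numeric(n))
  if (n == 1) u <- matrix(u, 1, d)
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

# heuristic data-driven start (start #1): centers the fixed effects on crude
# moment estimates from the observed series; no access to any truth
.data_driven_start <- function(prepared, structure, bounds) {
  pn <- structure$fixed_effect_names
  first_ct <- vapply(prepared, function(p) {
    ct <- p$obs[p$obs$type == "ctdna", ]
    ct$count[which.min(ct$time)]
  }, 0)
  first_bl <- vapply(prepared, function(p) {
    bl <- p$obs[p$obs$type == "blast", ]
    if (nrow(bl)) bl$count[which.min(bl$time)] else NA_real_
  }, 0)
  gd_guess <- {
    slopes <- vapply(prepared, function(p) {
      ct <- p$obs[p$obs$type == "ctdna", ]
      if (nrow(ct) < 2) return(NA_real_)
      ct <- ct[order(ct$time), ]
      f <- ct[1, ]; l <- ct[nrow(ct), ]
      if (l$time <= f$time || f$count <= 0 || l$count <= 0) return(NA_real_)
      (log(f$count) - log(l$count)) / (l$time - f$time)
    }, 0)
    m <- median(slopes[is.finite(slopes) & slopes > 0])
    if (!is.finite(m)) 0.5 else m
  }
  alpha0 <- 0.1
  guess <- c(B0 = log(max(mean(first_bl, na.rm = TRUE), 1e10, na.rm = TRUE)),
             c0pb = log(max(mean(first_ct) / alpha0, 1e3)),
             gamma_d = log(gd_guess), s_c = log(1), alpha = log(alpha0),
             gamma_t = log(3))
  beta0 <- pmin(pmax(guess[pn], bounds$beta[1, ]), bounds$beta[2, ])
  q <- .q_of(structure)
  sc0 <- log(0.15)
  if (sc0 < bounds$log_sigma_c[1] || sc0 > bounds$log_sigma_c[2])
    sc0 <- mean(bounds$log_sigma_c)
  c(beta0, rep(log(0.25^2), q), sc0)
}

#' Fit the population mixed-effects model
#'
#' Maximizes the first-order conditional (Laplace) marginal likelihood over
#' `(beta, delta, log sigma_c)` by multi-start bounded quasi-Newton
#' (`optim(method = "L-BFGS-B")`) from Latin-hypercube start points (plus
#' one data-driven start), deterministic given the seed.
#'
#' @param prepared a `prepared_cohort` (>= 2 patients).
#' @param model a [kinetic_model()] or kind string.
#' @param config a [fit_config()].
#' @return object of class `population_estimate`: `beta` (transformed
#'   scale, named), `delta` (named log-variances), `sigma_c`, `loglik`,
#'   `typical_values` (natural scale via the inverse links),
#'   `multistart_table` (waterfall, sorted by final objective, best first),
#'   `structure`, `config`, `seed`.
#' @export
fit_population <- function(prepared, model, config = fit_config()) {
  stopifnot(inherits(prepared, "prepared_cohort"))
  if (length(prepared) < 2)
    stop("need at least 2 patients to estimate random-effect variances")
  model <- .as_model(model)
  structure_ <- build_effect_structure(model)
  bounds <- config$bounds
  if (is.null(bounds)) bounds <- default_bounds(model, config$ctdna_noise_scale)
  p <- .p_of(structure_); q <- .q_of(structure_)
  lower <- c(bounds$beta[1, ], bounds$delta[1, ], bounds$log_sigma_c[1])
  upper <- c(bounds$beta[2, ], bounds$delta[2, ], bounds$log_sigma_c[2])
  npar <- p + q + 1
  kind <- .kind_code(model$kind)
  scode <- .scale_code(config$ctdna_noise_scale)
  pats <- unname(lapply(prepared, .pdata,
                        use_observables = model$observable_names))

  # warm-start cache of the conditional modes: successive objective calls
  # (line searches, finite-difference gradient bumps) move b_hat very
  # little, so the inner Gauss-Newton converges in 1-3 iterations
  bcache <- NULL
  negll <- function(par) {
    out <- cpp_cohort_laplace(kind, config$gamma_deg, par[seq_len(p)],
                              par[p + seq_len(q)], exp(par[npar]), scode,
                              pats, .RATE_MERGE_TOL, FALSE, bcache)
    v <- -out$loglik
    if (!is.finite(v)) return(1e12)
    bcache <<- out$b_hat
    v
  }
  grad <- function(par) {
    f0 <- negll(par)
    h <- 1e-6 * pmax(abs(par), 1)
    vapply(seq_len(npar), function(j) {
      pj <- par; pj[j] <- par[j] + h[j]
      (negll(pj) - f0) / h[j]
    }, 0)
  }

  set.seed(config$seed)
  # start-point draw is part of the seeded state; LHS within a slightly
  # shrunken box to keep starts off the bounds
  shrink <- 0.05 * (upper - lower)
  starts <- .latin_hypercube(config$n_starts, lower + shrink, upper - shrink)
  starts[1, ] <- pmin(pmax(.data_driven_start(prepared, structure_, bounds),
                           lower + shrink), upper - shrink)

  runs <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    bcache <- NULL  # fresh inner starts (b = 0) for each outer start
    fit <- tryCatch(
      optim(starts[s, ], negll, gr = grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = config$maxit, factr = 1e8)),
      error = function(e) NULL)
    runs[[s]] <- if (is.null(fit)) {
      list(par = starts[s, ], value = Inf, converged = FALSE)
    } else {
      list(par = fit$par, value = fit$value,
           converged = fit$convergence %in% c(0L, 1L))
    }
  }
  vals <- vapply(runs, `[[`, 0, "value")
  conv <- vapply(runs, `[[`, TRUE, "converged")
  if (!any(is.finite(vals) & conv))
    stop(structure(
      list(message = "no multi-start run converged", call = sys.call(),
           multistart_table = data.frame(start = seq_len(config$n_starts),
                                         objective = -vals,
                                         converged = conv)),
      class = c("estimation_failure", "error", "condition")))
  best <- which.min(ifelse(conv, vals, Inf))
  par_hat <- runs[[best]]$par
  beta <- setNames(par_hat[seq_len(p)], structure_$fixed_effect_names)
  delta <- setNames(par_hat[p + seq_len(q)], structure_$random_effect_names)
  sigma_c <- exp(par_hat[npar])
  ms <- data.frame(start = seq_len(config$n_starts),
                   objective = -vals, converged = conv)[order(vals), ]
  rownames(ms) <- NULL
  typical <- compose_effects(structure_, beta, gamma_deg = config$gamma_deg)
  structure(list(beta = beta, delta = delta, sigma_c = sigma_c,
                 loglik = -vals[best], typical_values = typical,
                 multistart_table = ms, structure = structure_,
                 config = config, seed = config$seed),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("<population_estimate>", x$structure$model$kind, "\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  typical values (natural scale):\n")
  tv <- unclass(x$typical_values)[x$structure$fixed_effect_names]
  for (nm in names(tv)) cat(sprintf("    %-8s %.4g\n", nm, tv[[nm]]))
  cat("  random-effect sds (transformed scale):\n")
  for (nm in names(x$delta))
    cat(sprintf("    %-8s %.3f\n", nm, exp(x$delta[[nm]] / 2)))
  cat("  sigma_c:", format(x$sigma_c), " (",
      x$config$ctdna_noise_scale, " scale)\n", sep = "")
  n_ok <- sum(x$multistart_table$converged)
  cat("  multistart: ", n_ok, "/", nrow(x$multistart_table),
      " converged; top objectives ",
      paste(format(head_(x$multistart_table$objective, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

head_ <- function(x, n) x[seq_len(min(n, length(x)))]
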