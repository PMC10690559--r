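# Plain-R reference implementation of the conditional-mode / Laplace
# machinery for arbitrary residual models. Deliberately independent of the
# compiled path: generic optimizer (nlminb on the penalized objective),
# Gauss-Newton curvature from a user-supplied Jacobian. Used by the test
# suite to validate the compiled cohort objective and to evaluate
# linear-Gaussian and 1-D nonlinear toys with known answers.

#' Conditional mode for a generic residual model (reference implementation)
#'
#' Maximizes `sum log N(r_i; 0, 1) + log N(b; 0, D)` where
#' `r = resid_fn(b)` are standardized residuals and `D = exp(diag(delta))`.
#'
#' @param resid_fn function(b) returning standardized residuals.
#' @param jac_fn function(b) returning the residual Jacobian `dr/db`
#'   (n x q); used for the Gauss-Newton curvature.
#' @param delta random-effect log-variances (length q).
#' @param log_norm_const sum of the per-observation normalization terms
#'   (`-log sd - 0.5 log 2pi`); only shifts the returned log densities.
#' @param b_init starting point (default 0).
#' @return list with `b_hat`, `curvature` (`J'J + D^{-1}`), `ll_joint`,
#'   `ll_laplace`, `converged`.
#' @export
laplace_conditional_mode_ref <- function(resid_fn, jac_fn, delta,
                                         log_norm_const = 0,
                                         b_init = NULL) {
  q <- length(delta)
  dinv <- exp(-delta)
  if (is.null(b_init)) b_init <- numeric(q)
  obj <- function(b) {
    r <- resid_fn(b)
    if (any(!is.finite(r))) return(1e12)
    0.5 * sum(r^2) + 0.5 * sum(b^2 * dinv)
  }
  fit <- stats::nlminb(b_init, obj,
                       control = list(abs.tol = 0, rel.tol = 1e-14,
                                      x.tol = 1e-14, iter.max = 500))
  b_hat <- fit$par
  J <- jac_fn(b_hat)
  H <- crossprod(J) + diag(dinv, q)
  n <- length(resid_fn(b_hat))
  ll_joint <- -obj(b_hat) + log_norm_const -
    0.5 * sum(delta) - 0.5 * q * log(2 * pi)
  ld <- determinant(H, logarithm = TRUE)$modulus
  list(b_hat = b_hat, curvature = H, ll_joint = ll_joint,
       ll_laplace = ll_joint + 0.5 * q * log(2 * pi) - 0.5 * as.numeric(ld),
       converged = fit$convergence == 0)
}

#' Laplace marginal log-likelihood for a generic residual model (reference)
#'
#' @inheritParams laplace_conditional_mode_ref
#' @return scalar Laplace marginal log-likelihood.
#' @export
laplace_marginal_ref <- function(resid_fn, jac_fn, delta,
                                 log_norm_const = 0) {
  laplace_conditional_mode_ref(resid_fn, jac_fn, delta,
                               log_norm_const)$ll_laplace
}

# residual closure for a prepared kinetic-model patient; mirrors the
# compiled likelihood definition but through the exported R-level pieces
.kinetic_resid_closure <- function(prepared_patient, structure, beta,
                                   sigma_c, ctdna_noise_scale = "log10",
                                   gamma_deg = gamma_deg_default(),
                                   use_observables = c("y_ctdna", "y_blast")) {
  d <- .pdata(prepared_patient, use_observables)
  model <- structure$model
  q <- .q_of(structure)
  resid_fn <- function(b) {
    eff <- compose_effects(structure, beta, b, gamma_deg)
    tr <- solve_analytic(model, eff, sort(unique(d$time)))
    idx <- match(d$time, tr$times)
    r <- numeric(length(d$time))
    for (i in seq_along(r)) {
      if (d$type[i] == 0L) {
        ym <- tr$observables[idx[i], "y_ctdna"]
        r[i] <- if (ctdna_noise_scale == "log10")
          (log10(d$value[i]) - log10(ym)) / sigma_c
        else (d$value[i] - ym) / sigma_c
      } else {
        r[i] <- (d$value[i] - tr$observables[idx[i], "y_blast"]) / d$sd[i]
      }
    }
    r
  }
  jac_fn <- function(b) {
    h <- 1e-6
    r0 <- resid_fn(b)
    vapply(seq_len(q), function(j) {
      bp <- b; bp[j] <- b[j] + h
      bm <- b; bm[j] <- b[j] - h
      (resid_fn(bp) - resid_fn(bm)) / (2 * h)
    }, numeric(length(r0)))
  }
  norm_const <- sum(ifelse(d$type == 0L,
                           -log(sigma_c) - 0.5 * log(2 * pi),
                           -log(d$sd) - 0.5 * log(2 * pi)))
  list(resid_fn = resid_fn, jac_fn = jac_fn, log_norm_const = norm_const)
}

#' Reference cohort marginal likelihood (plain R)
#'
#' Same quantity as [marginal_loglik_foce()], computed through the generic
#' plain-R Laplace path; used for cross-validation of the compiled
#' implementation on small cohorts.
#'
#' @inheritParams marginal_loglik_foce
#' @return scalar marginal log-likelihood.
#' @export
marginal_loglik_foce_ref <- function(prepared, structure, beta, delta,
                                     sigma_c, ctdna_noise_scale = "log10",
                                     gamma_deg = gamma_deg_default()) {
  sum(vapply(prepared, function(p) {
    cl <- .kinetic_resid_closure(p, structure, beta, sigma_c,
                                 ctdna_noise_scale, gamma_deg)
    laplace_marginal_ref(cl$resid_fn, cl$jac_fn, delta, cl$log_norm_const)
  }, 0))
}
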