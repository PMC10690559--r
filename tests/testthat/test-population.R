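# mixed-effects assembly, likelihood pieces, conditional modes, Laplace
# approximation, and the population fit

test_that("effect structures match the published parameter partition", {
  s1 <- build_effect_structure("one_step")
  expect_equal(s1$random_effect_names, c("c0pb", "alpha"))
  expect_equal(length(s1$fixed_effect_names) + length(s1$random_effect_names)
               + 1, 5)  # 2 beta + 2 delta + sigma_c
  s2 <- build_effect_structure("two_step")
  expect_equal(length(s2$random_effect_names), 3)
  expect_true("gamma_t" %in% s2$fixed_effect_names)
  s3 <- build_effect_structure("three_step")
  expect_equal(s3$random_effect_names,
               c("B0", "c0pb", "gamma_d", "s_c", "alpha"))
  # estimated-parameter counts: beta + delta + sigma_c
  for (kind in c("one_step", "two_step", "three_step")) {
    s <- build_effect_structure(kind)
    expect_equal(length(s$fixed_effect_names) +
                   length(s$random_effect_names) + 1L,
                 unname(count_parameters(kind)["population"]))
  }
})

test_that("compose_effects applies links and round-trips", {
  st <- build_effect_structure("three_step")
  beta <- c(log(9e11), log(1e6), log(0.5), log(1), log(0.2), log(3))
  eff <- compose_effects(st, beta)
  expect_equal(eff[["B0"]], 9e11)
  expect_equal(eff[["s_c"]], 2)  # 1 + exp(0)
  expect_equal(eff[["alpha"]], 0.2)
  set.seed(4)
  for (i in 1:10) {
    b <- rnorm(5, 0, 0.6)
    eff <- compose_effects(st, beta, b)
    expect_true(all(unclass(eff) > 0) && eff[["s_c"]] >= 1)
    expect_equal(unname(extract_random_effects(st, beta, eff)), b,
                 tolerance = 1e-12)
  }
  expect_error(compose_effects(st, beta[-1]), "length")
})

test_that("patient_loglik is a plain Gaussian density sum", {
  eff <- effect_vector(B0 = 9e11, c0pb = 1e6, gamma_d = 0.5, s_c = 2,
                       alpha = 0.2, gamma_t = 3)
  pat <- simulate_prepared(eff, ct_time = c(0, 1, 5), bl_time = numeric())
  # zero residuals: ll = -(m/2) log(2 pi sigma^2)
  expect_equal(patient_loglik(pat, eff, 0.2),
               -(3 / 2) * log(2 * pi * 0.2^2))
  # independently coded density sum on a 3-point toy with residuals
  noisy <- pat
  noisy$obs$count <- noisy$obs$count * c(1.3, 0.8, 1.1)
  tr <- solve_analytic("three_step", eff, noisy$obs$time)
  by_hand <- sum(dnorm(log10(noisy$obs$count),
                       log10(tr$observables[, "y_ctdna"]), 0.2, log = TRUE))
  expect_equal(patient_loglik(noisy, eff, 0.2), by_hand)
  # doubling a residual strictly decreases the log-likelihood
  worse <- pat
  worse$obs$count[2] <- worse$obs$count[2] * 10^(2 * 0.2)
  better <- pat
  better$obs$count[2] <- better$obs$count[2] * 10^0.2
  expect_lt(patient_loglik(worse, eff, 0.2),
            patient_loglik(better, eff, 0.2))
  # linear noise scale option
  expect_equal(patient_loglik(pat, eff, 1e4, ctdna_noise_scale = "linear"),
               -(3 / 2) * log(2 * pi * 1e8))
})

test_that("conditional mode solves the linear-Gaussian toy exactly", {
  # y = beta + b, one observation: b_hat = w^2/(w^2 + s^2) (y - beta)
  y <- 1.7; beta <- 0.4; s <- 0.3; w <- 0.8
  res <- laplace_conditional_mode_ref(
    resid_fn = function(b) (y - beta - b) / s,
    jac_fn = function(b) matrix(-1 / s, 1, 1),
    delta = log(w^2),
    log_norm_const = -log(s) - 0.5 * log(2 * pi))
  expect_equal(res$b_hat, w^2 / (w^2 + s^2) * (y - beta), tolerance = 1e-6)
  # vanishing prior variance: b_hat -> 0
  res0 <- laplace_conditional_mode_ref(
    function(b) (y - beta - b) / s, function(b) matrix(-1 / s, 1, 1),
    delta = log(1e-10))
  expect_lt(abs(res0$b_hat), 1e-8)
  # vanishing noise: b_hat -> y - beta
  res1 <- laplace_conditional_mode_ref(
    function(b) (y - beta - b) / 1e-6, function(b) matrix(-1e6, 1, 1),
    delta = log(w^2))
  expect_equal(res1$b_hat, y - beta, tolerance = 1e-4)
})

test_that("Laplace marginal is exact for linear-Gaussian models", {
  # m observations of y = beta + b + eps: marginal is N(y; beta,
  # sigma^2 I + omega^2 11')
  set.seed(11)
  for (i in 1:5) {
    m <- sample(1:4, 1)
    beta <- rnorm(1); w <- runif(1, 0.2, 1.5); s <- runif(1, 0.1, 0.8)
    y <- rnorm(m, beta, sqrt(s^2 + w^2))
    ll <- laplace_marginal_ref(
      resid_fn = function(b) (y - beta - b) / s,
      jac_fn = function(b) matrix(-1 / s, m, 1),
      delta = log(w^2),
      log_norm_const = m * (-log(s) - 0.5 * log(2 * pi)))
    Sigma <- diag(s^2, m) + w^2
    ll_exact <- -0.5 * (m * log(2 * pi) +
                          determinant(Sigma)$modulus +
                          mahalanobis(y, rep(beta, m), Sigma))
    expect_equal(ll, as.numeric(ll_exact), tolerance = 1e-7)
  }
})

test_that("Laplace marginal is within 1% of quadrature on nonlinear toys", {
  # y_i = exp(beta + b) + eps in the informative-data regime the cohort
  # model occupies (few-percent noise, several observations); quadrature
  # is centered on the conditional mode and normalized to avoid underflow
  set.seed(21)
  for (i in 1:20) {
    m <- sample(3:6, 1)
    beta <- runif(1, -0.3, 0.3); w <- runif(1, 0.2, 0.5)
    s <- runif(1, 0.02, 0.05)
    y <- exp(beta + rnorm(1, 0, w)) + rnorm(m, 0, s)
    res <- laplace_conditional_mode_ref(
      resid_fn = function(b) (y - exp(beta + b)) / s,
      jac_fn = function(b) matrix(-exp(beta + b) / s, m, 1),
      delta = log(w^2),
      log_norm_const = m * (-log(s) - 0.5 * log(2 * pi)))
    lpost <- function(b) sum(dnorm(y, exp(beta + b), s, log = TRUE)) +
      dnorm(b, 0, w, log = TRUE)
    l0 <- lpost(res$b_hat)
    sd0 <- 1 / sqrt(res$curvature[1, 1])
    marg <- integrate(function(bv) vapply(bv, function(b)
      exp(lpost(b) - l0), 0),
      res$b_hat - 12 * sd0, res$b_hat + 12 * sd0, rel.tol = 1e-12)$value
    # marginal within 1%: |log difference| <= log(1.01)
    expect_lt(abs(res$ll_laplace - (log(marg) + l0)), log(1.01))
  }
})

test_that("compiled cohort objective matches the plain-R reference", {
  sim <- simulate_cohort(default_truth_config(seed = 5, n = 3))
  prep <- prepare_cohort(sim$cohort)
  st <- build_effect_structure("three_step")
  beta <- sim$truth$beta
  delta <- log(c(0.2, 0.7, 0.3, 0.5, 0.5)^2)
  for (sig in c(0.1, 0.3)) {
    ll_cpp <- marginal_loglik_foce(prep, st, beta, delta, sig)
    ll_ref <- marginal_loglik_foce_ref(prep, st, beta, delta, sig)
    expect_equal(ll_cpp, ll_ref, tolerance = 1e-6)
  }
  # additivity over independent patients
  ll_all <- marginal_loglik_foce(prep, st, beta, delta, 0.1)
  ll_sum <- sum(vapply(names(prep), function(id) {
    one <- prep[id]; class(one) <- "prepared_cohort"
    marginal_loglik_foce(one, st, beta, delta, 0.1)
  }, 0))
  expect_equal(ll_all, ll_sum, tolerance = 1e-10)
})

test_that("compiled conditional mode agrees with the reference on patients", {
  sim <- simulate_cohort(default_truth_config(seed = 6, n = 2))
  prep <- prepare_cohort(sim$cohort)
  st <- build_effect_structure("three_step")
  beta <- sim$truth$beta
  delta <- log(c(0.2, 0.7, 0.3, 0.5, 0.5)^2)
  cm <- conditional_mode(prep[[1]], st, beta, delta, 0.1)
  cl <- ctdnakin:::.kinetic_resid_closure(prep[[1]], st, beta, 0.1)
  ref <- laplace_conditional_mode_ref(cl$resid_fn, cl$jac_fn, delta,
                                      cl$log_norm_const)
  expect_equal(unname(cm$b_hat), ref$b_hat, tolerance = 1e-5)
  expect_equal(cm$ll_joint, ref$ll_joint, tolerance = 1e-6)
  expect_true(cm$converged)
})

test_that("fit_population is deterministic and its waterfall is sorted", {
  sim <- simulate_cohort(default_truth_config(seed = 8, n = 6))
  prep <- prepare_cohort(sim$cohort)
  cfg <- fit_config(n_starts = 3, seed = 42)
  f1 <- fit_population(prep, "three_step", cfg)
  f2 <- fit_population(prep, "three_step", cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$multistart_table, f2$multistart_table)
  expect_true(all(diff(f1$multistart_table$objective) <= 0))
  # estimated parameter vector length equals the published population count
  expect_equal(length(f1$beta) + length(f1$delta) + 1L,
               unname(count_parameters("three_step")["population"]))
  expect_error(fit_population(prep[1], "three_step", cfg))
})

test_that("recovery error shrinks from n = 20 to n = 50", {
  # 10 replicate cohort pairs, scaled-down start count to stay within the
  # test-time budget (the acceptance suite runs the full fast profile)
  errs <- vapply(1:10, function(r) {
    out <- numeric(2)
    for (i in 1:2) {
      n <- c(20, 50)[i]
      cfg <- default_truth_config(seed = 3000 + r, n = n,
                                  relapse_factor = 1)
      sim <- simulate_cohort(cfg)
      prep <- prepare_cohort(sim$cohort)
      fit <- fit_population(prep, "three_step",
                            fit_config(n_starts = 2, seed = r))
      tv <- unlist(cfg$typical_values)
      est <- unlist(unclass(fit$typical_values)[names(cfg$typical_values)])
      out[i] <- median(abs(est / tv - 1))
    }
    out
  }, numeric(2))
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})
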