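# shared fixtures: random valid parameter draws, hand-built prepared
# patients, and population estimates assembled without fitting

draw_effects <- function(kind = "three_step") {
  p <- list(B0 = 10^runif(1, 10, 12.05), c0pb = 10^runif(1, 3, 9),
            gamma_d = 10^runif(1, -2, 2), s_c = 1 + 10^runif(1, -3, 2),
            alpha = 10^runif(1, -6, -0.01), gamma_t = 10^runif(1, -2, 2),
            gamma_deg = gamma_deg_default())
  do.call(effect_vector, p)
}

# prepared_patient built directly from count-scale observations
make_prepared <- function(id = "P1", ct_time = numeric(), ct_count = numeric(),
                          bl_time = numeric(), bl_count = numeric(),
                          bl_sd = 0.1 * bl_count, relapse = FALSE,
                          blood_volume = 4.5, mutation = "NPM1") {
  obs <- rbind(
    if (length(ct_time))
      data.frame(time = ct_time, type = "ctdna", count = ct_count,
                 sd = NA_real_),
    if (length(bl_time))
      data.frame(time = bl_time, type = "blast", count = bl_count,
                 sd = bl_sd))
  obs <- obs[order(obs$time, obs$type), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(patient_id = id, mutation = mutation, relapse = relapse,
                 blood_volume = blood_volume, obs = obs),
            class = "prepared_patient")
}

as_prepared_cohort <- function(...) {
  pats <- list(...)
  names(pats) <- vapply(pats, `[[`, "", "patient_id")
  structure(pats, class = "prepared_cohort")
}

# population estimate assembled from known parameters (no fitting)
make_population <- function(model = "three_step", beta, delta, sigma_c,
                            ctdna_noise_scale = "log10",
                            gamma_deg = gamma_deg_default()) {
  st <- build_effect_structure(model)
  cfg <- fit_config(n_starts = 1, ctdna_noise_scale = ctdna_noise_scale,
                    gamma_deg = gamma_deg)
  structure(list(beta = setNames(beta, st$fixed_effect_names),
                 delta = setNames(delta, st$random_effect_names),
                 sigma_c = sigma_c, loglik = NA_real_,
                 typical_values = compose_effects(st, beta,
                                                  gamma_deg = gamma_deg),
                 multistart_table = data.frame(start = 1, objective = NA,
                                               converged = TRUE),
                 structure = st, config = cfg, seed = 1L),
            class = "population_estimate")
}

# noiseless prepared patient simulated from known effects
simulate_prepared <- function(effects, id = "P1",
                              ct_time = c(0, 0.25, 0.5, 1, 2, 4, 8, 12, 16),
                              bl_time = c(0, 16), model = "three_step") {
  tr <- solve_analytic(model, effects, sort(unique(c(ct_time, bl_time))))
  yat <- function(tt, o) tr$observables[match(tt, tr$times), o]
  make_prepared(id,
                ct_time = ct_time, ct_count = yat(ct_time, "y_ctdna"),
                bl_time = bl_time, bl_count = yat(bl_time, "y_blast"))
}

default_truth_config <- function(seed = 1, n = 10, relapse_factor = 0.1) {
  cfg <- clinical_defaults(seed = seed)
  cfg$n_patients <- as.integer(n)
  cfg$relapse_alpha_factor <- relapse_factor
  cfg
}
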