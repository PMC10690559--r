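# Synthetic longitudinal cohort generator. The defaults state the world the
# analysis assumes: log-normal patient effects around physiologic typical
# values, the clinical sampling schedule (marrow at day 0 and day 16-18,
# 2-14 ctDNA samples in the first 18 days), 10% multiplicative blast noise
# and additive ctDNA noise on the configured scale. Ground truth is kept
# alongside the observations for recovery experiments.

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients.
#' @param mutation_split named fractions over `c(NPM1, IDH2)`, summing to 1.
#' @param typical_values named list of natural-scale typical values for
#'   `B0, c0pb, gamma_d, s_c, alpha, gamma_t`.
#' @param omega named per-effect random-effect sds on the transformed scale
#'   (log scale; `log(s_c - 1)` scale for `s_c`), for the mixed effects
#'   `B0, c0pb, gamma_d, s_c, alpha`.
#' @param sigma_c ctDNA noise sd on `ctdna_noise_scale`.
#' @param ctdna_noise_scale `"log10"` (default) or `"linear"`.
#' @param relapse_fraction fraction of patients flagged as relapsing.
#' @param relapse_alpha_factor multiplicative shrinkage of `alpha` for
#'   relapse patients (0.1 = one decade lower, mirroring the observed
#'   clonal-heterogeneity signal); 1 disables the perturbation.
#' @param blast_noise_cv multiplicative blast noise (0.10).
#' @param ctdna_n_range integer range of per-patient ctDNA sample counts.
#' @param ctdna_window days over which ctDNA samples are drawn uniformly.
#' @param second_blast_days integer days eligible for the second marrow.
#' @param blood_volume_range liters, uniform per patient.
#' @param gamma_deg fixed degradation rate.
#' @param seed integer seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10,
                          mutation_split = c(NPM1 = 0.7, IDH2 = 0.3),
                          typical_values = list(B0 = 9e11, c0pb = 1e6,
                                                gamma_d = 0.5, s_c = 2,
                                                alpha = 0.2, gamma_t = 3),
                          omega = c(B0 = 0.2, c0pb = 0.7, gamma_d = 0.3,
                                    s_c = 0.5, alpha = 0.5),
                          sigma_c = 0.1,
                          ctdna_noise_scale = "log10",
                          relapse_fraction = 0.3,
                          relapse_alpha_factor = 0.1,
                          blast_noise_cv = 0.10,
                          ctdna_n_range = c(2L, 14L),
                          ctdna_window = c(0, 18),
                          second_blast_days = 16:18,
                          blood_volume_range = c(3.5, 6.0),
                          gamma_deg = gamma_deg_default(),
                          seed = 1) {
  tv <- typical_values
  stopifnot(n_patients >= 1,
            abs(sum(mutation_split) - 1) < 1e-12,
            all(unlist(tv) > 0), tv$s_c >= 1,
            tv$alpha > 0, tv$alpha <= 1,
            all(omega >= 0), sigma_c >= 0,
            relapse_fraction >= 0, relapse_fraction <= 1,
            relapse_alpha_factor > 0, relapse_alpha_factor <= 1,
            ctdna_n_range[1] >= 2)
  structure(list(n_patients = as.integer(n_patients),
                 mutation_split = mutation_split,
                 typical_values = tv, omega = omega, sigma_c = sigma_c,
                 ctdna_noise_scale = match.arg(ctdna_noise_scale,
                                               c("log10", "linear")),
                 relapse_fraction = relapse_fraction,
                 relapse_alpha_factor = relapse_alpha_factor,
                 blast_noise_cv = blast_noise_cv,
                 ctdna_n_range = as.integer(ctdna_n_range),
                 ctdna_window = ctdna_window,
                 second_blast_days = as.integer(second_blast_days),
                 blood_volume_range = blood_volume_range,
                 gamma_deg = gamma_deg, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default configuration mirroring the clinical cohort structure
#'
#' 10 patients, 7:3 NPM1:IDH2, 3 of 10 relapsing, marrow at day 0 and day
#' 16-18, 2-14 ctDNA samples within the first 18 days. Typical values are
#' plausible physiologic magnitudes (near-packed marrow of ~1.2e12
#' nucleated cells, ctDNA pool ~1e6 copies, blast clearance ~0.5/day,
#' transition ~3/day), not estimates taken from any fitted cohort.
#'
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @export
clinical_defaults <- function(seed = 1) cohort_config(seed = seed)

# transformed-scale typical value per effect
.typical_transformed <- function(tv, nm) {
  if (nm == "s_c") log(tv[[nm]] - 1) else log(tv[[nm]])
}

#' Draw ground-truth patients
#'
#' Random effects `b_k ~ N(0, diag(omega^2))` are composed with the same
#' links as the fitting machinery (`exp`; `1 + exp` for `s_c`). Relapse
#' patients have `log(relapse_alpha_factor)` added to their alpha random
#' effect before composition.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_truth`: per-patient list with
#'   `patient_id`, `mutation`, `relapse`, `blood_volume`, `b` (true random
#'   effects), `effects` (true natural-scale [effect_vector()]); plus the
#'   `config` and the population-level transformed typical values.
#' @export
sample_patients <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  tv <- config$typical_values
  structure_ <- build_effect_structure("three_step")
  beta <- vapply(structure_$fixed_effect_names,
                 function(nm) .typical_transformed(tv, nm), 0)
  mix <- structure_$random_effect_names
  n_npm1 <- round(n * config$mutation_split[["NPM1"]])
  mutation <- c(rep("NPM1", n_npm1), rep("IDH2", n - n_npm1))
  n_rel <- round(n * config$relapse_fraction)
  relapse <- rep(FALSE, n)
  if (n_rel > 0) relapse[sample(n, n_rel)] <- TRUE
  bv <- runif(n, config$blood_volume_range[1], config$blood_volume_range[2])
  patients <- vector("list", n)
  for (k in seq_len(n)) {
    b <- rnorm(length(mix), 0, config$omega[mix])
    names(b) <- mix
    if (relapse[k]) b["alpha"] <- b["alpha"] + log(config$relapse_alpha_factor)
    eff <- compose_effects(structure_, beta, b, config$gamma_deg)
    patients[[k]] <- list(
      patient_id = sprintf("S%02d", k), mutation = mutation[k],
      relapse = relapse[k], blood_volume = bv[k], b = b, effects = eff)
  }
  structure(list(patients = patients, beta = beta, config = config),
            class = "synthetic_truth")
}

#' Simulate noisy observations from a ground truth
#'
#' Evaluates the three-step closed form on each patient's schedule. Blast
#' counts get 10% multiplicative Gaussian noise (re-drawn, up to 100 times,
#' if negative); ctDNA counts get additive Gaussian noise with `sigma_c` on
#' the configured scale (re-drawn if non-positive on the linear scale).
#' Measurements are emitted in clinical units (blast fraction of 1.2e12
#' nucleated cells; ctDNA copies/L of the patient's blood volume), so the
#' generated cohort round-trips through [prepare_cohort()] exactly.
#'
#' @param truth a [sample_patients()] result.
#' @param config the matching [cohort_config()] (defaults to the one stored
#'   in `truth`).
#' @return a `ctdna_cohort`; the noiseless trajectories are attached to
#'   each record as attribute `"noiseless"`.
#' @export
simulate_observations <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  # observation noise uses a seed offset so that truth draws and noise
  # draws are independent streams but jointly reproducible
  set.seed(config$seed + 1000003L)
  redraw <- function(mean, sd, lower) {
    for (i in 1:100) {
      v <- rnorm(1, mean, sd)
      if (v > lower) return(v)
    }
    mean  # noise-free fallback after 100 rejections
  }
  recs <- lapply(truth$patients, function(pt) {
    t2 <- sample(config$second_blast_days, 1)
    n_ct <- sample(seq(config$ctdna_n_range[1], config$ctdna_n_range[2]), 1)
    # blood collection starts with treatment: the first ctDNA sample sits at
    # the start of the window, the rest are uniform over it
    t_ct <- c(config$ctdna_window[1],
              sort(runif(n_ct - 1, config$ctdna_window[1],
                         config$ctdna_window[2])))
    t_bl <- c(0, t2)
    tr <- solve_analytic("three_step", pt$effects, sort(unique(c(t_bl, t_ct))))
    yat <- function(tt, o) tr$observables[match(tt, tr$times), o]
    blast_frac <- vapply(t_bl, function(tt) {
      y <- yat(tt, "y_blast")
      obs <- if (config$blast_noise_cv > 0)
        redraw(y, config$blast_noise_cv * y, 0) else y
      min(obs / .BM_NUCLEATED_CELLS, 1)
    }, 0)
    ct_conc <- vapply(t_ct, function(tt) {
      y <- yat(tt, "y_ctdna")
      cnt <- if (config$sigma_c > 0) {
        if (config$ctdna_noise_scale == "log10")
          10^rnorm(1, log10(y), config$sigma_c)
        else redraw(y, config$sigma_c, 0)
      } else y
      cnt / pt$blood_volume
    }, 0)
    rec <- patient_record(
      patient_id = pt$patient_id, mutation = pt$mutation,
      blood_volume = pt$blood_volume, relapse = pt$relapse,
      blast_obs = data.frame(time = t_bl, value = blast_frac),
      ctdna_obs = data.frame(time = t_ct, value = ct_conc))
    attr(rec, "noiseless") <- tr
    rec
  })
  cohort(recs)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [sample_patients()] then [simulate_observations()].
#'
#' @param config a [cohort_config()].
#' @return list with `cohort` (a `ctdna_cohort`) and `truth`
#'   (a `synthetic_truth`).
#' @export
simulate_cohort <- function(config = clinical_defaults()) {
  truth <- sample_patients(config)
  list(cohort = simulate_observations(truth, config), truth = truth)
}

#' Write the ground truth of a synthetic cohort as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output path (`truth.json`).
#' @return invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    beta = as.list(truth$beta),
    config = truth$config[c("n_patients", "sigma_c", "ctdna_noise_scale",
                            "relapse_fraction", "relapse_alpha_factor",
                            "gamma_deg", "seed")],
    patients = lapply(truth$patients, function(p)
      list(patient_id = p$patient_id, mutation = p$mutation,
           relapse = p$relapse, blood_volume = p$blood_volume,
           b = as.list(p$b),
           effects = as.list(unclass(p$effects)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
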