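# Bundled clinical reference table: published covariates and measurement
# counts of the 10-patient NPM1/IDH2 cohort (ages, sex, blood volumes,
# mutation, relapse status, ELN 2017 risk group, numbers of ctDNA and
# marrow blast measurements). The measurement VALUES themselves are not
# published; clinical_reference_cohort() therefore builds a structural
# stand-in with synthetic placeholder values, which is sufficient for
# schedule/summary statistics but not for refitting the clinical results.

#' Published covariates of the clinical cohort
#'
#' @return data frame with one row per patient: `patient_id`, `age`,
#'   `sex`, `blood_volume_l`, `mutation`, `relapse`, `risk_group`,
#'   `n_ctdna_measurements`, `n_blast_measurements`.
#' @export
clinical_table <- function() {
  read.csv(system.file("extdata", "clinical_table_patients.csv",
                       package = "ctdnakin"),
           stringsAsFactors = FALSE)
}

#' Structural stand-in cohort with the published schedule
#'
#' Builds a `ctdna_cohort` whose covariates and per-patient measurement
#' counts match the published clinical table; observation times are spread
#' over the first 17 days and observation values are synthetic
#' placeholders (the study's measurement values are not printed). Useful
#' for schedule summaries ([summarize_cohort()]) and interface tests only.
#'
#' @return a `ctdna_cohort`.
#' @export
clinical_reference_cohort <- function() {
  tab <- clinical_table()
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    n_ct <- r$n_ctdna_measurements
    n_bl <- r$n_blast_measurements
    bl_t <- if (n_bl >= 2) c(0, 16) else 0
    patient_record(
      patient_id = r$patient_id, mutation = r$mutation, sex = r$sex,
      blood_volume = r$blood_volume_l, relapse = r$relapse,
      blast_obs = data.frame(time = bl_t,
                             value = c(0.7, rep(0, n_bl - 1))),
      ctdna_obs = data.frame(time = seq(0, 17, length.out = n_ct),
                             value = rep(1e5, n_ct)))
  })
  cohort(recs)
}
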