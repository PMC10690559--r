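# Cohort data model and preprocessing: clinical measurements (bone-marrow
# blast fraction, ctDNA concentration) are converted to absolute whole-body
# counts before fitting.

.BM_NUCLEATED_CELLS <- 1.2e12  # nucleated cells in adult bone marrow
.BLAST_NOISE_CV <- 0.10        # multiplicative blast measurement noise

#' Total-blood-volume estimate (Nadler)
#'
#' Anthropometric blood-volume formula:
#' male `0.3669 h^3 + 0.03219 w + 0.6041`,
#' female `0.3561 h^3 + 0.03308 w + 0.1833` (h in meters, w in kg).
#'
#' @param sex `"male"` or `"female"`.
#' @param height_m height in meters.
#' @param weight_kg weight in kg.
#' @return blood volume in liters.
#' @export
#' @examples
#' nadler_blood_volume("male", 1.80, 80) # 5.319 L
nadler_blood_volume <- function(sex, height_m, weight_kg) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(height_m) || !is.finite(weight_kg))
    stop("height and weight must be numeric")
  if (height_m <= 0.5 || height_m >= 2.5 || weight_kg <= 20 || weight_kg >= 250)
    warning("anthropometrics outside the usual adult range; ",
            "returning the computed value anyway")
  if (sex == "male") 0.3669 * height_m^3 + 0.03219 * weight_kg + 0.6041
  else 0.3561 * height_m^3 + 0.03308 * weight_kg + 0.1833
}

#' Convert a bone-marrow blast fraction to an absolute count
#'
#' Assumes `1.2e12` nucleated cells in the bone marrow.
#'
#' @param fraction blast fraction in `[0, 1]`.
#' @return blast cell count.
#' @export
blasts_fraction_to_count <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("fraction must lie in [0, 1]")
  .BM_NUCLEATED_CELLS * fraction
}

#' Convert a ctDNA concentration to a whole-body count
#'
#' @param concentration copies per liter (>= 0).
#' @param blood_volume liters (>= 0).
#' @return ctDNA copy count, `concentration * blood_volume`.
#' @export
ctdna_concentration_to_count <- function(concentration, blood_volume) {
  if (any(concentration < 0) || any(blood_volume < 0))
    stop("concentration and blood_volume must be non-negative")
  concentration * blood_volume
}

#' Single patient clinical record
#'
#' @param patient_id character id.
#' @param mutation `"NPM1"` or `"IDH2"`.
#' @param sex `"male"` or `"female"` (optional if `blood_volume` given).
#' @param height_m,weight_kg anthropometrics (optional if `blood_volume`
#'   given).
#' @param blood_volume liters; overrides the Nadler computation when present.
#' @param relapse logical relapse flag.
#' @param blast_obs data frame with columns `time` (days) and `value`
#'   (fraction in `[0, 1]`); at least one row.
#' @param ctdna_obs data frame with columns `time` (days) and `value`
#'   (copies/L, >= 0); at least two rows.
#' @return object of class `patient_record`.
#' @export
patient_record <- function(patient_id, mutation = c("NPM1", "IDH2"),
                           sex = NULL, height_m = NULL, weight_kg = NULL,
                           blood_volume = NULL, relapse = FALSE,
                           blast_obs, ctdna_obs) {
  mutation <- match.arg(mutation)
  if (is.null(blood_volume) &&
      (is.null(sex) || is.null(height_m) || is.null(weight_kg)))
    stop("need blood_volume or (sex, height_m, weight_kg)")
  stopifnot(is.data.frame(blast_obs), is.data.frame(ctdna_obs))
  if (nrow(blast_obs) < 1) stop("blast_obs needs at least one measurement")
  if (nrow(ctdna_obs) < 2) stop("ctdna_obs needs at least two measurements")
  all_t <- c(blast_obs$time, ctdna_obs$time)
  if (any(all_t < -6) || any(all_t > 30))
    stop("measurement times must lie within [-6, 30] days")
  if (any(blast_obs$value < 0) || any(blast_obs$value > 1))
    stop("blast values are fractions in [0, 1]")
  if (any(ctdna_obs$value < 0)) stop("ctDNA concentrations must be >= 0")
  if (is.null(blood_volume))
    blood_volume <- nadler_blood_volume(sex, height_m, weight_kg)
  structure(list(patient_id = as.character(patient_id), mutation = mutation,
                 sex = sex, height_m = height_m, weight_kg = weight_kg,
                 blood_volume = blood_volume, relapse = isTRUE(relapse),
                 blast_obs = blast_obs[order(blast_obs$time), , drop = FALSE],
                 ctdna_obs = ctdna_obs[order(ctdna_obs$time), , drop = FALSE]),
            class = "patient_record")
}

#' Align measurement times to treatment start
#'
#' Pre-treatment samples (negative times, typically the diagnostic marrow
#' 1-6 days before chemotherapy) are used as the t = 0 starting point of the
#' modeled period; blasts are assumed not to proliferate appreciably in
#' between. A single distinct pre-treatment time maps to 0; if several
#' distinct pre-treatment times exist, the earliest maps to 0, their
#' relative spacing is preserved, and a warning is emitted. Post-treatment
#' times are unchanged.
#'
#' @param record a [patient_record()].
#' @return the record with aligned observation times (all >= 0).
#' @export
align_times <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  neg <- sort(unique(c(record$blast_obs$time[record$blast_obs$time < 0],
                       record$ctdna_obs$time[record$ctdna_obs$time < 0])))
  fix <- function(tv) {
    if (length(neg) == 0) return(tv)
    if (length(neg) == 1) { tv[tv < 0] <- 0; return(tv) }
    tv[tv < 0] <- tv[tv < 0] - neg[1]
    tv
  }
  if (length(neg) > 1)
    warning("multiple distinct pre-treatment times; earliest mapped to 0, ",
            "relative spacing preserved")
  record$blast_obs$time <- fix(record$blast_obs$time)
  record$ctdna_obs$time <- fix(record$ctdna_obs$time)
  record
}

#' Assemble a cohort from patient records
#'
#' @param records list of [patient_record()] objects with unique ids.
#' @return object of class `ctdna_cohort` (list of records).
#' @export
cohort <- function(records) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, TRUE, "patient_record")))
  ids <- vapply(records, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  structure(setNames(records, ids), class = "ctdna_cohort")
}

#' Prepare a cohort for fitting
#'
#' Aligns times, converts blast fractions and ctDNA concentrations to
#' absolute whole-body counts, and attaches blast measurement-noise standard
#' deviations (see [attach_noise()]). The ctDNA noise sd `sigma_c` is left
#' to be estimated during fitting.
#'
#' @param x a `ctdna_cohort`.
#' @return object of class `prepared_cohort`: list of `prepared_patient`
#'   objects, each holding `patient_id`, `mutation`, `relapse`,
#'   `blood_volume` and an observation data frame `obs` with columns
#'   `time`, `type` (`"ctdna"`/`"blast"`), `count`, `sd`.
#' @export
prepare_cohort <- function(x) {
  stopifnot(inherits(x, "ctdna_cohort"))
  prep <- lapply(x, function(r) {
    r <- align_times(r)
    obs <- rbind(
      data.frame(time = r$ctdna_obs$time, type = "ctdna",
                 count = ctdna_concentration_to_count(r$ctdna_obs$value,
                                                      r$blood_volume),
                 sd = NA_real_),
      data.frame(time = r$blast_obs$time, type = "blast",
                 count = blasts_fraction_to_count(r$blast_obs$value),
                 sd = NA_real_))
    obs <- obs[order(obs$time, obs$type), , drop = FALSE]
    rownames(obs) <- NULL
    structure(list(patient_id = r$patient_id, mutation = r$mutation,
                   relapse = r$relapse, blood_volume = r$blood_volume,
                   obs = obs),
              class = "prepared_patient")
  })
  attach_noise(structure(setNames(prep, names(x)), class = "prepared_cohort"))
}

#' Attach blast measurement-noise standard deviations
#'
#' Blast sd = 10% of the measured count (multiplicative noise). For
#' zero-valued blast measurements (typically the day-16 marrow), the sd is
#' substituted by the mean sd of non-zero blast measurements of other
#' patients at the matching time point (+- 1 day). If no non-zero
#' measurement exists in that window anywhere in the cohort, the fallback is
#' 10% of the smallest non-zero blast count in the cohort (with a message).
#'
#' @param prepared a `prepared_cohort`.
#' @return the cohort with every blast `sd` strictly positive.
#' @export
attach_noise <- function(prepared) {
  stopifnot(inherits(prepared, "prepared_cohort"))
  all_blast <- do.call(rbind, lapply(prepared, function(p) {
    b <- p$obs[p$obs$type == "blast", c("time", "count")]
    if (nrow(b)) cbind(b, patient_id = p$patient_id) else NULL
  }))
  pos <- all_blast[all_blast$count > 0, , drop = FALSE]
  for (id in names(prepared)) {
    obs <- prepared[[id]]$obs
    bi <- which(obs$type == "blast")
    for (i in bi) {
      if (obs$count[i] > 0) {
        obs$sd[i] <- .BLAST_NOISE_CV * obs$count[i]
      } else {
        win <- pos[abs(pos$time - obs$time[i]) <= 1, , drop = FALSE]
        if (nrow(win) > 0) {
          obs$sd[i] <- mean(.BLAST_NOISE_CV * win$count)
        } else if (nrow(pos) > 0) {
          obs$sd[i] <- .BLAST_NOISE_CV * min(pos$count)
          message("attach_noise: no non-zero blast measurement within 1 day ",
                  "of t = ", obs$time[i], "; using cohort-minimum fallback sd")
        } else {
          stop("cohort has no non-zero blast measurement to substitute ",
               "noise for zero-valued measurements")
        }
      }
    }
    prepared[[id]]$obs <- obs
  }
  prepared
}

#' Cohort summary statistics
#'
#' @param x a `ctdna_cohort` or `prepared_cohort`.
#' @return list with patient counts per mutation, and mean / sample standard
#'   deviation (n - 1 denominator) plus range of the per-patient ctDNA
#'   measurement counts, and the blast measurement counts.
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, c("ctdna_cohort", "prepared_cohort")))
  n_ct <- vapply(x, function(p) {
    if (inherits(p, "prepared_patient")) sum(p$obs$type == "ctdna")
    else nrow(p$ctdna_obs)
  }, 0L)
  n_bl <- vapply(x, function(p) {
    if (inherits(p, "prepared_patient")) sum(p$obs$type == "blast")
    else nrow(p$blast_obs)
  }, 0L)
  mut <- vapply(x, `[[`, "", "mutation")
  list(n_patients = length(x),
       n_per_mutation = table(factor(mut, levels = c("NPM1", "IDH2"))),
       ctdna_measurements = list(
         mean = mean(n_ct),
         sd = if (length(n_ct) > 1) sd(n_ct) else NA_real_,
         min = min(n_ct), max = max(n_ct)),
       blast_measurements = list(min = min(n_bl), max = max(n_bl)))
}

# ---------------------------------------------------------------------------
# file I/O: one tidy observation CSV + one covariate JSON
# ---------------------------------------------------------------------------

#' Write a cohort to disk
#'
#' Observations go to a tidy CSV (`patient_id, compartment, time_days,
#' value, unit` with compartments `blast_bm` (fraction) and `ctdna_pb`
#' (copies/L)); covariates go to a JSON array (id, mutation, sex,
#' height_m, weight_kg, blood_volume_l, relapse).
#'
#' @param x a `ctdna_cohort`.
#' @param obs_csv,covariates_json output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(x, obs_csv, covariates_json) {
  stopifnot(inherits(x, "ctdna_cohort"))
  obs <- do.call(rbind, lapply(x, function(r) rbind(
    data.frame(patient_id = r$patient_id, compartment = "blast_bm",
               time_days = r$blast_obs$time, value = r$blast_obs$value,
               unit = "fraction"),
    data.frame(patient_id = r$patient_id, compartment = "ctdna_pb",
               time_days = r$ctdna_obs$time, value = r$ctdna_obs$value,
               unit = "copies_per_liter"))))
  rownames(obs) <- NULL
  write.csv(obs, obs_csv, row.names = FALSE, quote = FALSE)
  cov <- lapply(unname(x), function(r)
    list(patient_id = r$patient_id, mutation = r$mutation,
         sex = r$sex, height_m = r$height_m, weight_kg = r$weight_kg,
         blood_volume_l = r$blood_volume, relapse = r$relapse))
  jsonlite::write_json(cov, covariates_json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(obs_csv, covariates_json))
}

#' Read a cohort from disk
#'
#' @param obs_csv,covariates_json paths written by [write_cohort()].
#' @return a `ctdna_cohort`.
#' @export
read_cohort <- function(obs_csv, covariates_json) {
  obs <- read.csv(obs_csv, stringsAsFactors = FALSE)
  cov <- jsonlite::read_json(covariates_json, simplifyVector = FALSE)
  recs <- lapply(cov, function(cv) {
    mine <- obs[obs$patient_id == cv$patient_id, , drop = FALSE]
    bl <- mine[mine$compartment == "blast_bm", , drop = FALSE]
    ct <- mine[mine$compartment == "ctdna_pb", , drop = FALSE]
    patient_record(
      patient_id = cv$patient_id, mutation = cv$mutation,
      sex = cv$sex, height_m = cv$height_m, weight_kg = cv$weight_kg,
      blood_volume = cv$blood_volume_l, relapse = isTRUE(cv$relapse),
      blast_obs = data.frame(time = bl$time_days, value = bl$value),
      ctdna_obs = data.frame(time = ct$time_days, value = ct$value))
  })
  cohort(recs)
}
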