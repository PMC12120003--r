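#' Default subcortical region labels
#'
#' The fourteen bilateral deep gray-matter structures (left/right caudate,
#' putamen, pallidum, hippocampus, nucleus accumbens, amygdala, thalamus),
#' in the fixed column order used throughout the package.
#'
#' @return Character vector of length 14.
#' @export
default_region_names <- function() {
  structures <- c("caudate", "putamen", "pallidum", "hippocampus",
                  "accumbens", "amygdala", "thalamus")
  as.vector(t(outer(structures, c("l", "r"), paste, sep = "_")))
}

# typical adult log mm^3 volumes per structure, both hemispheres
default_region_log_means <- function(region_names = default_region_names()) {
  base <- c(caudate = log(3500), putamen = log(4800), pallidum = log(1700),
            hippocampus = log(4000), accumbens = log(550),
            amygdala = log(1500), thalamus = log(6900))
  out <- base[sub("_[lr]$", "", region_names)]
  names(out) <- region_names
  out
}

#' Default planted pattern topography
#'
#' Raw topography: -1 on bilateral putamen, -0.7 on left nucleus accumbens,
#' +0.8 on bilateral caudate, 0 elsewhere; mean-removed and unit-normalized
#' so the vector lives in the double-centered region space. Negative weights
#' mark regions whose volume decreases with greater WMH burden.
#'
#' @param region_names Region labels (default [default_region_names()]).
#' @return Named numeric vector, unit Euclidean norm, zero sum.
#' @export
default_planted_weights <- function(region_names = default_region_names()) {
  w <- stats::setNames(numeric(length(region_names)), region_names)
  w[c("putamen_l", "putamen_r")] <- -1
  w["accumbens_l"] <- -0.7
  w[c("caudate_l", "caudate_r")] <- 0.8
  w <- w - mean(w)
  w / sqrt(sum(w^2))
}

# direct age paths (standardized) per outcome and slopes of each outcome on
# standardized log TMT-A; the defaults are the study-condition effect sizes
default_c_direct <- function() {
  c(tmt_a = 0.262, srt_cltr = -0.497, tmt_b = 0.234, wais_lns = -0.416,
    scwt = -0.423, gpt = 0.639)
}
default_d_speed <- function() {
  c(srt_cltr = -0.278, tmt_b = 0.539, wais_lns = -0.287,
    scwt = -0.347, gpt = 0.182)
}

# raw-score marginal moments used to place simulated cognition on natural
# test scales (timed scores are produced log-normally)
default_outcome_scales <- function() {
  list(tmt_a   = c(mean = 32.62, sd = 10.67),
       tmt_b   = c(mean = 75.80, sd = 30.27),
       gpt     = c(mean = 92.10, sd = 26.77),
       srt_cltr = c(mean = 63.38, sd = 37.16),
       wais_lns = c(mean = 18.77, sd = 2.80),
       scwt    = c(mean = 36.71, sd = 9.33))
}

#' Construct and validate synthetic cohort parameters
#'
#' Bundles every knob of the generative model: cohort size, age
#' distribution, regional log-volume baselines, the planted WMH-related
#' pattern topography and its couplings, residual noise, cognition path
#' coefficients, covariate marginals, and the target marginal moments of
#' untransformed WMH volume (mL). Defaults describe a healthy older-adult
#' cohort of 178 subjects.
#'
#' @param n_subjects Number of subjects (>= 30).
#' @param age_mean,age_sd Age marginal (years).
#' @param region_names Ordered labels of the 14 subcortical regions.
#' @param region_log_means Per-region baseline natural-log volume (log mm^3).
#' @param global_scale_sd SD of the per-subject whole-brain size factor
#'   (log scale).
#' @param planted_weights Unit-norm, zero-sum pattern topography.
#' @param coupling_age_pattern Standardized slope age -> pattern score.
#' @param coupling_pattern_logwmh Standardized slope pattern -> log WMH.
#' @param noise_sd_regions Residual log-volume noise SD.
#' @param b_pattern_speed Standardized slope pattern -> log TMT-A.
#' @param c_direct Named vector of standardized direct age paths per outcome
#'   (names `tmt_a`, `srt_cltr`, `tmt_b`, `wais_lns`, `scwt`, `gpt`).
#' @param d_speed Named vector of standardized slopes of each downstream
#'   outcome on standardized log TMT-A.
#' @param sex_prop,education_mean,education_sd,apoe4_prev,hypertension_prev,cholesterol_prev,smoking_prev,bmi_mean,bmi_sd,vo2max_mean,vo2max_sd,gds_mean,gds_sd,interval_mean,interval_sd
#'   Covariate marginals.
#' @param wmh_mean_ml,wmh_sd_ml Target mean/SD of untransformed WMH (mL).
#' @param tiv_mean Mean total intracranial volume (mm^3).
#' @param outcome_scales List of raw-score mean/sd per cognitive outcome.
#' @param n_missing_tmt_b,n_missing_gpt Number of subjects with missing
#'   TMT-B / GPT scores (missingness is allowed only in cognition columns).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 178,
                          age_mean = 69.77, age_sd = 10.22,
                          region_names = default_region_names(),
                          region_log_means = default_region_log_means(region_names),
                          global_scale_sd = 0.1,
                          planted_weights = default_planted_weights(region_names),
                          coupling_age_pattern = 0.492,
                          coupling_pattern_logwmh = sqrt(0.389),
                          noise_sd_regions = 0.1,
                          b_pattern_speed = 0.234,
                          c_direct = default_c_direct(),
                          d_speed = default_d_speed(),
                          sex_prop = 0.506,
                          education_mean = 16.72, education_sd = 2.80,
                          apoe4_prev = 0.315,
                          hypertension_prev = 0.331,
                          cholesterol_prev = 0.702,
                          smoking_prev = 0.399,
                          bmi_mean = 25.21, bmi_sd = 3.87,
                          vo2max_mean = 24.43, vo2max_sd = 5.81,
                          gds_mean = 1.01, gds_sd = 1.58,
                          interval_mean = 56.49, interval_sd = 46.69,
                          wmh_mean_ml = 6.68, wmh_sd_ml = 10.28,
                          tiv_mean = 1.45e6,
                          outcome_scales = default_outcome_scales(),
                          n_missing_tmt_b = 1L, n_missing_gpt = 1L,
                          seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), age_mean = age_mean,
            age_sd = age_sd, region_names = region_names,
            region_log_means = region_log_means,
            global_scale_sd = global_scale_sd,
            planted_weights = planted_weights,
            coupling_age_pattern = coupling_age_pattern,
            coupling_pattern_logwmh = coupling_pattern_logwmh,
            noise_sd_regions = noise_sd_regions,
            b_pattern_speed = b_pattern_speed,
            c_direct = c_direct, d_speed = d_speed,
            sex_prop = sex_prop,
            education_mean = education_mean, education_sd = education_sd,
            apoe4_prev = apoe4_prev, hypertension_prev = hypertension_prev,
            cholesterol_prev = cholesterol_prev, smoking_prev = smoking_prev,
            bmi_mean = bmi_mean, bmi_sd = bmi_sd,
            vo2max_mean = vo2max_mean, vo2max_sd = vo2max_sd,
            gds_mean = gds_mean, gds_sd = gds_sd,
            interval_mean = interval_mean, interval_sd = interval_sd,
            wmh_mean_ml = wmh_mean_ml, wmh_sd_ml = wmh_sd_ml,
            tiv_mean = tiv_mean, outcome_scales = outcome_scales,
            n_missing_tmt_b = as.integer(n_missing_tmt_b),
            n_missing_gpt = as.integer(n_missing_gpt),
            seed = as.integer(seed))
  class(p) <- "cohort_params"
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort parameter '%s': %s", field, msg),
         call. = FALSE)
  }
  if (is.na(p$n_subjects) || p$n_subjects < 30L)
    fail("n_subjects", "must be at least 30")
  nr <- length(p$region_names)
  if (nr < 2L || anyDuplicated(p$region_names))
    fail("region_names", "needs at least 2 unique labels")
  if (length(p$region_log_means) != nr)
    fail("region_log_means", "length must match region_names")
  if (length(p$planted_weights) != nr)
    fail("planted_weights", "length must match region_names")
  if (abs(sum(p$planted_weights^2) - 1) > 1e-8)
    fail("planted_weights", "must have unit Euclidean norm")
  if (abs(sum(p$planted_weights)) > 1e-8)
    fail("planted_weights", "must sum to zero (double-centered space)")
  for (f in c("age_sd", "global_scale_sd", "noise_sd_regions", "education_sd",
              "bmi_sd", "vo2max_sd", "gds_sd", "interval_sd",
              "wmh_mean_ml", "wmh_sd_ml")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) fail(f, "must be nonnegative")
  }
  for (f in c("coupling_age_pattern", "coupling_pattern_logwmh")) {
    if (abs(p[[f]]) > 1) fail(f, "standardized coupling must lie in [-1, 1]")
  }
  for (f in c("sex_prop", "apoe4_prev", "hypertension_prev",
              "cholesterol_prev", "smoking_prev")) {
    if (p[[f]] < 0 || p[[f]] > 1) fail(f, "must be a proportion in [0, 1]")
  }
  need <- c("tmt_a", "srt_cltr", "tmt_b", "wais_lns", "scwt", "gpt")
  if (!all(need %in% names(p$c_direct)))
    fail("c_direct", paste("must name all outcomes:", paste(need, collapse = ", ")))
  if (!all(setdiff(need, "tmt_a") %in% names(p$d_speed)))
    fail("d_speed", "must name all downstream outcomes")
  if (p$n_missing_tmt_b < 0 || p$n_missing_tmt_b >= p$n_subjects)
    fail("n_missing_tmt_b", "must be in [0, n_subjects)")
  if (p$n_missing_gpt < 0 || p$n_missing_gpt >= p$n_subjects)
    fail("n_missing_gpt", "must be in [0, n_subjects)")
  invisible(p)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  n_subjects: %d, age %.2f (%.2f)\n",
              x$n_subjects, x$age_mean, x$age_sd))
  cat(sprintf("  regions: %d; couplings age->pattern %.3f, pattern->logWMH %.3f\n",
              length(x$region_names), x$coupling_age_pattern,
              x$coupling_pattern_logwmh))
  cat(sprintf("  WMH marginal %.2f (%.2f) mL; seed %d\n",
              x$wmh_mean_ml, x$wmh_sd_ml, x$seed))
  invisible(x)
}
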