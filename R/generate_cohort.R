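#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a subject-by-variable cohort table from a fixed generative recipe:
#' a latent pattern score `s` coupled to standardized age; per-region
#' natural-log volumes built from a baseline profile, a per-subject global
#' size factor, the planted topography scaled by `s`, and independent
#' noise; log WMH coupled to `s` and affinely placed so untransformed WMH
#' matches the target mean/SD (log-normal marginal); log TMT-A driven by
#' `s` and age; the remaining cognitive outcomes driven by standardized
#' log TMT-A and age. Covariates are drawn from their stated marginals,
#' independent of the pattern. The returned table carries the latent score
#' in the non-analytic ground-truth column `true_s`.
#'
#' @param params A [cohort_params()] object.
#' @return A `data.frame` (one row per subject) with columns: `subject_id`,
#'   the 14 region volumes (mm^3), `wmh_ml`, `tiv`, `age`, `sex`,
#'   `education`, `apoe4`, `hypertension`, `high_cholesterol`, `smoking`,
#'   `bmi`, `vo2max`, `gds`, `interval_days`, `srt_cltr`, `tmt_a_sec`,
#'   `tmt_b_sec`, `wais_lns`, `scwt`, `gpt_sec`, `true_s`.
#' @seealso [generate_null_cohort()], [write_cohort()]
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("invalid cohort parameter 'params': expected a cohort_params object",
         call. = FALSE)
  }
  validate_cohort_params(params)
  simulate_cohort_impl(params, null_model = FALSE)
}

#' Generate a null cohort (no pattern, no mediated paths)
#'
#' Identical marginals to [generate_cohort()] but the planted topography is
#' not written into the volumes, WMH is independent of the volumes and of
#' the latent score, and no cognition path runs through the pattern; direct
#' age effects on cognition are retained. Used for type-I-error harnesses.
#'
#' @inheritParams generate_cohort
#' @return A cohort `data.frame`, same schema as [generate_cohort()].
#' @export
generate_null_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("invalid cohort parameter 'params': expected a cohort_params object",
         call. = FALSE)
  }
  validate_cohort_params(params)
  simulate_cohort_impl(params, null_model = TRUE)
}

simulate_cohort_impl <- function(p, null_model) {
  set.seed(p$seed)
  n <- p$n_subjects
  regions <- p$region_names
  np <- length(regions)

  age <- stats::rnorm(n, p$age_mean, p$age_sd)
  z_age <- (age - p$age_mean) / p$age_sd

  a <- if (null_model) 0 else p$coupling_age_pattern
  s <- a * z_age + sqrt(1 - a^2) * stats::rnorm(n)

  g <- stats::rnorm(n, 0, p$global_scale_sd)
  noise <- matrix(stats::rnorm(n * np, 0, p$noise_sd_regions), n, np)
  logvol <- matrix(p$region_log_means, n, np, byrow = TRUE) + g + noise
  if (!null_model) logvol <- logvol + outer(s, p$planted_weights)
  vol <- exp(logvol)
  colnames(vol) <- regions

  # log-normal WMH marginal: mean/SD of the untransformed volume hit the
  # targets exactly in population
  r <- if (null_model) 0 else p$coupling_pattern_logwmh
  z_wmh <- r * s + sqrt(1 - r^2) * stats::rnorm(n)
  sig2 <- log(1 + (p$wmh_sd_ml / p$wmh_mean_ml)^2)
  mu <- log(p$wmh_mean_ml) - sig2 / 2
  wmh_ml <- exp(mu + sqrt(sig2) * z_wmh)

  tiv <- p$tiv_mean * exp(g + stats::rnorm(n, 0, 0.03))

  sex <- stats::rbinom(n, 1, p$sex_prop)
  education <- stats::rnorm(n, p$education_mean, p$education_sd)
  apoe4 <- stats::rbinom(n, 1, p$apoe4_prev)
  hypertension <- stats::rbinom(n, 1, p$hypertension_prev)
  high_cholesterol <- stats::rbinom(n, 1, p$cholesterol_prev)
  smoking <- stats::rbinom(n, 1, p$smoking_prev)
  bmi <- stats::rnorm(n, p$bmi_mean, p$bmi_sd)
  vo2max <- stats::rnorm(n, p$vo2max_mean, p$vo2max_sd)
  gds <- if (p$gds_sd^2 > p$gds_mean) {
    size <- p$gds_mean^2 / (p$gds_sd^2 - p$gds_mean)
    stats::rnbinom(n, size = size, mu = p$gds_mean)
  } else {
    stats::rpois(n, p$gds_mean)
  }
  shape <- (p$interval_mean / p$interval_sd)^2
  interval_days <- stats::rgamma(n, shape = shape,
                                 scale = p$interval_sd^2 / p$interval_mean)

  # cognition: standardized log TMT-A first, downstream outcomes from it;
  # residual variances close each standardized variable to unit variance
  b <- if (null_model) 0 else p$b_pattern_speed
  ca <- p$c_direct[["tmt_a"]]
  v_expl <- b^2 + ca^2 + 2 * b * ca * a
  z_speed <- b * s + ca * z_age +
    stats::rnorm(n, 0, sqrt(max(1 - v_expl, 0.1)))
  cov_speed_age <- b * a + ca

  timed <- function(z, mom) {
    s2 <- log(1 + (mom[["sd"]] / mom[["mean"]])^2)
    exp(log(mom[["mean"]]) - s2 / 2 + sqrt(s2) * z)
  }
  tmt_a_sec <- timed(z_speed, p$outcome_scales$tmt_a)

  outcome_z <- function(name) {
    d <- if (null_model) 0 else p$d_speed[[name]]
    co <- p$c_direct[[name]]
    v <- d^2 + co^2 + 2 * d * co * cov_speed_age
    d * z_speed + co * z_age + stats::rnorm(n, 0, sqrt(max(1 - v, 0.1)))
  }
  srt_cltr <- p$outcome_scales$srt_cltr[["mean"]] +
    p$outcome_scales$srt_cltr[["sd"]] * outcome_z("srt_cltr")
  tmt_b_sec <- timed(outcome_z("tmt_b"), p$outcome_scales$tmt_b)
  wais_lns <- p$outcome_scales$wais_lns[["mean"]] +
    p$outcome_scales$wais_lns[["sd"]] * outcome_z("wais_lns")
  scwt <- p$outcome_scales$scwt[["mean"]] +
    p$outcome_scales$scwt[["sd"]] * outcome_z("scwt")
  gpt_sec <- timed(outcome_z("gpt"), p$outcome_scales$gpt)

  if (p$n_missing_tmt_b > 0L)
    tmt_b_sec[sample.int(n, p$n_missing_tmt_b)] <- NA_real_
  if (p$n_missing_gpt > 0L)
    gpt_sec[sample.int(n, p$n_missing_gpt)] <- NA_real_

  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    vol, wmh_ml = wmh_ml, tiv = tiv, age = age, sex = sex,
                    education = education, apoe4 = apoe4,
                    hypertension = hypertension,
                    high_cholesterol = high_cholesterol, smoking = smoking,
                    bmi = bmi, vo2max = vo2max, gds = gds,
                    interval_days = interval_days, srt_cltr = srt_cltr,
                    tmt_a_sec = tmt_a_sec, tmt_b_sec = tmt_b_sec,
                    wais_lns = wais_lns, scwt = scwt, gpt_sec = gpt_sec,
                    true_s = s,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "seed") <- p$seed
  out
}

#' Write / read a cohort table as CSV
#'
#' The CSV keeps the generator's fixed column order and records the seed in
#' a leading `#`-comment line, so identical parameters reproduce a
#' byte-identical file.
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  seed <- attr(cohort, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Write cohort parameters to YAML
#'
#' @param params A [cohort_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_params <- function(params, path) {
  plain <- unclass(params)
  plain$outcome_scales <- lapply(plain$outcome_scales, as.list)
  yaml::write_yaml(plain, path)
  invisible(path)
}
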