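#' Derived cognitive variables
#'
#' Adds the transformed cognition columns used by the mediation models:
#' natural logs of the timed scores (`log_tmt_a`, `log_tmt_b`, `log_gpt`,
#' to normalize their right-skewed distributions) and `tmt_b_resid`, the
#' z-scored residual of an ordinary least-squares regression of raw TMT-B
#' on raw TMT-A over complete pairs (set-shifting with simple processing
#' speed statistically removed; the residualization deliberately uses raw
#' scores even though TMT-A itself enters the models log-transformed).
#' Rows with missing inputs get missing outputs.
#'
#' @param cohort Cohort `data.frame` with `tmt_a_sec`, `tmt_b_sec`,
#'   `gpt_sec` columns.
#' @return The cohort with four added columns.
#' @export
preprocess_cognition <- function(cohort) {
  for (col in c("tmt_a_sec", "tmt_b_sec", "gpt_sec")) {
    if (!col %in% names(cohort)) {
      stop(sprintf("cohort is missing column '%s'", col), call. = FALSE)
    }
    v <- cohort[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("nonpositive timed score in '%s'", col), call. = FALSE)
    }
  }
  cohort$log_tmt_a <- log(cohort$tmt_a_sec)
  cohort$log_tmt_b <- log(cohort$tmt_b_sec)
  cohort$log_gpt <- log(cohort$gpt_sec)

  ok <- stats::complete.cases(cohort$tmt_a_sec, cohort$tmt_b_sec)
  z <- rep(NA_real_, nrow(cohort))
  if (sum(ok) >= 3L) {
    X <- cbind(1, cohort$tmt_a_sec[ok])
    cf <- ols_coef(X, cohort$tmt_b_sec[ok])
    res <- cohort$tmt_b_sec[ok] - drop(X %*% cf)
    sdr <- stats::sd(res)
    # a numerically perfect fit leaves no shifting signal to standardize
    z[ok] <- if (sdr > 1e-10 * stats::sd(cohort$tmt_b_sec[ok])) {
      (res - mean(res)) / sdr
    } else 0
  }
  cohort$tmt_b_resid <- z
  cohort
}

#' Covariate sets for the mediation models
#'
#' `"base"`: TIV, sex, education years, APOE e4 status, hypertension
#' status, scan-test interval. `"vascular"` adds high cholesterol, smoking
#' history, BMI and VO2max. `"depression"` further adds the depression
#' rating.
#'
#' @param tier One of `"base"`, `"vascular"`, `"depression"`.
#' @return Character vector of covariate column names.
#' @export
covariate_set <- function(tier = c("base", "vascular", "depression")) {
  tier <- match.arg(tier)
  covs <- c("tiv", "sex", "education", "apoe4", "hypertension",
            "interval_days")
  if (tier %in% c("vascular", "depression")) {
    covs <- c(covs, "high_cholesterol", "smoking", "bmi", "vo2max")
  }
  if (tier == "depression") covs <- c(covs, "gds")
  covs
}

#' Specify a mediation model
#'
#' @param x Predictor column (typically `"age"`).
#' @param mediators Ordered character vector of 1 (simple) or 2 (serial)
#'   mediator columns; for serial models the order is causal:
#'   `c(m1, m2)` means x -> m1 -> m2 -> y.
#' @param y Outcome column.
#' @param covariates Covariate columns; continuous covariates are z-scored,
#'   binary 0/1 covariates are left as is.
#' @param n_boot Bootstrap replicates for the percentile CIs.
#' @param seed Integer seed.
#' @param ci_level Confidence level (default 0.95).
#' @return An object of class `mediation_spec`.
#' @export
mediation_spec <- function(x, mediators, y,
                           covariates = covariate_set("base"),
                           n_boot = 5000L, seed = 1L, ci_level = 0.95) {
  if (!length(mediators) %in% 1:2) {
    stop("mediators must list 1 (simple) or 2 (serial) columns",
         call. = FALSE)
  }
  vars <- c(x, mediators, y, covariates)
  if (anyDuplicated(vars)) {
    stop("x, mediators, y and covariates must be disjoint", call. = FALSE)
  }
  structure(list(x = x, mediators = mediators, y = y,
                 covariates = covariates, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), ci_level = ci_level),
            class = "mediation_spec")
}

# path coefficients on an already-standardized matrix; columns of Z are
# x, m1[, m2], y, covariates in that order
med_paths <- function(Z, n_med, n_cov) {
  x <- Z[, 1L]
  m1 <- Z[, 2L]
  C <- if (n_cov > 0) Z[, (2L + n_med + 1L):(2L + n_med + n_cov), drop = FALSE]
       else NULL
  yv <- Z[, 2L + n_med]
  des <- function(...) cbind(1, ..., C)
  if (n_med == 1L) {
    cf_a <- ols_coef(des(x), m1)
    cf_y <- ols_coef(des(x, m1), yv)
    cf_t <- ols_coef(des(x), yv)
    if (is.null(cf_a) || is.null(cf_y) || is.null(cf_t)) return(NULL)
    c(a1 = cf_a[[2L]], b1 = cf_y[[3L]], c_prime = cf_y[[2L]],
      c_total = cf_t[[2L]])
  } else {
    m2 <- Z[, 3L]
    cf_a1 <- ols_coef(des(x), m1)
    cf_m2 <- ols_coef(des(x, m1), m2)
    cf_y <- ols_coef(des(x, m1, m2), yv)
    cf_t <- ols_coef(des(x), yv)
    if (is.null(cf_a1) || is.null(cf_m2) || is.null(cf_y) || is.null(cf_t))
      return(NULL)
    c(a1 = cf_a1[[2L]], a2 = cf_m2[[2L]], d21 = cf_m2[[3L]],
      b1 = cf_y[[3L]], b2 = cf_y[[4L]], c_prime = cf_y[[2L]],
      c_total = cf_t[[2L]])
  }
}

med_indirect <- function(paths, n_med) {
  if (n_med == 1L) {
    c(ind_m1 = unname(paths["a1"] * paths["b1"]))
  } else {
    c(ind_m1 = unname(paths["a1"] * paths["b1"]),
      ind_m2 = unname(paths["a2"] * paths["b2"]),
      ind_serial = unname(paths["a1"] * paths["d21"] * paths["b2"]))
  }
}

#' Fit a simple or serial mediation model with percentile-bootstrap CIs
#'
#' Ordinary least-squares path regressions on listwise-complete rows with
#' completely standardized coefficients: predictor, mediator(s), outcome
#' and continuous covariates are z-scored (binary covariates stay 0/1).
#' For a simple model the indirect effect is `a1*b1`; a serial model
#' reports `a1*b1`, `a2*b2` and the headline sequential effect
#' `a1*d21*b2`. Bootstrap resamples rows with replacement,
#' re-standardizes within each replicate, and recomputes every path; the
#' reported SE is the replicate SD and the CI the empirical percentiles.
#' In sample, `c_total = c_prime + sum(indirect effects)` holds exactly.
#'
#' @param data A cohort `data.frame`, typically after
#'   [preprocess_cognition()] with a pattern-expression column added.
#' @param spec A [mediation_spec()].
#' @return An object of class `mediation_result` with elements `paths`
#'   (estimate, SE, t, p per standardized path), `effects` (direct, total
#'   and indirect effects with bootstrap SE, percentile CI and
#'   significance flag), `n_used`, `n_boot`, `n_failed`, `seed`, `spec`.
#' @export
fit_mediation <- function(data, spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  vars <- c(spec$x, spec$mediators, spec$y, spec$covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("data is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  M <- as.matrix(data[, vars, drop = FALSE])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  n <- nrow(M)
  if (n < 10L + length(vars) - 1L) {
    stop(sprintf("too few complete rows (%d) for %d predictors",
                 n, length(vars) - 1L), call. = FALSE)
  }
  n_med <- length(spec$mediators)
  n_cov <- length(spec$covariates)
  cont <- !apply(M, 2L, is_binary)

  standardize <- function(M) {
    for (j in which(cont)) {
      s <- stats::sd(M[, j])
      if (s == 0) return(NULL)
      M[, j] <- (M[, j] - mean(M[, j])) / s
    }
    M
  }
  Z <- standardize(M)
  if (is.null(Z)) {
    stop("a continuous variable is constant after listwise deletion",
         call. = FALSE)
  }

  # point estimates with t-test p-values (full OLS on standardized design)
  pt_paths <- med_paths(Z, n_med, n_cov)
  if (is.null(pt_paths)) {
    # identify the offending columns for the error message
    X <- cbind(1, Z[, c(1L, 2L:(1L + n_med),
                        if (n_cov > 0) (2L + n_med + 1L):ncol(Z)),
                    drop = FALSE])
    colnames(X) <- c("(Intercept)", spec$x, spec$mediators, spec$covariates)
    ols_full(X, Z[, 2L + n_med])  # raises the collinearity error
    stop("collinear design", call. = FALSE)
  }
  path_tests <- med_path_tests(Z, spec, n_med, n_cov)
  indirect <- med_indirect(pt_paths, n_med)

  set.seed(spec$seed)
  stats_names <- c(names(indirect), "c_prime", "c_total")
  boot <- matrix(NA_real_, spec$n_boot, length(stats_names),
                 dimnames = list(NULL, stats_names))
  n_failed <- 0L
  for (b in seq_len(spec$n_boot)) {
    Zb <- standardize(M[sample.int(n, n, replace = TRUE), , drop = FALSE])
    if (is.null(Zb)) { n_failed <- n_failed + 1L; next }
    pb <- med_paths(Zb, n_med, n_cov)
    if (is.null(pb)) { n_failed <- n_failed + 1L; next }
    boot[b, ] <- c(med_indirect(pb, n_med), pb["c_prime"], pb["c_total"])
  }
  ok <- !is.na(boot[, 1L])
  alpha <- (1 - spec$ci_level) / 2
  est <- c(indirect, c_prime = unname(pt_paths["c_prime"]),
           c_total = unname(pt_paths["c_total"]))
  ci <- apply(boot[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  effects <- data.frame(effect = stats_names, estimate = unname(est),
                        boot_se = apply(boot[ok, , drop = FALSE], 2L,
                                        stats::sd),
                        ci_low = ci[1L, ], ci_high = ci[2L, ],
                        stringsAsFactors = FALSE, row.names = NULL)
  effects$significant <- effects$ci_low > 0 | effects$ci_high < 0

  structure(list(paths = path_tests, effects = effects, n_used = n,
                 n_boot = spec$n_boot, n_failed = n_failed,
                 seed = spec$seed, spec = spec),
            class = "mediation_result")
}

# per-path OLS t-tests on the standardized point-estimate design
med_path_tests <- function(Z, spec, n_med, n_cov) {
  x <- Z[, 1L]; m1 <- Z[, 2L]; yv <- Z[, 2L + n_med]
  C <- if (n_cov > 0) Z[, (2L + n_med + 1L):ncol(Z), drop = FALSE] else NULL
  run <- function(resp, ..., labels) {
    X <- cbind(1, ..., C)
    fit <- ols_full(X, resp)
    data.frame(path = labels,
               estimate = fit$coef[seq_along(labels) + 1L],
               se = fit$se[seq_along(labels) + 1L],
               p = fit$p[seq_along(labels) + 1L],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (n_med == 1L) {
    out <- rbind(run(m1, x, labels = "a1"),
                 run(yv, x, m1, labels = c("c_prime", "b1")),
                 run(yv, x, labels = "c_total"))
  } else {
    m2 <- Z[, 3L]
    out <- rbind(run(m1, x, labels = "a1"),
                 run(m2, x, m1, labels = c("a2", "d21")),
                 run(yv, x, m1, m2, labels = c("c_prime", "b1", "b2")),
                 run(yv, x, labels = "c_total"))
  }
  out[order(match(out$path,
                  c("a1", "a2", "d21", "b1", "b2", "c_prime", "c_total"))), ,
      drop = FALSE]
}

#' @export
print.mediation_result <- function(x, ...) {
  sp <- x$spec
  kind <- if (length(sp$mediators) == 1L) "Simple" else "Serial"
  cat(sprintf("%s mediation: %s -> %s -> %s (n = %d, %d bootstrap replicates)\n",
              kind, sp$x, paste(sp$mediators, collapse = " -> "), sp$y,
              x$n_used, x$n_boot))
  paths <- x$paths
  paths$estimate <- round(paths$estimate, 3)
  paths$se <- round(paths$se, 3)
  paths$p <- signif(paths$p, 3)
  print(paths, row.names = FALSE)
  eff <- x$effects
  eff$estimate <- round(eff$estimate, 3)
  eff$boot_se <- round(eff$boot_se, 3)
  eff$ci_low <- round(eff$ci_low, 3)
  eff$ci_high <- round(eff$ci_high, 3)
  print(eff, row.names = FALSE)
  invisible(x)
}
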