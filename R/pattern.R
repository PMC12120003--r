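#' Natural-log WMH volume
#'
#' @param cohort Cohort `data.frame` with a strictly positive `wmh_ml`
#'   column (total white-matter-hyperintensity volume, mL).
#' @return Numeric vector of natural-log WMH volumes.
#' @export
log_wmh <- function(cohort) {
  if (!"wmh_ml" %in% names(cohort)) {
    stop("cohort is missing column 'wmh_ml'", call. = FALSE)
  }
  w <- cohort$wmh_ml
  if (anyNA(w) || any(w <= 0)) {
    stop("WMH volume must be strictly positive for all subjects",
         call. = FALSE)
  }
  log(w)
}

#' Select the WMH-related pattern by BIC over nested component regressions
#'
#' For k = 1..k_max, regresses log WMH on the participant scores of the
#' first k SSM components (ordinary least squares with intercept) and
#' computes BIC(k) = n*log(RSS/n) + (k+1)*log(n). The k minimizing BIC is
#' selected (ties within 1e-9 resolve to the smaller k). The combined
#' regional weights are the coefficient-weighted sum of the selected
#' loadings, unit-normalized; per-subject pattern expression is the
#' z-scored fitted combination of component scores. The global sign is
#' anchored so expression correlates nonnegatively with log WMH.
#'
#' @param decomp An [ssm_decompose()] result.
#' @param y Numeric vector of log WMH volumes, one per subject.
#' @param k_max Largest candidate model size; default
#'   `min(n - 2, p - 1, 10)`.
#' @return An object of class `combined_pattern` with `weights` (unit norm,
#'   sign-anchored), `expression` (mean 0, SD 1), `k_selected`, `beta`,
#'   `r2`, `adj_r2`, `f_stat`, `df`, `bic_path`, and the training
#'   conventions (`region_means`, `proj_mean`, `proj_sd`) needed by
#'   [express_pattern()].
#' @export
select_pattern <- function(decomp, y, k_max = NULL) {
  stopifnot(inherits(decomp, "ssm_decomposition"))
  S <- decomp$scores
  n <- nrow(S)
  if (length(y) != n) stop("length(y) must equal the number of subjects",
                           call. = FALSE)
  p <- length(decomp$region_names)
  if (is.null(k_max)) k_max <- min(n - 2L, p - 1L, 10L)
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 1L) {
    stop("invalid parameter 'k_max': must be a positive integer",
         call. = FALSE)
  }
  if (k_max > ncol(S)) {
    stop(sprintf("k_max (%d) exceeds available components (%d)",
                 k_max, ncol(S)), call. = FALSE)
  }
  if (n <= k_max + 2L) {
    stop("need n > k_max + 2 subjects for model selection", call. = FALSE)
  }

  bic_path <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    X <- cbind(`(Intercept)` = 1, S[, seq_len(k), drop = FALSE])
    cf <- ols_coef(X, y)
    if (is.null(cf)) {
      stop(sprintf("rank-deficient design at k = %d", k), call. = FALSE)
    }
    rss <- sum((y - X %*% cf)^2)
    bic_path[k] <- n * log(rss / n) + (k + 1) * log(n)
    fits[[k]] <- list(coef = cf, rss = rss)
  }
  k_sel <- min(which(bic_path <= min(bic_path) + 1e-9))

  beta <- fits[[k_sel]]$coef[-1L]
  rss <- fits[[k_sel]]$rss
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k_sel - 1)
  f_stat <- (r2 / k_sel) / ((1 - r2) / (n - k_sel - 1))

  w_raw <- drop(decomp$loadings[, seq_len(k_sel), drop = FALSE] %*% beta)
  if (sqrt(sum(w_raw^2)) < 1e-12) {
    stop("degenerate pattern: combined weights have zero norm", call. = FALSE)
  }
  lin <- drop(S[, seq_len(k_sel), drop = FALSE] %*% beta)
  sgn <- if (stats::cor(lin, y) < 0) -1 else 1
  weights <- sgn * w_raw / sqrt(sum(w_raw^2))
  names(weights) <- decomp$region_names

  # projection-route standardization constants: raw projection of the
  # training residuals onto the unit weights
  proj <- sgn * lin / sqrt(sum(w_raw^2))
  proj_mean <- mean(proj)
  proj_sd <- stats::sd(proj)
  expression <- (proj - proj_mean) / proj_sd

  structure(list(weights = weights, expression = expression,
                 k_selected = k_sel, beta = sgn * beta,
                 r2 = r2, adj_r2 = adj_r2, f_stat = f_stat,
                 df = c(k_sel, n - k_sel - 1L), bic_path = bic_path,
                 region_names = decomp$region_names,
                 region_means = decomp$region_means,
                 proj_mean = proj_mean, proj_sd = proj_sd),
            class = "combined_pattern")
}

#' Score a cohort against a fitted pattern
#'
#' Forward application of a combined pattern to (possibly new) subjects:
#' log-transform the region volumes, remove each subject's own mean
#' (global-size adjustment), remove the stored training region means, dot
#' with the unit weights, and standardize by the training projection
#' mean/SD. On the training cohort this reproduces `pattern$expression`.
#'
#' @param pattern A `combined_pattern` from [select_pattern()].
#' @param cohort Cohort `data.frame` containing all pattern regions.
#' @return Numeric vector of standardized pattern expression scores.
#' @export
express_pattern <- function(pattern, cohort) {
  stopifnot(inherits(pattern, "combined_pattern"))
  lm_ <- log_volume_matrix(cohort, pattern$region_names)
  resid <- sweep(lm_ - rowMeans(lm_), 2L, pattern$region_means)
  proj <- unname(drop(resid %*% pattern$weights))
  (proj - pattern$proj_mean) / pattern$proj_sd
}

#' @export
print.combined_pattern <- function(x, ...) {
  cat(sprintf("WMH-related pattern: %d components (BIC-selected)\n",
              x$k_selected))
  cat(sprintf("  R^2 = %.3f (adj. %.3f), F(%d,%d) = %.2f\n",
              x$r2, x$adj_r2, x$df[1], x$df[2], x$f_stat))
  ord <- order(x$weights)
  cat("  most negative:", paste(names(x$weights)[ord[1:2]], collapse = ", "),
      "| most positive:",
      paste(names(x$weights)[rev(ord)[1:2]], collapse = ", "), "\n")
  invisible(x)
}
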