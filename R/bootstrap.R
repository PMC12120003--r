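# single pass: double-center a log-volume matrix, decompose, regress y on
# the first k component scores, return unit-norm combined weights (sign
# anchored to corr(fitted, y) >= 0); NULL when the design is degenerate
fit_weights_fixed_k <- function(logmat, y, k) {
  X <- logmat - rowMeans(logmat)
  X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X, nu = k, nv = k)
  d <- sv$d
  if (d[k] < 1e-10 * d[1]) return(NULL)
  S <- sv$u %*% diag(d[seq_len(k)], k, k)
  Xd <- cbind(1, S)
  cf <- ols_coef(Xd, y)
  if (is.null(cf)) return(NULL)
  beta <- cf[-1L]
  w <- drop(sv$v %*% beta)
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12) return(NULL)
  w <- w / nrm
  if (stats::cor(drop(S %*% beta), y) < 0) w <- -w
  w
}

#' Bootstrap confidence intervals for regional pattern weights
#'
#' Subject-resampling percentile bootstrap around the combined pattern at a
#' fixed number of components. Each replicate redraws `n` subjects with
#' replacement, reruns the log transform, double centering, decomposition
#' and the k-component regression of log WMH on component scores (no BIC
#' reselection unless `reselect = TRUE`), unit-normalizes the replicate
#' weights, and flips their sign so the dot product with the point-estimate
#' weights is nonnegative. Per-region confidence bounds are the empirical
#' percentiles of the aligned replicates; a region is flagged significant
#' when its interval excludes zero.
#'
#' @param cohort Cohort `data.frame`.
#' @param k_fixed Number of components, normally the BIC-selected
#'   `k_selected` of the point-estimate pattern.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param region_names Region labels (default [default_region_names()]).
#' @param level Confidence level (default 0.95).
#' @param reselect If `TRUE`, rerun BIC selection within each replicate
#'   instead of holding k fixed (sensitivity mode).
#' @param keep_replicates Keep the aligned replicate weight matrix in the
#'   result (default `TRUE`; needed to audit the percentile bounds).
#' @return An object of class `bootstrap_weights`: a `data.frame` with
#'   columns `region`, `weight`, `ci_low`, `ci_high`, `significant`, plus
#'   attributes `n_boot`, `seed`, `n_failed`, `alignment`, `level` and
#'   (optionally) `replicates`.
#' @export
bootstrap_pattern <- function(cohort, k_fixed, n_boot = 1000L, seed = 1L,
                              region_names = default_region_names(),
                              level = 0.95, reselect = FALSE,
                              keep_replicates = TRUE) {
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 100L) {
    stop("invalid parameter 'n_boot': need at least 100 replicates",
         call. = FALSE)
  }
  logmat <- log_volume_matrix(cohort, region_names)
  y <- log_wmh(cohort)
  n <- nrow(logmat)
  p <- ncol(logmat)
  k_fixed <- as.integer(k_fixed)
  if (is.na(k_fixed) || k_fixed < 1L || k_fixed > min(n - 1L, p - 1L)) {
    stop("invalid parameter 'k_fixed': must be in [1, min(n-1, p-1)]",
         call. = FALSE)
  }

  w0 <- fit_weights_fixed_k(logmat, y, k_fixed)
  if (is.null(w0)) {
    stop("point-estimate pattern is degenerate at k_fixed", call. = FALSE)
  }

  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, p)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    lb <- logmat[idx, , drop = FALSE]
    yb <- y[idx]
    kb <- k_fixed
    if (reselect) {
      cmb <- double_center(lb)
      db <- ssm_decompose(cmb)
      kb <- tryCatch(select_pattern(db, yb)$k_selected,
                     error = function(e) NA_integer_)
      if (is.na(kb)) { n_failed <- n_failed + 1L; next }
    }
    wb <- fit_weights_fixed_k(lb, yb, kb)
    if (is.null(wb)) { n_failed <- n_failed + 1L; next }
    dp <- sum(wb * w0)
    if (abs(dp) < 1e-12) { n_failed <- n_failed + 1L; next }
    if (dp < 0) wb <- -wb
    reps[b, ] <- wb
  }
  if (n_failed / n_boot > 0.01) {
    warning(sprintf("%d of %d bootstrap replicates were degenerate and discarded",
                    n_failed, n_boot))
  }
  ok <- !is.na(reps[, 1L])
  alpha <- (1 - level) / 2
  ci <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  out <- data.frame(region = region_names, weight = unname(w0),
                    ci_low = ci[1L, ], ci_high = ci[2L, ],
                    stringsAsFactors = FALSE)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "n_failed") <- n_failed
  attr(out, "level") <- level
  attr(out, "alignment") <- "dot-product-with-point-estimate"
  if (keep_replicates) {
    colnames(reps) <- region_names
    attr(out, "replicates") <- reps[ok, , drop = FALSE]
  }
  class(out) <- c("bootstrap_weights", "data.frame")
  out
}

#' @export
print.bootstrap_weights <- function(x, ...) {
  cat(sprintf("Bootstrap pattern weights: %d replicates (%d discarded), %.0f%% percentile CIs\n",
              attr(x, "n_boot"), attr(x, "n_failed"),
              100 * attr(x, "level")))
  df <- as.data.frame(x)
  df$weight <- round(df$weight, 3)
  df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
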