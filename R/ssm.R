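#' Natural-log region volume matrix
#'
#' Extracts the named region columns from a cohort table and returns the
#' subjects x regions matrix of natural-log volumes, the first step of the
#' Scaled Subprofile Model.
#'
#' @param cohort Cohort `data.frame` with one column per region (mm^3).
#' @param region_names Ordered region labels; fixes the column order.
#' @return Numeric matrix, `n_subjects` x `length(region_names)`.
#' @export
log_volume_matrix <- function(cohort, region_names = default_region_names()) {
  missing_cols <- setdiff(region_names, names(cohort))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort is missing region column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(cohort[, region_names, drop = FALSE])
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing volume for subject %d, region '%s'",
                 bad[1], region_names[bad[2]]), call. = FALSE)
  }
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive volume for subject %d, region '%s'",
                 bad[1], region_names[bad[2]]), call. = FALSE)
  }
  lm_ <- log(m)
  colnames(lm_) <- region_names
  rownames(lm_) <- if ("subject_id" %in% names(cohort)) cohort$subject_id
                   else NULL
  lm_
}

#' Double-center a log-volume matrix
#'
#' Removes each subject's mean log volume (the global-size adjustment) and
#' then each region's mean of the row-centered values (the group mean
#' profile). Both removed vectors are stored so new subjects can later be
#' scored against the same training means. Row and column centering
#' commute, so the order is immaterial.
#'
#' @param logmat Numeric matrix of natural-log volumes, no missing entries.
#' @return An object of class `centered_matrix` with elements `values`
#'   (double-centered residuals), `subject_means`, `region_means`,
#'   `region_names`.
#' @export
double_center <- function(logmat) {
  if (anyNA(logmat)) {
    stop("log-volume matrix contains missing entries; region volumes may not be imputed",
         call. = FALSE)
  }
  subject_means <- rowMeans(logmat)
  rc <- logmat - subject_means
  region_means <- colMeans(rc)
  values <- sweep(rc, 2L, region_means)
  structure(list(values = values,
                 subject_means = subject_means,
                 region_means = region_means,
                 region_names = colnames(logmat)),
            class = "centered_matrix")
}

#' Scaled Subprofile Model decomposition
#'
#' Principal component analysis of the double-centered log-volume residual
#' matrix, computed by singular value decomposition. Loadings (regional
#' weight vectors) are the right singular vectors (orthonormal); participant
#' scores are left singular vectors scaled by the singular values;
#' eigenvalues are squared singular values over `n - 1`. Components are
#' ordered by decreasing eigenvalue, and each loading column is signed so
#' its largest-magnitude element is positive.
#'
#' @param cm A `centered_matrix` from [double_center()].
#' @return An object of class `ssm_decomposition` with `loadings` (p x K),
#'   `scores` (n x K), `eigenvalues`, `variance_fraction`, `region_names`,
#'   and the training `region_means` carried along for out-of-sample use.
#' @export
ssm_decompose <- function(cm) {
  stopifnot(inherits(cm, "centered_matrix"))
  X <- cm$values
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 subjects to decompose", call. = FALSE)
  if (p < 2L) stop("need at least 2 regions to decompose", call. = FALSE)
  K <- min(n - 1L, p - 1L)
  sv <- svd(X, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  loadings <- sv$v
  scores <- sv$u %*% diag(d, K, K)
  # deterministic sign: largest-|.| loading element positive per component
  for (j in seq_len(K)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- cm$region_names
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(K))
  total_ss <- sum(X^2)
  structure(list(loadings = loadings, scores = scores,
                 eigenvalues = d^2 / (n - 1L),
                 variance_fraction = if (total_ss > 0) d^2 / total_ss
                                     else rep(0, K),
                 region_names = cm$region_names,
                 region_means = cm$region_means,
                 n_subjects = n),
            class = "ssm_decomposition")
}

#' @export
print.ssm_decomposition <- function(x, ...) {
  cat(sprintf("SSM decomposition: %d subjects x %d regions, %d components\n",
              x$n_subjects, length(x$region_names), ncol(x$loadings)))
  vf <- round(100 * x$variance_fraction[seq_len(min(5, ncol(x$loadings)))], 1)
  cat("  leading variance fractions (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}
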