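# independent oracles and small fixture builders used across test files

# dense centering-projector route: (I - J/n) M (I - J/p)
oracle_double_center <- function(M) {
  n <- nrow(M); p <- ncol(M)
  Pn <- diag(n) - matrix(1 / n, n, n)
  Pp <- diag(p) - matrix(1 / p, p, p)
  Pn %*% M %*% Pp
}

# eigendecomposition of the p x p covariance of the centered values
oracle_cov_eigen <- function(values) {
  eigen(crossprod(values) / (nrow(values) - 1), symmetric = TRUE)
}

# brute-force nested-model BIC path via normal equations on raw matrices
oracle_bic_path <- function(S, y, k_max) {
  n <- length(y)
  vapply(seq_len(k_max), function(k) {
    X <- cbind(1, S[, seq_len(k), drop = FALSE])
    beta <- solve(t(X) %*% X, t(X) %*% y)
    rss <- sum((y - X %*% beta)^2)
    n * log(rss / n) + (k + 1) * log(n)
  }, numeric(1))
}

oracle_ols <- function(X, y) unname(drop(solve(t(X) %*% X, t(X) %*% y)))

# random log-volume-like matrix (positive volumes, mild structure)
random_logvol <- function(n, p, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * p, mean = 8, sd = 0.3), n, p,
         dimnames = list(NULL, paste0("r", seq_len(p))))
}

quick_cohort <- function(n = 178, seed = 1, ...) {
  generate_cohort(cohort_params(n_subjects = n, seed = seed, ...))
}

# direct standardized-path simulators for mediation recovery checks;
# population variances are unity so coefficients are the planted values
sim_simple_paths <- function(n, a1, b1, cp, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- a1 * x + sqrt(1 - a1^2) * stats::rnorm(n)
  vres <- 1 - cp^2 - b1^2 - 2 * cp * b1 * a1
  y <- cp * x + b1 * m + sqrt(max(vres, 0.05)) * stats::rnorm(n)
  data.frame(x = x, m = m, y = y)
}

sim_serial_paths <- function(n, a1, d21, b2, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  m1 <- a1 * x + sqrt(1 - a1^2) * stats::rnorm(n)
  m2 <- d21 * m1 + sqrt(1 - d21^2) * stats::rnorm(n)
  y <- b2 * m2 + sqrt(max(1 - b2^2, 0.05)) * stats::rnorm(n)
  data.frame(x = x, m1 = m1, m2 = m2, y = y)
}
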