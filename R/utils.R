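# internal numerical helpers shared across modules

# z-score with explicit guard: a constant vector cannot be standardized
zscore <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("cannot standardize '%s': zero or undefined variance", what),
         call. = FALSE)
  }
  (x - mean(x)) / s
}

is_binary <- function(x) all(x %in% c(0, 1))

# coefficient-only least squares on an explicit design matrix; returns NULL
# on rank deficiency instead of silently dropping columns
ols_coef <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)
  cf <- fit$coefficients
  names(cf) <- colnames(X)
  cf
}

# full least squares with t-test p-values (used only for point estimates)
ols_full <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    piv <- qrX$pivot
    bad <- colnames(X)[piv[seq.int(qrX$rank + 1L, ncol(X))]]
    stop(sprintf("collinear design: offending column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cf <- qr.coef(qrX, y)
  res <- y - X %*% cf
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- cf / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  list(coef = cf, se = se, t = tval, p = pval, df = n - p,
       rss = sum(res^2), fitted = drop(X %*% cf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
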