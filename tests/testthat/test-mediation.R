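test_that("cognition preprocessing: logs and raw-score residualization", {
  co <- quick_cohort(n = 80, seed = 111)
  out <- preprocess_cognition(co)
  expect_equal(out$log_tmt_a, log(co$tmt_a_sec), tolerance = 1e-12)
  expect_equal(out$log_gpt, log(co$gpt_sec), tolerance = 1e-12)

  # residual matches a two-pass normal-equations oracle on complete pairs
  ok <- complete.cases(co$tmt_a_sec, co$tmt_b_sec)
  X <- cbind(1, co$tmt_a_sec[ok])
  res <- co$tmt_b_sec[ok] - X %*% solve(t(X) %*% X, t(X) %*% co$tmt_b_sec[ok])
  expect_equal(out$tmt_b_resid[ok], as.numeric(scale(res)), tolerance = 1e-10)
  expect_true(all(is.na(out$tmt_b_resid[!ok])))
  expect_true(all(is.na(out$log_gpt[is.na(co$gpt_sec)])))

  # TMT-B exactly proportional to TMT-A leaves no shifting residual
  co2 <- co
  co2$tmt_b_sec <- 2.3 * co2$tmt_a_sec
  expect_lt(max(abs(preprocess_cognition(co2)$tmt_b_resid), na.rm = TRUE),
            1e-8)

  co$tmt_a_sec[3] <- -1
  expect_error(preprocess_cognition(co), "nonpositive timed score")

  # a single row still gets its logs; residualization needs >= 3 pairs
  simple <- data.frame(tmt_a_sec = 30, tmt_b_sec = 60, gpt_sec = 90)
  one <- preprocess_cognition(simple)
  expect_equal(one$log_tmt_a, log(30), tolerance = 1e-6)
  expect_true(is.na(one$tmt_b_resid))
})

test_that("path coefficients equal an independent normal-equations solve", {
  co <- preprocess_cognition(quick_cohort(n = 150, seed = 121))
  d <- ssm_decompose(double_center(log_volume_matrix(co)))
  co$pattern_expression <- select_pattern(d, log_wmh(co))$expression

  covs <- covariate_set("base")
  spec <- mediation_spec("age", c("pattern_expression", "log_tmt_a"),
                         "srt_cltr", covariates = covs, n_boot = 200,
                         seed = 2)
  fit <- fit_mediation(co, spec)

  vars <- c("age", "pattern_expression", "log_tmt_a", "srt_cltr", covs)
  M <- as.matrix(co[, vars])
  M <- M[complete.cases(M), ]
  for (j in seq_len(ncol(M))) {
    if (!all(M[, j] %in% c(0, 1))) M[, j] <- drop(scale(M[, j]))
  }
  Cv <- M[, covs]
  cf_m1 <- oracle_ols(cbind(1, M[, "age"], Cv), M[, "pattern_expression"])
  cf_m2 <- oracle_ols(cbind(1, M[, "age"], M[, "pattern_expression"], Cv),
                      M[, "log_tmt_a"])
  cf_y <- oracle_ols(cbind(1, M[, "age"], M[, "pattern_expression"],
                           M[, "log_tmt_a"], Cv), M[, "srt_cltr"])
  cf_t <- oracle_ols(cbind(1, M[, "age"], Cv), M[, "srt_cltr"])

  est <- function(p) fit$paths$estimate[fit$paths$path == p]
  expect_equal(est("a1"), cf_m1[2], tolerance = 1e-10)
  expect_equal(est("a2"), cf_m2[2], tolerance = 1e-10)
  expect_equal(est("d21"), cf_m2[3], tolerance = 1e-10)
  expect_equal(est("c_prime"), cf_y[2], tolerance = 1e-10)
  expect_equal(est("b1"), cf_y[3], tolerance = 1e-10)
  expect_equal(est("b2"), cf_y[4], tolerance = 1e-10)
  expect_equal(est("c_total"), cf_t[2], tolerance = 1e-10)

  # listwise deletion: one missing TMT-B and one missing GPT by default,
  # but this serial model only uses TMT-A, so only rows lost elsewhere drop
  expect_identical(fit$n_used, sum(complete.cases(co[, vars])))
})

test_that("total effect decomposes into direct plus indirect in-sample", {
  co <- preprocess_cognition(quick_cohort(n = 150, seed = 131))
  d <- ssm_decompose(double_center(log_volume_matrix(co)))
  co$pattern_expression <- select_pattern(d, log_wmh(co))$expression

  for (meds in list("pattern_expression",
                    c("pattern_expression", "log_tmt_a"))) {
    fit <- fit_mediation(co, mediation_spec("age", meds, "wais_lns",
                                            n_boot = 200, seed = 4))
    eff <- setNames(fit$effects$estimate, fit$effects$effect)
    indirect <- sum(eff[startsWith(names(eff), "ind_")])
    expect_equal(eff[["c_total"]], eff[["c_prime"]] + indirect,
                 tolerance = 1e-8)
    expect_true(all(fit$effects$boot_se >= 0))
    expect_true(all(fit$effects$ci_low <= fit$effects$ci_high))
  }
})

test_that("completely standardized effects are scale invariant", {
  co <- preprocess_cognition(quick_cohort(n = 120, seed = 141))
  d <- ssm_decompose(double_center(log_volume_matrix(co)))
  co$pattern_expression <- select_pattern(d, log_wmh(co))$expression
  spec <- mediation_spec("age", c("pattern_expression", "log_tmt_a"),
                         "scwt", n_boot = 150, seed = 6)
  f1 <- fit_mediation(co, spec)
  co2 <- co
  co2$age <- co2$age * 12          # months instead of years
  co2$scwt <- co2$scwt * 4.5
  co2$tiv <- co2$tiv / 1000       # mL instead of mm^3
  f2 <- fit_mediation(co2, spec)
  expect_equal(f2$paths$estimate, f1$paths$estimate, tolerance = 1e-10)
  expect_equal(f2$effects$estimate, f1$effects$estimate, tolerance = 1e-10)
})

test_that("degenerate designs raise a collinearity error naming columns", {
  co <- preprocess_cognition(quick_cohort(n = 100, seed = 151))
  d <- ssm_decompose(double_center(log_volume_matrix(co)))
  co$pattern_expression <- select_pattern(d, log_wmh(co))$expression
  co$m2_copy <- co$pattern_expression  # second mediator identical to first
  expect_error(fit_mediation(co, mediation_spec("age",
                                                c("pattern_expression",
                                                  "m2_copy"),
                                                "scwt", n_boot = 150,
                                                seed = 6)),
               "collinear")
  expect_error(mediation_spec("age", c("m", "m"), "y"), "disjoint")
  expect_error(mediation_spec("age", character(0), "y"), "mediators")
})

test_that("planted simple and serial effects are recovered at scale", {
  dat <- sim_simple_paths(5000, a1 = 0.5, b1 = 0.4, cp = 0.2, seed = 9)
  fit <- fit_mediation(dat, mediation_spec("x", "m", "y",
                                           covariates = character(0),
                                           n_boot = 400, seed = 10))
  ind <- fit$effects[fit$effects$effect == "ind_m1", ]
  expect_lt(abs(ind$estimate - 0.2), 0.03)
  expect_true(ind$significant)

  dat2 <- sim_serial_paths(5000, a1 = 0.5, d21 = 0.3, b2 = -0.4, seed = 11)
  fit2 <- fit_mediation(dat2, mediation_spec("x", c("m1", "m2"), "y",
                                             covariates = character(0),
                                             n_boot = 400, seed = 12))
  ser <- fit2$effects[fit2$effects$effect == "ind_serial", ]
  expect_lt(abs(ser$estimate - (-0.06)), 0.02)
  expect_true(ser$significant)

  # determinism of the bootstrap machinery
  fit2b <- fit_mediation(dat2, mediation_spec("x", c("m1", "m2"), "y",
                                              covariates = character(0),
                                              n_boot = 400, seed = 12))
  expect_identical(fit2$effects, fit2b$effects)
})
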