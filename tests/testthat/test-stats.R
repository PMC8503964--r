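test_that("summaries give raw-scale means and n-1 SDs per key", {
  recs <- fake_records(1)[rep(1, 10), ]
  recs$matched_contrast <- 0.31
  recs$trial_index <- 1:10
  s <- summarize_matches(recs)
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean_match, 0.31)
  expect_equal(s$sd_match, 0)
  expect_identical(s$n, 10L)
})

test_that("summaries agree with a direct two-pass oracle", {
  recs <- fake_records(400, seed = 6)
  s <- summarize_matches(recs)
  for (i in seq_len(nrow(s))) {
    sel <- recs$observer_id == s$observer_id[i] &
      recs$condition == s$condition[i] &
      recs$upper_contrast == s$upper_contrast[i]
    v <- recs$matched_contrast[sel]
    m <- sum(v) / length(v)
    expect_equal(s$mean_match[i], m, tolerance = 1e-12)
    expect_equal(s$sd_match[i], sqrt(sum((v - m)^2) / (length(v) - 1)),
                 tolerance = 1e-12)
    expect_identical(s$n[i], length(v))
  }
})

test_that("practice trials are excluded from summaries by default", {
  recs <- fake_records(60, seed = 2)
  recs$is_practice <- rep(c(TRUE, FALSE), each = 30)
  expect_identical(sum(summarize_matches(recs)$n), 30L)
  expect_identical(sum(summarize_matches(recs, include_practice = TRUE)$n),
                   60L)
  expect_error(summarize_matches(recs[0, ]))
})

test_that("noise-free default observer yields the quantised model match", {
  p <- observer_params(sigma_eps = 0)
  recs <- run_headless_session(session_config("replication", "control",
                                              seed = 44), p)
  s <- summarize_matches(recs)
  rs <- replication_scale()
  for (i in seq_len(nrow(s))) {
    want <- contrast_at(rs, nearest_position(
      rs, exp(expected_log_match(p, "control", s$upper_contrast[i]))))
    expect_equal(s$mean_match[i], want, tolerance = 1e-12)
    expect_equal(s$sd_match[i], 0)
  }
})

test_that("fit_loglog is exact on collinear data", {
  x <- c(0.02, 0.05, 0.1, 0.3, 0.7)
  f <- suppressWarnings(fit_loglog(x, exp(-0.4) * x^1.2))
  expect_equal(f$slope, 1.2, tolerance = 1e-12)
  expect_equal(f$intercept, -0.4, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_lt(f$rmse, 1e-12)
})

test_that("fit_loglog matches the normal-equations oracle on random data", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    u <- exp(runif(n, log(0.01), 0))
    m <- exp(rnorm(n, 0.8 * log(u) - 0.1, 0.2))
    f <- fit_loglog(u, m)
    o <- ols_oracle(log(u), log(m))
    expect_equal(f$slope, o$slope, tolerance = 1e-9)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(f$coefficients$se[2], o$se_slope, tolerance = 1e-9)
    expect_equal(f$coefficients$se[1], o$se_intercept, tolerance = 1e-9)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-9)
    expect_equal(f$rmse, o$rmse, tolerance = 1e-9)
    expect_equal(f$f_statistic, o$f, tolerance = 1e-7)
    expect_identical(f$error_df, n - 2L)
  }
})

test_that("R-squared equals the squared correlation of fitted and observed", {
  set.seed(23)
  u <- exp(runif(20, log(0.02), 0))
  m <- exp(rnorm(20, log(u), 0.3))
  f <- fit_loglog(u, m)
  expect_equal(f$r_squared, cor(fitted(f$lm), log(m))^2, tolerance = 1e-12)
})

test_that("fit_loglog validates its inputs", {
  expect_error(fit_loglog(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
  expect_error(fit_loglog(rep(0.3, 5), runif(5)), "degenerate")
  expect_error(fit_loglog(c(0.1, 0.2, 0.3), c(0, 0.2, 0.3)), "> 0")
})

test_that("the desk replication reproduces the reference fit layout", {
  rep2 <- replicate_table2()
  expect_identical(rep2$control$n_obs, 22L)
  expect_identical(rep2$control$error_df, 20L)
  expect_identical(rep2$adaptation$n_obs, 12L)
  expect_identical(rep2$adaptation$error_df, 10L)
  expect_gt(rep2$control$slope, 0)
  expect_gt(rep2$adaptation$slope, rep2$control$slope)
  # CI brackets the estimate
  expect_true(all(rep2$control$coefficients$ci_lo <
                    rep2$control$coefficients$estimate &
                    rep2$control$coefficients$estimate <
                    rep2$control$coefficients$ci_hi))
})

test_that("noise-free generative data are recovered exactly", {
  p <- observer_params(beta0 = -0.084, beta1 = 0.982, beta2 = 0.052,
                       beta3 = 0.443, sigma_eps = 0)
  recs <- model_records(p, n_obs = 2)
  sc <- summarize_matches(recs)
  ctrl <- sc[sc$condition == "control", ]
  f <- suppressWarnings(fit_loglog(ctrl$upper_contrast, ctrl$mean_match))
  expect_equal(f$slope, p$beta1, tolerance = 1e-9)
  expect_equal(f$intercept, p$beta0, tolerance = 1e-9)
  ad <- sc[sc$condition == "adaptation", ]
  fa <- suppressWarnings(fit_loglog(ad$upper_contrast, ad$mean_match))
  expect_equal(fa$slope, p$beta1 + p$beta3, tolerance = 1e-9)
  expect_equal(fa$intercept, p$beta0 + p$beta2, tolerance = 1e-9)
})

test_that("the mixed model degenerates to OLS when groups carry no signal", {
  # identical noise per observer => zero between-observer variance
  set.seed(31)
  p <- observer_params(sigma_eps = 0)
  recs <- model_records(p, n_obs = 3)
  noise <- rnorm(nrow(recs) / 3, 0, 0.25)
  recs$matched_contrast <- exp(log(recs$matched_contrast) + rep(noise, 3))
  f <- fit_lmm(recs)
  ols <- lm(log(matched_contrast) ~ I(condition == "adaptation") *
              log(upper_contrast), data = recs)
  expect_true(f$boundary)
  expect_equal(f$sigma_id, 0)
  expect_equal(unname(f$fixed$estimate), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("the profiled likelihood at the optimum dominates the OLS fit", {
  recs <- simulate_replication_experiment(seed = 91)
  f <- fit_lmm(recs)
  ols_ll <- as.numeric(logLik(lm(
    log(matched_contrast) ~ I(condition == "adaptation") *
      log(upper_contrast), data = recs)))
  expect_gte(f$logLik, ols_ll)
  expect_gte(f$logLik + 1e-8, max(f$trace[, "loglik"]))
  expect_equal(f$deviance, -2 * f$logLik)
  expect_equal(f$AIC, f$deviance + 2 * f$n_par)
  expect_identical(f$fixed$df, rep(f$n_obs - 4L, 4))
})

test_that("the mixed model agrees with an independent ML fitter", {
  skip_if_not_installed("lme4")
  recs <- simulate_replication_experiment(seed = 17)
  f <- fit_lmm(recs)
  d <- data.frame(y = log(recs$matched_contrast),
                  lx = log(recs$upper_contrast),
                  ad = as.numeric(recs$condition == "adaptation"),
                  id = recs$observer_id)
  m <- lme4::lmer(y ~ ad * lx + (1 | id), data = d, REML = FALSE)
  expect_equal(unname(f$fixed$estimate), unname(lme4::fixef(m)),
               tolerance = 1e-5)
  expect_equal(f$logLik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(f$sigma_eps, sigma(m), tolerance = 1e-4)
  expect_equal(f$sigma_id, sqrt(unname(unlist(lme4::VarCorr(m)))),
               tolerance = 1e-3)
  expect_equal(unname(f$fixed$se), unname(sqrt(diag(as.matrix(vcov(m))))),
               tolerance = 1e-4)
})

test_that("zero matched contrasts are dropped from the LMM with a warning", {
  recs <- simulate_replication_experiment(seed = 5)
  recs$matched_contrast[c(3, 9)] <- 0
  expect_warning(f <- fit_lmm(recs), "2 record")
  expect_identical(f$n_obs, nrow(recs) - 2L)
})

test_that("fit_lmm enforces its preconditions", {
  recs <- simulate_replication_experiment(seed = 3)
  one <- recs[recs$observer_id == "obs01", ]
  expect_error(fit_lmm(one), "2 observers")
  expect_error(fit_lmm(recs[c(1, 171), ]), "10 records")
})

test_that("fits are invariant to the logarithm base", {
  t3 <- table3_matches()
  d <- t3[t3$condition == "control", ]
  fe <- fit_loglog(d$upper_contrast, d$mean_match)
  f10 <- fit_loglog(d$upper_contrast, d$mean_match, base = 10)
  expect_equal(f10$slope, fe$slope, tolerance = 1e-10)
  expect_equal(f10$r_squared, fe$r_squared, tolerance = 1e-10)
  expect_equal(f10$intercept * log(10), fe$intercept, tolerance = 1e-10)
})

test_that("the results figure is written with both conditions", {
  s <- table3_matches()
  path <- withr::local_tempfile(fileext = ".png")
  make_results_figure(s, path = path)
  expect_gt(file.size(path), 1000)
  expect_error(make_results_figure(s[s$condition == "control", ],
                                   path = path), "both conditions")
})
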