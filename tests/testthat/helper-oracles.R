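# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and lm()) so that agreement is informative.

# simple linear regression by explicit normal equations / moment sums
ols_oracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  s2 <- sse / (n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + mx^2 / sxx)),
       r_squared = 1 - sse / sst,
       rmse = sqrt(s2),
       f = ((sst - sse) / 1) / s2,
       n = n)
}

# list rotation by modular indexing (vs the package's splice-based rotate)
rotate_oracle <- function(values, cut) {
  n <- length(values)
  values[((cut + seq_len(n) - 1L) %% n) + 1L]
}

# hand-built trial records for summary tests
fake_records <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    observer_id = sample(c("a", "b"), n, replace = TRUE),
    mode = "replication",
    condition = sample(c("control", "adaptation"), n, replace = TRUE),
    trial_index = seq_len(n),
    is_practice = FALSE,
    upper_contrast = sample(c(0.1183, 0.2409, 0.7), n, replace = TRUE),
    cut_index = NA_integer_,
    matched_position = 0L,
    matched_contrast = exp(rnorm(n, log(0.2), 0.3)),
    seed = 1L)
}

# noise-free records straight from the matching model, no slider quantisation
model_records <- function(p, n_obs = 2, offsets = NULL) {
  levels_c <- control_levels()
  levels_a <- adaptation_levels()
  do.call(rbind, lapply(seq_len(n_obs), function(i) {
    pi <- p
    if (!is.null(offsets)) pi$id_offset <- offsets[i]
    do.call(rbind, lapply(c("control", "adaptation"), function(cond) {
      lv <- if (cond == "control") levels_c else levels_a
      lv <- rep(lv, each = 10)
      tibble::tibble(
        observer_id = sprintf("o%d", i), mode = "replication",
        condition = cond, trial_index = seq_along(lv),
        is_practice = FALSE, upper_contrast = lv,
        cut_index = NA_integer_, matched_position = 0L,
        matched_contrast = exp(expected_log_match(pi, cond, lv)),
        seed = 0L)
    }))
  }))
}

# the printed 11-value control contrast list (4 dp)
printed_control_levels <- c(0.0200, 0.0285, 0.0407, 0.0581, 0.0829, 0.1183,
                            0.1688, 0.2409, 0.3438, 0.4906, 0.7000)
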