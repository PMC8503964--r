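#' Parameters of the generative simulated observer
#'
#' The simulated observer produces contrast matches from a log-log matching
#' model: the natural log of the matched contrast is linear in the natural
#' log of the upper (reference) contrast, with an additive shift and slope
#' increment under adaptation, a per-observer intercept deviation, and
#' Gaussian trial noise on the log scale (so matches are lognormal).
#'
#' Defaults are the fixed-effect and variance estimates from the reference
#' mixed-model fit, so that simulation followed by analysis targets those
#' same values.
#'
#' @param beta0 Intercept on the natural-log scale.
#' @param beta1 Slope against `ln` upper contrast.
#' @param beta2 Additive intercept shift under adaptation.
#' @param beta3 Slope increment under adaptation (the interaction).
#' @param sigma_eps Residual SD of trial noise on the log scale, >= 0.
#' @param id_offset This observer's intercept deviation (log scale).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(beta0 = -0.084, beta1 = 0.982, beta2 = 0.052,
                            beta3 = 0.443, sigma_eps = 0.2875,
                            id_offset = 0) {
  p <- list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
            sigma_eps = sigma_eps, id_offset = id_offset)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("all observer parameters must be single finite numbers")
  if (sigma_eps < 0) stop("`sigma_eps` must be >= 0")
  structure(p, class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> b0=%.4g b1=%.4g b2=%.4g b3=%.4g sigma_eps=%.4g id_offset=%.4g\n",
    x$beta0, x$beta1, x$beta2, x$beta3, x$sigma_eps, x$id_offset))
  invisible(x)
}

#' Population-level observer parameters
#'
#' Fixed effects shared by all observers plus the SD of the per-observer
#' intercept deviation, from which individual observers are drawn by
#' [sample_observer()].
#'
#' @inheritParams observer_params
#' @param sigma_id SD of `id_offset` across observers, >= 0.
#' @return An object of class `population_params`.
#' @export
population_params <- function(beta0 = -0.084, beta1 = 0.982, beta2 = 0.052,
                              beta3 = 0.443, sigma_eps = 0.2875,
                              sigma_id = 0.0424) {
  if (!is.numeric(sigma_id) || sigma_id < 0) stop("`sigma_id` must be >= 0")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 sigma_eps = sigma_eps, sigma_id = sigma_id),
            class = "population_params")
}

#' Draw one observer from a population
#'
#' Copies the fixed effects and draws `id_offset ~ Normal(0, sigma_id^2)`.
#'
#' @param pop A [population_params()].
#' @return An [observer_params()].
#' @export
sample_observer <- function(pop) {
  stopifnot(inherits(pop, "population_params"))
  observer_params(beta0 = pop$beta0, beta1 = pop$beta1, beta2 = pop$beta2,
                  beta3 = pop$beta3, sigma_eps = pop$sigma_eps,
                  id_offset = stats::rnorm(1, 0, pop$sigma_id))
}

#' Expected log contrast match
#'
#' The deterministic part of the matching model:
#' `(beta0 + id_offset) + beta1 * ln(c) + (beta2 + beta3 * ln(c)) * 1(adaptation)`.
#'
#' @param p An [observer_params()].
#' @param condition `"control"` or `"adaptation"`.
#' @param c Upper-grating Michelson contrast, > 0 (vectorised).
#' @return Expected matched contrast on the natural-log scale.
#' @export
expected_log_match <- function(p, condition, c) {
  stopifnot(inherits(p, "observer_params"))
  condition <- match.arg(condition, c("control", "adaptation"))
  if (any(!is.finite(c)) || any(c <= 0))
    stop("upper contrast must be > 0")
  adapt <- as.numeric(condition == "adaptation")
  (p$beta0 + p$id_offset) + p$beta1 * log(c) +
    (p$beta2 + p$beta3 * log(c)) * adapt
}

#' Simulate one (or more) contrast matches
#'
#' Draws `exp(expected_log_match + eps)` with
#' `eps ~ Normal(0, sigma_eps^2)` independently per trial. The raw match is
#' unconstrained on (0, Inf); the session engine clamps it into the active
#' scale's range and quantises it onto a slider position.
#'
#' @inheritParams expected_log_match
#' @return Simulated matched contrast(s), same length as `c`.
#' @export
simulate_match <- function(p, condition, c) {
  mu <- expected_log_match(p, condition, c)
  exp(mu + stats::rnorm(length(mu), 0, p$sigma_eps))
}
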