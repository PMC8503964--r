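#' Per-observer reference contrast-match table
#'
#' The packaged table of mean (and SD of) matched contrasts: for each of two
#' observers, the mean of 10 matches at each upper contrast, separately for
#' the control condition (11 levels) and the adaptation condition (6 levels).
#' This is the desk input for [replicate_table2()].
#'
#' @return A tibble with columns `observer_id`, `condition`,
#'   `upper_contrast`, `mean_match`, `sd_match`, `n`.
#' @export
table3_matches <- function() {
  path <- system.file("extdata", "table3_matches.csv",
                      package = "contrastfade", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(
    path, colClasses = c(observer_id = "character")))
}

#' Summarise trial records into per-level means
#'
#' For each observer, condition and upper contrast, the mean and sample SD
#' (n - 1 denominator) of the matched contrasts on the raw contrast scale,
#' plus the match count. Practice trials are excluded by default.
#'
#' @param records Trial-record tibble (see [run_headless_session()]).
#' @param include_practice Keep practice trials? Default `FALSE`.
#' @return A tibble with one row per (observer_id, condition,
#'   upper_contrast): `mean_match`, `sd_match`, `n`.
#' @export
summarize_matches <- function(records, include_practice = FALSE) {
  if (!nrow(records)) stop("no records to summarise")
  if (!include_practice) records <- records[!records$is_practice, ]
  if (!nrow(records)) stop("no non-practice records to summarise")
  dplyr::summarise(
    dplyr::group_by(records, .data$observer_id, .data$condition,
                    .data$upper_contrast),
    mean_match = mean(.data$matched_contrast),
    sd_match = stats::sd(.data$matched_contrast),
    n = dplyr::n(),
    .groups = "drop")
}

#' Pooled log-log linear regression of contrast matches
#'
#' Ordinary least squares of `log(match)` on `log(upper)` with both
#' variables transformed in the same base (natural log by default). Returns
#' the full inferential summary: coefficient estimates, standard errors,
#' two-sided 95% confidence intervals and p values from the Student t
#' distribution on `n - 2` df, R-squared and adjusted R-squared, the root
#' mean squared error `sqrt(SSE / (n - 2))`, and the F test against the
#' constant model.
#'
#' The slope, R-squared and all test statistics are invariant to the choice
#' of base; the intercept is expressed in the chosen base (dividing by
#' `log(base)` converts from the natural-log intercept).
#'
#' @param upper Upper-grating contrasts, all > 0.
#' @param match Matched contrasts (typically per-level means), all > 0.
#' @param base Logarithm base applied to both axes.
#' @return An object of class `loglog_fit`.
#' @export
fit_loglog <- function(upper, match, base = exp(1)) {
  upper <- as.numeric(upper)
  match <- as.numeric(match)
  if (length(upper) != length(match)) stop("`upper` and `match` lengths differ")
  if (length(upper) < 3L) stop("need at least 3 points")
  if (any(!is.finite(upper)) || any(!is.finite(match)) ||
      any(upper <= 0) || any(match <= 0))
    stop("all contrasts must be finite and > 0 (drop zero matches first)")
  x <- log(upper, base = base)
  y <- log(match, base = base)
  if (max(x) - min(x) < .Machine$double.eps * 100)
    stop("degenerate design: all upper contrasts equal")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  co <- s$coefficients
  fstat <- s$fstatistic
  structure(list(
    coefficients = tibble::tibble(
      term = c("intercept", "log(upper_contrast)"),
      estimate = unname(co[, 1]), se = unname(co[, 2]),
      ci_lo = unname(ci[, 1]), ci_hi = unname(ci[, 2]),
      t = unname(co[, 3]), p = unname(co[, 4])),
    intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    rmse = s$sigma,
    f_statistic = unname(fstat[1]),
    f_p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n_obs = length(x), error_df = length(x) - 2L,
    base = base, lm = fit),
    class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "Log-log linear model (base %s)\n  n = %d, error df = %d, RMSE = %.4g, R^2 = %.4g (adj %.4g)\n  F vs constant model = %.4g, p = %.4g\n",
    if (abs(x$base - exp(1)) < 1e-12) "e" else format(x$base),
    x$n_obs, x$error_df, x$rmse, x$r_squared, x$adj_r_squared,
    x$f_statistic, x$f_p))
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-22s %10.5g  SE %.5g  95%% CI [%.5g, %.5g]  t = %.5g  p = %.4g\n",
                co$term[i], co$estimate[i], co$se[i], co$ci_lo[i],
                co$ci_hi[i], co$t[i], co$p[i]))
  invisible(x)
}

# GLS pieces for the compound-symmetric random-intercept model at variance
# ratio lambda = sigma_id^2 / sigma_eps^2, exploiting the block structure:
# (I + lambda J)^{-1} = I - lambda/(1 + lambda n_i) J within each group.
lmm_gls <- function(X, y, group, lambda) {
  k <- ncol(X)
  n <- length(y)
  idx <- split(seq_len(n), group)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  logdet <- 0
  for (ii in idx) {
    w <- lambda / (1 + lambda * length(ii))
    sx <- colSums(X[ii, , drop = FALSE])
    XtX <- XtX - w * tcrossprod(sx)
    Xty <- Xty - w * sx * sum(y[ii])
    logdet <- logdet + log1p(lambda * length(ii))
  }
  beta <- solve(XtX, Xty)
  r <- y - X %*% beta
  q <- sum(r^2)
  for (ii in idx) q <- q - lambda / (1 + lambda * length(ii)) * sum(r[ii])^2
  sigma2 <- q / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdet / 2
  list(beta = drop(beta), sigma2 = sigma2, logdet = logdet, q = q,
       loglik = ll, XtVinvX = XtX)
}

# full (non-profiled-in-sigma) negative log-likelihood at given component
# SDs, with the fixed effects profiled out by GLS; used for the Wald
# curvature of the variance components on the log-SD scale
lmm_nll_sds <- function(log_sigma_id, log_sigma_eps, X, y, group) {
  s_id <- exp(log_sigma_id)
  s_eps <- exp(log_sigma_eps)
  lambda <- (s_id / s_eps)^2
  g <- lmm_gls(X, y, group, lambda)
  n <- length(y)
  n / 2 * log(2 * pi * s_eps^2) + g$logdet / 2 + g$q / (2 * s_eps^2)
}

#' Random-intercept linear mixed model of log contrast matches
#'
#' Fits, by maximum likelihood, the model
#' `log(match) = b0 + b1 * log(upper) + b2 * adapt + b3 * adapt * log(upper)
#' + u[observer] + eps`, with `adapt` an indicator for the adaptation
#' condition, `u ~ Normal(0, sigma_id^2)` a per-observer random intercept
#' and `eps ~ Normal(0, sigma_eps^2)` trial noise, all on the natural-log
#' scale.
#'
#' Estimation profiles the likelihood over the variance ratio
#' `lambda = sigma_id^2 / sigma_eps^2`: for each candidate lambda the fixed
#' effects and the residual variance have closed forms via generalised least
#' squares under the block compound-symmetric covariance, and lambda is
#' optimised by a 1-D bounded search (on `sqrt(lambda)`, so the boundary
#' `sigma_id = 0` is reachable; a boundary estimate is flagged). Standard
#' errors of the fixed effects use the ML plug-in covariance
#' `sigmahat^2 (X' V^{-1} X)^{-1}`; degrees of freedom follow the residual
#' convention `n - 4` for every fixed effect. Confidence intervals for the
#' two variance components are Wald intervals on the log-SD scale from the
#' numerical curvature of the profile likelihood.
#'
#' Practice trials are dropped; records with a zero matched contrast cannot
#' enter a log-scale fit and are dropped with a warning reporting the count.
#'
#' @param records Trial-record tibble with at least `observer_id`,
#'   `condition`, `upper_contrast`, `matched_contrast` (and optionally
#'   `is_practice`).
#' @return An object of class `mixed_fit`: fixed-effect table (estimate,
#'   SE, 95% CI, t, df, p), variance components with CIs, log-likelihood,
#'   AIC, BIC, deviance, observation and group counts, the optimised
#'   lambda, a boundary flag, and the profiled-likelihood trace.
#' @export
fit_lmm <- function(records) {
  if (!is.null(records$is_practice)) records <- records[!records$is_practice, ]
  zero <- records$matched_contrast <= 0
  if (any(zero)) {
    warning(sprintf("dropping %d record(s) with zero matched contrast from the log-scale fit",
                    sum(zero)))
    records <- records[!zero, ]
  }
  if (length(unique(records$observer_id)) < 2L)
    stop("need at least 2 observers to fit a random intercept")
  if (nrow(records) < 10L) stop("need at least 10 records")
  y <- log(records$matched_contrast)
  lx <- log(records$upper_contrast)
  adapt <- as.numeric(records$condition == "adaptation")
  X <- cbind(1, adapt, lx, adapt * lx)
  colnames(X) <- c("intercept", "condition", "log(upper_contrast)",
                   "condition:log(upper_contrast)")
  group <- factor(records$observer_id)
  n <- nrow(X)
  k <- ncol(X)

  trace_env <- new.env()
  trace_env$tab <- list()
  obj <- function(theta) {  # theta = sqrt(lambda)
    g <- lmm_gls(X, y, group, theta^2)
    trace_env$tab[[length(trace_env$tab) + 1L]] <- c(lambda = theta^2,
                                                     loglik = g$loglik)
    -g$loglik
  }
  opt <- stats::optimize(obj, interval = c(0, 50), tol = 1e-9)
  ll0 <- lmm_gls(X, y, group, 0)$loglik
  boundary <- -opt$objective <= ll0 + 1e-10
  lambda <- if (boundary) 0 else opt$minimum^2
  g <- lmm_gls(X, y, group, lambda)
  if (!is.finite(g$loglik))
    stop("mixed-model fit did not converge; profiled-likelihood trace attached",
         call. = FALSE)
  sigma_eps <- sqrt(g$sigma2)
  sigma_id <- sqrt(lambda) * sigma_eps
  vcov_beta <- g$sigma2 * solve(g$XtVinvX)
  se <- sqrt(diag(vcov_beta))
  df <- n - k
  tval <- g$beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df)

  # Wald CIs for the component SDs on the log scale
  rand <- tibble::tibble(component = c("observer (random intercept SD)",
                                       "residual SD"),
                         sd = c(sigma_id, sigma_eps),
                         ci_lo = NA_real_, ci_hi = NA_real_)
  if (!boundary) {
    h <- 1e-4
    f <- function(a, b) lmm_nll_sds(a, b, X, y, group)
    a0 <- log(sigma_id); b0 <- log(sigma_eps)
    H <- matrix(0, 2, 2)
    H[1, 1] <- (f(a0 + h, b0) - 2 * f(a0, b0) + f(a0 - h, b0)) / h^2
    H[2, 2] <- (f(a0, b0 + h) - 2 * f(a0, b0) + f(a0, b0 - h)) / h^2
    H[1, 2] <- H[2, 1] <-
      (f(a0 + h, b0 + h) - f(a0 + h, b0 - h) -
         f(a0 - h, b0 + h) + f(a0 - h, b0 - h)) / (4 * h^2)
    se_log <- tryCatch(sqrt(diag(solve(H))), error = function(e) c(NA, NA))
    z <- stats::qnorm(0.975)
    rand$ci_lo <- c(sigma_id, sigma_eps) * exp(-z * se_log)
    rand$ci_hi <- c(sigma_id, sigma_eps) * exp(z * se_log)
  }

  loglik <- g$loglik
  npar <- k + 2L
  structure(list(
    fixed = tibble::tibble(
      term = colnames(X), estimate = unname(g$beta), se = unname(se),
      ci_lo = unname(g$beta - tcrit * se), ci_hi = unname(g$beta + tcrit * se),
      t = unname(tval), df = df, p = unname(pval)),
    random = rand,
    sigma_id = sigma_id, sigma_eps = sigma_eps, lambda = lambda,
    boundary = boundary,
    logLik = loglik, deviance = -2 * loglik,
    AIC = -2 * loglik + 2 * npar, BIC = -2 * loglik + log(n) * npar,
    n_obs = n, n_groups = nlevels(group), n_par = npar,
    trace = do.call(rbind, trace_env$tab)),
    class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept linear mixed model (maximum likelihood)\n  n = %d observations, %d observers\n  logLik = %.4f, deviance = %.4f, AIC = %.4f, BIC = %.4f\n",
    x$n_obs, x$n_groups, x$logLik, x$deviance, x$AIC, x$BIC))
  cat("Fixed effects:\n")
  co <- x$fixed
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-30s %9.4g  SE %.4g  95%% CI [%.4g, %.4g]  t = %.4g  df = %d  p = %.4g\n",
                co$term[i], co$estimate[i], co$se[i], co$ci_lo[i],
                co$ci_hi[i], co$t[i], co$df[i], co$p[i]))
  cat("Random effects:\n")
  for (i in seq_len(nrow(x$random)))
    cat(sprintf("  %-30s %9.4g  95%% CI [%.4g, %.4g]\n",
                x$random$component[i], x$random$sd[i],
                x$random$ci_lo[i], x$random$ci_hi[i]))
  if (x$boundary)
    cat("  (random-intercept SD estimated at the zero boundary)\n")
  invisible(x)
}

#' Desk replication of the reference regression table
#'
#' Runs [fit_loglog()] on the packaged per-observer match table
#' ([table3_matches()]): the 22 pooled control means (2 observers x 11
#' levels) and the 12 pooled adaptation means (2 observers x 6 levels),
#' natural-log transformed, each condition fitted separately.
#'
#' @return A list with elements `control` and `adaptation`, each a
#'   `loglog_fit`.
#' @export
replicate_table2 <- function() {
  t3 <- table3_matches()
  fit1 <- function(cond) {
    d <- t3[t3$condition == cond, ]
    fit_loglog(d$upper_contrast, d$mean_match)
  }
  out <- list(control = fit1("control"), adaptation = fit1("adaptation"))
  class(out) <- "table2_replication"
  out
}

#' @export
print.table2_replication <- function(x, ...) {
  cat("== Control condition ==\n"); print(x$control)
  cat("== Adaptation condition ==\n"); print(x$adaptation)
  invisible(x)
}

#' Results figure: perceived vs physical contrast
#'
#' Log-log scatter of the per-level mean matches, control and adaptation in
#' distinct colours, with each condition's fitted log-log line overlaid.
#'
#' @param summary Per-level summary from [summarize_matches()] (or the
#'   packaged [table3_matches()] table), containing both conditions.
#' @param fits Named list with `loglog_fit` elements `control` and
#'   `adaptation`; defaults to fitting each condition of `summary`.
#' @param path Output file (extension selects the device, e.g. `.png`,
#'   `.svg`, `.pdf`).
#' @return `path`, invisibly.
#' @export
make_results_figure <- function(summary, fits = NULL, path) {
  conds <- unique(summary$condition)
  if (!all(c("control", "adaptation") %in% conds))
    stop("summary must contain both conditions")
  if (is.null(fits))
    fits <- lapply(stats::setNames(nm = c("control", "adaptation")),
                   function(cc) {
                     d <- summary[summary$condition == cc, ]
                     fit_loglog(d$upper_contrast, d$mean_match)
                   })
  pred <- do.call(rbind, lapply(c("control", "adaptation"), function(cc) {
    d <- summary[summary$condition == cc, ]
    xg <- exp(seq(log(min(d$upper_contrast)), log(max(d$upper_contrast)),
                  length.out = 50))
    data.frame(condition = cc, upper_contrast = xg,
               mean_match = exp(fits[[cc]]$intercept * log(fits[[cc]]$base) +
                                  fits[[cc]]$slope * log(xg)))
  }))
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$upper_contrast,
                                    y = .data$mean_match,
                                    colour = .data$condition)) +
    ggplot2::geom_line(data = pred) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(control = "black",
                                            adaptation = "red")) +
    ggplot2::labs(x = "Physical contrast (upper grating)",
                  y = "Perceived contrast (matched)",
                  colour = "Condition") +
    ggplot2::theme_classic()
  ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 150)
  invisible(path)
}
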