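#' Standard contrast level lists
#'
#' The 11 control-condition upper-grating contrasts are 11 log-spaced values
#' from 0.02 to 0.70; the 6 adaptation-condition contrasts are the upper 6
#' of the same list. The exercise protocol uses the 6-level list for both of
#' its conditions.
#'
#' @return Numeric vector of Michelson contrasts.
#' @export
control_levels <- function() log_spaced(0.02, 0.7, 11L)

#' @rdname control_levels
#' @export
adaptation_levels <- function() control_levels()[6:11]

#' Session configuration
#'
#' Bundles everything that defines one matching session: the protocol
#' (`replication` runs a single condition; `exercise` runs practice, then
#' control, then adaptation back to back), the contrast level lists, the
#' repetition count, and the timing constants. In headless runs the timing
#' fields (180 s initial adaptation, 10 s inter-trial interval, 0.7-contrast
#' top-up grating) are carried as metadata only — nothing sleeps.
#'
#' @param mode `"replication"` or `"exercise"`.
#' @param condition For replication mode, `"control"` or `"adaptation"`.
#'   Ignored in exercise mode, which always runs both in order.
#' @param contrast_levels Upper-grating contrasts; defaults to the standard
#'   list for the mode/condition.
#' @param reps Matches per contrast level (default 10).
#' @param adaptation_duration Initial adaptation period, seconds.
#' @param isi Inter-trial pause, seconds.
#' @param topup_contrast Contrast of the top-up adapting grating.
#' @param n_practice Unrecorded practice trials before the exercise proper.
#' @param seed Integer seed governing trial order, cut points and the
#'   simulated observer's noise for this session.
#' @return An object of class `session_config`.
#' @export
session_config <- function(mode = c("replication", "exercise"),
                           condition = c("control", "adaptation"),
                           contrast_levels = NULL,
                           reps = 10L,
                           adaptation_duration = 180,
                           isi = 10,
                           topup_contrast = 0.7,
                           n_practice = 6L,
                           seed = 1L) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  if (is.null(contrast_levels)) {
    contrast_levels <-
      if (mode == "exercise" || condition == "adaptation")
        adaptation_levels() else control_levels()
  }
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("`reps` must be >= 1")
  if (!length(contrast_levels) ||
      any(contrast_levels <= 0) || any(contrast_levels > 1))
    stop("contrast levels must lie in (0, 1]")
  if (topup_contrast <= 0 || topup_contrast > 1)
    stop("`topup_contrast` must lie in (0, 1]")
  structure(list(mode = mode, condition = condition,
                 contrast_levels = as.numeric(contrast_levels),
                 reps = reps,
                 adaptation_duration = adaptation_duration, isi = isi,
                 topup_contrast = topup_contrast,
                 n_practice = as.integer(n_practice),
                 seed = as.integer(seed)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> mode=%s%s, %d level(s) x %d reps, seed=%d\n",
              x$mode,
              if (x$mode == "replication") paste0("/", x$condition) else "",
              length(x$contrast_levels), x$reps, x$seed))
  invisible(x)
}

#' Read / write a session configuration as YAML
#'
#' The file mirrors the [session_config()] fields as a flat key-value map;
#' omitted keys take their defaults, so a file containing only
#' `mode: exercise` reproduces the full exercise protocol.
#'
#' @param path File path.
#' @param config A `session_config` (for writing).
#' @return `read_session_config()` returns a `session_config`.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(session_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(session_config, raw)
}

#' @rdname read_session_config
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Balanced randomised trial plan
#'
#' Builds a deck with each contrast level repeated exactly `reps` times and
#' shuffles it into a uniformly random order — exact per-level counts, not
#' independent draws.
#'
#' @param levels Non-empty vector of upper-grating contrasts.
#' @param reps Repetitions per level.
#' @return Numeric vector of length `length(levels) * reps`: the upper
#'   contrast of each trial in presentation order.
#' @export
make_trial_plan <- function(levels, reps) {
  if (!length(levels)) stop("`levels` must be non-empty")
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("`reps` must be >= 1")
  deck <- rep(as.numeric(levels), times = reps)
  sample(deck)
}

run_block <- function(config, observer, base_scale, condition, uppers,
                      is_practice, start_index) {
  rotated <- !base_scale$has_zero
  n <- length(uppers)
  cut <- if (rotated)
    sample.int(length(base_scale$values), n, replace = TRUE) - 1L
  else rep(NA_integer_, n)
  pos <- integer(n)
  match_c <- numeric(n)
  minpos <- min(base_scale$values[base_scale$values > 0])
  maxval <- max(base_scale$values)
  raw <- simulate_match(observer, condition, uppers)
  if (any(!is.finite(raw)))
    stop(sprintf("observer produced non-finite match on trial %d of block '%s'",
                 which(!is.finite(raw))[1], condition))
  raw <- pmin(pmax(raw, minpos), maxval)
  for (i in seq_len(n)) {
    sc <- if (rotated) rotate_scale(base_scale, cut[i]) else base_scale
    pos[i] <- nearest_position(sc, raw[i])
    match_c[i] <- contrast_at(sc, pos[i])
  }
  tibble::tibble(
    condition = condition,
    trial_index = start_index + seq_len(n) - 1L,
    is_practice = is_practice,
    upper_contrast = uppers,
    cut_index = cut,
    matched_position = pos,
    matched_contrast = match_c)
}

#' Run a headless matching session
#'
#' Executes a full session against a simulated observer without any display
#' or timing: trials are planned with [make_trial_plan()], the observer's
#' intended match is drawn from its lognormal matching model, clamped into
#' the active scale's positive range, and quantised onto the nearest slider
#' position in log space. In exercise mode each trial (including practice)
#' uses a freshly rotated scale whose cut index is drawn uniformly and
#' recorded; the replication slider is never rotated.
#'
#' Runs are exactly reproducible: the configuration's seed initialises the
#' RNG that governs trial order, cut points and observer noise.
#'
#' @param config A [session_config()].
#' @param observer An [observer_params()].
#' @param scale The backing `contrast_scale`; defaults to
#'   [replication_scale()] or [exercise_scale()] according to the mode.
#' @param observer_id Label written into each record.
#' @return A tibble of trial records with columns `observer_id`, `mode`,
#'   `condition`, `trial_index`, `is_practice`, `upper_contrast`,
#'   `cut_index` (NA in replication mode), `matched_position` (0-based),
#'   `matched_contrast`, `seed`.
#' @export
run_headless_session <- function(config, observer, scale = NULL,
                                 observer_id = "sim01") {
  stopifnot(inherits(config, "session_config"),
            inherits(observer, "observer_params"))
  if (is.null(scale))
    scale <- if (config$mode == "exercise") exercise_scale()
             else replication_scale()
  stopifnot(inherits(scale, "contrast_scale"))
  if (config$mode == "replication" && !scale$has_zero)
    stop("replication mode expects the zero-prepended replication scale")
  if (config$mode == "exercise" && scale$has_zero)
    stop("exercise mode expects the rotatable (no-zero) exercise scale")
  # session RNG is self-contained: seed it here, restore the caller's state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  blocks <- list()
  idx <- 1L
  if (config$mode == "exercise") {
    if (config$n_practice > 0L) {
      practice_levels <- sample(rep(config$contrast_levels,
                                    length.out = config$n_practice))
      blocks[[1]] <- run_block(config, observer, scale, "control",
                               practice_levels, TRUE, idx)
      idx <- idx + config$n_practice
    }
    for (cond in c("control", "adaptation")) {
      uppers <- make_trial_plan(config$contrast_levels, config$reps)
      blocks[[length(blocks) + 1L]] <-
        run_block(config, observer, scale, cond, uppers, FALSE, idx)
      idx <- idx + length(uppers)
    }
  } else {
    uppers <- make_trial_plan(config$contrast_levels, config$reps)
    blocks[[1]] <- run_block(config, observer, scale, config$condition,
                             uppers, FALSE, idx)
  }
  out <- do.call(rbind, blocks)
  tibble::as_tibble(cbind(
    data.frame(observer_id = observer_id, mode = config$mode,
               stringsAsFactors = FALSE),
    as.data.frame(out),
    data.frame(seed = config$seed)))
}

records_columns <- c("observer_id", "mode", "condition", "trial_index",
                     "is_practice", "upper_contrast", "cut_index",
                     "matched_position", "matched_contrast", "seed")

#' Write / read trial records as CSV
#'
#' Fixed-header comma-separated files with one row per trial. Floating-point
#' fields are serialised at full precision so that a write/read round trip
#' reproduces the records exactly; malformed numeric fields are reported
#' with their line number.
#'
#' @param records A tibble of trial records from [run_headless_session()].
#' @param path File path.
#' @return `read_records_csv()` returns the records tibble.
#' @export
write_records_csv <- function(records, path) {
  stopifnot(all(records_columns %in% names(records)))
  out <- as.data.frame(records)[, records_columns]
  for (col in c("upper_contrast", "matched_contrast"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "")
  if (!identical(names(raw), records_columns))
    stop("unexpected CSV header; expected: ",
         paste(records_columns, collapse = ", "))
  parse_num <- function(col, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("malformed %s field at line %d of %s",
                   what, bad[1] + 1L, path))
    if (integer) as.integer(v) else v
  }
  tibble::tibble(
    observer_id = raw$observer_id,
    mode = raw$mode,
    condition = raw$condition,
    trial_index = parse_num("trial_index", "trial_index", TRUE),
    is_practice = as.logical(raw$is_practice),
    upper_contrast = parse_num("upper_contrast", "upper_contrast"),
    cut_index = parse_num("cut_index", "cut_index", TRUE),
    matched_position = parse_num("matched_position", "matched_position", TRUE),
    matched_contrast = parse_num("matched_contrast", "matched_contrast"),
    seed = parse_num("seed", "seed", TRUE))
}
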