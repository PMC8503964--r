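#' Logarithmically spaced contrast values
#'
#' Generates `n` values forming a geometric sequence from `lo` to `hi`,
#' i.e. evenly spaced on a logarithmic axis, with both endpoints exact.
#' This is the spacing rule behind every contrast list in the package:
#' the i-th value (0-based) is `lo * (hi/lo)^(i/(n-1))`.
#'
#' @param lo Smallest value, must be strictly positive.
#' @param hi Largest value, must exceed `lo`.
#' @param n Number of values, at least 2.
#' @return Numeric vector of length `n`, strictly increasing.
#' @examples
#' round(log_spaced(0.02, 0.7, 11), 4)
#' @export
log_spaced <- function(lo, hi, n) {
  if (!is.numeric(lo) || length(lo) != 1L || !is.finite(lo) || lo <= 0)
    stop("`lo` must be a single positive number")
  if (!is.numeric(hi) || length(hi) != 1L || !is.finite(hi) || hi <= lo)
    stop("`hi` must be a single number greater than `lo`")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2")
  v <- lo * (hi / lo)^((seq_len(n) - 1) / (n - 1))
  v[1L] <- lo
  v[n] <- hi
  v
}

#' Construct a contrast scale for the matching slider
#'
#' A `contrast_scale` is the ordered list of contrast values backing the
#' 1000-step slider: each slider position (0-based) selects one contrast.
#' Use [replication_scale()] and [exercise_scale()] for the two standard
#' variants rather than calling this directly.
#'
#' @param values Numeric vector of contrasts in `[0, 1]`.
#' @param lo,hi Range of the positive (log-spaced) part of the scale.
#' @param has_zero Whether a literal zero is prepended as position 0,
#'   letting the matched grating be switched off entirely.
#' @param cut_index Rotation offset applied by [rotate_scale()]; 0 means
#'   the scale is in its canonical increasing order.
#' @return An object of class `contrast_scale`.
#' @export
contrast_scale <- function(values, lo, hi, has_zero = FALSE, cut_index = 0L) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("all scale values must be finite and in [0, 1]")
  structure(
    list(values = values, lo = lo, hi = hi,
         n_steps = length(values) - as.integer(has_zero),
         has_zero = isTRUE(has_zero), cut_index = as.integer(cut_index)),
    class = "contrast_scale")
}

#' @export
print.contrast_scale <- function(x, ...) {
  cat(sprintf(
    "<contrast_scale> %d positions%s, range [%g, %g], cut_index %d\n",
    length(x$values), if (x$has_zero) " (zero prepended)" else "",
    x$lo, x$hi, x$cut_index))
  invisible(x)
}

#' @export
length.contrast_scale <- function(x) length(x$values)

#' The replication slider scale
#'
#' 1000 contrasts spaced evenly on a logarithmic scale between 0.01 and 1.0,
#' with the value zero prepended as the first position so the matched grating
#' can be made effectively invisible. Length 1001; never rotated.
#'
#' @return A `contrast_scale` with `has_zero = TRUE`.
#' @export
replication_scale <- function() {
  contrast_scale(c(0, log_spaced(0.01, 1.0, 1000L)),
                 lo = 0.01, hi = 1.0, has_zero = TRUE)
}

#' The exercise slider scale
#'
#' 1000 contrasts spaced evenly on a logarithmic scale between 0.05 and 1.0,
#' without a zero entry. This is the variant that gets cut and rotated at a
#' random position on every exercise trial (see [rotate_scale()]), so that an
#' untrained observer cannot reuse remembered slider positions across trials.
#'
#' @return A `contrast_scale` with `has_zero = FALSE`.
#' @export
exercise_scale <- function() {
  contrast_scale(log_spaced(0.05, 1.0, 1000L),
                 lo = 0.05, hi = 1.0, has_zero = FALSE)
}

#' Cut and rotate a contrast scale
#'
#' Cuts the scale at position `cut` (0-based): the contrast at the cut
#' becomes position 0, all greater contrasts shift down in position, and all
#' lesser contrasts are appended at the right-most end. The multiset of
#' contrasts is unchanged; only the position-to-contrast pairing moves.
#' Scales with a zero entry (the replication slider) are never rotated.
#'
#' @param scale A `contrast_scale` with `has_zero = FALSE`.
#' @param cut Integer in `[0, length(scale) - 1]`.
#' @return A new `contrast_scale` with `cut_index` recording the total
#'   rotation applied so far (mod scale length).
#' @export
rotate_scale <- function(scale, cut) {
  stopifnot(inherits(scale, "contrast_scale"))
  if (scale$has_zero)
    stop("a scale with a zero entry cannot be rotated")
  cut <- as.integer(cut)
  nv <- length(scale$values)
  if (is.na(cut) || cut < 0L || cut >= nv)
    stop(sprintf("`cut` must be in [0, %d]", nv - 1L))
  v <- if (cut == 0L) scale$values
       else c(scale$values[(cut + 1L):nv], scale$values[seq_len(cut)])
  contrast_scale(v, lo = scale$lo, hi = scale$hi, has_zero = FALSE,
                 cut_index = (scale$cut_index + cut) %% nv)
}

#' Contrast at a slider position
#'
#' @param scale A `contrast_scale`.
#' @param position 0-based slider position: 0 selects the first entry.
#' @return The contrast paired with that position.
#' @export
contrast_at <- function(scale, position) {
  stopifnot(inherits(scale, "contrast_scale"))
  position <- as.integer(position)
  nv <- length(scale$values)
  if (any(is.na(position)) || any(position < 0L) || any(position >= nv))
    stop(sprintf("position must be in [0, %d]", nv - 1L))
  scale$values[position + 1L]
}

#' Slider position nearest a target contrast
#'
#' Finds the 0-based position whose contrast is closest to `target` in log
#' space (the natural metric for a geometric scale). A target of exactly 0
#' maps to the zero entry when the scale has one; targets below the smallest
#' positive value map to that value's position.
#'
#' @param scale A `contrast_scale`.
#' @param target Contrast in `[0, 1]`.
#' @return Integer 0-based position.
#' @export
nearest_position <- function(scale, target) {
  stopifnot(inherits(scale, "contrast_scale"))
  if (!is.numeric(target) || length(target) != 1L || is.na(target) ||
      target < 0 || target > 1)
    stop("`target` must be a single number in [0, 1]")
  if (target == 0) {
    if (scale$has_zero) return(0L)
    target <- min(scale$values[scale$values > 0])
  }
  pos <- scale$values > 0
  d <- abs(log(scale$values[pos]) - log(target))
  which(pos)[which.min(d)] - 1L
}
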