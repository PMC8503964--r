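#' Display geometry for stimulus rendering
#'
#' Maps degrees of visual angle (DVA) to pixels and fixes the layout
#' constants of the matching display: a mid-gray full-screen background, a
#' central fixation cross, and grating patches centred 3 DVA above and below
#' fixation.
#'
#' @param pixels_per_degree Pixels per DVA, > 0.
#' @param background_luminance Normalised background luminance in `[0, 1]`;
#'   0.5 is mid-gray.
#' @param fixation_size Side of the fixation cross in DVA.
#' @param grating_offset Vertical distance of each patch centre from
#'   fixation, in DVA.
#' @return An object of class `display_geometry`.
#' @export
display_geometry <- function(pixels_per_degree = 40,
                             background_luminance = 0.5,
                             fixation_size = 0.5,
                             grating_offset = 3.0) {
  stopifnot(is.numeric(pixels_per_degree), pixels_per_degree > 0,
            is.numeric(background_luminance),
            background_luminance >= 0, background_luminance <= 1,
            fixation_size > 0, grating_offset > 0)
  structure(list(pixels_per_degree = pixels_per_degree,
                 background_luminance = background_luminance,
                 fixation_size = fixation_size,
                 grating_offset = grating_offset),
            class = "display_geometry")
}

#' Specification of a grating patch
#'
#' A vertical sinusoidally modulated luminance grating enveloped in a
#' Gaussian mask (a Gabor-like patch). Contrast is Michelson contrast of the
#' underlying sinusoid; the envelope attenuates modulation away from the
#' patch centre. The mask width defaults to `size / 6` so that +/- 3 sigma of
#' the envelope fills the patch.
#'
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param spatial_frequency Cycles per DVA, > 0.
#' @param size Patch side in DVA.
#' @param phase Phase of the sinusoid at patch centre, radians.
#' @param envelope_sigma Gaussian mask SD in DVA; `Inf` disables the mask.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(contrast, spatial_frequency = 3, size = 3,
                         phase = 0, envelope_sigma = size / 6) {
  if (!is.numeric(contrast) || length(contrast) != 1L || is.na(contrast) ||
      contrast < 0 || contrast > 1)
    stop("`contrast` must be a single number in [0, 1]")
  stopifnot(spatial_frequency > 0, size > 0, envelope_sigma > 0)
  structure(list(contrast = contrast,
                 spatial_frequency = spatial_frequency,
                 size = size, phase = phase,
                 envelope_sigma = envelope_sigma),
            class = "grating_spec")
}

#' Render a grating patch as a luminance image
#'
#' Evaluates, on a pixel grid covering `size x size` DVA,
#' `L(x, y) = Lb * (1 + c * exp(-(x^2 + y^2) / (2 sigma^2)) * sin(2 pi f x + phi))`
#' with `Lb` the background luminance and `(x, y)` patch-centred DVA
#' coordinates (x rightward, y downward). The result is a square matrix of
#' side `round(size * pixels_per_degree)` with values clipped to `[0, 1]`
#' (clipping only engages when `Lb != 0.5`).
#'
#' @param spec A [grating_spec()].
#' @param geometry A [display_geometry()].
#' @return A numeric matrix of class `luminance_image`, values in `[0, 1]`.
#' @export
render_grating <- function(spec, geometry = display_geometry()) {
  stopifnot(inherits(spec, "grating_spec"),
            inherits(geometry, "display_geometry"))
  n <- round(spec$size * geometry$pixels_per_degree)
  if (n < 1) stop("patch smaller than one pixel at this resolution")
  coords <- (seq_len(n) - (n + 1) / 2) / geometry$pixels_per_degree
  x <- matrix(coords, n, n, byrow = TRUE)   # columns: rightward
  y <- matrix(coords, n, n)                 # rows: downward
  env <- if (is.finite(spec$envelope_sigma))
    exp(-(x^2 + y^2) / (2 * spec$envelope_sigma^2)) else 1
  lb <- geometry$background_luminance
  img <- lb * (1 + spec$contrast * env *
                 sin(2 * pi * spec$spatial_frequency * x + spec$phase))
  img <- pmin(pmax(img, 0), 1)
  structure(img, class = c("luminance_image", class(img)))
}

#' Michelson contrast of a luminance image
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` over all pixels. Zero for any uniform
#' non-black image; undefined (an error) when `Lmax + Lmin = 0`.
#'
#' @param image A numeric matrix of luminances in `[0, 1]`.
#' @return A single number in `[0, 1]`.
#' @export
michelson_contrast <- function(image) {
  if (length(image) == 0) stop("empty image")
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop("image values must be finite and in [0, 1]")
  lmax <- max(image)
  lmin <- min(image)
  if (lmax + lmin == 0) stop("Michelson contrast undefined for an all-black image")
  (lmax - lmin) / (lmax + lmin)
}

#' Compose a full display frame
#'
#' Lays out an optional upper and lower grating patch, centred
#' `grating_offset` DVA above and below a central white fixation cross, on a
#' uniform background frame. Used for demo and figure output; the headless
#' session engine never rasterises frames.
#'
#' @param upper,lower A [grating_spec()] or `NULL` for an empty location.
#' @param geometry A [display_geometry()].
#' @return A `luminance_image` matrix.
#' @export
compose_frame <- function(upper = NULL, lower = NULL,
                          geometry = display_geometry()) {
  stopifnot(inherits(geometry, "display_geometry"))
  sizes <- vapply(Filter(Negate(is.null), list(upper, lower)),
                  function(s) s$size, numeric(1))
  patch_dva <- if (length(sizes)) max(sizes) else 3
  if (!is.null(upper) && !is.null(lower) &&
      2 * geometry$grating_offset < max(sizes))
    stop("grating patches overlap at this offset")
  ppd <- geometry$pixels_per_degree
  half_h_dva <- geometry$grating_offset + patch_dva / 2 + 0.5
  half_w_dva <- patch_dva / 2 + 0.5
  h <- 2 * round(half_h_dva * ppd) + 1
  w <- 2 * round(half_w_dva * ppd) + 1
  frame <- matrix(geometry$background_luminance, h, w)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  put <- function(frame, img, row_centre) {
    np <- nrow(img)
    r0 <- round(row_centre - np / 2)
    c0 <- round(cx - np / 2)
    frame[r0 + seq_len(np) - 1L, c0 + seq_len(np) - 1L] <- img
    frame
  }
  if (!is.null(upper))
    frame <- put(frame, render_grating(upper, geometry),
                 cy - geometry$grating_offset * ppd)
  if (!is.null(lower))
    frame <- put(frame, render_grating(lower, geometry),
                 cy + geometry$grating_offset * ppd)
  # fixation cross: two white bars of fixation_size DVA
  arm <- max(1L, round(geometry$fixation_size * ppd / 2))
  frame[round(cy), round(cx - arm):round(cx + arm)] <- 1
  frame[round(cy - arm):round(cy + arm), round(cx)] <- 1
  structure(frame, class = c("luminance_image", class(frame)))
}

#' Export a luminance image to an 8-bit grayscale PNG
#'
#' @param image A `luminance_image` (or any matrix with values in `[0, 1]`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the `png` package is required for PNG export")
  png::writePNG(unclass(image), target = path)
  invisible(path)
}
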