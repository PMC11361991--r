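#' M-mode image geometry and intensity specification
#'
#' Describes the synthetic M-mode rendering: the depth axis covered by the
#' image (cm, increasing downward), the pixel counts of the depth and time
#' axes, the width of the bright diaphragm band, and the 8-bit background
#' and band intensities.
#'
#' @param depth_range Length-2 numeric, depth extent `c(lo, hi)` in cm.
#' @param pixels_depth,pixels_time Image dimensions (positive integers;
#'   `pixels_time` may be `NULL` to follow the trace length).
#' @param band_width Full width at half maximum of the Gaussian band, cm.
#' @param background_level,band_level 8-bit intensities, band brighter than
#'   background.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(depth_range = c(0, 6), pixels_depth = 240,
                       pixels_time = NULL, band_width = 0.3,
                       background_level = 20, band_level = 220) {
  if (length(depth_range) != 2L || depth_range[2L] <= depth_range[1L]) {
    abort("`depth_range` must be c(lo, hi) with hi > lo")
  }
  if (pixels_depth < 2) abort("`pixels_depth` must be >= 2")
  if (band_level <= background_level) {
    abort("`band_level` must exceed `background_level`")
  }
  if (band_width <= 0) abort("`band_width` must be > 0")
  structure(list(depth_range = depth_range,
                 pixels_depth = as.integer(pixels_depth),
                 pixels_time = if (!is.null(pixels_time)) as.integer(pixels_time),
                 band_width = band_width,
                 background_level = background_level,
                 band_level = band_level),
            class = "image_spec")
}

depth_pixel_size <- function(spec) {
  diff(spec$depth_range) / spec$pixels_depth
}

# depth (cm) of the center of pixel row k (row 1 = shallowest)
pixel_center_depth <- function(spec, k) {
  spec$depth_range[1L] + (k - 0.5) * depth_pixel_size(spec)
}

#' Render a displacement trace as a synthetic M-mode image
#'
#' One image column per time sample: a Gaussian-profile bright band centered
#' at the depth given by the displacement value, over a uniform background,
#' quantized to 8-bit. Depth increases downward (row 1 is shallowest), the
#' M-mode display convention.
#'
#' @param displacement Depth trace, cm; every value must lie inside
#'   `spec$depth_range`.
#' @param spec An [image_spec()].
#' @return Integer matrix (`pixels_depth` rows x one column per sample) of
#'   class `mmode_image`, values 0-255.
#' @export
render_mmode <- function(displacement, spec) {
  check_finite(displacement, "displacement")
  lo <- spec$depth_range[1L]; hi <- spec$depth_range[2L]
  if (any(displacement < lo | displacement > hi)) {
    abort("displacement values exceed the image depth_range")
  }
  sigma <- spec$band_width / (2 * sqrt(2 * log(2)))
  depths <- pixel_center_depth(spec, seq_len(spec$pixels_depth))
  img <- vapply(displacement, function(d) {
    v <- spec$background_level +
      (spec$band_level - spec$background_level) *
        exp(-0.5 * ((depths - d) / sigma)^2)
    as.integer(round(pmin(pmax(v, 0), 255)))
  }, integer(spec$pixels_depth))
  structure(img, class = c("mmode_image", "matrix"))
}

#' Trace the diaphragm curve from an M-mode image
#'
#' Per column, the band depth is located as the argmax of the column
#' intensity after a 3-pixel vertical moving-average smoothing; the
#' per-column depths are then passed through a 5-column running median to
#' enforce continuity, and pixel rows are mapped to cm through the image
#' spec. Columns with no signal (flat intensity) fall back to neighbor
#' interpolation and count against the `quality` fraction.
#'
#' @param image A matrix as produced by [render_mmode()] (rows = depth).
#' @param spec The matching [image_spec()].
#' @return A tibble of class `traced_curve` with `t_index` and `depth` (cm);
#'   attribute `quality` is the fraction of columns traced without fallback.
#' @export
trace_mmode <- function(image, spec) {
  if (!is.matrix(image)) abort("`image` must be a matrix")
  if (nrow(image) != spec$pixels_depth) {
    abort("image depth dimension does not match `spec`")
  }
  n_col <- ncol(image)
  rows <- apply(image, 2L, function(col) {
    if (max(col) == min(col)) return(NA_real_)
    sm <- as.numeric(filter(col, rep(1 / 3, 3), sides = 2))
    sm[1L] <- (col[1L] + col[2L]) / 2
    sm[length(sm)] <- (col[length(col)] + col[length(col) - 1L]) / 2
    which.max(sm)
  })
  quality <- mean(!is.na(rows))
  if (all(is.na(rows))) abort("image has no traceable columns")
  if (anyNA(rows)) {
    ok <- which(!is.na(rows))
    rows <- approx(ok, rows[ok], xout = seq_len(n_col), rule = 2)$y
  }
  if (n_col >= 5L) rows <- runmed(rows, 5L)
  out <- tibble::tibble(t_index = seq_len(n_col),
                        depth = pixel_center_depth(spec, rows))
  class(out) <- c("traced_curve", class(out))
  attr(out, "quality") <- quality
  out
}

#' Excursion of a traced diaphragm curve
#'
#' Peak-to-trough amplitude (max - min) of the traced depth curve, the
#' quantity reported from M-mode measurements.
#'
#' @param curve A [trace_mmode()] result (or any tibble with a `depth`
#'   column).
#' @return Excursion, cm.
#' @export
excursion_from_curve <- function(curve) {
  if (NROW(curve) == 0L) abort("empty curve")
  ptp(curve$depth)
}

#' Write / read an M-mode image as 8-bit grayscale PNG
#'
#' @param image An `mmode_image` matrix (0-255).
#' @param path File path.
#' @return `write_mmode_png` returns `path` invisibly; `read_mmode_png`
#'   returns the integer matrix.
#' @export
write_mmode_png <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' @rdname write_mmode_png
#' @export
read_mmode_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  structure(as.integer(round(m * 255)) |> matrix(nrow = nrow(m)),
            class = c("mmode_image", "matrix"))
}
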