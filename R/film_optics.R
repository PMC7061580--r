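#' Tilt-corrected film thickness
#'
#' Film cross-sections are scanned along the microscope Z-axis with the
#' slide mounted on a tilted stage (default 75 degrees from horizontal).
#' The acquired Z-distance underestimates the true thickness by the cosine
#' of the residual tilt, so the corrected value is
#' `acquired_um / cos((90 - tilt_deg) degrees)`.
#'
#' @param acquired_um acquired Z-distance(s), micrometres (>= 0); vectorized.
#' @param tilt_deg stage tilt from horizontal, degrees, in (0, 90].
#' @return Corrected thickness(es), micrometres.
#' @examples
#' corrected_thickness(30, 75)  # 30 / cos(15 deg) ~ 31.06
#' @export
corrected_thickness <- function(acquired_um, tilt_deg = 75) {
  if (!is.numeric(acquired_um) || any(!is.finite(acquired_um)) ||
      any(acquired_um < 0))
    stop("`acquired_um` must be finite and >= 0", call. = FALSE)
  stopifnot_scalar(tilt_deg, "tilt_deg")
  if (tilt_deg <= 0 || tilt_deg > 90)
    stop("`tilt_deg` must be in (0, 90]", call. = FALSE)
  acquired_um / cos((90 - tilt_deg) * pi / 180)
}

#' Grayscale image with a circular region of interest
#'
#' Represents the optically active sensing window: a grayscale pixel matrix
#' and a circular mask (the black mask with a circular hole placed over the
#' film).  Mask membership uses the pixel-center-in-circle rule.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param center_xy circle center `c(x, y)` in pixel coordinates
#'   (column, row).
#' @param radius_px circle radius in pixels (> 0).
#' @param pixel_scale micrometres per pixel (metadata).
#' @return An object of class `masked_image`.
#' @export
masked_image <- function(pixels, center_xy, radius_px, pixel_scale = NA_real_) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("`pixels` must be a finite numeric matrix", call. = FALSE)
  if (length(center_xy) != 2L || !all(is.finite(center_xy)))
    stop("`center_xy` must be c(x, y)", call. = FALSE)
  stopifnot_scalar(radius_px, "radius_px", positive = TRUE)
  if (center_xy[1] - radius_px < 0.5 || center_xy[1] + radius_px > ncol(pixels) + 0.5 ||
      center_xy[2] - radius_px < 0.5 || center_xy[2] + radius_px > nrow(pixels) + 0.5)
    stop("mask circle extends outside the image bounds", call. = FALSE)
  structure(list(pixels = pixels, center_xy = as.numeric(center_xy),
                 radius_px = radius_px, pixel_scale = pixel_scale),
            class = "masked_image")
}

# Logical matrix of pixels whose centers fall inside the mask circle.
mask_membership <- function(img) {
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  dx2 <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - img$center_xy[1])^2
  dy2 <- (matrix(seq_len(nr), nr, nc) - img$center_xy[2])^2
  dx2 + dy2 <= img$radius_px^2
}

#' Mean gray value over the circular mask
#'
#' Arithmetic mean of the pixel intensities whose centers lie inside the
#' circle; pixels outside the mask are excluded.
#'
#' @param image a [masked_image].
#' @return Mean intensity (scalar).
#' @export
mean_gray_value <- function(image) {
  stopifnot(inherits(image, "masked_image"))
  inside <- mask_membership(image)
  if (!any(inside)) stop("mask contains no pixel centers", call. = FALSE)
  mean(image$pixels[inside])
}

#' Gray-value time series from an image stack
#'
#' Computes the mean gray value of each frame over a shared circular mask,
#' producing the optical response of the film as transmitted-light intensity
#' over time.  The result is a [signal_trace] and can be fed straight into
#' [smooth_trace()], [segment_cycles()] and [extract_features()].
#'
#' @param stack list of [masked_image] frames with identical geometry.
#' @param frame_rate frames per second (> 0).
#' @return A [signal_trace] with one sample per frame.
#' @export
optical_response_timeseries <- function(stack, frame_rate) {
  stopifnot(is.list(stack), length(stack) > 0)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  ref <- stack[[1L]]
  stopifnot(inherits(ref, "masked_image"))
  for (fr in stack) {
    if (!inherits(fr, "masked_image") ||
        !identical(dim(fr$pixels), dim(ref$pixels)) ||
        !identical(fr$center_xy, ref$center_xy) ||
        !identical(fr$radius_px, ref$radius_px))
      stop("all frames must share image and mask geometry", call. = FALSE)
  }
  vals <- vapply(stack, mean_gray_value, 0)
  signal_trace(vals, sampling_hz = frame_rate)
}

#' Monotonic trend of an optical quantity against film thickness
#'
#' Summarizes how a per-film quantity (baseline signal, optically active
#' area fraction, ...) varies with measured thickness: the direction of the
#' monotonic trend and a Spearman rank correlation.
#'
#' @param thickness_um measured thicknesses (>= 3 values).
#' @param values the quantity measured per film (same length).
#' @return List with `direction` (`"increasing"`, `"decreasing"` or
#'   `"none"`) and `rank_correlation` (Spearman's rho).
#' @export
baseline_vs_thickness_trend <- function(thickness_um, values) {
  if (length(thickness_um) < 3L || length(values) != length(thickness_um))
    stop("need >= 3 (thickness, value) pairs of equal length", call. = FALSE)
  rho <- cor(thickness_um, values, method = "spearman")
  direction <- if (!is.finite(rho) || rho == 0) "none"
               else if (rho > 0) "increasing" else "decreasing"
  list(direction = direction, rank_correlation = rho)
}

#' Read / write plain-text PGM (P2) grayscale images
#'
#' Minimal portable graymap support for the film-optics module: `read_pgm`
#' parses an ASCII P2 file into a numeric matrix (rows = image rows);
#' `write_pgm` writes one.  Comments (`#`) are honoured on reading.
#'
#' @param path file path.
#' @return `read_pgm`: list with `pixels` (matrix) and `max_value`.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1L] != "P2")
    stop("not a plain (P2) PGM file: ", path, call. = FALSE)
  dims <- as.integer(tok[2:3])          # width, height
  maxv <- as.numeric(tok[4L])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != prod(dims))
    stop("PGM pixel count does not match header", call. = FALSE)
  list(pixels = matrix(px, nrow = dims[2L], ncol = dims[1L], byrow = TRUE),
       max_value = maxv)
}

#' @param pixels numeric matrix of non-negative intensities.
#' @param max_value maximum gray value recorded in the header.
#' @rdname read_pgm
#' @export
write_pgm <- function(pixels, path, max_value = 255) {
  pixels <- round(as.matrix(pixels))
  if (any(pixels < 0) || any(pixels > max_value))
    stop("pixel values must lie in [0, max_value]", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)),
               format(max_value)), con)
  apply(pixels, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
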