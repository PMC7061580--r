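#' Smoothing configuration
#'
#' The raw traces are filtered with a normalized sliding-window convolution
#' before cycle division.  The default window is 100 points (about 1.1 s at
#' 90 Hz) with a Hanning shape; a rectangular (moving-average) window is
#' available.  Edges are handled by reflective padding so the output length
#' equals the input length.
#'
#' @param window_points window length in samples (>= 1).
#' @param window_shape `"hanning"` (default) or `"rectangular"`.
#' @return An object of class `smooth_config`.
#' @export
smooth_config <- function(window_points = 100L,
                          window_shape = c("hanning", "rectangular")) {
  stopifnot_scalar(window_points, "window_points", positive = TRUE,
                   integerish = TRUE)
  window_shape <- match.arg(window_shape)
  structure(list(window_points = as.integer(window_points),
                 window_shape = window_shape, edge_mode = "reflect"),
            class = "smooth_config")
}

# Unit-sum smoothing kernel for a given config.  Hann windows shorter than
# 3 points are all-zero by definition and degenerate to rectangular.
smooth_kernel <- function(cfg) {
  w <- cfg$window_points
  k <- switch(cfg$window_shape,
    rectangular = rep(1, w),
    hanning = if (w <= 2L) rep(1, w)
              else 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / (w - 1)))
  )
  k / sum(k)
}

#' Smooth a signal trace
#'
#' Applies the normalized window convolution of `cfg` with reflective edge
#' padding.  Output length equals input length; constant traces are fixed
#' points; the operation is linear.
#'
#' @param trace a [signal_trace].
#' @param cfg a [smooth_config].
#' @return A [signal_trace] with smoothed values and unchanged metadata.
#' @export
smooth_trace <- function(trace, cfg = smooth_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(cfg, "smooth_config"))
  if (length(trace$values) < cfg$window_points)
    stop(sprintf("trace (%d samples) is shorter than the smoothing window (%d)",
                 length(trace$values), cfg$window_points), call. = FALSE)
  out <- trace
  out$values <- .smooth_conv(trace$values, smooth_kernel(cfg))
  out
}

#' One exposure/recovery cycle cut from a trace
#'
#' @param values cycle intensity values.
#' @param onset_index sample index of the cycle start in the parent trace.
#' @param baseline pre-exposure baseline estimate.
#' @param voc,thickness_um,replicate_id metadata inherited from the trace.
#' @param cycle_index 1-based cycle number within the assay.
#' @return An object of class `cycle_window`.
#' @export
cycle_window <- function(values, onset_index, baseline, voc = NA_character_,
                         thickness_um = NA_real_, replicate_id = NA_integer_,
                         cycle_index = NA_integer_) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("cycle values must be finite", call. = FALSE)
  if (!is.finite(baseline)) stop("baseline must be finite", call. = FALSE)
  structure(list(values = values, onset_index = as.integer(onset_index),
                 baseline = baseline, voc = as.character(voc),
                 thickness_um = as.numeric(thickness_um),
                 replicate_id = as.integer(replicate_id),
                 cycle_index = as.integer(cycle_index)),
            class = "cycle_window")
}

#' Estimate the pre-exposure baseline of a cycle
#'
#' Arithmetic mean of the first `n_pre` samples.  The default used by
#' [segment_cycles()] is the first 0.5 s of the cycle
#' (`n_pre = round(0.5 * sampling_hz)`), which lies before any appreciable
#' response under the standard schedule.
#'
#' @param values numeric cycle values (or a `cycle_window`).
#' @param n_pre number of leading samples to average (1 <= n_pre <= length).
#' @return Baseline intensity (scalar).
#' @export
estimate_baseline <- function(values, n_pre) {
  if (inherits(values, "cycle_window")) values <- values$values
  stopifnot_scalar(n_pre, "n_pre", positive = TRUE, integerish = TRUE)
  if (n_pre > length(values))
    stop("`n_pre` exceeds the cycle length", call. = FALSE)
  mean(values[seq_len(n_pre)])
}

#' Divide a trace into exposure/recovery cycles
#'
#' Fixed-schedule slicing: cycle k spans samples
#' `[(k-1) * cycle_samples + 1, k * cycle_samples]`.  A trailing partial
#' cycle is dropped with a warning; a trace shorter than one cycle is an
#' error.  Each window's baseline is the mean of its first
#' `round(0.5 * sampling_hz)` samples.
#'
#' @param trace a [signal_trace].
#' @param schedule an [assay_schedule].
#' @param baseline_s duration (seconds) of the leading baseline window.
#' @return List of [cycle_window] objects, contiguous and in temporal order.
#' @export
segment_cycles <- function(trace, schedule, baseline_s = 0.5) {
  stopifnot(inherits(trace, "signal_trace"), inherits(schedule, "assay_schedule"))
  cs <- schedule$cycle_samples
  n  <- length(trace$values)
  if (n < cs)
    stop(sprintf("trace (%d samples) is shorter than one cycle (%d samples)",
                 n, cs), call. = FALSE)
  k <- n %/% cs
  if (n %% cs != 0L)
    warning(sprintf("dropping trailing partial cycle (%d samples)", n %% cs),
            call. = FALSE)
  n_pre <- max(1L, as.integer(round(baseline_s * trace$sampling_hz)))
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * cs + 1L):(i * cs)
    vals <- trace$values[idx]
    cycle_window(vals, onset_index = idx[1L],
                 baseline = estimate_baseline(vals, n_pre),
                 voc = trace$voc, thickness_um = trace$thickness_um,
                 replicate_id = trace$replicate_id, cycle_index = i)
  })
}
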