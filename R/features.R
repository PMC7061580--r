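# Guard epsilon for ratio features (divisors floored at this magnitude).
.feature_eps <- 1e-8

#' First derivative by finite differences
#'
#' Central differences in the interior, one-sided differences at the two
#' ends; output length equals input length.
#'
#' @param values numeric sequence (length >= 3).
#' @param dt sampling interval in seconds (> 0).
#' @return Numeric vector of rates (units of values per second).
#' @export
first_derivative <- function(values, dt) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("`values` must have length >= 3", call. = FALSE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  d <- numeric(n)
  d[1L] <- (values[2L] - values[1L]) / dt
  d[n]  <- (values[n] - values[n - 1L]) / dt
  i <- 2:(n - 1L)
  d[i] <- (values[i + 1L] - values[i - 1L]) / (2 * dt)
  d
}

# Trapezoidal integral of a uniformly sampled sequence.
trapezoid <- function(values, dt) {
  n <- length(values)
  if (n < 2L) return(0)
  dt * (sum(values) - (values[1L] + values[n]) / 2)
}

#' Nine morphological cycle descriptors
#'
#' Computed on one baseline-referenced cycle:
#' \describe{
#'   \item{f1}{peak relative amplitude, `(max - baseline) / baseline`}
#'   \item{f2}{time to peak from cycle start, s (earliest index on ties)}
#'   \item{f3}{trapezoidal area under the baseline-subtracted cycle}
#'   \item{f4}{maximum rise rate (max of the first derivative)}
#'   \item{f5}{maximum decay rate (signed minimum of the first derivative)}
#'   \item{f6}{time of the maximum rise rate, s}
#'   \item{f7}{maximum curvature (max of the second derivative)}
#'   \item{f8}{recovery residual, last sample minus baseline}
#'   \item{f9}{rise/decay ratio `f4 / |f5|` (|f5| floored at 1e-8)}
#' }
#'
#' @param cycle a [cycle_window] with its baseline set.
#' @param schedule the governing [assay_schedule].
#' @return Named numeric vector `f1`..`f9`, all finite.
#' @export
morphological_features <- function(cycle, schedule) {
  stopifnot(inherits(cycle, "cycle_window"), inherits(schedule, "assay_schedule"))
  v  <- cycle$values
  b  <- cycle$baseline
  dt <- 1 / schedule$sampling_hz
  y  <- v - b
  d1 <- first_derivative(v, dt)
  d2 <- first_derivative(d1, dt)
  i_peak <- which.max(v)              # earliest index on ties
  i_rise <- which.max(d1)
  c(f1 = (max(v) - b) / max(abs(b), .feature_eps) * sign(b + (b == 0)),
    f2 = (i_peak - 1) * dt,
    f3 = trapezoid(y, dt),
    f4 = max(d1),
    f5 = min(d1),
    f6 = (i_rise - 1) * dt,
    f7 = max(d2),
    f8 = y[length(y)],
    f9 = max(d1) / max(abs(min(d1)), .feature_eps))
}

#' Fit a three-parameter logistic to the exposure segment
#'
#' Least-squares fit of `g(t) = A / (1 + exp(-k (t - t0)))` to the
#' baseline-subtracted exposure segment (cycle start through the end of the
#' exposure window).  Initialization: `A0 = max(y)`, `t0_0` = time of
#' half-maximum, `k0 = 4 / exposure_s`.  On non-convergence (or a degenerate
#' all-zero segment) the initialization values are returned with
#' `converged = FALSE`; fitting never raises on bad cycles.
#'
#' @param cycle a [cycle_window] with its baseline set.
#' @param schedule the governing [assay_schedule].
#' @return List with `A`, `k`, `t0`, `rss`, `converged`.
#' @export
fit_logistic <- function(cycle, schedule) {
  stopifnot(inherits(cycle, "cycle_window"), inherits(schedule, "assay_schedule"))
  hz <- schedule$sampling_hz
  ne <- min(length(cycle$values), as.integer(round(schedule$exposure_s * hz)))
  y  <- cycle$values[seq_len(ne)] - cycle$baseline
  t  <- (seq_len(ne) - 1) / hz
  A0 <- max(y)
  k0 <- 4 / schedule$exposure_s
  if (!is.finite(A0) || A0 <= .feature_eps) {
    return(list(A = 0, k = k0, t0 = schedule$exposure_s / 2,
                rss = sum(y^2), converged = FALSE))
  }
  t00 <- t[which(y >= A0 / 2)[1L]]
  init <- list(A = A0, k = k0, t0 = t00)
  fit <- tryCatch(
    nls(y ~ A / (1 + exp(-k * (t - t0))), start = init,
        algorithm = "port",
        lower = c(A = 0, k = 1e-9, t0 = -10 * schedule$exposure_s),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(A = init$A, k = init$k, t0 = init$t0,
                rss = sum((y - init$A / (1 + exp(-init$k * (t - init$t0))))^2),
                converged = FALSE))
  }
  p <- coef(fit)
  conv <- isTRUE(fit$convInfo$isConv) && p[["k"]] > 0
  list(A = p[["A"]], k = p[["k"]], t0 = p[["t0"]],
       rss = sum(stats::residuals(fit)^2), converged = conv)
}

#' Extract the 12 per-cycle features
#'
#' Concatenates the nine morphological descriptors of
#' [morphological_features()] with the three logistic-fit parameters
#' (`f10 = A`, `f11 = k`, `f12 = t0`) of [fit_logistic()].  Always returns
#' 12 finite values; a non-converged fit contributes its flagged
#' initialization values.
#'
#' @param cycle a [cycle_window].
#' @param schedule the governing [assay_schedule].
#' @return Named numeric vector `f1`..`f12`.
#' @examples
#' sch <- assay_schedule(n_cycles = 1)
#' tr <- simulate_assay(default_voc_library(0)[["acetone"]],
#'                      default_film_set()[["30"]], sch, seed = 1)
#' cyc <- segment_cycles(tr, sch)[[1]]
#' extract_features(cyc, sch)
#' @export
extract_features <- function(cycle, schedule) {
  m <- morphological_features(cycle, schedule)
  fit <- fit_logistic(cycle, schedule)
  out <- c(m, f10 = fit$A, f11 = fit$k, f12 = fit$t0)
  stopifnot(length(out) == 12L, all(is.finite(out)))
  out
}

#' Feature table for a set of traces
#'
#' Runs the preprocessing chain (smoothing, then cycle division) and feature
#' extraction over a list of traces and returns one row per cycle.
#'
#' @param traces list of [signal_trace] objects.
#' @param schedule the governing [assay_schedule].
#' @param smooth_cfg a [smooth_config], or `NULL` to skip smoothing.
#' @return A data.frame with columns `voc`, `thickness_um`, `replicate_id`,
#'   `cycle_index`, `f1`..`f12`.
#' @export
extract_feature_table <- function(traces, schedule,
                                  smooth_cfg = smooth_config()) {
  stopifnot(is.list(traces), length(traces) > 0)
  rows <- lapply(traces, function(tr) {
    if (!is.null(smooth_cfg)) tr <- smooth_trace(tr, smooth_cfg)
    cycles <- segment_cycles(tr, schedule)
    feats <- t(vapply(cycles, extract_features, numeric(12L),
                      schedule = schedule))
    data.frame(voc = tr$voc, thickness_um = tr$thickness_um,
               replicate_id = tr$replicate_id,
               cycle_index = vapply(cycles, function(cw) cw$cycle_index, 1L),
               feats, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
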