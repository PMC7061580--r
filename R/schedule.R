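#' Acquisition schedule for an exposure/recovery assay
#'
#' Describes the pump-clocked acquisition protocol: `n_cycles` consecutive
#' cycles, each consisting of `exposure_s` seconds of VOC exposure followed by
#' `recovery_s` seconds of clean-air recovery, sampled at `sampling_hz`.
#' The defaults encode the standard protocol: 45 cycles of 5 s exposure +
#' 15 s recovery at 90 Hz, i.e. a 15-minute assay of 81,000 samples.
#'
#' @param n_cycles number of consecutive cycles (>= 1).
#' @param exposure_s exposure duration in seconds (> 0).
#' @param recovery_s recovery duration in seconds (> 0).
#' @param sampling_hz sampling rate in Hz (> 0).
#'
#' @return An object of class `assay_schedule` with fields `n_cycles`,
#'   `exposure_s`, `recovery_s`, `sampling_hz` and the derived
#'   `cycle_samples = round((exposure_s + recovery_s) * sampling_hz)`.
#' @examples
#' sch <- assay_schedule()
#' sch$cycle_samples  # 1800
#' @export
assay_schedule <- function(n_cycles = 45L, exposure_s = 5, recovery_s = 15,
                           sampling_hz = 90) {
  stopifnot_scalar(n_cycles, "n_cycles", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(exposure_s, "exposure_s", positive = TRUE)
  stopifnot_scalar(recovery_s, "recovery_s", positive = TRUE)
  stopifnot_scalar(sampling_hz, "sampling_hz", positive = TRUE)
  structure(list(
    n_cycles     = as.integer(n_cycles),
    exposure_s   = exposure_s,
    recovery_s   = recovery_s,
    sampling_hz  = sampling_hz,
    cycle_samples = as.integer(round((exposure_s + recovery_s) * sampling_hz))
  ), class = "assay_schedule")
}

#' @export
print.assay_schedule <- function(x, ...) {
  cat(sprintf(
    "assay_schedule: %d cycles x (%g s exposure + %g s recovery) @ %g Hz (%d samples/cycle)\n",
    x$n_cycles, x$exposure_s, x$recovery_s, x$sampling_hz, x$cycle_samples))
  invisible(x)
}

# Total number of samples in a complete assay under a schedule.
assay_samples <- function(schedule) schedule$n_cycles * schedule$cycle_samples
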