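#' Construct a signal trace
#'
#' A `signal_trace` is a uniformly sampled optical intensity series with its
#' acquisition metadata.  Values must be finite.
#'
#' @param values numeric vector of intensities, arbitrary units.
#' @param sampling_hz sampling rate, Hz.
#' @param voc analyte label (or NA for unlabeled traces).
#' @param thickness_um nominal film thickness, micrometres (or NA).
#' @param replicate_id replicate assay index (or NA).
#' @param seed seed the trace was generated with (or NA for measured data).
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(values, sampling_hz, voc = NA_character_,
                         thickness_um = NA_real_, replicate_id = NA_integer_,
                         seed = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite everywhere", call. = FALSE)
  stopifnot_scalar(sampling_hz, "sampling_hz", positive = TRUE)
  structure(list(values = values, sampling_hz = sampling_hz,
                 voc = as.character(voc), thickness_um = as.numeric(thickness_um),
                 replicate_id = as.integer(replicate_id),
                 seed = as.integer(seed)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf(
    "signal_trace: %d samples @ %g Hz (%.1f s), voc=%s, thickness=%s um, replicate=%s\n",
    length(x$values), x$sampling_hz, length(x$values) / x$sampling_hz,
    x$voc, format(x$thickness_um), format(x$replicate_id)))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$values)

# Noiseless response shape of one cycle, on the cycle's time grid.
# Exposure: saturating logistic rise with midpoint t0 = log(99)/k, shifted
# and rescaled so the response is exactly 0 at cycle onset and still
# saturates toward `amplitude` for exposures long relative to t0.
# Recovery: continuous first-order decay from the end-of-exposure value.
# Response is >= 0 throughout.
cycle_response_shape <- function(amplitude, rise_rate, decay_rate, schedule) {
  n  <- schedule$cycle_samples
  t  <- (seq_len(n) - 1) / schedule$sampling_hz
  t0 <- log(99) / rise_rate
  sig <- function(tt) 1 / (1 + exp(-rise_rate * (tt - t0)))
  s0 <- sig(0)
  rise <- function(tt) amplitude * (sig(tt) - s0) / (1 - s0)
  resp <- numeric(n)
  expo <- t < schedule$exposure_s
  resp[expo] <- rise(t[expo])
  resp[!expo] <- rise(schedule$exposure_s) *
    exp(-decay_rate * (t[!expo] - schedule$exposure_s))
  resp
}

#' Simulate one exposure/recovery cycle
#'
#' Forward model of a single cycle: `film$baseline_level` plus a response
#' that rises along a saturating logistic toward
#' `voc$amplitude * film$active_area_fraction` during exposure and decays
#' exponentially during recovery, plus additive i.i.d. Gaussian noise.
#' The noiseless output is deterministic; noise is drawn from the current
#' RNG state (seed at the assay level for reproducibility).
#'
#' @param voc a [voc_kinetics] object.
#' @param film a [film_model] object.
#' @param schedule an [assay_schedule] object.
#' @param baseline_offset additional baseline offset (used by
#'   [simulate_assay()] for per-cycle drift accumulation).
#' @return Numeric vector of `schedule$cycle_samples` intensities.
#' @export
simulate_cycle_values <- function(voc, film, schedule, baseline_offset = 0) {
  stopifnot(inherits(voc, "voc_kinetics"), inherits(film, "film_model"),
            inherits(schedule, "assay_schedule"))
  amp <- voc$amplitude * film$active_area_fraction
  resp <- cycle_response_shape(amp, voc$rise_rate, voc$decay_rate, schedule)
  out <- film$baseline_level + baseline_offset + resp
  if (voc$noise_sd > 0)
    out <- out + rnorm(schedule$cycle_samples, sd = voc$noise_sd)
  out
}

#' Simulate a complete assay for one VOC on one film
#'
#' Concatenates `schedule$n_cycles` cycles.  The baseline of cycle k is
#' shifted by `(k - 1) * voc$matrix_shift` (linear per-cycle drift emulating
#' slow matrix reorganization under protic analytes).  All randomness is
#' governed by `seed`; the same inputs always produce the same trace.
#'
#' @inheritParams simulate_cycle_values
#' @param replicate_id replicate index recorded in the trace metadata.
#' @param seed integer seed for the noise.
#' @return A [signal_trace] of `n_cycles * cycle_samples` samples.
#' @examples
#' sch <- assay_schedule()
#' tr <- simulate_assay(default_voc_library(0)[["ethanol"]],
#'                      default_film_set()[["30"]], sch, seed = 1)
#' length(tr$values)  # 81000
#' @export
simulate_assay <- function(voc, film, schedule, replicate_id = 1L, seed = 0L) {
  stopifnot(inherits(voc, "voc_kinetics"), inherits(film, "film_model"),
            inherits(schedule, "assay_schedule"))
  values <- with_seed(seed, {
    cycles <- lapply(seq_len(schedule$n_cycles), function(k) {
      simulate_cycle_values(voc, film, schedule,
                            baseline_offset = (k - 1) * voc$matrix_shift)
    })
    unlist(cycles, use.names = FALSE)
  })
  signal_trace(values, schedule$sampling_hz, voc = voc$name,
               thickness_um = film$predefined_um,
               replicate_id = replicate_id, seed = seed)
}

#' Simulate a full multi-VOC, multi-film experiment
#'
#' Produces one trace per (VOC, film, replicate) combination.  Each trace's
#' seed is derived deterministically from `seed` and the combination index,
#' so any single trace can be regenerated in isolation with
#' [simulate_assay()].
#'
#' @param vocs list of [voc_kinetics] (default: [default_voc_library()]).
#' @param films list of [film_model] (default: [default_film_set()]).
#' @param schedule an [assay_schedule].
#' @param n_replicates number of replicate assays per combination (>= 1).
#' @param seed master seed.
#' @return A list of [signal_trace] objects of length
#'   `length(vocs) * length(films) * n_replicates`.
#' @export
simulate_experiment <- function(vocs = default_voc_library(seed),
                                films = default_film_set(),
                                schedule = assay_schedule(),
                                n_replicates = 2L, seed = 0L) {
  stopifnot_scalar(n_replicates, "n_replicates", positive = TRUE,
                   integerish = TRUE)
  combos <- expand.grid(rep = seq_len(n_replicates),
                        film = seq_along(films), voc = seq_along(vocs))
  traces <- lapply(seq_len(nrow(combos)), function(i) {
    simulate_assay(vocs[[combos$voc[i]]], films[[combos$film[i]]], schedule,
                   replicate_id = combos$rep[i],
                   seed = derive_seed(seed, i))
  })
  traces
}
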