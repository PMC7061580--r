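# Shared fixtures, built in code: reduced schedules keep unit tests fast
# while preserving the 5 s + 15 s @ 90 Hz cycle geometry.

short_schedule <- function(n_cycles = 4L) assay_schedule(n_cycles = n_cycles)

# Coarse schedule for tests that only need the cycle structure.
coarse_schedule <- function(n_cycles = 3L)
  assay_schedule(n_cycles = n_cycles, exposure_s = 5, recovery_s = 15,
                 sampling_hz = 10)

# A noiseless, driftless kinetics profile for deterministic checks.
clean_voc <- function(amplitude = 50, rise = 2, decay = 1)
  voc_kinetics("testvoc", amplitude, rise, decay, matrix_shift = 0,
               noise_sd = 0)

test_film <- function(baseline = 500, frac = 1)
  film_model(30, 36, baseline_level = baseline, active_area_fraction = frac)

# Build a cycle_window directly from raw values (baseline given, not
# estimated), bypassing segmentation.
raw_cycle <- function(values, baseline, voc = "x", cycle_index = 1L)
  cycle_window(values, onset_index = 1L, baseline = baseline, voc = voc,
               cycle_index = cycle_index)
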