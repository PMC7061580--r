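test_that("default VOC library has the 11 solvent profiles and is seed-deterministic", {
  lib <- default_voc_library(seed = 0)
  expect_length(lib, 11L)
  expect_identical(names(lib),
                   c("heptane", "hexane", "chloroform", "toluene",
                     "dichloromethane", "diethyl ether", "ethyl acetate",
                     "acetonitrile", "acetone", "ethanol", "methanol"))
  expect_identical(lib, default_voc_library(seed = 0))

  lib1 <- default_voc_library(seed = 1)
  expect_identical(names(lib1), names(lib))
  expect_false(identical(
    vapply(lib, `[[`, 0, "amplitude"), vapply(lib1, `[[`, 0, "amplitude")))

  # pairwise separability margin: every profile pair differs by > 10%
  # relative distance in at least one kinetic parameter
  pars <- t(vapply(lib, function(v)
    c(v$amplitude, v$rise_rate, v$decay_rate), numeric(3)))
  for (i in 1:10) for (j in (i + 1):11) {
    rel <- abs(pars[i, ] - pars[j, ]) / pmax(abs(pars[i, ]), abs(pars[j, ]))
    expect_gt(max(rel), 0.10)
  }
})

test_that("simulate_cycle_values follows the rise/decay forward model", {
  sch <- short_schedule(1L)
  film <- test_film()

  flat <- simulate_cycle_values(clean_voc(amplitude = 0), film, sch)
  expect_equal(flat, rep(film$baseline_level, sch$cycle_samples))

  v <- simulate_cycle_values(clean_voc(), film, sch)
  expect_length(v, sch$cycle_samples)
  # monotone rise then decay: the max sits in the exposure window or at the
  # first recovery sample
  n_exp <- round(sch$exposure_s * sch$sampling_hz)
  expect_lte(which.max(v), n_exp + 1L)
  expect_true(all(v >= film$baseline_level))   # response is non-negative

  # long-exposure plateau reaches baseline + amplitude within 1%
  long <- assay_schedule(n_cycles = 1, exposure_s = 60, recovery_s = 5,
                         sampling_hz = 10)
  vl <- simulate_cycle_values(clean_voc(amplitude = 10), film, long)
  n_exp <- round(long$exposure_s * long$sampling_hz)
  expect_lt(abs(vl[n_exp] - (film$baseline_level + 10)) / 10, 0.01)
})

test_that("simulate_assay concatenates cycles with linear drift accumulation", {
  sch <- short_schedule(4L)
  film <- test_film()

  full <- simulate_assay(clean_voc(), film, assay_schedule(), seed = 3)
  expect_length(full$values, 81000L)             # 45 x 20 s x 90 Hz

  tr <- simulate_assay(clean_voc(), film, sch, seed = 5)
  cyc <- matrix(tr$values, ncol = sch$n_cycles)
  for (k in 2:sch$n_cycles) expect_equal(cyc[, k], cyc[, 1])  # no drift/noise

  drift <- voc_kinetics("d", 50, 2, 1, matrix_shift = 0.3, noise_sd = 0)
  trd <- simulate_assay(drift, film, sch, seed = 5)
  cycd <- matrix(trd$values, ncol = sch$n_cycles)
  for (k in 2:sch$n_cycles)
    expect_equal(cycd[, k] - cycd[, 1], rep(0.3 * (k - 1), sch$cycle_samples))

  expect_identical(simulate_assay(drift, film, sch, seed = 5)$values,
                   trd$values)                   # seed determinism
})

test_that("simulate_experiment yields one reproducible trace per combination", {
  sch <- coarse_schedule(2L)
  traces <- simulate_experiment(schedule = sch, n_replicates = 2L, seed = 11)
  expect_length(traces, 11L * 4L * 2L)

  again <- simulate_experiment(schedule = sch, n_replicates = 2L, seed = 11)
  expect_identical(lapply(traces, `[[`, "values"),
                   lapply(again, `[[`, "values"))

  # any single trace is regenerable in isolation from its recorded seed
  tr <- traces[[17L]]
  films <- default_film_set()
  film <- films[[which(vapply(films, `[[`, 0, "predefined_um") == tr$thickness_um)]]
  lone <- simulate_assay(default_voc_library(11)[[tr$voc]], film, sch,
                         replicate_id = tr$replicate_id, seed = tr$seed)
  expect_identical(lone$values, tr$values)
})

test_that("noiseless trace means strictly decrease with film thickness", {
  sch <- coarse_schedule(2L)
  films <- default_film_set()
  voc <- clean_voc(amplitude = 130, rise = 3, decay = 1.4)  # largest responder
  means <- vapply(films, function(fm)
    mean(simulate_assay(voc, fm, sch, seed = 1)$values), 0)
  expect_true(all(diff(means) < 0))
  # and active-area fraction strictly increases across the default set
  expect_true(all(diff(vapply(films, `[[`, 0, "active_area_fraction")) > 0))
  expect_true(all(diff(vapply(films, `[[`, 0, "baseline_level")) < 0))
})
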