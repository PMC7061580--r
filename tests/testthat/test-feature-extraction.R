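test_that("first_derivative matches the finite-difference oracle", {
  expect_equal(first_derivative(rep(3, 10), 0.1), rep(0, 10))
  t <- (0:49) * 0.02
  expect_equal(first_derivative(t, 0.02), rep(1, 50))

  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(50)
    dt <- runif(1, 0.01, 1)
    got <- first_derivative(x, dt)
    expect_identical(got, oracle_derivative(x, dt))
  }
  expect_error(first_derivative(c(1, 2), 0.1), "length >= 3")
})

test_that("morphological features: flat cycle, triangle geometry, simulator truth", {
  sch <- coarse_schedule(1L)
  n <- sch$cycle_samples
  dt <- 1 / sch$sampling_hz

  flat <- raw_cycle(rep(4, n), baseline = 4)
  f <- morphological_features(flat, sch)
  expect_equal(unname(f[c("f1", "f3", "f4", "f5", "f7", "f8")]), rep(0, 6))
  expect_equal(unname(f["f2"]), 0)               # earliest index on ties

  # symmetric triangular pulse of height h over baseline b
  b <- 2; h <- 3
  half <- 40L
  tri <- c(seq(0, h, length.out = half + 1), seq(h, 0, length.out = half + 1)[-1])
  vals <- rep(b, n); vals[101:(101 + 2 * half)] <- b + tri
  f <- morphological_features(raw_cycle(vals, baseline = b), sch)
  expect_equal(unname(f["f1"]), h / b)
  expect_equal(unname(f["f9"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["f2"]), (101 + half - 1) * dt)
  # triangle area: base (2*half) panels * height/2
  expect_equal(unname(f["f3"]), 2 * half * dt * h / 2, tolerance = 1e-12)

  # noiseless simulated cycle: amplitude 10 on baseline 100 gives f1 ~ 0.1
  film <- film_model(30, 36, baseline_level = 100, active_area_fraction = 1)
  sch90 <- short_schedule(1L)
  tr <- simulate_assay(clean_voc(amplitude = 10), film, sch90, seed = 1)
  cw <- segment_cycles(tr, sch90)[[1]]
  f <- morphological_features(cw, sch90)
  expect_lt(abs(f[["f1"]] - 0.1) / 0.1, 0.02)
})

test_that("trapezoidal areas match the brute-force oracle", {
  set.seed(29)
  for (i in 1:20) {
    x <- rnorm(sample(20:200, 1))
    dt <- runif(1, 0.01, 0.5)
    expect_lt(rel_err(lcnose:::trapezoid(x, dt), oracle_trapezoid(x, dt)),
              1e-12)
  }
})

test_that("fit_logistic recovers noiseless parameters and flags degenerate fits", {
  sch <- short_schedule(1L)
  hz <- sch$sampling_hz
  n <- sch$cycle_samples
  t <- (seq_len(n) - 1) / hz
  truth <- list(A = 1, k = 1.0, t0 = 2.5)
  y <- truth$A / (1 + exp(-truth$k * (t - truth$t0)))
  fit <- fit_logistic(raw_cycle(100 + y, baseline = 100), sch)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$A, truth$A), 1e-6)
  expect_lt(rel_err(fit$k, truth$k), 1e-6)
  expect_lt(rel_err(fit$t0, truth$t0), 1e-6)

  flat <- fit_logistic(raw_cycle(rep(0, n), baseline = 0), sch)
  expect_false(flat$converged)
  expect_equal(flat$A, 0)
})

test_that("noisy logistic fits beat the grid-search oracle and stay near truth", {
  sch <- short_schedule(1L)
  hz <- sch$sampling_hz
  ne <- round(sch$exposure_s * hz)
  t_exp <- (seq_len(ne) - 1) / hz
  t_full <- (seq_len(sch$cycle_samples) - 1) / hz
  set.seed(55)
  ok <- 0L
  n_cases <- 25L
  for (i in seq_len(n_cases)) {
    A <- runif(1, 5, 50); k <- runif(1, 0.8, 3); t0 <- runif(1, 1, 3.5)
    clean <- A / (1 + exp(-k * (t_full - t0)))
    noisy <- clean + rnorm(sch$cycle_samples, sd = 0.02 * A)
    fit <- fit_logistic(raw_cycle(noisy, baseline = 0), sch)
    grid <- oracle_logistic_grid(t_exp, noisy[seq_len(ne)])
    expect_lte(fit$rss, grid$rss * (1 + 1e-6))   # at least as good as the grid
    if (all(c(rel_err(fit$A, A), rel_err(fit$k, k), rel_err(fit$t0, t0)) < 0.05))
      ok <- ok + 1L
  }
  expect_gte(ok / n_cases, 0.95)
})

test_that("extract_features returns 12 finite values with the stated symmetries", {
  sch <- short_schedule(1L)
  film <- test_film(baseline = 100)
  tr <- simulate_assay(clean_voc(), film, sch, seed = 9)
  cw <- segment_cycles(tr, sch)[[1]]
  f <- extract_features(cw, sch)
  expect_length(f, 12L)
  expect_true(all(is.finite(f)))
  expect_identical(names(f), paste0("f", 1:12))
  expect_identical(extract_features(cw, sch), f)   # determinism

  # scale behavior: scaling the baseline-subtracted cycle by c scales the
  # amplitude-like features and leaves timing/shape features invariant
  c_ <- 3
  scaled <- raw_cycle(cw$baseline + c_ * (cw$values - cw$baseline),
                      baseline = cw$baseline)
  fs <- extract_features(scaled, sch)
  for (nm in c("f3", "f4", "f5", "f7", "f8", "f10"))
    expect_equal(fs[[nm]], c_ * f[[nm]], tolerance = 1e-4)
  for (nm in c("f2", "f6", "f9"))
    expect_equal(fs[[nm]], f[[nm]], tolerance = 1e-6)
  for (nm in c("f11", "f12"))
    expect_equal(fs[[nm]], f[[nm]], tolerance = 1e-3)

  # time-shift behavior: delaying the onset shifts f2/f6/f12, keeps amplitudes
  hz <- sch$sampling_hz
  t <- (seq_len(sch$cycle_samples) - 1) / hz
  mk <- function(delay) {
    y <- 20 / (1 + exp(-2 * (t - 1.5 - delay)))
    y[t >= sch$exposure_s] <- y[max(which(t < sch$exposure_s))] *
      exp(-1 * (t[t >= sch$exposure_s] - sch$exposure_s))
    raw_cycle(100 + y, baseline = 100)
  }
  d <- 0.5
  f0 <- extract_features(mk(0), sch); fd <- extract_features(mk(d), sch)
  expect_equal(fd[["f12"]] - f0[["f12"]], d, tolerance = 0.01)
  expect_equal(fd[["f6"]] - f0[["f6"]], d, tolerance = 0.05)
  expect_equal(fd[["f10"]], f0[["f10"]], tolerance = 0.02 * f0[["f10"]])

  # two profiles differing only in amplitude: f1/f3/f10 differ, f11/f12 agree
  tr2 <- simulate_assay(clean_voc(amplitude = 100), film, sch, seed = 9)
  cw2 <- segment_cycles(tr2, sch)[[1]]
  f2 <- extract_features(cw2, sch)
  for (nm in c("f1", "f3", "f10")) expect_gt(f2[[nm]], 1.5 * f[[nm]])
  for (nm in c("f11", "f12"))
    expect_equal(f2[[nm]], f[[nm]], tolerance = 0.02 * abs(f[[nm]]))
})

test_that("extract_feature_table emits one labeled row per cycle", {
  sch <- coarse_schedule(3L)
  traces <- list(
    simulate_assay(clean_voc(), test_film(), sch, replicate_id = 1L, seed = 1),
    simulate_assay(clean_voc(), test_film(), sch, replicate_id = 2L, seed = 2))
  tab <- extract_feature_table(traces, sch, smooth_config(5L))
  expect_equal(nrow(tab), 6L)
  expect_identical(names(tab),
                   c("voc", "thickness_um", "replicate_id", "cycle_index",
                     paste0("f", 1:12)))
  expect_identical(tab$replicate_id, rep(1:2, each = 3L))
})
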