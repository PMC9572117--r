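test_that("tilt traces honour class amplitudes and are seed-deterministic", {
  cfg <- rig_config(seed = 11)
  # zero-amplitude stable case is identically zero
  cfg0 <- rig_config(amp_stable = 0, amp_unstable = 0.1)
  t0 <- simulate_tilt_trace("ST", cfg0, seed = 5)
  expect_identical(t0$theta_ap, numeric(1000))
  expect_identical(t0$theta_ml, numeric(1000))

  # AP pattern: unstable peak on AP (within the amplitude jitter band),
  # quiet ML axis well below the stable amplitude
  tr <- simulate_tilt_trace("AP", cfg, seed = 21)
  expect_lte(max(abs(tr$theta_ap)), cfg$amp_unstable)
  expect_gte(max(abs(tr$theta_ap)), 0.85 * cfg$amp_unstable)
  expect_lte(max(abs(tr$theta_ml)), cfg$amp_stable)

  tr2 <- simulate_tilt_trace("AP", cfg, seed = 21)
  expect_identical(tr, tr2)
  expect_error(simulate_tilt_trace("WALK", cfg), "arg")
})

test_that("gravity projection inverts exactly through the displacement formula", {
  cfg <- rig_config(H1 = 1.1, H2 = 0.6, sensor_noise_std = 0)
  n <- 200
  # upright rest
  acc <- tilt_to_acceleration(numeric(n), numeric(n), cfg)
  expect_equal(acc$ax, numeric(n))
  expect_equal(acc$az, numeric(n))
  expect_equal(acc$ay, rep(cfg$g, n))

  # single-axis tilt: reconstruction returns H1 * tan(theta) exactly
  th <- 0.1
  acc <- tilt_to_acceleration(rep(th, n), numeric(n), cfg)
  stab <- compute_displacements(acc, cfg$H1, cfg$H2)
  expect_equal(stab$dap, rep(cfg$H1 * tan(th), n), tolerance = 1e-12)
  expect_equal(stab$dml, numeric(n))

  # negating the ML tilt flips Ax only
  thml <- seq(-0.1, 0.1, length.out = n)
  a1 <- tilt_to_acceleration(rep(0.05, n), thml, cfg)
  a2 <- tilt_to_acceleration(rep(0.05, n), -thml, cfg)
  expect_equal(a1$ax, -a2$ax)
  expect_equal(a1$ay, a2$ay)
  expect_equal(a1$az, a2$az)

  expect_error(tilt_to_acceleration(numeric(3), numeric(4), cfg), "length")
})

test_that("noiseless generated patterns reconstruct their tilt geometry", {
  cfg <- rig_config(H1 = 1.2, H2 = 0.5, sensor_noise_std = 0)
  for (cls in c("AP", "ML", "UNS")) {
    tr <- simulate_tilt_trace(cls, cfg, seed = 31)
    acc <- tilt_to_acceleration(tr$theta_ap, tr$theta_ml, cfg)
    stab <- compute_displacements(acc, cfg$H1, cfg$H2)
    # exact inverse of the gravity projection, both axes active
    dap_expect <- cfg$H1 * sin(tr$theta_ap) /
      sqrt(cos(tr$theta_ap)^2 * cos(tr$theta_ml)^2 + sin(tr$theta_ml)^2)
    expect_equal(stab$dap, dap_expect, tolerance = 1e-12)
  }
})

test_that("dataset generation honours counts, labels and the separability margin", {
  cases <- default_rig_cases()
  # the six-case reference design totals 1239 patterns
  ds <- generate_dataset(cases, reference_counts(), seed = 2)
  expect_equal(ds$N, 1239)
  expect_equal(sum(reference_counts()), 1239)
  expect_equal(nrow(ds$manifest), 1239)

  # empty and label bookkeeping
  expect_equal(generate_dataset(cases[[1]], c(ST = 0), seed = 1)$N, 0)
  small <- generate_dataset(cases[[1]], c(ST = 2, UNS = 2), seed = 1)
  expect_equal(small$manifest$label, c(0L, 0L, 1L, 1L))
  expect_equal(small$manifest$class, c("ST", "ST", "UNS", "UNS"))

  # determinism: identical (config, seed) => identical dataset
  again <- generate_dataset(cases[[1]], c(ST = 2, UNS = 2), seed = 1)
  expect_identical(small, again)

  # separability margin on noiseless patterns: unstable displacement above
  # the configured bound, stable below half of it
  sub <- generate_dataset(cases, c(ST = 2, AP = 2, ML = 2, UNS = 2), seed = 3)
  for (p in sub$patterns) {
    stab <- compute_displacements(p$accel, p$config$H1, p$config$H2)
    dmax <- max(abs(stab$dap), abs(stab$dml))
    if (p$label_binary == 1L) {
      expect_gt(dmax, p$config$instability_displacement)
    } else {
      expect_lt(dmax, 0.5 * p$config$instability_displacement)
    }
  }
})

test_that("rig config validates its invariants", {
  expect_error(rig_config(H1 = -1), "positive")
  expect_error(rig_config(amp_stable = 0.2, amp_unstable = 0.1), "amp_unstable")
  expect_error(rig_config(sway_band = c(0.1, 60)), "sway_band")
  expect_error(rig_config(window_s = 0.005, fs = 100), "integer")
})

test_that("dataset CSV writer round-trips patterns and manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(rig_config(), c(ST = 1, UNS = 1), seed = 4)
  write_dataset(ds, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  p1 <- read_pattern(file.path(dir, "pattern_00001.csv"))
  expect_equal(nrow(p1), 1000)
  expect_equal(p1$ax, ds$patterns[[1]]$accel$ax, tolerance = 1e-12)
})
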