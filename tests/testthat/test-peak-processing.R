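# Baseline, noise, S/N-gated detection, internal recalibration and
# control-list matching.

test_that("baseline: flat input is returned exactly", {
  sp <- mass_spectrum(seq(8000, 9200, 0.5), rep(7, 2401))
  expect_equal(estimate_baseline(sp), rep(7, 2401), tolerance = 1e-12)
})

test_that("baseline stays near zero under an isolated peak", {
  sp <- simulate_spectrum(simulation_spec(
    species = data.frame(label = "x", mz = 8600, abundance = 100),
    noise_sd = 0, baseline_amplitude = 0))
  b <- estimate_baseline(sp, window = 100)
  expect_lt(max(b[abs(sp$mz - 8600) < 20]), 0.01 * 100)
})

test_that("baseline recovers a smooth exponential within 5% everywhere", {
  sp <- simulate_spectrum(simulation_spec(noise_sd = 0,
                                          baseline_amplitude = 50,
                                          baseline_decay = 300))
  truth <- 50 * exp(-(sp$mz - sp$mz[1]) / 300)
  expect_lt(max(abs(estimate_baseline(sp) - truth) / truth), 0.05)
})

test_that("baseline window bounds are enforced", {
  sp <- mass_spectrum(seq(8000, 9200, 0.5), rep(1, 2401))
  expect_error(estimate_baseline(sp, window = 0.1), "exceed the grid step")
  expect_error(estimate_baseline(sp, window = 2000), "smaller than the full")
})

test_that("noise estimate is MAD-consistent, with and without peaks", {
  m <- seq(8000, 9200, 0.5)
  set.seed(301)
  sp <- mass_spectrum(m, pmax(stats::rnorm(length(m), 20, 1), 0))
  est <- estimate_noise(sp, rep(20, length(m)))
  expect_gt(est, 0.9)
  expect_lt(est, 1.1)
  # noise-free trace
  spf <- mass_spectrum(m, rep(3, length(m)))
  expect_identical(estimate_noise(spf, rep(3, length(m))), 0)
  # masking excludes a tall peak
  set.seed(302)
  y <- 100 + stats::rnorm(length(m), 0, 5) +
    2000 * exp(-0.5 * ((m - 8600) / 4)^2)
  sp2 <- mass_spectrum(m, pmax(y, 0))
  est2 <- estimate_noise(sp2, rep(100, length(m)))
  expect_gt(est2, 4.5)
  expect_lt(est2, 5.5)
  expect_error(estimate_noise(mass_spectrum(1:10, rep(1, 10))), "50 points")
})

test_that("detection: empty trace yields no peaks, S/N gate filters", {
  m <- seq(8000, 9200, 0.5)
  expect_identical(nrow(detect_peaks(mass_spectrum(m, rep(0, length(m))),
                                     noise_sd = 1)), 0L)
  # two Gaussians, apexes 100 and 3; noise 1, threshold 5 -> only one survives
  sp <- simulate_spectrum(simulation_spec(
    species = data.frame(label = c("big", "small"), mz = c(8300, 8900),
                         abundance = c(100, 3)),
    noise_sd = 0, baseline_amplitude = 0))
  pk <- detect_peaks(sp, noise_sd = 1, snr_threshold = 5)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$centroid_mz - 8300), 0.5)
  expect_gt(pk$snr, 50)
})

test_that("centroid lands within one grid step of the simulated mean", {
  sp <- simulate_spectrum(simulation_spec(
    species = data.frame(label = "x", mz = 8612.3, abundance = 100),
    noise_sd = 1, baseline_amplitude = 0, seed = 17L))
  pk <- detect_peaks(sp, noise_sd = 1)
  main <- pk[which.max(pk$area), ]
  expect_lt(abs(main$centroid_mz - 8612.3), 0.5)
  # area of a unit-apex Gaussian: abundance * sigma * sqrt(2*pi)
  expect_equal(main$area, 100 * 4 * sqrt(2 * pi), tolerance = 0.05)
})

test_that("raising the threshold never adds peaks (monotone shrinkage)", {
  set.seed(411)
  for (rep_i in 1:20) {
    sp <- simulate_spectrum(simulation_spec(
      species = data.frame(label = letters[1:2],
                           mz = sort(stats::runif(2, 8100, 9100)),
                           abundance = stats::runif(2, 3, 60)),
      noise_sd = 1, baseline_amplitude = 5,
      seed = sample.int(1e6, 1)))
    b <- estimate_baseline(sp)
    nz <- estimate_noise(sp, b)
    apexes <- lapply(c(3, 5, 8, 15), function(thr) {
      detect_peaks(sp, b, nz, snr_threshold = thr)$apex_mz
    })
    for (j in 2:length(apexes)) {
      expect_true(all(apexes[[j]] %in% apexes[[j - 1]]))
    }
  }
})

test_that("areas scale exactly with intensity", {
  sp <- simulate_spectrum(simulation_spec(
    species = data.frame(label = "x", mz = 8600, abundance = 80),
    noise_sd = 1, baseline_amplitude = 0, seed = 23L))
  pk1 <- detect_peaks(sp, noise_sd = 1)
  sp3 <- mass_spectrum(sp$mz, sp$intensity * 3)
  pk3 <- detect_peaks(sp3, noise_sd = 3)
  expect_identical(nrow(pk1), nrow(pk3))
  expect_equal(pk3$area, 3 * pk1$area, tolerance = 1e-12)
})

test_that("apex enumeration equals the brute-force oracle on short grids", {
  set.seed(500)
  for (rep_i in 1:10) {
    m <- seq(100, 199.5, 0.5) # 200 points
    y <- pmax(stats::rnorm(length(m), 2, 1) +
                30 * exp(-0.5 * ((m - stats::runif(1, 120, 180)) / 2)^2), 0)
    sp <- mass_spectrum(m, y)
    pk <- detect_peaks(sp, baseline = rep(0, length(m)), noise_sd = 1,
                       snr_threshold = 5)
    expect_identical(pk$apex_mz,
                     brute_force_apexes(sp, rep(0, length(m)), 1, 5))
  }
})

test_that("calibration recovers an injected offset and is idempotent", {
  cl <- well_control_list("Ac-T")
  rx <- reaction_spec("UBE2Q1", "Ac-T")
  sp <- simulate_well(rx, c(`Ub-T` = 0.4), cl, noise_sd = 1,
                      calibration_offset = 3, seed = 31L)
  b <- estimate_baseline(sp)
  pk <- detect_peaks(sp, b, estimate_noise(sp, b))
  cal <- calibrate(pk, cl)
  expect_equal(cal$model$shift, -3, tolerance = 0.5 / 3)
  expect_lt(abs(cal$model$residual), 1e-9)
  # idempotence: a second calibration is the identity
  cal2 <- calibrate(cal$peaks, cl)
  expect_lt(abs(cal2$model$shift), 1e-9)
  expect_equal(cal2$peaks$centroid_mz, cal$peaks$centroid_mz,
               tolerance = 1e-12)
})

test_that("no-standard mode yields an identity calibration with a message", {
  ub <- ub_species()
  cl <- build_mass_control_list(ub, nucleophile_panel()["Ac-K"])
  pk <- data.frame(centroid_mz = 8565.9, apex_mz = 8565.5,
                   apex_intensity = 10, area = 100, snr = 10,
                   matched_label = NA_character_)
  expect_message(cal <- calibrate(pk, cl), "identity")
  expect_identical(cal$model$shift, 0)
})

test_that("calibration fails loudly when the standard peak is absent", {
  cl <- well_control_list("Ac-K")
  pk <- data.frame(centroid_mz = 8565.9, apex_mz = 8565.5,
                   apex_intensity = 10, area = 100, snr = 10,
                   matched_label = NA_character_)
  expect_error(calibrate(pk, cl), "calibration failed")
})

test_that("matching: nearest assignment, ties to lower m/z, zero for misses", {
  cl <- well_control_list("Ac-K") # Ub 8565.9, Ub-K 8736.1, 15N 8670.2
  pk <- data.frame(centroid_mz = c(8735.5, 8670.2),
                   apex_mz = c(8735.5, 8670.2),
                   apex_intensity = c(5, 50), area = c(55, 500),
                   snr = c(6, 60), matched_label = NA_character_)
  mm <- match_peaks(pk, cl)
  expect_identical(
    mm$matches$matched[mm$matches$label %in% c("Ub-K", "15N-Ub")],
    c(TRUE, TRUE))
  expect_identical(mm$matches$area[mm$matches$label == "Ub"], 0)
  expect_identical(mm$peaks$matched_label, c("Ub-K", "15N-Ub"))
  # no peaks: every entry reported unmatched with zero area
  mm0 <- match_peaks(pk[0, ], cl)
  expect_true(all(!mm0$matches$matched))
  expect_true(all(mm0$matches$area == 0))
  # equidistant peak between two synthetic entries -> lower-m/z entry wins
  cl2 <- structure(
    data.frame(label = c("lo", "hi"), expected_mz = c(100, 104),
               role = c("adduct", "adduct"),
               source = c("computed", "computed")),
    tolerance = 5, class = c("mass_control_list", "data.frame"))
  pk2 <- data.frame(centroid_mz = 102, apex_mz = 102, apex_intensity = 10,
                    area = 10, snr = 10, matched_label = NA_character_)
  expect_warning(mm2 <- match_peaks(pk2, cl2), "equidistant")
  expect_identical(mm2$peaks$matched_label, "lo")
})
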