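test_that("amplitude calibration is zero at zero target and monotone", {
  expect_equal(calibrate_amplitude(0, 1, 80), 0)
  amps <- vapply(c(10, 30, 80, 160), calibrate_amplitude,
                 numeric(1), freq_hz = 1, sample_rate_hz = 80)
  expect_true(all(diff(amps) > 0))
  expect_error(calibrate_amplitude(-5, 1, 80), ">= 0")
  expect_error(calibrate_amplitude(1e6, 1, 80), "unreachable")
})

test_that("a calibrated amplitude reproduces its ENMO target on simulation", {
  p <- make_participant(101)
  proto <- protocol_spec("t", 80, "hip",
    activity_template("steady", 600, 2, 0, 1.0, c(hip = 50), c(hip = 0)))
  sim <- simulate_raw_signal(p, proto, "hip", noise_scale = 0)
  measured <- mean(enmo_per_second(sim$signal)$enmo_mg)
  expect_gte(measured, 47.5)
  expect_lte(measured, 52.5)
})

test_that("zero-movement templates give a pure gravity signal", {
  p <- make_participant(7)
  proto <- protocol_spec("t", 80, "hip",
    activity_template("still", 60, 1, 0, 0.5, c(hip = 0), c(hip = 0)))
  sim <- simulate_raw_signal(p, proto, "hip")
  e <- mean(enmo_per_second(sim$signal)$enmo_mg)
  expect_lt(e, 1.5)  # only the sensor noise floor remains
  norms <- with(sim$signal, sqrt(x_g^2 + y_g^2 + z_g^2))
  expect_equal(mean(norms), 1, tolerance = 0.005)
})

test_that("per-activity bout ENMO tracks the published per-site targets", {
  proto <- default_calibration_protocol()
  check_bout <- function(label, target, n_participants = 6) {
    vals <- vapply(seq_len(n_participants), function(i) {
      p <- make_participant(1000 + i)
      sub <- proto
      keep <- sub$activities$label == label
      sub$activities <- sub$activities[keep, ]
      sim <- simulate_raw_signal(p, sub, "hip", noise_scale = 0)
      mean(enmo_per_second(sim$signal)$enmo_mg)
    }, numeric(1))
    mean(vals)
  }
  lying <- check_bout("lying_still", 3.4)
  expect_gte(lying, 3.4 * 0.8)
  expect_lte(lying, 3.4 * 1.2)
  brisk <- check_bout("brisk_walk", 137.2)
  expect_gte(brisk, 137.2 * 0.8)
  expect_lte(brisk, 137.2 * 1.2)
})

test_that("unknown wear sites are refused by name", {
  p <- make_participant(3)
  expect_error(simulate_raw_signal(p, tiny_protocol(), "ankle"), "ankle")
})

test_that("identical seeds give identical output, different seeds differ", {
  p <- make_participant(77)
  proto <- tiny_protocol()
  s1 <- simulate_raw_signal(p, proto, "hip")
  s2 <- simulate_raw_signal(p, proto, "hip")
  expect_identical(s1$signal, s2$signal)
  expect_identical(s1$annotation, s2$annotation)
  b1 <- simulate_breath_series(p, proto)
  b2 <- simulate_breath_series(p, proto)
  expect_identical(b1, b2)
  s3 <- simulate_raw_signal(make_participant(78), proto, "hip")
  expect_false(identical(s1$signal, s3$signal))
})

test_that("steady-state breath VO2 follows mass x resting rate at 1 MET", {
  p <- make_participant(55, mass = 100, rv = 2.8)
  proto <- protocol_spec("t", 80, "hip",
    activity_template("lie", 600, 1.0, 0, 0.5, c(hip = 3), c(hip = 0)))
  b <- simulate_breath_series(p, proto, artifact_rate = 0, noise_cv = 0)
  late <- b$vo2_mlmin[b$time_s > 300]
  expect_equal(mean(late), 280, tolerance = 0.01)
})

test_that("artifact-free breaths stay within 4 SD at steady state", {
  p <- make_participant(56)
  proto <- protocol_spec("t", 80, "hip",
    activity_template("sit", 600, 1.2, 0, 0.5, c(hip = 5), c(hip = 0)))
  b <- simulate_breath_series(p, proto, artifact_rate = 0)
  late <- b$vo2_mlmin[b$time_s > 200]
  dev <- abs(late - mean(late)) / sd(late)
  expect_true(all(dev <= 4))
})

test_that("breath gaps stay within the physiological 1.5-6 s band", {
  p <- make_participant(57)
  b <- simulate_breath_series(p, tiny_protocol())
  gaps <- diff(b$time_s)
  expect_true(all(gaps >= 1.5 - 1e-9 & gaps <= 6 + 1e-9))
  expect_error(simulate_breath_series(p, tiny_protocol(), artifact_rate = 0.5),
               "0.2")
})

test_that("bout METs recovered through the calorimetry chain stay within 0.15", {
  p <- make_participant(58, mass = 75, rv = 2.8)
  proto <- tiny_protocol()
  b <- simulate_breath_series(p, proto, artifact_rate = 0.05, noise_scale = 0)
  ann <- attr(b, "annotation")
  # 90 s bouts: average over the post-transient half of each bout
  mets <- activity_mets(b, ann, 75, window_s = 45)
  expect_true(all(abs(mets$met - proto$activities$met_mean) <= 0.15))
})

test_that("ground-truth classes accompany every bout and cover all classes", {
  p <- make_participant(59)
  bouts <- attr(simulate_breath_series(p, default_calibration_protocol()),
                "annotation")
  expect_true(all(!is.na(bouts$intensity_true)))
  expect_identical(bouts$intensity_true,
                   classify_intensity(bouts$met_true))
  # default protocols cover >= 2 bouts of every class at template level
  for (proto in list(default_calibration_protocol(),
                     default_crossval_protocol())) {
    tpl_class <- classify_intensity(proto$activities$met_mean)
    expect_true(all(table(tpl_class) >= 2))
  }
})

test_that("participant draws are deterministic per arm and seed", {
  a <- simulate_participants(8, 123, "calibration")
  b <- simulate_participants(8, 123, "calibration")
  expect_identical(a, b)
  cv <- simulate_participants(8, 123, "crossval")
  expect_false(identical(a$body_mass_kg, cv$body_mass_kg))
  expect_true(all(a$body_mass_kg > 0 & a$resting_vo2_mlkgmin > 0))
})
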