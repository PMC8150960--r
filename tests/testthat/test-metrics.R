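test_that("ENMO of static signals matches the norm-minus-one definition", {
  expect_equal(enmo_per_second(make_signal(0, 0, 1))$enmo_mg, c(0, 0))
  # norm exactly 1 on an oblique orientation
  expect_equal(enmo_per_second(make_signal(0.6, 0, 0.8))$enmo_mg, c(0, 0))
  expect_equal(enmo_per_second(make_signal(0, 0, 1.05))$enmo_mg, c(50, 50))
  # negative norms truncate to zero, they do not go negative
  expect_equal(enmo_per_second(make_signal(0, 0, 0.9))$enmo_mg, c(0, 0))
})

test_that("per-sample truncation happens before per-second averaging", {
  # alternate 1.1 g and 0.9 g: per-sample ENMO is 100 and 0 -> mean 50 mg,
  # whereas truncating the per-second mean of (norm - 1) would give 0
  z <- rep(c(1.1, 0.9), 40)
  sig <- make_signal(0, 0, 0, seconds = 1)
  sig$z_g <- z
  expect_equal(enmo_per_second(sig)$enmo_mg, 50)
})

test_that("ENMO is invariant under rotation of the static orientation", {
  set.seed(11)
  sig <- make_sinusoid_signal(0.1, 1, seconds = 4)
  base <- enmo_per_second(sig)$enmo_mg
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3)
    rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
    rot <- as.matrix(sig[, c("x_g", "y_g", "z_g")]) %*% (rx %*% rz)
    rsig <- tibble::tibble(time_s = sig$time_s, x_g = rot[, 1],
                           y_g = rot[, 2], z_g = rot[, 3])
    attr(rsig, "sample_rate_hz") <- 80
    expect_equal(enmo_per_second(rsig)$enmo_mg, base, tolerance = 1e-9)
  }
})

test_that("ENMO errors on an empty or sub-second signal", {
  expect_error(enmo_per_second(make_signal(0, 0, 1)[0, ]), "full second")
  short <- make_signal(0, 0, 1)[1:40, ]
  attr(short, "sample_rate_hz") <- 80
  expect_error(enmo_per_second(short), "full second")
})

test_that("counts are zero for static signals and reject DC", {
  z <- counts_per_second(make_signal(0, 0, 0, seconds = 4))
  expect_true(all(z$counts_x == 0 & z$counts_y == 0 & z$counts_z == 0))
  dc <- counts_per_second(make_signal(0, 0, 1, seconds = 4))
  expect_true(all(dc$counts_vm == 0))
})

test_that("counts follow the 0.25-2.5 Hz pass band", {
  in_band <- counts_per_second(make_sinusoid_signal(1, 1, seconds = 12))
  out_band <- counts_per_second(make_sinusoid_signal(1, 5, seconds = 12))
  # drop filter-settle edges
  mid <- 4:9
  expect_true(mean(out_band$counts_vm[mid]) < mean(in_band$counts_vm[mid]))
  expect_true(all(in_band$counts_vm >= 0))
  expect_true(is.integer(in_band$counts_vm))
})

test_that("counts require a sample rate of at least 30 Hz", {
  slow <- make_signal(0, 0, 1, rate = 20)
  expect_error(counts_per_second(slow), ">= 30")
})

test_that("epoch aggregation averages ENMO, sums counts, drops partials", {
  expect_equal(aggregate_epochs(rep(10, 5), 5, "mean")$value, 10)
  expect_equal(aggregate_epochs(1:5, 5, "sum")$value, 15)
  expect_equal(nrow(aggregate_epochs(rep(1, 7), 5, "sum")), 1)
  # aggregate-then-mean equals mean of per-second values over whole epochs
  set.seed(3)
  v <- runif(40)
  expect_equal(mean(aggregate_epochs(v, 5, "mean")$value), mean(v))
})

test_that("activity windows are trimmed, capped at 3 min and centered", {
  ann <- tibble::tibble(activity = c("a", "b", "c"),
                        start_s = c(0, 300, 700),
                        end_s = c(200, 660, 725))
  w <- trim_activity_window(ann)
  expect_equal(w$win_end_s[1] - w$win_start_s[1], 170)  # 200 - 30 < 180
  expect_equal(w$win_end_s[2] - w$win_start_s[2], 180)  # capped at 3 min
  expect_equal(w$win_start_s[2], 300 + 90)              # centered
  expect_true(w$excluded[3])                            # 25 s bout
  expect_false(any(w$excluded[1:2]))
  # windows align to whole epochs
  expect_equal((w$win_end_s[1] - w$win_start_s[1]) %% 5, 0)
})

test_that("bout ENMO increases strictly with sinusoid amplitude", {
  enmo_at <- function(a) {
    mean(enmo_per_second(make_sinusoid_signal(a, 1, seconds = 6))$enmo_mg)
  }
  vals <- vapply(c(0.02, 0.04, 0.08, 0.16), enmo_at, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(enmo_at(0.08), enmo_at(0.04))
})

test_that("epoch_table cuts windows per bout and carries identifiers", {
  p <- make_participant(5)
  proto <- tiny_protocol()
  sim <- simulate_raw_signal(p, proto, "hip")
  eps <- epoch_table(sim$signal, sim$annotation)
  expect_setequal(unique(eps$activity), proto$activities$label)
  # 90 s bouts -> 60 s windows -> 12 epochs each
  expect_equal(nrow(eps), 6 * 12)
  expect_true(all(eps$enmo_mg >= 0))
  expect_true(all(eps$counts_per_epoch >= 0))
  expect_equal(unique(eps$site), "hip")
  expect_equal(unique(eps$participant), p$id)
})
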