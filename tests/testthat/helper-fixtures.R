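# Shared fixtures and independent oracles for the test suite.

# constant-valued tri-axial signal
make_signal <- function(x, y, z, seconds = 2, rate = 80) {
  n <- seconds * rate
  sig <- tibble::tibble(
    time_s = (seq_len(n) - 1) / rate,
    x_g = rep_len(x, n), y_g = rep_len(y, n), z_g = rep_len(z, n)
  )
  attr(sig, "sample_rate_hz") <- rate
  sig
}

# sinusoid of given amplitude/frequency on the z axis around 1 g
make_sinusoid_signal <- function(amplitude, freq_hz, seconds = 10, rate = 80) {
  t <- (seq_len(seconds * rate) - 1) / rate
  sig <- tibble::tibble(
    time_s = t, x_g = 0, y_g = 0,
    z_g = 1 + amplitude * sin(2 * pi * freq_hz * t)
  )
  attr(sig, "sample_rate_hz") <- rate
  sig
}

make_participant <- function(seed = 42L, mass = 70, rv = 2.8) {
  tibble::tibble(id = paste0("T", seed), body_mass_kg = mass,
                 height_cm = 165, resting_vo2_mlkgmin = rv,
                 seed = as.integer(seed))
}

# small two-site protocol with clearly separated intensity classes;
# durations sized so tests stay fast
tiny_protocol <- function(rate = 80, epoch_s = 5) {
  s <- function(hip, wrist) c(hip = hip, nondom_wrist = wrist)
  acts <- dplyr::bind_rows(
    activity_template("rest_a", 90, 1.0, 0.1, 0.5, s(4, 7), s(2, 3)),
    activity_template("rest_b", 90, 1.2, 0.1, 0.6, s(6, 10), s(2, 4)),
    activity_template("chore_a", 90, 2.0, 0.15, 1.0, s(12, 60), s(4, 15)),
    activity_template("chore_b", 90, 2.4, 0.15, 1.0, s(20, 80), s(5, 20)),
    activity_template("walk_a", 90, 3.4, 0.2, 1.6, s(90, 110), s(20, 30)),
    activity_template("walk_b", 90, 4.0, 0.2, 1.9, s(130, 180), s(30, 45))
  )
  protocol_spec("tiny", rate, c("hip", "nondom_wrist"), acts, epoch_s)
}

# brute-force Mann-Whitney AUC with ties counted one half, oriented so that
# larger (gte) or smaller (lt) values indicate the positive class
oracle_auc <- function(values, positive, direction = "gte") {
  pos <- values[positive]
  neg <- values[!positive]
  cmp <- outer(pos, neg, function(a, b) {
    if (direction == "gte") (a > b) + 0.5 * (a == b) else (a < b) + 0.5 * (a == b)
  })
  mean(cmp)
}

# exhaustive scan over a curve's candidate thresholds for the
# distance-to-corner minimum (ties: higher specificity, then lower threshold)
oracle_select <- function(curve) {
  ok <- is.finite(curve$thresholds)
  thr <- curve$thresholds[ok]
  sens <- curve$sensitivities[ok]
  spec <- curve$specificities[ok]
  d <- (1 - sens)^2 + (1 - spec)^2
  best <- order(d, -spec, thr)[1]
  list(threshold = thr[best], distance = d[best],
       sensitivity = sens[best], specificity = spec[best])
}

# exhaustive scan for the specificity-priority rule
oracle_select_spec <- function(curve, min_sens) {
  ok <- is.finite(curve$thresholds) & curve$sensitivities >= min_sens
  thr <- curve$thresholds[ok]
  sens <- curve$sensitivities[ok]
  spec <- curve$specificities[ok]
  best <- order(-spec, -sens, thr)[1]
  list(threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best])
}
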