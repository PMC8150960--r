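#' Simulate participant characteristics
#'
#' Draws body mass, height and resting oxygen uptake from distributions
#' matching the descriptive statistics of the two study arms (calibration:
#' mass 73.3 +/- 12.4 kg, height 166.0 +/- 8.5 cm, resting VO2 3.0 +/- 0.7
#' mL/kg/min; cross-validation: 72.6 +/- 11.9 kg, 159.9 +/- 8.7 cm,
#' 2.7 +/- 0.7 mL/kg/min).
#'
#' @param n Number of participants.
#' @param seed Integer seed; every participant receives a derived sub-seed.
#' @param arm `"calibration"` or `"crossval"`.
#'
#' @return A tibble with columns `id`, `body_mass_kg`, `height_cm`,
#'   `resting_vo2_mlkgmin`, `seed`.
#' @export
simulate_participants <- function(n, seed = 1L, arm = c("calibration", "crossval")) {
  arm <- match.arg(arm)
  pars <- switch(arm,
    calibration = list(mass = c(73.3, 12.4), height = c(166.0, 8.5), rv = c(3.0, 0.7)),
    crossval    = list(mass = c(72.6, 11.9), height = c(159.9, 8.7), rv = c(2.7, 0.7))
  )
  set.seed(sub_seed(seed, "participants", arm))
  tibble(
    id = sprintf("%s%02d", if (arm == "calibration") "C" else "V", seq_len(n)),
    body_mass_kg = pmax(rnorm(n, pars$mass[1], pars$mass[2]), 40),
    height_cm = pmax(rnorm(n, pars$height[1], pars$height[2]), 130),
    resting_vo2_mlkgmin = pmax(rnorm(n, pars$rv[1], pars$rv[2]), 1.5),
    seed = vapply(seq_len(n), function(i) sub_seed(seed, arm, i), integer(1))
  )
}

# Perpendicular (horizontal) movement SD in g for along-gravity amplitude
# `a`: proportional at small amplitudes, saturating near `cap` — body sway
# grows with task vigour but levels off, while vertical amplitude keeps
# growing during ambulation.
perp_sd_g <- function(a, perp_ratio, perp_cap_g) {
  perp_ratio * a / (1 + perp_ratio * a / perp_cap_g)
}

# 8-point Gauss-Hermite nodes for integrating over the lognormal jitter
# envelope (mean-1, log-SD `env_sigma`).
gh_nodes <- list(
  x = c(-2.93063742, -1.98165676, -1.15719371, -0.38118699,
        0.38118699, 1.15719371, 1.98165676, 2.93063742),
  w = c(1.99604072e-04, 1.70779830e-02, 2.07802326e-01, 6.61147013e-01,
        6.61147013e-01, 2.07802326e-01, 1.70779830e-02, 1.99604072e-04) /
    sqrt(pi)
)

# Expected per-sample ENMO (mg) of the synthetic waveform at sinusoid
# amplitude `a` (g). The waveform is: static norm bias + a*sin(2*pi*f*t)
# along gravity, Gaussian jitter of SD jitter_ratio*a*env along gravity,
# perpendicular jitter of SD perp_sd_g(a)*env on two axes, and a white
# sensor-noise floor; `env` is a slowly varying mean-1 lognormal envelope.
# Along-gravity terms enter the norm linearly, perpendicular ones to second
# order (p^2 / 2), so per-sample ENMO ~ max(mu + N(0, sigma), 0) with
# expectation mu*pnorm(mu/sigma) + sigma*dnorm(mu/sigma), averaged over the
# phase grid and the envelope distribution.
expected_enmo_mg <- function(a, jitter_ratio, noise_floor_mg, bias_mg = 0,
                             perp_ratio = 0, perp_cap_g = 0.15,
                             env_sigma = 0) {
  floor_g <- noise_floor_mg / 1000
  mu0 <- bias_mg / 1000 + a * sin(2 * pi * seq(0, 1, length.out = 181)[-181])
  ps <- perp_sd_g(a, perp_ratio, perp_cap_g)
  total <- 0
  for (k in seq_along(gh_nodes$x)) {
    env <- exp(env_sigma * sqrt(2) * gh_nodes$x[k] - env_sigma^2 / 2)
    sigma <- sqrt((jitter_ratio * a * env)^2 + floor_g^2)
    mu <- mu0 + (ps * env)^2  # two perp axes, each contributing p^2/2
    e_k <- if (sigma == 0) mean(pmax(mu, 0)) else {
      mean(mu * pnorm(mu / sigma) + sigma * dnorm(mu / sigma))
    }
    total <- total + gh_nodes$w[k] * e_k
  }
  total * 1000
}

#' Calibrate the sinusoid amplitude for a target mean ENMO
#'
#' Finds, by monotone bisection, the movement amplitude (in g) at which the
#' synthetic gravity-plus-movement waveform has the requested mean per-second
#' ENMO. The waveform model is a sinusoid at the movement frequency plus
#' Gaussian jitter whose SD scales with the amplitude (see the methods
#' vignette); its expected ENMO has a closed form, so the search is
#' deterministic.
#'
#' @param target_enmo_mg Target mean ENMO in mg (>= 0).
#' @param freq_hz Movement frequency in Hz (the expectation does not depend
#'   on it, but it is part of the waveform contract).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param jitter_ratio SD of along-gravity movement jitter as a multiple of
#'   the sinusoid amplitude (default 2).
#' @param noise_floor_mg White sensor-noise SD per axis in mg (default 1.5).
#' @param bias_mg Static norm bias of this recording in mg (default 0); when
#'   the bias alone meets or exceeds the target the amplitude is 0.
#' @param perp_ratio,perp_cap_g Perpendicular-movement scaling and
#'   saturation (defaults 4 and 0.15 g).
#' @param env_sigma Log-SD of the slowly varying jitter envelope
#'   (default 0.75).
#'
#' @return Amplitude in g.
#' @export
#' @examples
#' calibrate_amplitude(0, 1, 80)    # no movement
#' calibrate_amplitude(50, 1, 80)   # approx 50 mg mean ENMO
calibrate_amplitude <- function(target_enmo_mg, freq_hz, sample_rate_hz,
                                jitter_ratio = 2, noise_floor_mg = 1.5,
                                bias_mg = 0, perp_ratio = 4,
                                perp_cap_g = 0.15, env_sigma = 0.75) {
  if (target_enmo_mg < 0) abort("`target_enmo_mg` must be >= 0")
  if (target_enmo_mg == 0) return(0)
  f <- function(a) expected_enmo_mg(a, jitter_ratio, noise_floor_mg, bias_mg,
                                    perp_ratio, perp_cap_g, env_sigma)
  if (target_enmo_mg <= f(0)) return(0)
  hi <- 6  # beyond the +/-8 g dynamic range the target is unreachable
  if (f(hi) < target_enmo_mg) {
    abort(paste0("target of ", target_enmo_mg,
                 " mg is unreachable within the device dynamic range"))
  }
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_enmo_mg) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Band-limited Gaussian jitter: white noise smoothed with a moving average
# of `width` samples (width ~ rate/3 keeps the energy below ~3 Hz so it
# survives the 0.25-2.5 Hz counts band-pass), rescaled to unit marginal SD.
colored_noise <- function(n, width) {
  w <- max(3L, as.integer(width))
  x <- rnorm(n + 2 * w)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- sm[(w + 1):(w + n)]
  sm * sqrt(w)
}

# One bout's movement components (g): `along` the gravity axis (sinusoid
# plus envelope-modulated jitter) and two perpendicular jitter series
# (`perp1`, `perp2`). The mean-1 lognormal envelope varies on a ~1 s
# timescale, emulating the burst structure of everyday movement.
movement_series <- function(n, amplitude, freq_hz, sample_rate_hz,
                            jitter_ratio, perp_ratio, perp_cap_g,
                            env_sigma) {
  if (amplitude <= 0) {
    return(list(along = numeric(n), perp1 = numeric(n), perp2 = numeric(n)))
  }
  t <- (seq_len(n) - 1) / sample_rate_hz
  phase <- runif(1, 0, 2 * pi)
  base <- amplitude * sin(2 * pi * freq_hz * t + phase)
  env <- exp(env_sigma * colored_noise(n, sample_rate_hz) - env_sigma^2 / 2)
  jw <- sample_rate_hz / 3
  ps <- perp_sd_g(amplitude, perp_ratio, perp_cap_g)
  list(
    along = base + colored_noise(n, jw) * jitter_ratio * amplitude * env,
    perp1 = colored_noise(n, jw) * ps * env,
    perp2 = colored_noise(n, jw) * ps * env
  )
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Orthonormal basis completing `u` to a right-handed frame.
perp_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- ref - sum(ref * u) * u
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  list(v1 = v1, v2 = v2)
}

#' Simulate a raw tri-axial acceleration recording
#'
#' Generates one participant's continuous recording for one wear site: per
#' activity bout, a fixed random orientation of the 1 g gravity vector plus a
#' movement component (sinusoid at the activity's dominant frequency plus
#' band-limited Gaussian jitter) whose amplitude is calibrated so the bout's
#' mean ENMO matches a per-participant draw around the activity's per-site
#' target. White sensor noise is added on all three axes and samples are
#' clipped to the +/-8 g dynamic range.
#'
#' @param participant One row of [simulate_participants()] (or a list with
#'   `id` and `seed`).
#' @param protocol An [protocol_spec()] object.
#' @param site Wear site; must be one of `protocol$wear_sites`.
#' @param noise_scale Multiplier (default 1) on the between-participant SD of
#'   bout ENMO targets and on the static norm bias; 0 pins every bout to the
#'   template mean.
#' @param jitter_ratio,noise_floor_mg,perp_ratio,perp_cap_g,env_sigma
#'   Waveform parameters, see [calibrate_amplitude()].
#' @param bias_sd_mg SD of the per-recording static norm bias in mg
#'   (default 2.5, truncated at +/- 3.5 mg).
#'
#' @return A list with `signal` (tibble: `time_s`, `x_g`, `y_g`, `z_g`, with
#'   attributes `sample_rate_hz` and `participant`) and `annotation` (tibble:
#'   `participant`, `activity`, `start_s`, `end_s`, `met_true`,
#'   `intensity_true`).
#' @export
simulate_raw_signal <- function(participant, protocol, site,
                                noise_scale = 1, jitter_ratio = 2,
                                noise_floor_mg = 1.5, perp_ratio = 4,
                                perp_cap_g = 0.15, env_sigma = 0.75,
                                bias_sd_mg = 2.5) {
  if (!site %in% protocol$wear_sites) {
    abort(paste0("unknown wear site '", site, "'; protocol '", protocol$name,
                 "' has: ", paste(protocol$wear_sites, collapse = ", ")))
  }
  acts <- protocol$activities
  rate <- protocol$sample_rate_hz
  pseed <- participant$seed[[1]]
  bouts <- bout_truths(participant, protocol, noise_scale)

  # static norm bias of this recording (calibration / posture offset):
  # present in ENMO but invisible to the band-pass counts filter
  set.seed(sub_seed(pseed, "bias", site))
  bias_mg <- max(min(rnorm(1, 0, bias_sd_mg * noise_scale), 3.5), -3.5)

  sig_list <- vector("list", nrow(acts))
  for (i in seq_len(nrow(acts))) {
    n <- round(acts$duration_s[i] * rate)
    target_i <- draw_bout_enmo(pseed, acts, i, site, noise_scale)
    set.seed(sub_seed(pseed, "signal", site, i))
    bout_bias <- if (target_i == 0) 0 else bias_mg
    amp <- calibrate_amplitude(target_i, acts$movement_freq_hz[i], rate,
                               jitter_ratio, noise_floor_mg, bout_bias,
                               perp_ratio, perp_cap_g, env_sigma)
    u <- random_unit_vector()
    pb <- perp_basis(u)
    mv <- movement_series(n, amp, acts$movement_freq_hz[i], rate,
                          jitter_ratio, perp_ratio, perp_cap_g, env_sigma)
    mag <- 1 + bout_bias / 1000 + mv$along
    xyz <- cbind(mag * u[1], mag * u[2], mag * u[3]) +
      outer(mv$perp1, pb$v1) + outer(mv$perp2, pb$v2) +
      matrix(rnorm(3 * n, 0, noise_floor_mg / 1000), ncol = 3)
    xyz[xyz > 8] <- 8
    xyz[xyz < -8] <- -8
    sig_list[[i]] <- xyz
  }
  xyz <- do.call(rbind, sig_list)
  signal <- tibble(
    time_s = (seq_len(nrow(xyz)) - 1) / rate,
    x_g = xyz[, 1], y_g = xyz[, 2], z_g = xyz[, 3]
  )
  attr(signal, "sample_rate_hz") <- rate
  attr(signal, "participant") <- participant$id[[1]]
  attr(signal, "site") <- site
  list(signal = signal, annotation = bouts)
}

# Ground-truth bout table shared by the signal and breath generators: one MET
# draw per participant x activity (independent of site), with the implied
# intensity class stored alongside for parameter-recovery tests.
bout_truths <- function(participant, protocol, noise_scale = 1) {
  acts <- protocol$activities
  pseed <- participant$seed[[1]]
  start_s <- cumsum(c(0, head(acts$duration_s, -1)))
  met_true <- vapply(seq_len(nrow(acts)), function(i) {
    set.seed(sub_seed(pseed, "met", i))
    max(rnorm(1, acts$met_mean[i], acts$met_sd[i] * noise_scale), 0.5)
  }, numeric(1))
  tibble(
    participant = participant$id[[1]],
    activity = acts$label,
    start_s = start_s,
    end_s = start_s + acts$duration_s,
    met_true = met_true,
    intensity_true = classify_intensity(met_true)
  )
}

draw_bout_enmo <- function(pseed, acts, i, site, noise_scale) {
  tgt <- acts$enmo_target_mg[[i]][[site]]
  sdv <- acts$enmo_sd_mg[[i]][[site]]
  if (tgt == 0) return(0)
  set.seed(sub_seed(pseed, "enmo", site, i))
  max(rnorm(1, tgt, sdv * noise_scale), 0.3)
}

#' Simulate a breath-by-breath gas-exchange recording
#'
#' Breath events arrive with exponential inter-breath gaps (clipped to
#' 1.5-6 s, rate increasing with intensity). Each bout's steady-state oxygen
#' uptake is `mass * (resting_vo2 + (MET - 1) * met_constant)` mL/min — the
#' participant's own resting rate plus the activity's net cost — approached
#' through a first-order exponential on-transient (tau = 25 s) from the
#' previous bout's level, with multiplicative Gaussian noise. A fraction
#' `artifact_rate` of breaths is replaced by upward spikes well above 2 SD of
#' the local level, emulating measurement artifacts.
#'
#' @inheritParams simulate_raw_signal
#' @param artifact_rate Fraction of breaths replaced by spikes (0 to < 0.2).
#' @param met_constant mL O2/kg/min per MET used to convert net MET cost to
#'   VO2 (default 2.8, the older-adult value).
#' @param noise_cv Coefficient of variation of breath-to-breath noise
#'   (default 0.05).
#'
#' @return A tibble (`time_s`, `vo2_mlmin`, `vco2_mlmin`) with the bout table
#'   attached as attribute `annotation`.
#' @export
simulate_breath_series <- function(participant, protocol, artifact_rate = 0.02,
                                   noise_scale = 1, met_constant = 2.8,
                                   noise_cv = 0.05) {
  if (artifact_rate < 0 || artifact_rate >= 0.2) {
    abort("`artifact_rate` must be in [0, 0.2)")
  }
  bouts <- bout_truths(participant, protocol, noise_scale)
  mass <- participant$body_mass_kg[[1]]
  rv <- participant$resting_vo2_mlkgmin[[1]]
  if (is.null(rv) || is.na(rv)) rv <- met_constant
  pseed <- participant$seed[[1]]
  set.seed(sub_seed(pseed, "breaths"))

  total_s <- max(bouts$end_s)
  # steady-state VO2 level per bout (mL/min)
  level <- mass * (rv + (bouts$met_true - 1) * met_constant)

  times <- numeric(0)
  t <- 0
  while (t < total_s) {
    i <- which(bouts$start_s <= t & t < bouts$end_s)[1]
    gap <- min(max(rexp(1, rate = (10 + 5 * bouts$met_true[i]) / 60), 1.5), 6)
    t <- t + gap
    if (t < total_s) times <- c(times, t)
  }
  tau <- 25
  vo2 <- numeric(length(times))
  prev_level <- mass * rv
  for (b in seq_len(nrow(bouts))) {
    idx <- which(times >= bouts$start_s[b] & times < bouts$end_s[b])
    dt <- times[idx] - bouts$start_s[b]
    mu <- level[b] + (prev_level - level[b]) * exp(-dt / tau)
    vo2[idx] <- mu * (1 + rnorm(length(idx), 0, noise_cv))
    if (length(idx) > 0) {
      prev_level <- level[b] + (prev_level - level[b]) *
        exp(-(bouts$end_s[b] - bouts$start_s[b]) / tau)
    }
  }
  if (artifact_rate > 0) {
    spike <- runif(length(vo2)) < artifact_rate
    vo2[spike] <- vo2[spike] * (1 + runif(sum(spike), 0.35, 0.7))
  }
  vo2 <- pmax(vo2, 0)
  out <- tibble(
    time_s = times,
    vo2_mlmin = vo2,
    vco2_mlmin = vo2 * 0.85 * (1 + rnorm(length(vo2), 0, noise_cv))
  )
  attr(out, "annotation") <- bouts
  attr(out, "participant") <- participant$id[[1]]
  out
}
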