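#' Match breath-by-breath VO2 to a per-second grid
#'
#' Each breath is assigned to the second containing it (floor of its
#' timestamp); seconds with several breaths take their mean, and seconds
#' without a breath carry the most recent value forward for up to
#' `max_gap_s` seconds, beyond which they are missing.
#'
#' @param breaths Tibble with `time_s` and `vo2_mlmin` (strictly increasing
#'   times).
#' @param max_gap_s Longest gap (s) bridged by last-observation-carried-
#'   forward (default 10).
#'
#' @return A tibble with `second` (0-based, covering the recording) and
#'   `vo2_mlmin` (NA where no breath within `max_gap_s`).
#' @export
match_breaths_to_seconds <- function(breaths, max_gap_s = 10) {
  if (nrow(breaths) == 0) abort("`breaths` must be non-empty")
  if (any(diff(breaths$time_s) <= 0)) abort("breath times must be strictly increasing")
  sec <- floor(breaths$time_s)
  by_sec <- tibble(second = sec, vo2 = breaths$vo2_mlmin) %>%
    group_by(.data$second) %>%
    summarise(vo2_mlmin = mean(.data$vo2), .groups = "drop")
  grid_sec <- 0:max(sec)
  # carry the most recent breath value forward, tracking its age
  idx <- findInterval(grid_sec, by_sec$second)
  filled <- by_sec$vo2_mlmin[pmax(idx, 1)]
  age <- grid_sec - by_sec$second[pmax(idx, 1)]
  filled[idx == 0 | age > max_gap_s] <- NA_real_
  tibble(second = grid_sec, vo2_mlmin = filled)
}

#' Remove VO2 measurement peaks
#'
#' Drops values deviating more than `sd_mult` standard deviations from the
#' whole-window mean, in a single pass by default. Artifact spikes are
#' typically upward, but dropouts are as unphysiological, so the test is
#' two-sided by default; set `two_sided = FALSE` for spikes only. With
#' `iterate = TRUE` the pass is repeated until no value is removed.
#'
#' @param x Numeric values (NAs ignored for the statistics and kept out of
#'   the output).
#' @param sd_mult SD multiplier (default 2).
#' @param two_sided Drop both high and low deviants (default TRUE).
#' @param iterate Repeat until stable (default FALSE, matching a single
#'   screening pass).
#'
#' @return The surviving values.
#' @export
#' @examples
#' remove_vo2_peaks(c(rep(300, 119), 3000))  # spike removed
remove_vo2_peaks <- function(x, sd_mult = 2, two_sided = TRUE,
                             iterate = FALSE) {
  x <- x[!is.na(x)]
  if (length(x) < 3) {
    warn("fewer than 3 values; returning unchanged")
    return(x)
  }
  repeat {
    m <- mean(x)
    s <- sd(x)
    dev <- if (two_sided) abs(x - m) else (x - m)
    keep <- is.na(s) | s == 0 | dev <= sd_mult * s
    if (all(keep) || !iterate) return(x[keep])
    x <- x[keep]
    if (length(x) < 3) return(x)
  }
}

#' Steady-state MET value of one activity bout
#'
#' Averages the peak-cleaned per-second VO2 over the last part of the bout
#' (default 2 min) and divides by body mass and the 1-MET oxygen-uptake
#' constant (default 2.8 mL/kg/min, the older-adult value; 3.5 is the usual
#' adult value).
#'
#' @param vo2_seconds Per-second VO2 tibble from
#'   [match_breaths_to_seconds()].
#' @param start_s,end_s Bout limits in seconds.
#' @param mass_kg Body mass in kg.
#' @param met_constant mL O2/kg/min corresponding to 1 MET (default 2.8).
#' @param window_s Averaging window at the end of the bout (default 120 s,
#'   capped at the bout length).
#' @param sd_mult,two_sided Peak-removal settings, see
#'   [remove_vo2_peaks()].
#' @param min_usable_s Minimum usable seconds required (default 30); below
#'   it the bout is flagged unusable.
#'
#' @return A one-row tibble: `met`, `vo2_mlkgmin`, `n_seconds_used`,
#'   `usable`.
#' @export
steady_state_met <- function(vo2_seconds, start_s, end_s, mass_kg,
                             met_constant = 2.8, window_s = 120,
                             sd_mult = 2, two_sided = TRUE,
                             min_usable_s = 30) {
  stopifnot_scalar_pos(mass_kg, "mass_kg")
  win_start <- max(start_s, end_s - window_s)
  vals <- vo2_seconds$vo2_mlmin[vo2_seconds$second >= win_start &
                                  vo2_seconds$second < end_s]
  vals <- vals[!is.na(vals)]
  if (length(vals) < min_usable_s) {
    return(tibble(met = NA_real_, vo2_mlkgmin = NA_real_,
                  n_seconds_used = length(vals), usable = FALSE))
  }
  cleaned <- remove_vo2_peaks(vals, sd_mult = sd_mult, two_sided = two_sided)
  vo2_rel <- mean(cleaned) / mass_kg
  tibble(met = vo2_rel / met_constant, vo2_mlkgmin = vo2_rel,
         n_seconds_used = length(cleaned), usable = TRUE)
}

#' Resting metabolic rate from a lying-still bout
#'
#' Averages peak-cleaned per-second VO2 over the last 5 min of the bout and
#' divides by body mass, giving the participant's own 1-MET value in
#' mL/kg/min.
#'
#' @inheritParams steady_state_met
#'
#' @return Resting VO2 in mL/kg/min.
#' @export
resting_rate <- function(vo2_seconds, start_s, end_s, mass_kg,
                         sd_mult = 2, two_sided = TRUE) {
  stopifnot_scalar_pos(mass_kg, "mass_kg")
  if (end_s - start_s < 300) {
    abort("lying bout must last at least 5 min to estimate the resting rate")
  }
  vals <- vo2_seconds$vo2_mlmin[vo2_seconds$second >= end_s - 300 &
                                  vo2_seconds$second < end_s]
  vals <- vals[!is.na(vals)]
  cleaned <- remove_vo2_peaks(vals, sd_mult = sd_mult, two_sided = two_sided)
  mean(cleaned) / mass_kg
}

#' Per-activity MET values for one participant
#'
#' Converts a breath series into per-second VO2, computes the steady-state
#' MET of each annotated bout, and classifies its intensity (ST / light /
#' MVPA).
#'
#' @param breaths Breath tibble (`time_s`, `vo2_mlmin`).
#' @param annotation Bout table (`activity`, `start_s`, `end_s`).
#' @param mass_kg Body mass in kg.
#' @inheritParams steady_state_met
#' @param st_max,mvpa_min Intensity boundaries in METs (defaults 1.5 and 3).
#'
#' @return A tibble with one row per bout: `activity`, `met`,
#'   `vo2_mlkgmin`, `n_seconds_used`, `usable`, `intensity_class`.
#' @export
activity_mets <- function(breaths, annotation, mass_kg, met_constant = 2.8,
                          window_s = 120, sd_mult = 2, two_sided = TRUE,
                          st_max = 1.5, mvpa_min = 3) {
  vo2_sec <- match_breaths_to_seconds(breaths)
  res <- purrr::pmap(
    list(annotation$activity, annotation$start_s, annotation$end_s),
    function(act, s0, s1) {
      met <- steady_state_met(vo2_sec, s0, s1, mass_kg,
                              met_constant = met_constant,
                              window_s = window_s, sd_mult = sd_mult,
                              two_sided = two_sided)
      mutate(met, activity = act, .before = 1)
    }
  ) %>% bind_rows()
  res %>%
    mutate(intensity_class = ifelse(
      .data$usable,
      as.character(classify_intensity(pmax(.data$met, 0.1), st_max, mvpa_min)),
      NA_character_
    ))
}
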