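signal_rate <- function(signal) {
  rate <- attr(signal, "sample_rate_hz")
  if (is.null(rate)) abort("signal lacks a `sample_rate_hz` attribute")
  rate
}

#' Per-second ENMO from raw acceleration
#'
#' ENMO (Euclidean Norm Minus One g) is computed per sample as
#' `max(sqrt(x^2 + y^2 + z^2) - 1, 0)` — the negative-value truncation is
#' applied per sample, before averaging — then averaged within each whole
#' second and expressed in milli-g. A trailing partial second is dropped.
#'
#' @param signal Tibble with columns `x_g`, `y_g`, `z_g` and a
#'   `sample_rate_hz` attribute (see [simulate_raw_signal()]).
#'
#' @return A tibble with `second` (0-based start of each second) and
#'   `enmo_mg`.
#' @export
#' @examples
#' sig <- tibble::tibble(time_s = (0:79) / 80, x_g = 0, y_g = 0, z_g = 1.05)
#' attr(sig, "sample_rate_hz") <- 80
#' enmo_per_second(sig)  # 50 mg
enmo_per_second <- function(signal) {
  rate <- signal_rate(signal)
  n <- nrow(signal)
  n_sec <- floor(n / rate)
  if (n == 0 || n_sec < 1) abort("signal must contain at least one full second")
  e <- pmax(sqrt(signal$x_g^2 + signal$y_g^2 + signal$z_g^2) - 1, 0)
  e <- e[seq_len(n_sec * rate)]
  sec_mean <- colMeans(matrix(e, nrow = rate))
  tibble(second = seq_len(n_sec) - 1L, enmo_mg = sec_mean * 1000)
}

# 0.25-2.5 Hz band-pass at 30 Hz: 3rd-order Butterworth, applied forward and
# backward (zero phase). Coefficients are fixed constants of the counts
# reconstruction, computed once per session.
counts_bandpass <- local({
  coefs <- NULL
  function() {
    if (is.null(coefs)) {
      coefs <<- signal::butter(3, c(0.25, 2.5) / (30 / 2), type = "pass")
    }
    coefs
  }
})

count_axis <- function(x, rate) {
  n_sec <- floor(length(x) / rate)
  x <- x[seq_len(n_sec * rate)]
  if (rate != 30) {
    t_in <- (seq_along(x) - 1) / rate
    t_out <- (seq_len(n_sec * 30) - 1) / 30
    x <- approx(t_in, x, xout = t_out, rule = 2)$y
  }
  bp <- counts_bandpass()
  # demean (the pass band excludes DC anyway) and reflection-pad so the
  # filter's slow step response does not leak into the edges
  x <- x - mean(x)
  pad <- min(240L, length(x))
  x <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1]))
  x <- signal::filtfilt(bp, x)
  x <- x[(pad + 1):(length(x) - pad)]
  x <- pmin(pmax(x, -2.13), 2.13)        # clip to the counts dynamic range
  x <- round(x * 256) / 256              # quantize at 1/256 g
  x <- abs(x)
  x[x < 0.068] <- 0                      # dead-band
  x10 <- matrix(x, nrow = 3)             # decimate 30 -> 10 Hz, running max
  x10 <- apply(x10, 2, max)
  per_sec <- colSums(matrix(x10, nrow = 10))
  as.integer(round(per_sec * 256))       # integer counts (1/256 g units)
}

#' Per-second activity counts from raw acceleration
#'
#' An open reconstruction of the proprietary activity-counts metric: each
#' axis is resampled to 30 Hz (linear interpolation), band-pass filtered to
#' the 0.25-2.5 Hz body-movement band, clipped to +/-2.13 g, quantized at
#' 1/256 g, rectified, dead-banded (values below 0.068 g zeroed), decimated
#' to 10 Hz by running maxima, and summed per second. The per-second vector
#' magnitude across axes is rounded to the nearest integer. Bit-identity with
#' vendor software is not claimed.
#'
#' @inheritParams enmo_per_second
#'
#' @return A tibble with `second`, `counts_x`, `counts_y`, `counts_z` and
#'   `counts_vm`.
#' @export
counts_per_second <- function(signal) {
  rate <- signal_rate(signal)
  if (rate < 30) abort("sample rate must be >= 30 Hz for activity counts")
  cx <- count_axis(signal$x_g, rate)
  cy <- count_axis(signal$y_g, rate)
  cz <- count_axis(signal$z_g, rate)
  tibble(
    second = seq_along(cx) - 1L,
    counts_x = cx, counts_y = cy, counts_z = cz,
    counts_vm = as.integer(round(sqrt(cx^2 + cy^2 + cz^2)))
  )
}

#' Aggregate a per-second series into epochs
#'
#' ENMO is averaged within each epoch; counts are summed. An incomplete
#' trailing epoch is dropped.
#'
#' @param values Numeric per-second values.
#' @param epoch_s Epoch length in seconds (>= 1).
#' @param stat `"mean"` (ENMO) or `"sum"` (counts).
#'
#' @return A tibble with `epoch_start_s` (0-based) and `value`.
#' @export
#' @examples
#' aggregate_epochs(c(1, 2, 3, 4, 5), 5, "sum")  # 15 counts / 5 s
aggregate_epochs <- function(values, epoch_s, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  if (epoch_s < 1) abort("`epoch_s` must be >= 1")
  n_ep <- floor(length(values) / epoch_s)
  if (n_ep == 0) return(tibble(epoch_start_s = integer(0), value = numeric(0)))
  m <- matrix(values[seq_len(n_ep * epoch_s)], nrow = epoch_s)
  v <- if (stat == "mean") colMeans(m) else colSums(m)
  tibble(epoch_start_s = (seq_len(n_ep) - 1L) * as.integer(epoch_s), value = v)
}

#' Centered analysis window per activity bout
#'
#' The first and last seconds of each bout are excluded to ensure signal
#' stability, and at most `target_s` (default 3 min) of the remainder is
#' kept, centered within the bout and floored to a whole number of epochs.
#' Bouts too short to yield one epoch after trimming are flagged excluded.
#'
#' @param annotation Tibble with `activity`, `start_s`, `end_s` (one row per
#'   bout).
#' @param trim_s Seconds trimmed from each end (default 15).
#' @param target_s Maximum window length in seconds (default 180).
#' @param epoch_s Epoch length the window must align to (default 5).
#'
#' @return The annotation with added `win_start_s`, `win_end_s`, `excluded`.
#' @export
trim_activity_window <- function(annotation, trim_s = 15, target_s = 180,
                                 epoch_s = 5) {
  dur <- annotation$end_s - annotation$start_s
  usable <- dur - 2 * trim_s
  win_len <- pmin(usable, target_s)
  win_len <- floor(win_len / epoch_s) * epoch_s
  excluded <- usable < epoch_s
  win_start <- floor(annotation$start_s + (dur - win_len) / 2)
  annotation %>%
    mutate(
      win_start_s = ifelse(excluded, NA_real_, win_start),
      win_end_s = ifelse(excluded, NA_real_, win_start + win_len),
      excluded = excluded
    )
}

#' Per-epoch metric table for one recording
#'
#' Runs [enmo_per_second()] and [counts_per_second()] over a recording, cuts
#' the trimmed analysis window of each annotated bout, and aggregates both
#' metrics into epochs (ENMO averaged, counts summed). Epochs start at the
#' window start of each bout.
#'
#' @inheritParams enmo_per_second
#' @param annotation Bout table with `activity`, `start_s`, `end_s` (extra
#'   columns such as ground-truth METs are carried through).
#' @param epoch_s,trim_s,target_s Window policy, see
#'   [trim_activity_window()].
#'
#' @return An epoch table: one row per epoch with `participant`, `site`,
#'   `activity`, `epoch_start_s`, `enmo_mg`, `counts_per_epoch`.
#' @export
epoch_table <- function(signal, annotation, epoch_s = 5, trim_s = 15,
                        target_s = 180) {
  enmo <- enmo_per_second(signal)
  cnts <- counts_per_second(signal)
  windows <- trim_activity_window(annotation, trim_s, target_s, epoch_s)
  pid <- attr(signal, "participant") %||% NA_character_
  site <- attr(signal, "site") %||% NA_character_

  rows <- purrr::pmap(
    list(windows$activity, windows$win_start_s, windows$win_end_s,
         windows$excluded),
    function(act, ws, we, excl) {
      if (excl) return(NULL)
      sec_idx <- which(enmo$second >= ws & enmo$second < we)
      ep_en <- aggregate_epochs(enmo$enmo_mg[sec_idx], epoch_s, "mean")
      ep_ct <- aggregate_epochs(cnts$counts_vm[sec_idx], epoch_s, "sum")
      tibble(
        participant = pid, site = site, activity = act,
        epoch_start_s = ws + ep_en$epoch_start_s,
        enmo_mg = ep_en$value,
        counts_per_epoch = as.integer(ep_ct$value)
      )
    }
  )
  out <- bind_rows(rows)
  attr(out, "epoch_s") <- epoch_s
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
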