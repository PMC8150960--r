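#' Apply fixed cut-points to an independent labelled sample
#'
#' Classifies every epoch with the calibrated thresholds (same direction
#' convention as calibration: ST when the value is below the ST threshold,
#' MVPA when at or above the MVPA threshold — an epoch exactly at a
#' threshold is therefore not ST but is MVPA), tabulates against the
#' MET-derived intensity classes, and reports sensitivity and specificity
#' with the full confusion matrix. Sites present in the cut-point table but
#' absent from the epochs are skipped (e.g. a wear site not worn in the
#' cross-validation arm).
#'
#' @param epochs Labelled epoch table (`site`, `enmo_mg`,
#'   `counts_per_epoch`, `intensity_class`).
#' @param cutpoints An `accel_cutpoints` table (or any tibble with `site`,
#'   `metric`, `boundary` and threshold columns).
#' @param use Which threshold to apply: `"raw"` (default; reproduces the
#'   calibration sensitivity/specificity exactly on the calibration sample)
#'   or `"reported"` (the integer-rounded value).
#'
#' @return A tibble with one row per applied cut-point: `site`, `metric`,
#'   `boundary`, `threshold`, `sensitivity`, `specificity`, `tp`, `fp`,
#'   `fn`, `tn`, `n_pos`, `n_neg`.
#' @export
apply_cutpoints <- function(epochs, cutpoints, use = c("raw", "reported")) {
  use <- match.arg(use)
  ep_len <- attr(epochs, "epoch_s")
  cp_len <- attr(cutpoints, "epoch_s")
  if (!is.null(ep_len) && !is.null(cp_len) && ep_len != cp_len) {
    abort(paste0("epoch length mismatch (cut-points: ", cp_len,
                 " s, epochs: ", ep_len,
                 " s); rescale counts thresholds with scale_cutpoint()"))
  }
  metric_cols <- c(enmo_mg = "enmo_mg", counts_per_epoch = "counts_per_epoch")
  rows <- list()
  for (i in seq_len(nrow(cutpoints))) {
    site <- cutpoints$site[i]
    if (!site %in% epochs$site) next
    eps <- dichotomize(filter(epochs, .data$site == !!site),
                       cutpoints$boundary[i])
    t <- if (use == "raw") cutpoints$threshold_raw[i] else cutpoints$threshold[i]
    v <- eps[[metric_cols[[cutpoints$metric[i]]]]]
    pred <- if (cutpoints$boundary[i] == "ST") v < t else v >= t
    tp <- sum(pred & eps$positive)
    fp <- sum(pred & !eps$positive)
    fn <- sum(!pred & eps$positive)
    tn <- sum(!pred & !eps$positive)
    rows[[i]] <- tibble(
      site = site, metric = cutpoints$metric[i],
      boundary = cutpoints$boundary[i], threshold = t,
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      tp = tp, fp = fp, fn = fn, tn = tn,
      n_pos = tp + fn, n_neg = tn + fp
    )
  }
  bind_rows(rows)
}

#' Rescale a counts cut-point to a different epoch length
#'
#' Counts accumulate over the epoch, so a threshold in counts per `epoch_a`
#' seconds scales linearly to counts per `epoch_b` seconds (rounded to the
#' nearest integer). ENMO is an average and is invariant to epoch length, so
#' rescaling it is refused.
#'
#' @param threshold Threshold in counts per `from_epoch_s`.
#' @param from_epoch_s,to_epoch_s Epoch lengths in seconds.
#' @param metric Metric name; anything containing "enmo" is rejected.
#'
#' @return The threshold in counts per `to_epoch_s`.
#' @export
#' @examples
#' scale_cutpoint(1, 5, 60)    # 12 counts/min
#' scale_cutpoint(54, 5, 15)   # 162 counts/15 s
scale_cutpoint <- function(threshold, from_epoch_s, to_epoch_s,
                           metric = "counts_per_epoch") {
  stopifnot_scalar_pos(from_epoch_s, "from_epoch_s")
  stopifnot_scalar_pos(to_epoch_s, "to_epoch_s")
  if (grepl("enmo", tolower(metric))) {
    abort("ENMO is an epoch average and does not scale with epoch length")
  }
  round_half_up(threshold * to_epoch_s / from_epoch_s)
}

#' Body mass index
#'
#' Body mass (kg) divided by squared height (m^2).
#'
#' @param mass_kg Body mass in kg.
#' @param height_cm Standing height in cm.
#'
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(72, 160)  # 28.125
bmi <- function(mass_kg, height_cm) {
  if (any(mass_kg <= 0) || any(height_cm <= 0)) {
    abort("mass and height must be positive")
  }
  mass_kg / (height_cm / 100)^2
}
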