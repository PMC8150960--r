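#' Dichotomize labelled epochs for one intensity boundary
#'
#' For the ST boundary the behaviour of interest is sedentary time (light and
#' MVPA epochs are the negatives); for the MVPA boundary it is
#' moderate-to-vigorous activity (ST and light are the negatives).
#'
#' @param epochs Epoch table with an `intensity_class` column (`ST`, `light`,
#'   `MVPA`).
#' @param boundary `"ST"` (ST-to-light cut) or `"MVPA"` (light-to-MVPA cut).
#'
#' @return The epochs with a logical `positive` column.
#' @export
dichotomize <- function(epochs, boundary = c("ST", "MVPA")) {
  boundary <- match.arg(boundary)
  cls <- as.character(epochs$intensity_class)
  if (anyNA(cls)) {
    epochs <- epochs[!is.na(cls), , drop = FALSE]
    cls <- cls[!is.na(cls)]
  }
  pos <- cls == boundary
  if (!any(pos)) {
    abort(paste0("no '", boundary, "' epochs: ROC for the ", boundary,
                 " boundary is undefined"))
  }
  if (all(pos)) {
    abort(paste0("only '", boundary, "' epochs present: no negatives for the ",
                 boundary, " boundary"))
  }
  mutate(epochs, positive = pos)
}

#' Build a ROC curve over all candidate thresholds
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' metric values, plus open ends at -Inf and +Inf. Directionality follows the
#' boundary semantics: for the ST boundary an epoch is called positive when
#' its value is *below* the threshold (`direction = "lt"`; the threshold
#' reads as an upper bound for sedentary behaviour), for the MVPA boundary
#' when its value is *at or above* it (`direction = "gte"`). The AUC is the
#' trapezoidal area under sensitivity versus 1 - specificity, which equals
#' the Mann-Whitney concordance probability with ties counted one half.
#'
#' @param values Numeric metric values (ENMO mg or counts/epoch).
#' @param positive Logical vector, TRUE for the behaviour of interest.
#' @param direction `"gte"` (positive at or above threshold) or `"lt"`
#'   (positive below threshold).
#'
#' @return An object of class `accel_roc`.
#' @export
roc_curve <- function(values, positive, direction = c("gte", "lt")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(positive))
  keep <- !is.na(values) & !is.na(positive)
  values <- values[keep]
  positive <- as.logical(positive[keep])
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos < 1 || n_neg < 1) {
    abort("need at least one positive and one negative")
  }
  u <- sort(unique(values))
  degenerate <- length(u) < 2
  thr <- if (degenerate) {
    c(-Inf, Inf)
  } else {
    c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  }
  pos_sorted <- sort(values[positive])
  neg_sorted <- sort(values[!positive])
  # counts strictly below each threshold (thresholds never equal data values)
  pos_below <- findInterval(thr, pos_sorted)
  neg_below <- findInterval(thr, neg_sorted)
  if (direction == "gte") {
    sens <- (n_pos - pos_below) / n_pos
    spec <- neg_below / n_neg
  } else {
    sens <- pos_below / n_pos
    spec <- (n_neg - neg_below) / n_neg
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(
    list(direction = direction, thresholds = thr,
         sensitivities = sens, specificities = spec,
         auc = auc, n_pos = n_pos, n_neg = n_neg,
         degenerate = degenerate,
         values = values, positive = positive),
    class = "accel_roc"
  )
}

#' @export
print.accel_roc <- function(x, ...) {
  ci <- auc_ci(x)
  cat("<accel_roc> direction: ", x$direction,
      "; n_pos ", x$n_pos, ", n_neg ", x$n_neg, "\n", sep = "")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), grade: %s\n",
              x$auc, ci[1], ci[2], as.character(grade_auc(x$auc))))
  invisible(x)
}

# DeLong structural components: placement values of positives among
# negatives (V10) and vice versa (V01), via midranks.
delong_components <- function(curve) {
  v <- if (curve$direction == "lt") -curve$values else curve$values
  x <- v[curve$positive]
  y <- v[!curve$positive]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

delong_var <- function(comp) {
  s10 <- if (comp$m > 1) stats::var(comp$v10) else 0
  s01 <- if (comp$n > 1) stats::var(comp$v01) else 0
  s10 / comp$m + s01 / comp$n
}

#' DeLong 95% confidence interval for an AUC
#'
#' Uses the DeLong structural-components variance estimator with a normal
#' approximation; the interval is clipped to \[0, 1\]. Zero variance (e.g. a
#' perfectly separated curve) yields the degenerate interval (auc, auc).
#'
#' @param curve An [roc_curve()] object.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return Numeric vector `c(lo, hi)`.
#' @export
auc_ci <- function(curve, conf_level = 0.95) {
  comp <- delong_components(curve)
  v <- delong_var(comp)
  if (v <= 0) return(c(curve$auc, curve$auc))
  z <- qnorm(1 - (1 - conf_level) / 2)
  lo <- max(0, curve$auc - z * sqrt(v))
  hi <- min(1, curve$auc + z * sqrt(v))
  c(lo, hi)
}

#' DeLong test comparing two AUCs
#'
#' Paired comparison (default) uses the covariance of the DeLong placement
#' components, appropriate when both curves score the same epochs (e.g. ENMO
#' versus counts at one site); it requires identical positives in identical
#' order. The unpaired version treats the curves as independent.
#'
#' @param curve_a,curve_b [roc_curve()] objects.
#' @param paired Logical (default TRUE).
#'
#' @return A one-row tibble: `auc_a`, `auc_b`, `diff`, `z`, `p_value`,
#'   `paired`.
#' @export
compare_auc <- function(curve_a, curve_b, paired = TRUE) {
  ca <- delong_components(curve_a)
  cb <- delong_components(curve_b)
  d <- curve_a$auc - curve_b$auc
  if (paired) {
    if (ca$m != cb$m || ca$n != cb$n) {
      abort("paired comparison requires matching positive/negative counts")
    }
    if (!identical(curve_a$positive, curve_b$positive)) {
      abort("paired comparison requires the same epochs in the same order")
    }
    v <- delong_var(ca) + delong_var(cb) -
      2 * (stats::cov(ca$v10, cb$v10) / ca$m + stats::cov(ca$v01, cb$v01) / ca$n)
  } else {
    v <- delong_var(ca) + delong_var(cb)
  }
  if (v <= 1e-15) {
    z <- 0
    p <- if (abs(d) < 1e-12) 1 else 0
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(auc_a = curve_a$auc, auc_b = curve_b$auc, diff = d,
         z = z, p_value = p, paired = paired)
}

#' Grade diagnostic accuracy from an AUC
#'
#' AUC of at least 0.90 is excellent, 0.80-0.89 good, 0.70-0.79 fair,
#' below 0.70 poor.
#'
#' @param auc Numeric vector of AUC values in \[0, 1\].
#'
#' @return A factor with levels `poor`, `fair`, `good`, `excellent`.
#' @export
#' @examples
#' grade_auc(c(0.62, 0.74, 0.85, 0.90))
grade_auc <- function(auc) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) abort("`auc` must lie in [0, 1]")
  g <- ifelse(auc >= 0.90, "excellent",
              ifelse(auc >= 0.80, "good",
                     ifelse(auc >= 0.70, "fair", "poor")))
  factor(g, levels = c("poor", "fair", "good", "excellent"))
}

#' Select the cut-point closest to perfect classification
#'
#' Minimises `(1 - sensitivity)^2 + (1 - specificity)^2` over all candidate
#' thresholds — the squared distance to the top-left corner of ROC space.
#' Ties are broken toward the threshold with higher specificity, then the
#' smaller threshold value. The reported threshold is the raw midpoint
#' rounded to the nearest integer in native units (mg or counts/epoch); the
#' raw value is retained for reuse.
#'
#' @param curve An [roc_curve()] object.
#'
#' @return A one-row tibble: `threshold`, `threshold_raw`, `sensitivity`,
#'   `specificity`, `distance`, `auc`, `grade`.
#' @export
select_cutpoint <- function(curve) {
  finite <- is.finite(curve$thresholds)
  if (!any(finite)) {
    # degenerate curve: all values identical, no informative threshold
    return(tibble(threshold = NA_real_, threshold_raw = NA_real_,
                  sensitivity = NA_real_, specificity = NA_real_,
                  distance = NA_real_, auc = curve$auc,
                  grade = grade_auc(curve$auc)))
  }
  thr <- curve$thresholds[finite]
  sens <- curve$sensitivities[finite]
  spec <- curve$specificities[finite]
  d <- (1 - sens)^2 + (1 - spec)^2
  cand <- which(d <= min(d) + 1e-12)
  cand <- cand[spec[cand] >= max(spec[cand]) - 1e-12]
  best <- cand[which.min(thr[cand])]
  tibble(
    threshold = round_half_up(thr[best]),
    threshold_raw = thr[best],
    sensitivity = sens[best], specificity = spec[best],
    distance = d[best], auc = curve$auc, grade = grade_auc(curve$auc)
  )
}

#' Specificity-priority cut-point selection
#'
#' Among thresholds whose sensitivity is at least `min_sens`, picks the one
#' with maximal specificity (then maximal sensitivity, then the smaller
#' threshold). This is the alternative rule that keeps sensitivity at a
#' floor (0.6 by default) while pushing specificity as high as possible, to
#' avoid misclassifying light activity as MVPA.
#'
#' @param curve An [roc_curve()] object.
#' @param min_sens Sensitivity floor (default 0.6).
#'
#' @return A one-row tibble as in [select_cutpoint()].
#' @export
select_cutpoint_spec_priority <- function(curve, min_sens = 0.6) {
  finite <- is.finite(curve$thresholds)
  ok <- finite & curve$sensitivities >= min_sens
  if (!any(ok)) {
    abort(paste0("no threshold reaches sensitivity >= ", min_sens))
  }
  thr <- curve$thresholds[ok]
  sens <- curve$sensitivities[ok]
  spec <- curve$specificities[ok]
  cand <- which(spec >= max(spec) - 1e-12)
  cand <- cand[sens[cand] >= max(sens[cand]) - 1e-12]
  best <- cand[which.min(thr[cand])]
  tibble(
    threshold = round_half_up(thr[best]),
    threshold_raw = thr[best],
    sensitivity = sens[best], specificity = spec[best],
    distance = (1 - sens[best])^2 + (1 - spec[best])^2,
    auc = curve$auc, grade = grade_auc(curve$auc)
  )
}

#' @export
tidy.accel_roc <- function(x, ...) {
  tibble(threshold = x$thresholds,
         sensitivity = x$sensitivities,
         specificity = x$specificities)
}

#' @export
glance.accel_roc <- function(x, ...) {
  ci <- auc_ci(x)
  tibble(auc = x$auc, ci_lo = ci[1], ci_hi = ci[2],
         n_pos = x$n_pos, n_neg = x$n_neg,
         grade = grade_auc(x$auc), degenerate = x$degenerate)
}

#' @export
autoplot.accel_roc <- function(object, ...) {
  df <- tidy(object)
  cp <- select_cutpoint(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = tibble(specificity = cp$specificity,
                                      sensitivity = cp$sensitivity),
                        colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f (%s)", object$auc,
                      as.character(grade_auc(object$auc)))
    ) +
    ggplot2::coord_equal()
}
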