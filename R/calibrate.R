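#' Calibrate cut-points for every site, metric and boundary
#'
#' Pools labelled epochs across participants (one ROC per combination),
#' builds ROC curves for the ST-to-light and light-to-MVPA boundaries on
#' each wear site and acceleration metric, computes DeLong confidence
#' intervals, grades the AUC, and selects the threshold minimising the
#' squared distance to perfect sensitivity and specificity.
#'
#' @param epochs Labelled epoch table with columns `site`, `enmo_mg`,
#'   `counts_per_epoch`, `intensity_class`.
#' @param metrics Named character vector mapping metric names to epoch-table
#'   columns.
#' @param boundaries Boundaries to calibrate (default both).
#' @param conf_level Confidence level for the AUC interval.
#'
#' @return A tibble of class `accel_cutpoints` with one row per site x
#'   metric x boundary; the underlying `accel_roc` curves are attached as
#'   attribute `curves` (named `site|metric|boundary`).
#' @export
calibrate_cutpoints <- function(epochs,
                                metrics = c(enmo_mg = "enmo_mg",
                                            counts_per_epoch = "counts_per_epoch"),
                                boundaries = c("ST", "MVPA"),
                                conf_level = 0.95) {
  sites <- unique(epochs$site)
  curves <- list()
  rows <- list()
  for (site in sites) {
    eps <- filter(epochs, .data$site == !!site)
    for (mi in seq_along(metrics)) {
      metric_name <- names(metrics)[mi]
      col <- metrics[[mi]]
      for (boundary in boundaries) {
        lab <- dichotomize(eps, boundary)
        direction <- if (boundary == "ST") "lt" else "gte"
        curve <- roc_curve(lab[[col]], lab$positive, direction)
        ci <- auc_ci(curve, conf_level)
        cp <- select_cutpoint(curve)
        key <- paste(site, metric_name, boundary, sep = "|")
        curves[[key]] <- curve
        rows[[key]] <- mutate(cp,
          site = site, metric = metric_name, boundary = boundary,
          auc_lo = ci[1], auc_hi = ci[2],
          n_pos = curve$n_pos, n_neg = curve$n_neg,
          .before = 1
        )
      }
    }
  }
  out <- bind_rows(rows) %>%
    select("site", "metric", "boundary", "threshold", "threshold_raw",
           "sensitivity", "specificity", "distance", "auc", "auc_lo",
           "auc_hi", "grade", "n_pos", "n_neg")
  attr(out, "curves") <- curves
  attr(out, "epoch_s") <- attr(epochs, "epoch_s")
  class(out) <- c("accel_cutpoints", class(out))
  out
}

#' Retrieve a calibration ROC curve
#'
#' @param cutpoints An `accel_cutpoints` table.
#' @param site,metric,boundary The combination to fetch.
#'
#' @return The stored `accel_roc` object.
#' @export
get_curve <- function(cutpoints, site, metric, boundary) {
  key <- paste(site, metric, boundary, sep = "|")
  curve <- attr(cutpoints, "curves")[[key]]
  if (is.null(curve)) abort(paste0("no calibrated curve for ", key))
  curve
}

#' @export
glance.accel_cutpoints <- function(x, ...) {
  tibble(
    n_cutpoints = nrow(x),
    n_sites = length(unique(x$site)),
    auc_min = min(x$auc), auc_max = max(x$auc),
    all_graded_fair_or_better = all(x$auc >= 0.70)
  )
}

#' @export
autoplot.accel_cutpoints <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$threshold_raw,
                                   colour = .data$boundary)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Threshold (native units)",
                  colour = "Boundary") +
    ggplot2::scale_y_log10()
}
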