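#' Simulate and label one study arm's epochs
#'
#' For each participant: generates the breath series and derives per-bout
#' steady-state METs and intensity classes; then, per wear site, generates
#' the raw signal, computes ENMO and counts epochs over the trimmed analysis
#' windows, and joins the MET-derived labels (plus the generator's ground
#' truth). Raw signals are discarded after processing, so memory stays flat
#' in the number of participants.
#'
#' @param protocol An [protocol_spec()] object.
#' @param participants Tibble from [simulate_participants()].
#' @param epoch_s,trim_s,target_s Analysis-window policy (see
#'   [trim_activity_window()]).
#' @param met_constant,sd_mult MET derivation settings (see
#'   [activity_mets()]).
#' @param artifact_rate Breath artifact rate passed to
#'   [simulate_breath_series()].
#' @param noise_scale Generator noise multiplier (see
#'   [simulate_raw_signal()]).
#'
#' @return A labelled epoch table: one row per epoch with metric values,
#'   MET-derived `met` and `intensity_class`, and ground-truth `met_true`
#'   and `intensity_true`.
#' @export
build_labelled_epochs <- function(protocol, participants, epoch_s = 5,
                                  trim_s = 15, target_s = 180,
                                  met_constant = 2.8, sd_mult = 2,
                                  artifact_rate = 0.02, noise_scale = 1) {
  per_participant <- purrr::map(seq_len(nrow(participants)), function(i) {
    p <- participants[i, ]
    breaths <- simulate_breath_series(p, protocol,
                                      artifact_rate = artifact_rate,
                                      noise_scale = noise_scale,
                                      met_constant = met_constant)
    ann <- attr(breaths, "annotation")
    mets <- activity_mets(breaths, ann, p$body_mass_kg,
                          met_constant = met_constant, sd_mult = sd_mult)
    labels <- ann %>%
      left_join(select(mets, "activity", "met", "intensity_class", "usable"),
                by = "activity")
    site_eps <- purrr::map(protocol$wear_sites, function(site) {
      sim <- simulate_raw_signal(p, protocol, site, noise_scale = noise_scale)
      epoch_table(sim$signal, sim$annotation, epoch_s = epoch_s,
                  trim_s = trim_s, target_s = target_s)
    })
    bind_rows(site_eps) %>%
      left_join(select(labels, "activity", "met", "intensity_class",
                       "usable", "met_true", "intensity_true"),
                by = "activity") %>%
      filter(.data$usable) %>%
      select(-"usable")
  })
  out <- bind_rows(per_participant)
  attr(out, "epoch_s") <- epoch_s
  out
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the two protocols, sample
#' sizes, the master seed, window policy, MET constant, peak-removal SD
#' multiplier, breath artifact rate and generator noise scale.
#'
#' @param seed Master integer seed; all randomness derives from it.
#' @param n_calibration,n_crossval Participants per arm (defaults 59
#'   and 19, the study-arm sample sizes).
#' @param calibration_protocol,crossval_protocol Protocol objects.
#' @param epoch_s,trim_s,target_s Analysis-window policy.
#' @param met_constant mL O2/kg/min per MET (default 2.8).
#' @param sd_mult Peak-removal SD multiplier (default 2).
#' @param artifact_rate Breath artifact rate (default 0.02).
#' @param noise_scale Generator noise multiplier (default 1).
#'
#' @return A named list of class `accel_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_calibration = 59, n_crossval = 19,
                            calibration_protocol = default_calibration_protocol(),
                            crossval_protocol = default_crossval_protocol(),
                            epoch_s = 5, trim_s = 15, target_s = 180,
                            met_constant = 2.8, sd_mult = 2,
                            artifact_rate = 0.02, noise_scale = 1) {
  cfg <- list(
    seed = as.integer(seed),
    n_calibration = n_calibration, n_crossval = n_crossval,
    calibration_protocol = calibration_protocol,
    crossval_protocol = crossval_protocol,
    epoch_s = epoch_s, trim_s = trim_s, target_s = target_s,
    met_constant = met_constant, sd_mult = sd_mult,
    artifact_rate = artifact_rate, noise_scale = noise_scale
  )
  class(cfg) <- "accel_config"
  cfg
}

config_hash <- function(config) {
  sprintf("%08x", sub_seed(1L, paste(deparse(unclass(config)), collapse = "")))
}

#' Run the calibration / cross-validation pipeline
#'
#' Executes, in order, the requested stages: `simulate` (both arms'
#' labelled epoch tables, fusing signal generation, metric extraction and
#' MET labelling), `calibrate` (ROC cut-points on the calibration arm) and
#' `crossval` (fixed thresholds applied to the cross-validation arm). A
#' later stage without its upstream artifact raises an error naming the
#' stage to run first; partial results can be resumed via `state`.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of `c("simulate", "calibrate",
#'   "crossval")`.
#' @param state A previous result bundle to resume from (optional).
#'
#' @return A list of class `accel_run`: `config`, `config_hash`, `seed`,
#'   `calibration_epochs`, `crossval_epochs`, `cutpoints`,
#'   `crossval_results`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "calibrate", "crossval"),
                         state = NULL) {
  stages <- match.arg(stages, c("simulate", "calibrate", "crossval"),
                      several.ok = TRUE)
  res <- state %||% list()
  res$config <- config
  res$config_hash <- config_hash(config)
  res$seed <- config$seed
  res$log <- res$log %||% list()

  if ("simulate" %in% stages) {
    cal_parts <- simulate_participants(config$n_calibration, config$seed,
                                       "calibration")
    cv_parts <- simulate_participants(config$n_crossval, config$seed,
                                      "crossval")
    res$calibration_participants <- cal_parts
    res$crossval_participants <- cv_parts
    res$calibration_epochs <- build_labelled_epochs(
      config$calibration_protocol, cal_parts,
      epoch_s = config$epoch_s, trim_s = config$trim_s,
      target_s = config$target_s, met_constant = config$met_constant,
      sd_mult = config$sd_mult, artifact_rate = config$artifact_rate,
      noise_scale = config$noise_scale
    )
    res$crossval_epochs <- build_labelled_epochs(
      config$crossval_protocol, cv_parts,
      epoch_s = config$epoch_s, trim_s = config$trim_s,
      target_s = config$target_s, met_constant = config$met_constant,
      sd_mult = config$sd_mult, artifact_rate = config$artifact_rate,
      noise_scale = config$noise_scale
    )
    res$log$simulate <- list(
      calibration_epochs = nrow(res$calibration_epochs),
      crossval_epochs = nrow(res$crossval_epochs)
    )
  }

  if ("calibrate" %in% stages) {
    if (is.null(res$calibration_epochs)) {
      abort("no calibration epochs available; run stage 'simulate' first")
    }
    res$cutpoints <- calibrate_cutpoints(res$calibration_epochs)
    res$log$calibrate <- list(n_cutpoints = nrow(res$cutpoints))
  }

  if ("crossval" %in% stages) {
    if (is.null(res$cutpoints)) {
      abort("no calibrated cut-points available; run stage 'calibrate' first")
    }
    if (is.null(res$crossval_epochs)) {
      abort("no cross-validation epochs available; run stage 'simulate' first")
    }
    res$crossval_results <- apply_cutpoints(res$crossval_epochs, res$cutpoints)
    res$log$crossval <- list(n_results = nrow(res$crossval_results))
  }

  class(res) <- "accel_run"
  res
}

#' @export
print.accel_run <- function(x, ...) {
  cat("<accel_run> seed ", x$seed, ", config ", x$config_hash, "\n", sep = "")
  for (stage in names(x$log)) {
    cat("  ", stage, ": ",
        paste(names(x$log[[stage]]), unlist(x$log[[stage]]),
              sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
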