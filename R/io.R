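accel_origin <- as.POSIXct("2021-06-01 08:00:00", tz = "UTC")

iso_time <- function(time_s, digits = 4) {
  format(accel_origin + time_s, paste0("%Y-%m-%dT%H:%M:%OS", digits),
         tz = "UTC")
}

parse_iso <- function(x) {
  as.numeric(difftime(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"),
                      accel_origin, units = "secs"))
}

#' Write / read a raw-signal CSV
#'
#' Columns `timestamp_iso, x_g, y_g, z_g`; the sampling rate is recovered
#' from the timestamp spacing on read.
#'
#' @param signal Signal tibble (see [simulate_raw_signal()]).
#' @param path File path.
#' @export
write_raw_signal_csv <- function(signal, path) {
  df <- data.frame(
    timestamp_iso = iso_time(signal$time_s),
    x_g = signal$x_g, y_g = signal$y_g, z_g = signal$z_g
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raw_signal_csv
#' @export
read_raw_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  time_s <- parse_iso(df$timestamp_iso)
  out <- tibble(time_s = time_s - time_s[1],
                x_g = df$x_g, y_g = df$y_g, z_g = df$z_g)
  dt <- stats::median(diff(out$time_s))
  attr(out, "sample_rate_hz") <- round(1 / dt)
  out
}

#' Write / read a breath-by-breath CSV
#'
#' Columns `timestamp_iso, vo2_mlmin, vco2_mlmin`.
#'
#' @param breaths Breath tibble (see [simulate_breath_series()]).
#' @param path File path.
#' @export
write_breath_csv <- function(breaths, path) {
  df <- data.frame(
    timestamp_iso = iso_time(breaths$time_s, digits = 2),
    vo2_mlmin = breaths$vo2_mlmin, vco2_mlmin = breaths$vco2_mlmin
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_breath_csv
#' @export
read_breath_csv <- function(path) {
  df <- utils::read.csv(path)
  t <- parse_iso(df$timestamp_iso)
  tibble(time_s = t - floor(min(t)), vo2_mlmin = df$vo2_mlmin,
         vco2_mlmin = df$vco2_mlmin)
}

#' Write / read an activity-annotation CSV
#'
#' Columns `participant, activity, start_iso, end_iso` (ground-truth columns
#' are carried when present).
#'
#' @param annotation Bout table with `start_s`, `end_s`.
#' @param path File path.
#' @export
write_annotation_csv <- function(annotation, path) {
  df <- data.frame(
    participant = annotation$participant,
    activity = annotation$activity,
    start_iso = iso_time(annotation$start_s, digits = 0),
    end_iso = iso_time(annotation$end_s, digits = 0)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble(participant = df$participant, activity = df$activity,
         start_s = parse_iso(df$start_iso), end_s = parse_iso(df$end_iso))
}

#' Write / read a protocol specification as YAML
#'
#' @param protocol An [protocol_spec()] object.
#' @param path File path.
#' @export
write_protocol_yaml <- function(protocol, path) {
  rlang::check_installed("yaml")
  acts <- purrr::map(seq_len(nrow(protocol$activities)), function(i) {
    a <- protocol$activities[i, ]
    list(label = a$label, duration_s = a$duration_s,
         met_mean = a$met_mean, met_sd = a$met_sd,
         movement_freq_hz = a$movement_freq_hz,
         enmo_target_mg = as.list(a$enmo_target_mg[[1]]),
         enmo_sd_mg = as.list(a$enmo_sd_mg[[1]]))
  })
  yaml::write_yaml(list(
    name = protocol$name, sample_rate_hz = protocol$sample_rate_hz,
    wear_sites = protocol$wear_sites, epoch_s = protocol$epoch_s,
    activities = acts
  ), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  rlang::check_installed("yaml")
  spec <- yaml::read_yaml(path)
  acts <- bind_rows(purrr::map(spec$activities, function(a) {
    activity_template(a$label, a$duration_s, a$met_mean, a$met_sd,
                      a$movement_freq_hz, unlist(a$enmo_target_mg),
                      unlist(a$enmo_sd_mg))
  }))
  protocol_spec(spec$name, spec$sample_rate_hz, unlist(spec$wear_sites),
                acts, spec$epoch_s)
}

#' Write a cut-point bundle as JSON
#'
#' Serialises the cut-point table (with its epoch length) for reuse by
#' cross-validation runs.
#'
#' @param cutpoints An `accel_cutpoints` table.
#' @param path File path.
#' @export
write_cutpoint_json <- function(cutpoints, path) {
  rlang::check_installed("jsonlite")
  payload <- list(
    epoch_s = attr(cutpoints, "epoch_s"),
    cutpoints = as.data.frame(
      mutate(as_tibble(cutpoints), grade = as.character(.data$grade))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutpoint_json
#' @export
read_cutpoint_json <- function(path) {
  rlang::check_installed("jsonlite")
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(payload$cutpoints)
  attr(out, "epoch_s") <- payload$epoch_s
  class(out) <- c("accel_cutpoints", class(out))
  out
}
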