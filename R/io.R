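SESSION_FORMAT_VERSION <- 1L

TRACE_COLUMNS <- c("t_s", "gyro_x_dps", "gyro_y_dps", "gyro_z_dps",
                   "acc_x_ms2", "acc_y_ms2", "acc_z_ms2",
                   "eye_h_deg", "eye_v_deg", "photodiode_v")
TRIAL_COLUMNS <- c("trial_id", "direction", "trigger_time_s",
                   "orientation_deg", "response_deg", "correct",
                   "nominal_delay_frames", "nominal_duration_frames")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a session recording to a plain-text bundle
#'
#' Serializes a session to a directory with three files: `meta.yaml`
#' (format version, sampling rate, protocol, display, and free-form
#' metadata), `traces.tsv` (the synchronized channels, one row per sample)
#' and `trials.tsv` (the trial table). Floats are written with 17
#' significant digits, so a read/write round trip preserves them exactly;
#' output is deterministic, so equal sessions produce byte-identical
#' bundles. The session is validated first and refused (with the violation
#' list) if malformed.
#'
#' @param s a `hitd_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(s, path) {
  viol <- validate_session(s)
  if (length(viol) > 0)
    stop("invalid session, refusing to write:\n  ",
         paste(viol, collapse = "\n  "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- s$traces
  meta <- list(
    format_version = SESSION_FORMAT_VERSION,
    fs_hz = tr$fs,
    n_samples = length(tr$t),
    protocol = unclass(s$protocol),
    display = unclass(s$display),
    meta = s$meta)
  writeLines(yaml::as.yaml(meta, precision = 15L),
             file.path(path, "meta.yaml"))
  tab <- cbind(fmt_num(tr$t),
               fmt_num(tr$gyro[, 1]), fmt_num(tr$gyro[, 2]),
               fmt_num(tr$gyro[, 3]),
               fmt_num(tr$linacc[, 1]), fmt_num(tr$linacc[, 2]),
               fmt_num(tr$linacc[, 3]),
               fmt_num(tr$eye_h), fmt_num(tr$eye_v),
               fmt_num(tr$photodiode))
  con <- file(file.path(path, "traces.tsv"), "wb")
  writeLines(c(paste(TRACE_COLUMNS, collapse = "\t"),
               apply(tab, 1, paste, collapse = "\t")), con)
  close(con)
  trl <- s$trials
  tab2 <- cbind(as.character(trl$trial_id), trl$direction,
                fmt_num(trl$trigger_time_s), fmt_num(trl$orientation_deg),
                fmt_num(trl$response_deg),
                ifelse(is.na(trl$correct), "NA",
                       ifelse(trl$correct, "TRUE", "FALSE")),
                as.character(trl$nominal_delay_frames),
                as.character(trl$nominal_duration_frames))
  con <- file(file.path(path, "trials.tsv"), "wb")
  if (nrow(trl) == 0)
    writeLines(paste(TRIAL_COLUMNS, collapse = "\t"), con)
  else
    writeLines(c(paste(TRIAL_COLUMNS, collapse = "\t"),
                 apply(tab2, 1, paste, collapse = "\t")), con)
  close(con)
  invisible(path)
}

#' Read a session recording from a plain-text bundle
#'
#' Faithful inverse of [write_session()]: reconstructs the session object,
#' preserving unknown metadata keys. Errors explicitly on a missing file,
#' an unsupported format version, a missing or renamed column, or a trace
#' row count inconsistent with the declared sample count.
#'
#' @param path bundle directory.
#' @return A `hitd_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.yaml")
  tf <- file.path(path, "traces.tsv")
  lf <- file.path(path, "trials.tsv")
  for (f in c(mf, tf, lf))
    if (!file.exists(f)) stop("missing session file: ", f)
  meta <- yaml::read_yaml(mf)
  if (is.null(meta$format_version) ||
      meta$format_version != SESSION_FORMAT_VERSION)
    stop("unsupported session format version: ",
         if (is.null(meta$format_version)) "(absent)" else meta$format_version)
  traces <- utils::read.table(tf, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  miss <- setdiff(TRACE_COLUMNS, names(traces))
  if (length(miss) > 0)
    stop("traces.tsv is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(traces) != meta$n_samples)
    stop("traces.tsv has ", nrow(traces),
         " rows but meta declares n_samples = ", meta$n_samples)
  trl <- utils::read.table(lf, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(trial_id = "integer",
                                          direction = "character",
                                          trigger_time_s = "numeric",
                                          orientation_deg = "numeric",
                                          response_deg = "numeric",
                                          correct = "logical",
                                          nominal_delay_frames = "integer",
                                          nominal_duration_frames = "integer"))
  miss2 <- setdiff(TRIAL_COLUMNS, names(trl))
  if (length(miss2) > 0)
    stop("trials.tsv is missing column(s): ", paste(miss2, collapse = ", "))
  p <- meta$protocol
  protocol <- protocol_config(
    velocity_threshold = p$velocity_threshold,
    acceleration_threshold = p$acceleration_threshold,
    bin_width = p$bin_width,
    bin_upper_bounds = unlist(p$bin_upper_bounds),
    min_thrusts_per_bin = p$min_thrusts_per_bin,
    escalated_thrusts_per_bin = p$escalated_thrusts_per_bin,
    sva_increment = p$sva_increment,
    viewing_distance = p$viewing_distance)
  d <- meta$display
  display <- display_config(refresh_rate = d$refresh_rate,
                            nominal_delay_frames = d$nominal_delay_frames,
                            nominal_duration_frames = d$nominal_duration_frames)
  ts <- trace_set(
    gyro = as.matrix(traces[, c("gyro_x_dps", "gyro_y_dps", "gyro_z_dps")]),
    linacc = as.matrix(traces[, c("acc_x_ms2", "acc_y_ms2", "acc_z_ms2")]),
    eye_h = traces$eye_h_deg, eye_v = traces$eye_v_deg,
    photodiode = traces$photodiode_v, fs = meta$fs_hz, t = traces$t_s)
  session_recording(ts, protocol, display, trl,
                    meta = if (is.null(meta$meta)) list() else meta$meta)
}
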