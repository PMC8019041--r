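# Trajectory container and plain-text round-tripping. CSV dialect is pinned:
# UTF-8, comma-separated, dot decimal, '#' metadata/comment header lines.

#' Construct a trajectory
#'
#' Time-stamped planar positions with detection flags. Undetected samples may
#' carry `NA` positions; interpolated samples carry a position and are flagged.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param x,y Positions in metres (`NA` allowed where `detected` is `FALSE`).
#' @param detected Logical detection flag per sample.
#' @param interpolated Logical: position filled by interpolation.
#' @param frame_rate Acquisition rate in Hz.
#' @param calibration Metres per pixel (kept as metadata).
#' @param individual_id Optional id.
#' @param body_mass_mg,body_length_mm Optional animal size metadata.
#' @return A `trajectory` (data frame with metadata attributes).
#' @export
trajectory <- function(t, x, y, detected = TRUE, interpolated = FALSE,
                       frame_rate = 25, calibration = NA_real_,
                       individual_id = NA_character_,
                       body_mass_mg = NA_real_, body_length_mm = NA_real_) {
  n <- length(t)
  detected <- rep_len(detected, n)
  interpolated <- rep_len(interpolated, n)
  if (n == 0) stop("empty trajectory")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (length(x) != n || length(y) != n) stop("t, x, y lengths differ")
  miss <- (detected | interpolated) & (!is.finite(x) | !is.finite(y))
  if (any(miss)) stop("positioned samples must have finite coordinates")
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                    detected = as.logical(detected),
                    interpolated = as.logical(interpolated))
  attr(out, "frame_rate") <- frame_rate
  attr(out, "calibration") <- calibration
  attr(out, "individual_id") <- individual_id
  attr(out, "body_mass_mg") <- body_mass_mg
  attr(out, "body_length_mm") <- body_length_mm
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples over %.1f s (%.1f%% detected)\n",
              nrow(x), max(x$t) - min(x$t), 100 * mean(x$detected)))
  if (!is.na(attr(x, "individual_id"))) {
    cat(sprintf("  individual: %s\n", attr(x, "individual_id")))
  }
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  ok <- x$detected | x$interpolated
  plot(x$x[ok], x$y[ok], type = "l", asp = 1, xlab = "x [m]", ylab = "y [m]", ...)
  invisible(x)
}

.pkg_version <- function() {
  as.character(utils::packageVersion("mazetrack"))
}

# small deterministic fingerprint for config echoing (not cryptographic)
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.num <- function(v) {
  ifelse(is.na(v), "NA", sprintf("%.15g", v))
}

.write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# mazetrack %s", .pkg_version()), con)
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
  }
  is_num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(is_num)) out[[j]] <- .num(df[[j]])
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  }
  invisible(path)
}

.read_meta <- function(path) {
  lines <- readLines(path, n = 100, encoding = "UTF-8")
  lines <- lines[startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^# ([A-Za-z_]+): (.*)$", lines))
  m <- m[lengths(m) == 3]
  stats::setNames(lapply(m, `[`, 3), vapply(m, `[`, character(1), 2))
}

#' Write a trajectory CSV
#'
#' Columns `time_s,x_m,y_m,detected,interpolated`, preceded by `#` metadata
#' lines (tool version, frame rate, calibration, individual id, body size).
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_s = traj$t, x_m = traj$x, y_m = traj$y,
                   detected = as.integer(traj$detected),
                   interpolated = as.integer(traj$interpolated))
  .write_csv_meta(df, path, list(
    type = "trajectory",
    frame_rate = .num(attr(traj, "frame_rate")),
    calibration = .num(attr(traj, "calibration")),
    individual_id = as.character(attr(traj, "individual_id")),
    body_mass_mg = .num(attr(traj, "body_mass_mg")),
    body_length_mm = .num(attr(traj, "body_length_mm"))
  ))
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path Input path.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path) {
  meta <- .read_meta(path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed trajectory CSV '", path, "': ",
                             conditionMessage(e))
  )
  need <- c("time_s", "x_m", "y_m", "detected", "interpolated")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  gnum <- function(k) if (is.null(meta[[k]]) || meta[[k]] == "NA") NA_real_
                      else as.numeric(meta[[k]])
  gchr <- function(k) if (is.null(meta[[k]]) || meta[[k]] == "NA") NA_character_
                      else meta[[k]]
  trajectory(df$time_s, df$x_m, df$y_m,
             detected = df$detected == 1, interpolated = df$interpolated == 1,
             frame_rate = gnum("frame_rate"), calibration = gnum("calibration"),
             individual_id = gchr("individual_id"),
             body_mass_mg = gnum("body_mass_mg"),
             body_length_mm = gnum("body_length_mm"))
}

#' Write visits, transitions, occupancy or summary tables
#'
#' Thin CSV writers with the pinned dialect and `#` metadata headers.
#'
#' @param visits,transitions,occupancy Data frames from the space-use module.
#' @param summary A `space_use_summary`.
#' @param path Output path.
#' @param meta Named list of extra metadata lines.
#' @name space_use_io
NULL

#' @rdname space_use_io
#' @export
write_visits <- function(visits, path, meta = list()) {
  df <- data.frame(patch_id = visits$patch_id, t_enter_s = visits$t_enter,
                   t_exit_s = visits$t_exit, duration_s = visits$duration,
                   qualifying = as.integer(visits$qualifying))
  .write_csv_meta(df, path, c(list(type = "visits"), meta))
}

#' @rdname space_use_io
#' @export
write_transitions <- function(transitions, path, meta = list()) {
  df <- data.frame(channel_id = transitions$channel_id,
                   direction = transitions$direction, t_s = transitions$t)
  .write_csv_meta(df, path, c(list(type = "transitions"), meta))
}

#' @rdname space_use_io
#' @export
write_occupancy <- function(occupancy, path, meta = list()) {
  .write_csv_meta(occupancy, path, c(list(type = "occupancy"), meta))
}

#' @rdname space_use_io
#' @export
write_space_use_summary <- function(summary, path, meta = list()) {
  df <- data.frame(
    n_visits_total = summary$n_visits_total,
    n_resource_visits = summary$n_resource_visits,
    gut_min = summary$gut_min,
    total_time_patches_min = summary$total_time_patches_min,
    percent_time_patches = summary$percent_time_patches,
    cumulative_space_m2 = summary$cumulative_space_m2,
    cumulative_space_geometric_m2 = summary$cumulative_space_geometric_m2,
    n_transitions = summary$n_transitions,
    net_transitions = summary$net_transitions
  )
  .write_csv_meta(df, path, c(list(
    type = "space_use_summary",
    per_visit_area = .num(summary$per_visit_area),
    min_residence = .num(summary$min_residence),
    duration_s = .num(summary$duration_s)
  ), meta))
}
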