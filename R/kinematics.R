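# Locomotory parameters: step length, speed, acceleration, the in-patch
# wall-exclusion filter, and 30-s binned activity profiles. Speeds and step
# lengths are reported in cm and cm/s; positions remain in metres.

#' Resample a trajectory and compute steps
#'
#' The trajectory is resampled onto a regular grid of spacing `resample_dt`
#' (each grid point takes the nearest sample in time), then step lengths are
#' the Euclidean distances between consecutive grid positions. Steps whose
#' span covers an unpositioned sample (undetected and not interpolated) are
#' excluded, as are steps at grid points that map to unpositioned samples.
#'
#' @param traj A `trajectory`.
#' @param resample_dt Grid spacing in seconds (>= the native frame interval).
#'   Default 1 s: at the native 25 Hz, centimetre-scale animals are dominated
#'   by centroid jitter.
#' @return Data frame with columns `t` (start of step), `dt`, `dx`, `dy`
#'   (m) and `step_cm`.
#' @export
compute_steps <- function(traj, resample_dt = 1) {
  t <- traj$t
  n <- length(t)
  if (n < 2) stop("need at least 2 samples")
  native <- stats::median(diff(t))
  if (resample_dt < native - 1e-9) {
    stop("resample_dt must be >= the native frame interval")
  }
  grid <- seq(t[1], t[n], by = resample_dt)
  if (length(grid) < 2) stop("fewer than 2 usable resampled positions")
  # nearest sample to each grid time
  lo <- findInterval(grid, t, all.inside = TRUE)
  hi <- pmin(lo + 1, n)
  idx <- ifelse(abs(t[lo] - grid) <= abs(t[hi] - grid), lo, hi)
  pos_ok <- traj$detected | traj$interpolated
  has_gap_before <- cumsum(!pos_ok)   # gaps strictly between two indices
  g <- length(grid)
  i0 <- idx[-g]; i1 <- idx[-1]
  usable <- pos_ok[i0] & pos_ok[i1] &
    (has_gap_before[i1] - has_gap_before[i0]) == 0
  dx <- traj$x[i1] - traj$x[i0]
  dy <- traj$y[i1] - traj$y[i0]
  out <- data.frame(t = grid[-g], dt = diff(grid), dx = dx, dy = dy,
                    step_cm = 100 * sqrt(dx^2 + dy^2))
  out <- out[usable, , drop = FALSE]
  if (nrow(out) < 1) stop("fewer than 2 usable resampled positions")
  rownames(out) <- NULL
  out
}

#' Speed and acceleration from a step series
#'
#' Speed is step length per time unit; acceleration is the rate of change of
#' speed between consecutive steps. Acceleration is only defined where two
#' steps are adjacent on the resampling grid.
#'
#' @param steps Data frame from [compute_steps()].
#' @return Data frame `t`, `speed_cmps`, `accel_cmps2` (`NA` where undefined).
#' @export
speed_acceleration <- function(steps) {
  if (any(steps$dt <= 0)) stop("zero or negative dt in step series")
  sp <- steps$step_cm / steps$dt
  acc <- rep(NA_real_, length(sp))
  if (length(sp) >= 2) {
    i <- 2:length(sp)
    adjacent <- abs(steps$t[i] - (steps$t[i - 1] + steps$dt[i - 1])) < 1e-9
    acc[i][adjacent] <- (sp[i] - sp[i - 1])[adjacent] / steps$dt[i][adjacent]
  }
  data.frame(t = steps$t, speed_cmps = sp, accel_cmps2 = acc)
}

#' Wall-exclusion filter
#'
#' Patch walls distort locomotion (thigmotactic animals hug them), so samples
#' within `margin` of a patch wall — and all samples in channels or outside
#' patches — are excluded from kinematic summaries. With the standard 13-cm
#' patch and a 1-cm margin this leaves an 11-cm-diameter measurement arena
#' per patch. The returned trajectory keeps its full length; excluded samples
#' have their position flags cleared so that steps bridging an exclusion are
#' dropped rather than truncated.
#'
#' @param traj A `trajectory`.
#' @param maze A `maze_geometry`.
#' @param margin Exclusion margin from the patch wall in metres (default 0.01).
#' @return A `trajectory` with excluded samples unflagged; attribute
#'   `n_retained` counts the survivors.
#' @export
wall_filter <- function(traj, maze, margin = 0.01) {
  radii <- maze$patches$diameter / 2
  if (any(margin >= radii)) {
    stop("margin must be smaller than every patch radius")
  }
  keep <- rep(FALSE, nrow(traj))
  for (i in seq_len(nrow(maze$patches))) {
    r <- radii[i] - margin
    keep <- keep | ((traj$x - maze$patches$cx[i])^2 +
                      (traj$y - maze$patches$cy[i])^2) < r^2
  }
  keep <- keep & (traj$detected | traj$interpolated)
  out <- traj
  out$detected[!keep] <- FALSE
  out$interpolated[!keep] <- FALSE
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Bin a time series into fixed intervals
#'
#' Arithmetic mean per consecutive bin (default 30 s, the standard
#' compilation interval). A trailing bin shorter than `bin` is kept and
#' flagged `partial`.
#'
#' @param t Sample times (s), ordered.
#' @param value Values to average (`NA`s dropped within a bin).
#' @param bin Bin width in seconds.
#' @return Data frame `bin_start_s`, `mean`, `n`, `partial`.
#' @export
bin_profile <- function(t, value, bin = 30) {
  if (bin <= 0) stop("bin must be > 0")
  if (length(t) != length(value)) stop("t and value lengths differ")
  if (is.unsorted(t)) stop("t must be ordered")
  k <- floor((t - t[1]) / bin)
  ks <- sort(unique(k))
  m <- vapply(ks, function(kk) mean(value[k == kk], na.rm = TRUE), numeric(1))
  n <- vapply(ks, function(kk) sum(k == kk & !is.na(value)), integer(1))
  span_last <- max(t) - (t[1] + max(ks) * bin)
  data.frame(bin_start_s = t[1] + ks * bin, mean = m, n = n,
             partial = ks == max(ks) & span_last < bin - 1e-9)
}

#' Locomotory summary for one individual
#'
#' Applies the wall-exclusion filter (when a maze is given), resamples,
#' and reports mean/SD speed, maximum absolute acceleration, mean/SD step
#' length, and 30-s binned profiles of all three.
#'
#' @param traj A `trajectory`.
#' @param maze Optional `maze_geometry` for wall exclusion.
#' @param resample_dt Resampling interval in seconds (default 1).
#' @param margin Wall margin in metres (default the maze's `wall_margin`).
#' @param bin Profile bin width (s), default 30.
#' @return A `kinematics_summary` list.
#' @export
summarize_kinematics <- function(traj, maze = NULL, resample_dt = 1,
                                 margin = NULL, bin = 30) {
  if (!is.null(maze)) {
    if (is.null(margin)) margin <- maze$wall_margin
    traj <- wall_filter(traj, maze, margin)
  }
  steps <- compute_steps(traj, resample_dt)
  sa <- speed_acceleration(steps)
  profile <- data.frame(
    bin_start_s = bin_profile(sa$t, sa$speed_cmps, bin)$bin_start_s,
    mean_speed_cmps = bin_profile(sa$t, sa$speed_cmps, bin)$mean,
    mean_accel_cmps2 = bin_profile(sa$t, abs(sa$accel_cmps2), bin)$mean,
    mean_step_cm = bin_profile(steps$t, steps$step_cm, bin)$mean
  )
  out <- list(
    mean_speed_cmps = mean(sa$speed_cmps),
    sd_speed_cmps = stats::sd(sa$speed_cmps),
    max_acceleration_cmps2 = if (all(is.na(sa$accel_cmps2))) NA_real_
                             else max(abs(sa$accel_cmps2), na.rm = TRUE),
    mean_step_cm = mean(steps$step_cm),
    sd_step_cm = stats::sd(steps$step_cm),
    n_samples_used = nrow(steps) + 1L,
    resample_dt = resample_dt,
    profile = profile
  )
  class(out) <- "kinematics_summary"
  out
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat("kinematics_summary\n")
  cat(sprintf("  speed: %.2f +/- %.2f cm/s\n", x$mean_speed_cmps, x$sd_speed_cmps))
  cat(sprintf("  max |acceleration|: %.2f cm/s^2\n", x$max_acceleration_cmps2))
  cat(sprintf("  step length: %.2f +/- %.2f cm (dt = %g s)\n",
              x$mean_step_cm, x$sd_step_cm, x$resample_dt))
  cat(sprintf("  samples used: %d\n", x$n_samples_used))
  invisible(x)
}
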