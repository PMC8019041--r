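# Zone sequences, directional channel transitions, patch visits and the four
# space-use descriptors (visit counts, giving-up time, total/percent time in
# patches, cumulative space used).

.parse_zone_labels <- function(labels) {
  kind <- rep("outside", length(labels))
  patch_id <- rep(NA_character_, length(labels))
  channel_id <- rep(NA_character_, length(labels))
  subzone <- rep(NA_character_, length(labels))
  is_patch <- startsWith(labels, "patch:")
  kind[is_patch] <- "patch"
  patch_id[is_patch] <- substring(labels[is_patch], 7)
  other <- !is_patch & labels != "outside"
  if (any(other)) {
    parts <- regmatches(labels[other], regexec("^(.*):([abc])$", labels[other]))
    ok <- lengths(parts) == 3
    if (!all(ok)) stop("malformed zone labels: ",
                       paste(labels[other][!ok], collapse = ", "))
    kind[other] <- "subzone"
    channel_id[other] <- vapply(parts, `[`, character(1), 2)
    subzone[other] <- vapply(parts, `[`, character(1), 3)
  }
  data.frame(kind = kind, patch_id = patch_id, channel_id = channel_id,
             subzone = subzone, label = labels, stringsAsFactors = FALSE)
}

#' Construct a zone sequence
#'
#' A zone sequence is an ordered set of contiguous, non-overlapping dwell
#' segments, each labeled with the zone occupied: `"patch:<id>"`,
#' `"<channel_id>:<a|b|c>"`, or `"outside"`. Consecutive segments with the
#' same label are merged.
#'
#' @param labels Character vector of zone labels, one per segment.
#' @param t_start,t_end Segment boundaries in seconds (equal length to
#'   `labels`; contiguous: `t_start[i+1] == t_end[i]`).
#' @param id Optional source trajectory/individual id.
#' @return A `zone_sequence` data frame with columns `label`, `kind`,
#'   `patch_id`, `channel_id`, `subzone`, `t_start`, `t_end`.
#' @export
zone_sequence <- function(labels, t_start, t_end, id = NA_character_) {
  stopifnot(length(labels) == length(t_start), length(labels) == length(t_end))
  if (length(labels) == 0) stop("empty zone sequence")
  if (any(t_end < t_start)) stop("segment t_end < t_start")
  if (length(labels) > 1 &&
      any(abs(t_start[-1] - t_end[-length(t_end)]) > 1e-9)) {
    stop("segments must be contiguous")
  }
  keep <- c(TRUE, labels[-1] != labels[-length(labels)])
  grp <- cumsum(keep)
  t0 <- tapply(t_start, grp, min)
  t1 <- tapply(t_end, grp, max)
  lab <- labels[keep]
  out <- cbind(.parse_zone_labels(lab),
               data.frame(t_start = as.numeric(t0), t_end = as.numeric(t1)))
  rownames(out) <- NULL
  attr(out, "id") <- id
  class(out) <- c("zone_sequence", "data.frame")
  out
}

#' Label a trajectory by maze zone
#'
#' Maps every sample to a zone with [locate_points()] and merges runs of equal
#' labels into dwell segments. Samples without a position (undetected, not
#' interpolated) inherit the preceding label — the animal is assumed to have
#' stayed where it was last seen. Each sample's label holds from its timestamp
#' to the next sample's, so summed segment durations equal the trajectory span
#' exactly.
#'
#' @param traj A `trajectory`.
#' @param maze A `maze_geometry`.
#' @return A `zone_sequence`.
#' @export
label_zones <- function(traj, maze) {
  if (nrow(traj) == 0) stop("empty trajectory")
  has_pos <- traj$detected | traj$interpolated
  if (!any(has_pos)) stop("trajectory has no positioned samples")
  x <- traj$x; y <- traj$y
  # carry positions forward over undetected runs (and backward at the start)
  idx <- which(has_pos)
  carry <- findInterval(seq_along(x), idx)
  carry[carry == 0] <- 1
  x <- x[idx[carry]]; y <- y[idx[carry]]
  loc <- locate_points(maze, x, y)
  zone_sequence(loc$label, traj$t, c(traj$t[-1], traj$t[nrow(traj)]),
                id = attr(traj, "individual_id"))
}

# Transition automaton states: "", "a", "ab" (ascending), "c", "cb"
# (descending). "ab" + c completes a forward (+1) crossing, "cb" + a a reverse
# (-1) one; the machine resets on completion and on any exit from the channel.
.transition_step <- function(state, s) {
  if (state == "" ) return(switch(s, a = "a", c = "c", b = ""))
  if (state == "a") return(switch(s, b = "ab", c = "c", a = "a"))
  if (state == "ab") {
    if (s == "c") return("+")          # completion forward
    return(switch(s, a = "a", b = "ab"))
  }
  if (state == "c") return(switch(s, b = "cb", a = "a", c = "c"))
  if (state == "cb") {
    if (s == "a") return("-")          # completion reverse
    return(switch(s, c = "c", b = "cb"))
  }
  ""
}

#' Count directional channel transitions
#'
#' Emits one signed event per completed ordered traversal of a channel's three
#' subzones: a→b→c counts +1 (from the channel's `from` patch towards `to`),
#' c→b→a counts −1. Partial entries that turn back (e.g. a→b→a) emit nothing.
#' The per-channel state machine resets on completion and whenever the animal
#' leaves the channel. Event times are the entry times into the completing
#' subzone.
#'
#' @param zseq A `zone_sequence`.
#' @return Data frame with columns `channel_id`, `direction` (+1/−1), `t`.
#' @export
count_transitions <- function(zseq) {
  ch_id <- character(0); dir <- integer(0); tt <- numeric(0)
  state <- ""
  cur_channel <- NA_character_
  for (i in seq_len(nrow(zseq))) {
    if (zseq$kind[i] != "subzone") {
      state <- ""; cur_channel <- NA_character_
      next
    }
    if (!identical(zseq$channel_id[i], cur_channel)) {
      state <- ""; cur_channel <- zseq$channel_id[i]
    }
    state <- .transition_step(state, zseq$subzone[i])
    if (state == "+" || state == "-") {
      ch_id <- c(ch_id, cur_channel)
      dir <- c(dir, if (state == "+") 1L else -1L)
      tt <- c(tt, zseq$t_start[i])
      state <- ""
    }
  }
  data.frame(channel_id = ch_id, direction = dir, t = tt,
             stringsAsFactors = FALSE)
}

#' Detect patch visits
#'
#' Every maximal residence in a patch becomes a visit. A brief excursion into
#' a channel that returns to the same patch without completing a transition
#' does not split the visit: the patch segments are merged and the excursion
#' time is excluded from the visit duration (so for merged visits
#' `duration <= t_exit - t_enter`). A visit qualifies when its duration is at
#' least `min_residence` seconds.
#'
#' @param zseq A `zone_sequence`.
#' @param min_residence Minimum residence for a qualifying visit (s), default 30.
#' @return Data frame with columns `patch_id`, `t_enter`, `t_exit`,
#'   `duration`, `qualifying`.
#' @export
detect_visits <- function(zseq, min_residence = 30) {
  ev <- count_transitions(zseq)
  pid <- character(0); t_en <- numeric(0); t_ex <- numeric(0); dur <- numeric(0)
  cur <- NULL   # list(patch, t_enter, t_exit, duration)
  flush <- function() {
    if (!is.null(cur)) {
      pid <<- c(pid, cur$patch); t_en <<- c(t_en, cur$t_enter)
      t_ex <<- c(t_ex, cur$t_exit); dur <<- c(dur, cur$duration)
    }
    cur <<- NULL
  }
  i <- 1
  n <- nrow(zseq)
  while (i <= n) {
    if (zseq$kind[i] != "patch") { i <- i + 1; next }
    p <- zseq$patch_id[i]
    seg_dur <- zseq$t_end[i] - zseq$t_start[i]
    if (!is.null(cur) && cur$patch == p) {
      # returning segment: merge only if the excursion was channel-only and
      # completed no transition
      exc_ok <- cur$channel_only_excursion &&
        !any(ev$t > cur$t_exit - 1e-12 & ev$t < zseq$t_start[i] + 1e-12)
      if (exc_ok) {
        cur$duration <- cur$duration + seg_dur
        cur$t_exit <- zseq$t_end[i]
      } else {
        flush()
        cur <- list(patch = p, t_enter = zseq$t_start[i], t_exit = zseq$t_end[i],
                    duration = seg_dur)
      }
    } else {
      flush()
      cur <- list(patch = p, t_enter = zseq$t_start[i], t_exit = zseq$t_end[i],
                  duration = seg_dur)
    }
    # scan the following non-patch run to see whether it is channel-only
    j <- i + 1
    channel_only <- TRUE
    while (j <= n && zseq$kind[j] != "patch") {
      if (zseq$kind[j] != "subzone") channel_only <- FALSE
      j <- j + 1
    }
    cur$channel_only_excursion <- channel_only
    i <- i + 1
  }
  flush()
  data.frame(patch_id = pid, t_enter = t_en, t_exit = t_ex, duration = dur,
             qualifying = dur >= min_residence, stringsAsFactors = FALSE)
}

#' Per-bin zone occupancy fractions
#'
#' Splits the recording into fixed bins (default 30 s) and reports the
#' fraction of each bin spent in resource patches, empty patches, channels,
#' and outside any zone.
#'
#' @param zseq A `zone_sequence`.
#' @param maze A `maze_geometry` (defines which patches carry resource).
#' @param bin Bin width in seconds.
#' @return Data frame `bin_start_s`, `frac_resource`, `frac_empty`,
#'   `frac_channel`, `frac_outside`, `partial` (last bin shorter than `bin`).
#' @export
occupancy_bins <- function(zseq, maze, bin = 30) {
  if (bin <= 0) stop("bin must be > 0")
  t0 <- zseq$t_start[1]
  t1 <- zseq$t_end[nrow(zseq)]
  res_ids <- maze$patches$id[maze$patches$resource_g > 0]
  cls <- ifelse(zseq$kind == "patch",
                ifelse(zseq$patch_id %in% res_ids, "resource", "empty"),
                ifelse(zseq$kind == "subzone", "channel", "outside"))
  nb <- max(1L, ceiling((t1 - t0) / bin - 1e-12))
  acc <- matrix(0, nb, 4, dimnames = list(NULL, c("resource", "empty", "channel", "outside")))
  for (i in seq_len(nrow(zseq))) {
    a <- zseq$t_start[i]; b <- zseq$t_end[i]
    if (b <= a) next
    k0 <- floor((a - t0) / bin) + 1
    k1 <- min(nb, floor((b - t0 - 1e-12) / bin) + 1)
    for (k in k0:k1) {
      lo <- t0 + (k - 1) * bin; hi <- lo + bin
      acc[k, cls[i]] <- acc[k, cls[i]] + max(0, min(b, hi) - max(a, lo))
    }
  }
  bin_start <- t0 + (seq_len(nb) - 1) * bin
  width <- pmin(t1, bin_start + bin) - bin_start
  data.frame(bin_start_s = bin_start,
             frac_resource = acc[, "resource"] / width,
             frac_empty = acc[, "empty"] / width,
             frac_channel = acc[, "channel"] / width,
             frac_outside = acc[, "outside"] / width,
             partial = width < bin - 1e-12)
}

#' Summarise space use for one individual
#'
#' Computes the four space-use descriptors: per-patch qualifying visit counts;
#' giving-up time (GUT, mean duration of qualifying visits to resource
#' patches, in minutes); total and percent time in patches; and cumulative
#' space used, the number of qualifying resource-patch visits times a
#' per-visit area constant (default 0.01 m² — the conventional formula
#' constant; the geometric patch-area version is reported alongside).
#'
#' @param visits Data frame from [detect_visits()].
#' @param transitions Data frame from [count_transitions()].
#' @param maze A `maze_geometry`.
#' @param duration Experiment duration in seconds.
#' @param per_visit_area Area credited per qualifying resource visit (m²).
#' @param min_residence Qualifying threshold (s); re-applied to `visits`.
#' @param zseq Optional `zone_sequence` for 30-s occupancy bins.
#' @return A `space_use_summary` list.
#' @export
summarize_space_use <- function(visits, transitions, maze, duration,
                                per_visit_area = 0.01, min_residence = 30,
                                zseq = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  res_ids <- maze$patches$id[maze$patches$resource_g > 0]
  qual <- visits[visits$duration >= min_residence, , drop = FALSE]
  counts <- table(factor(qual$patch_id, levels = maze$patches$id))
  rq <- qual[qual$patch_id %in% res_ids, , drop = FALSE]
  n_res <- nrow(rq)
  gut_min <- if (n_res > 0) mean(rq$duration) / 60 else NA_real_
  total_min <- sum(visits$duration) / 60
  geom_area <- if (n_res > 0) {
    d <- maze$patches$diameter[match(rq$patch_id, maze$patches$id)]
    sum(patch_area(d))
  } else 0
  out <- list(
    visit_counts = counts,
    n_visits_total = nrow(qual),
    n_resource_visits = n_res,
    gut_min = gut_min,
    total_time_patches_min = total_min,
    percent_time_patches = 100 * total_min * 60 / duration,
    cumulative_space_m2 = n_res * per_visit_area,
    cumulative_space_geometric_m2 = geom_area,
    per_visit_area = per_visit_area,
    min_residence = min_residence,
    duration_s = duration,
    n_transitions = nrow(transitions),
    net_transitions = sum(transitions$direction),
    occupancy = if (!is.null(zseq)) occupancy_bins(zseq, maze) else NULL
  )
  class(out) <- "space_use_summary"
  out
}

#' @export
print.space_use_summary <- function(x, ...) {
  cat("space_use_summary\n")
  cat(sprintf("  qualifying visits: %d (%d to resource patches)\n",
              x$n_visits_total, x$n_resource_visits))
  cat(sprintf("  GUT: %s min\n",
              if (is.na(x$gut_min)) "undefined (no qualifying resource visits)"
              else sprintf("%.2f", x$gut_min)))
  cat(sprintf("  time in patches: %.2f min (%.1f%% of %.0f s)\n",
              x$total_time_patches_min, x$percent_time_patches, x$duration_s))
  cat(sprintf("  cumulative space used: %.3f m^2 (geometric: %.3f m^2)\n",
              x$cumulative_space_m2, x$cumulative_space_geometric_m2))
  cat(sprintf("  channel transitions: %d (net %+d)\n",
              x$n_transitions, x$net_transitions))
  invisible(x)
}
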