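# Synthetic foragers: a correlated random walk confined to the maze, with
# exponential patch-leaving hazard and scripted channel traversals; cohorts
# with size-dependent foraging; and an NIR-style video renderer. Every
# simulated individual carries a ground-truth log (per-frame positions and
# zone labels, visit schedule, transition list) derived from the simulator's
# own bookkeeping, independently of the measurement chain.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Forager movement parameters
#'
#' Defaults reflect the reference magnitudes for a mid-sized gammarid:
#' mean speed 2.45 cm/s (SD 1.03), wall-following (thigmotactic) tendency,
#' and a mean patch residence implying a giving-up time of roughly half an
#' hour on the full 6-h protocol.
#'
#' @param mean_speed Mean speed, cm/s.
#' @param speed_sd Per-step speed SD, cm/s.
#' @param turn_sd Per-step heading change SD, radians (CRW persistence).
#' @param thigmotaxis Wall-following weight in \[0, 1\]: probability that a
#'   wall encounter aligns the heading with the wall tangent rather than
#'   reflecting.
#' @param mean_residence Mean patch residence before departure, s
#'   (exponential leaving hazard `1/mean_residence`).
#' @param resource_attraction Extra weight in \[0, 1\] for choosing a channel
#'   that leads to a resource patch.
#' @param channel_abort_prob Probability that a channel entry turns back
#'   before completing the crossing (a Figure-style partial traversal).
#' @param seed Default RNG seed for [simulate_individual()].
#' @return A `forager_params` list.
#' @export
forager_params <- function(mean_speed = 2.45, speed_sd = 1.03, turn_sd = 0.5,
                           thigmotaxis = 0.3, mean_residence = 1668,
                           resource_attraction = 0.5,
                           channel_abort_prob = 0.1, seed = NULL) {
  stopifnot(mean_speed >= 0, speed_sd >= 0, turn_sd >= 0,
            thigmotaxis >= 0, thigmotaxis <= 1,
            mean_residence > 0,
            resource_attraction >= 0, resource_attraction <= 1,
            channel_abort_prob >= 0, channel_abort_prob <= 1)
  structure(list(mean_speed = mean_speed, speed_sd = speed_sd,
                 turn_sd = turn_sd, thigmotaxis = thigmotaxis,
                 mean_residence = mean_residence,
                 resource_attraction = resource_attraction,
                 channel_abort_prob = channel_abort_prob, seed = seed),
            class = "forager_params")
}

# CRW confined to a circle (specular reflection at radius r_in, or tangent
# alignment with probability `thigmo`). Returns K positions and final heading.
.walk_in_circle <- function(p0, h0, K, center, r_in, mean_step, step_sd,
                            turn_sd, thigmo) {
  xs <- numeric(K); ys <- numeric(K)
  pos <- p0; h <- h0
  k <- 0
  stuck <- 0
  while (k < K) {
    m <- min(512L, K - k)
    v <- pmax(stats::rnorm(m, mean_step, step_sd), 0)
    hs <- h + cumsum(stats::rnorm(m, 0, turn_sd))
    px <- pos[1] + cumsum(v * cos(hs))
    py <- pos[2] + cumsum(v * sin(hs))
    out <- (px - center[1])^2 + (py - center[2])^2 > r_in^2
    j <- if (any(out)) which(out)[1] else m + 1L
    take <- j - 1L
    if (take > 0) {
      xs[(k + 1):(k + take)] <- px[seq_len(take)]
      ys[(k + 1):(k + take)] <- py[seq_len(take)]
      pos <- c(px[take], py[take])
      h <- hs[take]
      k <- k + take
      stuck <- 0
    }
    if (j <= m) {                       # wall encounter: redirect
      stuck <- stuck + 1
      phi <- atan2(pos[2] - center[2], pos[1] - center[1])
      if (stuck > 3) {
        h <- phi + pi                   # force inward after repeated grazing
      } else if (stats::runif(1) < thigmo) {
        tang <- phi + pi / 2
        # pick the tangent direction closer to the current heading
        if (cos(h - tang) < 0) tang <- tang + pi
        h <- tang
      } else {
        nx <- cos(phi); ny <- sin(phi)
        vx <- cos(h); vy <- sin(h)
        dot <- vx * nx + vy * ny
        h <- atan2(vy - 2 * dot * ny, vx - 2 * dot * nx)
      }
    }
  }
  list(x = xs, y = ys, pos = pos, heading = h)
}

# straight walk from p0 to target in K steps with speed jitter
.walk_straight <- function(p0, target, mean_step, step_sd) {
  D <- sqrt(sum((target - p0)^2))
  K <- max(1L, ceiling(D / max(mean_step, 1e-6)))
  v <- pmax(stats::rnorm(K, mean_step, step_sd), 1e-6)
  f <- cumsum(v) / sum(v)
  list(x = p0[1] + f * (target[1] - p0[1]),
       y = p0[2] + f * (target[2] - p0[2]), K = K)
}

# labels for channel-frame samples, honouring the patch > subzone precedence
.channel_labels <- function(ch, maze, u, v) {
  r1 <- maze$patches$diameter[match(ch$from, maze$patches$id)] / 2
  r2 <- maze$patches$diameter[match(ch$to, maze$patches$id)] / 2
  off1 <- .chord_offset(r1, ch$width)
  off2 <- .chord_offset(r2, ch$width)
  in1 <- (off1 + u)^2 + v^2 <= r1^2
  in2 <- (off2 + (ch$length - u))^2 + v^2 <= r2^2
  f <- u / ch$length
  sz <- ifelse(f < ch$subzone_breaks[1], "a",
               ifelse(f < ch$subzone_breaks[2], "b", "c"))
  ifelse(in1, paste0("patch:", ch$from),
         ifelse(in2, paste0("patch:", ch$to), paste0(ch$id, ":", sz)))
}

# Transition oracle on a label stream: per contiguous same-channel block,
# repeatedly take the earliest-ending occurrence of "abc" (+1) or "cba" (-1)
# in the collapsed subzone string. Independent of count_transitions().
.transitions_from_labels <- function(run_labels, run_kind, run_channel,
                                     run_sub, run_t) {
  ch_id <- character(0); dir <- integer(0); tt <- numeric(0)
  R <- length(run_labels)
  i <- 1
  while (i <= R) {
    if (run_kind[i] != "subzone") { i <- i + 1; next }
    j <- i
    while (j + 1 <= R && run_kind[j + 1] == "subzone" &&
           run_channel[j + 1] == run_channel[i]) j <- j + 1
    s <- paste0(run_sub[i:j], collapse = "")
    pos <- 1
    repeat {
      rest <- substr(s, pos, nchar(s))
      ia <- regexpr("abc", rest, fixed = TRUE)
      ic <- regexpr("cba", rest, fixed = TRUE)
      enda <- if (ia > 0) ia + 2 else Inf
      endc <- if (ic > 0) ic + 2 else Inf
      if (!is.finite(enda) && !is.finite(endc)) break
      if (enda <= endc) { sgn <- 1L; e <- enda } else { sgn <- -1L; e <- endc }
      ch_id <- c(ch_id, run_channel[i])
      dir <- c(dir, sgn)
      tt <- c(tt, run_t[i + pos - 1 + e - 1])
      pos <- pos + e
    }
    i <- j + 1
  }
  data.frame(channel_id = ch_id, direction = dir, t = tt,
             stringsAsFactors = FALSE)
}

# Visit oracle on a label stream (run-level scan with the same merge
# semantics as the measurement chain, written against the run table).
.visits_from_labels <- function(run_labels, run_kind, run_patch, run_t0,
                                run_t1, events, min_residence = 30) {
  R <- length(run_labels)
  pid <- character(0); t_en <- numeric(0); t_ex <- numeric(0); dur <- numeric(0)
  cur <- NULL
  for (i in seq_len(R)) {
    if (run_kind[i] != "patch") next
    p <- run_patch[i]
    d <- run_t1[i] - run_t0[i]
    merged <- FALSE
    if (!is.null(cur) && cur$patch == p) {
      between <- which(run_t0 > cur$t_exit - 1e-12 & run_t1 < run_t0[i] + 1e-12)
      chan_only <- all(run_kind[between] == "subzone")
      no_event <- !any(events$t > cur$t_exit - 1e-12 &
                         events$t < run_t0[i] + 1e-12)
      if (chan_only && no_event) {
        cur$duration <- cur$duration + d
        cur$t_exit <- run_t1[i]
        merged <- TRUE
      }
    }
    if (!merged) {
      if (!is.null(cur)) {
        pid <- c(pid, cur$patch); t_en <- c(t_en, cur$t_enter)
        t_ex <- c(t_ex, cur$t_exit); dur <- c(dur, cur$duration)
      }
      cur <- list(patch = p, t_enter = run_t0[i], t_exit = run_t1[i],
                  duration = d)
    }
  }
  if (!is.null(cur)) {
    pid <- c(pid, cur$patch); t_en <- c(t_en, cur$t_enter)
    t_ex <- c(t_ex, cur$t_exit); dur <- c(dur, cur$duration)
  }
  data.frame(patch_id = pid, t_enter = t_en, t_exit = t_ex, duration = dur,
             qualifying = dur >= min_residence, stringsAsFactors = FALSE)
}

.ground_truth_from_labels <- function(labels, t, min_residence = 30) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  parsed <- .parse_zone_labels(r$values)
  run_t0 <- t[starts]
  run_t1 <- c(t[starts[-1]], t[length(t)])
  ev <- .transitions_from_labels(r$values, parsed$kind, parsed$channel_id,
                                 parsed$subzone, run_t0)
  vis <- .visits_from_labels(r$values, parsed$kind, parsed$patch_id,
                             run_t0, run_t1, ev, min_residence)
  list(transitions = ev, visits = vis)
}

#' Simulate one forager in the maze
#'
#' A correlated random walk at the acquisition rate, confined to the maze:
#' within a patch the walk reflects off (or, with the thigmotaxis weight,
#' follows) the wall; departure is governed by an exponential leaving hazard;
#' departures traverse a connecting channel (with a small probability of
#' turning back partway). The returned ground-truth log carries per-frame
#' zone labels, the visit schedule and the signed transition list, all
#' derived from the simulator's own state.
#'
#' @param params A `forager_params`.
#' @param maze A `maze_geometry`.
#' @param duration Recording length in seconds.
#' @param seed RNG seed (defaults to `params$seed`). Same seed, same output.
#' @param frame_rate Samples per second (default 25).
#' @param start_patch Patch id to start in (default the first patch).
#' @param individual_id Id stored on the trajectory.
#' @param body_mass_mg Optional mass metadata.
#' @return List with elements `trajectory` (a [trajectory()]) and
#'   `ground_truth` (list: `labels`, `visits`, `transitions`).
#' @export
simulate_individual <- function(params, maze, duration, seed = params$seed,
                                frame_rate = 25, start_patch = NULL,
                                individual_id = "sim", body_mass_mg = NA_real_) {
  stopifnot(duration > 0)
  .with_seed(seed, {
    dt <- 1 / frame_rate
    n <- max(2L, floor(duration * frame_rate))
    mean_step <- params$mean_speed * dt / 100       # m per frame
    step_sd <- params$speed_sd * dt / 100
    pid <- if (is.null(start_patch)) maze$patches$id[1] else as.character(start_patch)
    prow <- match(pid, maze$patches$id)
    if (is.na(prow)) stop("unknown start patch ", pid)
    pos <- c(maze$patches$cx[prow], maze$patches$cy[prow])
    h <- stats::runif(1, 0, 2 * pi)
    xs <- numeric(n); ys <- numeric(n); labs <- character(n)
    filled <- 0L
    emit <- function(x, y, lab) {
      m <- length(x)
      take <- min(m, n - filled)
      if (take > 0) {
        idx <- (filled + 1):(filled + take)
        xs[idx] <<- x[seq_len(take)]
        ys[idx] <<- y[seq_len(take)]
        labs[idx] <<- rep_len(lab, m)[seq_len(take)]
        filled <<- filled + take
      }
    }
    adj <- lapply(maze$channels, function(ch) c(ch$from, ch$to))
    while (filled < n) {
      # --- residence in patch `pid`
      prow <- match(pid, maze$patches$id)
      center <- c(maze$patches$cx[prow], maze$patches$cy[prow])
      r_in <- maze$patches$diameter[prow] / 2 - 0.001
      if (params$mean_speed == 0) {
        emit(rep(pos[1], n - filled), rep(pos[2], n - filled),
             paste0("patch:", pid))
        break
      }
      K <- max(1L, min(n - filled,
                       round(stats::rexp(1, 1 / params$mean_residence) * frame_rate)))
      w <- .walk_in_circle(pos, h, K, center, r_in, mean_step, step_sd,
                           params$turn_sd, params$thigmotaxis)
      emit(w$x, w$y, paste0("patch:", pid))
      pos <- w$pos; h <- w$heading
      if (filled >= n) break
      # --- choose a channel out of this patch
      cands <- which(vapply(maze$channels, function(ch) {
        ch$from == pid || ch$to == pid
      }, logical(1)))
      if (length(cands) == 0) next      # isolated patch: stay put
      wts <- vapply(cands, function(k) {
        ch <- maze$channels[[k]]
        other <- if (ch$from == pid) ch$to else ch$from
        res <- maze$patches$resource_g[match(other, maze$patches$id)] > 0
        1 + params$resource_attraction * res
      }, numeric(1))
      k <- if (length(cands) == 1) cands else sample(cands, 1, prob = wts)
      ch <- maze$channels[[k]]
      forward <- ch$from == pid
      # walk to the channel mouth (still inside the patch)
      mouth <- if (forward) ch$p0 else ch$p0 + ch$length * ch$axis
      sw <- .walk_straight(pos, mouth, mean_step, step_sd)
      emit(sw$x, sw$y, paste0("patch:", pid))
      pos <- mouth
      if (filled >= n) break
      # --- channel traversal (possibly aborted partway)
      abort <- stats::runif(1) < params$channel_abort_prob
      L <- ch$length
      u0 <- if (forward) 0 else L
      u_goal <- if (forward) L else 0
      u_turn <- if (abort) {
        stats::runif(1, 0.1, max(0.15, ch$subzone_breaks[2] - 0.05)) * L
      } else NA
      if (abort && !forward) u_turn <- L - u_turn
      u <- u0; vlat <- 0
      uu <- numeric(0); vv <- numeric(0)
      legs <- if (abort) list(c(u0, u_turn), c(u_turn, u0)) else list(c(u0, u_goal))
      for (leg in legs) {
        sgn <- sign(leg[2] - leg[1])
        D <- abs(leg[2] - leg[1])
        Ks <- max(1L, ceiling(D / max(mean_step, 1e-6)))
        v <- pmax(stats::rnorm(Ks, mean_step, step_sd), 1e-6)
        f <- cumsum(v) / sum(v)
        us <- leg[1] + sgn * f * D
        vs <- numeric(Ks)
        vmax <- ch$width / 2 - 0.001
        for (q in seq_len(Ks)) {
          vlat <- 0.8 * vlat + stats::rnorm(1, 0, 0.002)
          vlat <- max(-vmax, min(vmax, vlat))
          vs[q] <- vlat
        }
        uu <- c(uu, us); vv <- c(vv, vs)
      }
      px <- ch$p0[1] + uu * ch$axis[1] + vv * ch$perp[1]
      py <- ch$p0[2] + uu * ch$axis[2] + vv * ch$perp[2]
      emit(px, py, .channel_labels(ch, maze, uu, vv))
      if (abort) {
        pos <- c(px[length(px)], py[length(py)])
        h <- atan2(center[2] - pos[2], center[1] - pos[1])
        # pid unchanged: back in the same patch
      } else {
        pid <- if (forward) ch$to else ch$from
        pos <- c(px[length(px)], py[length(py)])
        h <- atan2(ch$axis[2], ch$axis[1]) + if (forward) 0 else pi
      }
    }
    t <- (seq_len(n) - 1) * dt
    traj <- trajectory(t, xs, ys, detected = TRUE, interpolated = FALSE,
                       frame_rate = frame_rate,
                       individual_id = individual_id,
                       body_mass_mg = body_mass_mg)
    gt <- .ground_truth_from_labels(labs, t)
    list(trajectory = traj,
         ground_truth = list(labels = labs, t = t,
                             visits = gt$visits, transitions = gt$transitions))
  })
}

#' Cohort specification
#'
#' @param n Number of individuals.
#' @param mass_range Body-mass range, mg dry weight (default 0.6–12.41, the
#'   size span of animals the detection system resolves).
#' @param visit_exponent Allometric exponent for the expected qualifying
#'   resource-visit count (default 0.77).
#' @param gut_slope Allometric slope for mean visit duration (negative:
#'   larger animals give patches up sooner). Used by the event-level
#'   generator; the trajectory generator implies its residence scaling from
#'   the visit-count target.
#' @param noise_sd SD of the multiplicative lognormal noise on the expected
#'   visit count (log scale).
#' @param reference_mass Mass (mg) at which `reference_rate` applies.
#' @param reference_rate Expected qualifying resource visits per second at
#'   the reference mass (default 0.005 /s, i.e. ~108 visits over 6 h,
#'   matching a cumulative space of ~1 m² at 0.01 m² per visit).
#' @param seed Master seed; each individual gets its own derived stream.
#' @param mode `"trajectory"` simulates full 25-Hz walks;
#'   `"events"` draws the visit schedules directly (fast, for large
#'   replicate studies of the cohort statistics).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 24, mass_range = c(0.6, 12.41),
                        visit_exponent = 0.77, gut_slope = -0.3,
                        noise_sd = 0.3, reference_mass = 6.9,
                        reference_rate = 0.005, seed = 1,
                        mode = c("trajectory", "events")) {
  stopifnot(n >= 1, all(mass_range > 0), mass_range[1] < mass_range[2],
            noise_sd >= 0, reference_mass > 0, reference_rate > 0)
  structure(list(n = n, mass_range = mass_range,
                 visit_exponent = visit_exponent, gut_slope = gut_slope,
                 noise_sd = noise_sd, reference_mass = reference_mass,
                 reference_rate = reference_rate, seed = seed,
                 mode = match.arg(mode)),
            class = "cohort_spec")
}

.derived_seed <- function(master, i) {
  (as.numeric(master) * 7919 + i * 104729) %% 2000000000
}

# event-level schedule: qualifying visit count ~ Poisson(rate * duration *
# lognormal noise); durations 30 s + Exp with a mass-dependent mean.
.simulate_events <- function(mass, duration, spec, maze) {
  res_ids <- maze$patches$id[maze$patches$resource_g > 0]
  all_ids <- maze$patches$id
  lam <- spec$reference_rate * (mass / spec$reference_mass)^spec$visit_exponent *
    stats::rlnorm(1, -spec$noise_sd^2 / 2, spec$noise_sd)
  k_res <- stats::rpois(1, lam * duration)
  k_emp <- stats::rpois(1, 0.5 * lam * duration)
  k <- k_res + k_emp
  if (k == 0) {
    return(data.frame(patch_id = character(0), t_enter = numeric(0),
                      t_exit = numeric(0), duration = numeric(0),
                      qualifying = logical(0)))
  }
  mean_extra <- 300 * (mass / spec$reference_mass)^spec$gut_slope
  durs <- 30 + stats::rexp(k, 1 / mean_extra)
  to_res <- sample(c(rep(TRUE, k_res), rep(FALSE, k_emp)))
  pids <- ifelse(to_res,
                 sample(res_ids, k, replace = TRUE),
                 sample(setdiff(all_ids, res_ids), k, replace = TRUE))
  starts <- sort(stats::runif(k, 0, duration))
  data.frame(patch_id = pids, t_enter = starts, t_exit = starts + durs,
             duration = durs, qualifying = TRUE, stringsAsFactors = FALSE)
}

#' Simulate a cohort of foragers
#'
#' Masses are drawn uniformly over the cohort's range; the expected
#' qualifying resource-visit count scales as mass^exponent with
#' multiplicative lognormal noise. In `"trajectory"` mode each individual is
#' a full [simulate_individual()] run whose mean patch residence is set from
#' its visit-count target; in `"events"` mode the visit schedules are drawn
#' directly.
#'
#' @param spec A `cohort_spec`.
#' @param maze A `maze_geometry`.
#' @param duration Recording length per individual (s).
#' @param ... Additional `forager_params` overrides for trajectory mode.
#' @return A `cohort`: list of individuals, each with `id`, `mass_mg`,
#'   `seed`, `trajectory` (or `NULL` in events mode) and `ground_truth`
#'   (with at least a `visits` schedule).
#' @export
simulate_cohort <- function(spec, maze, duration, ...) {
  inds <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    si <- .derived_seed(spec$seed, i)
    ind <- .with_seed(si, {
      mass <- stats::runif(1, spec$mass_range[1], spec$mass_range[2])
      if (spec$mode == "events") {
        vis <- .simulate_events(mass, duration, spec, maze)
        list(mass = mass, trajectory = NULL,
             ground_truth = list(visits = vis,
                                 transitions = data.frame(
                                   channel_id = character(0),
                                   direction = integer(0), t = numeric(0))))
      } else {
        lam <- spec$reference_rate *
          (mass / spec$reference_mass)^spec$visit_exponent *
          stats::rlnorm(1, -spec$noise_sd^2 / 2, spec$noise_sd)
        travel_est <- 10
        residence <- max(45, 1 / lam - travel_est)
        par <- forager_params(mean_residence = residence, ...)
        sim <- simulate_individual(par, maze, duration, seed = si + 1,
                                   individual_id = sprintf("ind%02d", i),
                                   body_mass_mg = mass)
        list(mass = mass, trajectory = sim$trajectory,
             ground_truth = sim$ground_truth)
      }
    })
    inds[[i]] <- list(id = sprintf("ind%02d", i), mass_mg = ind$mass,
                      seed = si, trajectory = ind$trajectory,
                      ground_truth = ind$ground_truth)
  }
  structure(list(spec = spec, duration = duration, individuals = inds),
            class = "cohort")
}

#' Space-use table for a cohort
#'
#' Runs the measurement chain (zone labeling, visit detection, summary) on
#' each individual's trajectory — or, in events mode, summarises the scripted
#' visit schedule — and returns one row per individual.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param maze A `maze_geometry`.
#' @param per_visit_area Area per qualifying resource visit (m²).
#' @param min_residence Qualifying threshold (s).
#' @return Data frame: `id`, `mass_mg`, `n_resource_visits`,
#'   `cumulative_space_m2`, `gut_min`, `total_time_patches_min`.
#' @export
cohort_space_use <- function(cohort, maze, per_visit_area = 0.01,
                             min_residence = 30) {
  res_ids <- maze$patches$id[maze$patches$resource_g > 0]
  rows <- lapply(cohort$individuals, function(ind) {
    if (!is.null(ind$trajectory)) {
      zs <- label_zones(ind$trajectory, maze)
      vis <- detect_visits(zs, min_residence)
      trans <- count_transitions(zs)
    } else {
      vis <- ind$ground_truth$visits
      vis$qualifying <- vis$duration >= min_residence
      trans <- ind$ground_truth$transitions
    }
    s <- summarize_space_use(vis, trans, maze, cohort$duration,
                             per_visit_area, min_residence)
    data.frame(id = ind$id, mass_mg = ind$mass_mg,
               n_resource_visits = s$n_resource_visits,
               cumulative_space_m2 = s$cumulative_space_m2,
               gut_min = s$gut_min,
               total_time_patches_min = s$total_time_patches_min,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render an NIR-style video of a trajectory
#'
#' Bright backlit field with maze walls drawn slightly darker; the animal is
#' an anisotropic Gaussian dark blob of peak depth `contrast`, oriented along
#' its heading, plus additive Gaussian pixel noise. Returns the clean
#' background plate and ground-truth pixel centres for tracker validation.
#'
#' @param traj A `trajectory` (positions in metres).
#' @param maze A `maze_geometry` (drawn into the background).
#' @param contrast Peak blob depth in 8-bit intensity units.
#' @param noise_sd Additive pixel noise SD (8-bit units).
#' @param body_length_px Blob length (4 sigma along the body axis), >= 2.
#' @param frame_size `c(width, height)` in px.
#' @param calibration Metres per pixel; default fits the arena into the frame.
#' @param background_level Field brightness (8-bit units).
#' @param seed RNG seed for the pixel noise.
#' @return List `stack` (`[row, col, frame]`, 0–255), `background` (clean
#'   plate), `truth` (data frame `x_px`, `y_px` per frame), `calibration`.
#' @export
render_video <- function(traj, maze, contrast = 80, noise_sd = 2,
                         body_length_px = 8, frame_size = c(320, 256),
                         calibration = NULL, background_level = 220,
                         seed = NULL) {
  if (body_length_px < 2) stop("body_length_px must be >= 2 (sub-resolution target)")
  W <- frame_size[1]; H <- frame_size[2]
  if (is.null(calibration)) {
    ext_x <- max(maze$arena[, 1]) - min(maze$arena[, 1])
    ext_y <- max(maze$arena[, 2]) - min(maze$arena[, 2])
    calibration <- max(ext_x / W, ext_y / H)
  }
  bg <- matrix(background_level, H, W)
  # walls: patch rims and channel edges a touch darker than the field
  cc <- px_to_m(rep(seq_len(W), each = H), rep(seq_len(H), W), H, calibration)
  pxx <- matrix(cc$x, H, W); pyy <- matrix(cc$y, H, W)
  for (i in seq_len(nrow(maze$patches))) {
    r <- maze$patches$diameter[i] / 2
    d <- sqrt((pxx - maze$patches$cx[i])^2 + (pyy - maze$patches$cy[i])^2)
    bg[abs(d - r) < calibration] <- background_level - 15
  }
  for (ch in maze$channels) {
    dx <- pxx - ch$p0[1]; dy <- pyy - ch$p0[2]
    u <- dx * ch$axis[1] + dy * ch$axis[2]
    v <- dx * ch$perp[1] + dy * ch$perp[2]
    edge <- u >= 0 & u <= ch$length &
      abs(abs(v) - ch$width / 2) < calibration
    bg[edge] <- background_level - 15
  }
  n <- nrow(traj)
  .with_seed(seed, {
    stack <- array(0, dim = c(H, W, n))
    sig_l <- body_length_px / 4
    sig_s <- body_length_px / 8
    px <- m_to_px(traj$x, traj$y, H, calibration)
    hx <- c(diff(px$x), 0); hy <- c(diff(px$y), 0)
    for (i in seq_len(n)) {
      fr <- bg
      if (traj$detected[i] && contrast > 0) {
        x0 <- px$x[i]; y0 <- px$y[i]
        th <- if (hx[i] != 0 || hy[i] != 0) atan2(hy[i], hx[i]) else 0
        w <- ceiling(4 * sig_l)
        cset <- max(1, floor(x0 - w)):min(W, ceiling(x0 + w))
        rset <- max(1, floor(y0 - w)):min(H, ceiling(y0 + w))
        dxm <- outer(rep(1, length(rset)), cset - x0)
        dym <- outer(rset - y0, rep(1, length(cset)))
        a <- dxm * cos(th) + dym * sin(th)
        b <- -dxm * sin(th) + dym * cos(th)
        blob <- contrast * exp(-0.5 * ((a / sig_l)^2 + (b / sig_s)^2))
        fr[rset, cset] <- fr[rset, cset] - blob
      }
      if (noise_sd > 0) fr <- fr + stats::rnorm(H * W, 0, noise_sd)
      stack[, , i] <- pmin(pmax(fr, 0), 255)
    }
    list(stack = stack, background = bg,
         truth = data.frame(x_px = px$x, y_px = px$y),
         calibration = calibration)
  })
}
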