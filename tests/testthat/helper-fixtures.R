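# Shared fixtures and independent oracles, all built in code.

# minimal two-patch, one-channel maze config
two_patch_config <- function(resource = c(1, 0), width = 0.025) {
  list(
    patches = list(
      list(id = "1", cx = 0.10, cy = 0.10, diameter = 0.13, resource_g = resource[1]),
      list(id = "2", cx = 0.40, cy = 0.10, diameter = 0.13, resource_g = resource[2])
    ),
    channels = list(list(id = "c12", from = "1", to = "2", width = width))
  )
}

# zone sequence from labels with unit (or given) segment durations
zseq_of <- function(labels, durations = rep(1, length(labels)), t0 = 0) {
  ends <- t0 + cumsum(durations)
  zone_sequence(labels, c(t0, ends[-length(ends)]), ends)
}

# shoelace area, independent of the package internals
shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]; n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# brute-force scan oracle for channel crossings: repeatedly consume the
# earliest-ending occurrence of "abc" (+1) or "cba" (-1) in the collapsed
# subzone string
oracle_crossings <- function(subs) {
  s <- paste(rle(subs)$values, collapse = "")
  out <- integer(0)
  repeat {
    ia <- regexpr("abc", s, fixed = TRUE)
    ic <- regexpr("cba", s, fixed = TRUE)
    ea <- if (ia > 0) ia + 2 else Inf
    ec <- if (ic > 0) ic + 2 else Inf
    if (!is.finite(ea) && !is.finite(ec)) break
    if (ea <= ec) { out <- c(out, 1L); s <- substring(s, ea + 1) }
    else { out <- c(out, -1L); s <- substring(s, ec + 1) }
  }
  out
}

# hand implementation of the Kruskal-Wallis defining formula (mid-ranks,
# tie correction), independent of stats::kruskal.test
oracle_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  groups <- factor(groups)
  Ri <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(ni * (Ri - (N + 1) / 2)^2)
  tj <- table(values)
  D <- 1 - sum(tj^3 - tj) / (N^3 - N)
  H / D
}

# ray-casting point-in-polygon, independent of the package
in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# straight-line trajectory at constant velocity (m/s), 25 Hz
straight_traj <- function(v = 0.0245, duration = 10, fps = 25,
                          x0 = 0.15, y0 = 0.12, angle = 0) {
  t <- seq(0, duration, by = 1 / fps)
  trajectory(t, x0 + v * t * cos(angle), y0 + v * t * sin(angle),
             frame_rate = fps)
}
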