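# Maze geometry: circular patches joined by straight channels, each channel
# split along its axis into three ordered subzones a|b|c (oriented from the
# `from` patch towards the `to` patch). All lengths are in metres; the origin
# is the lower-left corner of the arena bounding box, y increasing upward.

#' Area of a circular patch
#'
#' @param diameter Patch diameter in metres.
#' @return Area in square metres, \eqn{\pi (d/2)^2}.
#' @examples
#' patch_area(0.13)   # ~0.013 m^2, the standard 13-cm patch
#' @export
patch_area <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter < 0)) {
    stop("patch diameter must be finite and >= 0")
  }
  pi * (diameter / 2)^2
}

# Trim offset: axial distance from a patch centre to the chord where a channel
# of width `w` meets the circle. Trimming at the chord (not at the circle/axis
# intersection) leaves no unlabeled sliver at the channel mouth; the small
# circular segment where rectangle and circle overlap is resolved by the
# patch > subzone precedence in locate().
.chord_offset <- function(r, w) {
  if (w / 2 >= r) stop("channel width must be smaller than patch diameter")
  sqrt(r^2 - (w / 2)^2)
}

.build_channel <- function(ch, patches) {
  i <- match(ch$from, patches$id)
  j <- match(ch$to, patches$id)
  if (is.na(i) || is.na(j)) {
    stop(sprintf("channel '%s': endpoint patch not found ('%s' -> '%s')",
                 ch$id, ch$from, ch$to))
  }
  if (i == j) stop(sprintf("channel '%s' connects a patch to itself", ch$id))
  c1 <- c(patches$cx[i], patches$cy[i])
  c2 <- c(patches$cx[j], patches$cy[j])
  d <- sqrt(sum((c2 - c1)^2))
  r1 <- patches$diameter[i] / 2
  r2 <- patches$diameter[j] / 2
  u <- (c2 - c1) / d
  off1 <- .chord_offset(r1, ch$width)
  off2 <- .chord_offset(r2, ch$width)
  len <- d - off1 - off2
  if (!is.finite(len) || len <= 0) {
    stop(sprintf("channel '%s' has non-positive free length (patches too close)",
                 ch$id))
  }
  p0 <- c1 + off1 * u                 # axis origin at the `from` chord
  perp <- c(-u[2], u[1])
  hw <- ch$width / 2
  poly <- rbind(p0 + hw * perp,
                p0 - hw * perp,
                p0 + len * u - hw * perp,
                p0 + len * u + hw * perp)
  breaks <- ch$subzone_breaks
  if (is.null(breaks)) breaks <- c(1, 2) / 3
  breaks <- as.numeric(breaks)
  if (length(breaks) != 2 || any(!is.finite(breaks)) ||
      breaks[1] <= 0 || breaks[2] >= 1 || breaks[1] >= breaks[2]) {
    stop(sprintf("channel '%s': subzone_breaks must be two fractions in (0,1), increasing",
                 ch$id))
  }
  list(id = as.character(ch$id), from = patches$id[i], to = patches$id[j],
       width = ch$width, p0 = p0, axis = u, perp = perp, length = len,
       polygon = poly, subzone_breaks = breaks)
}

#' Build a validated maze from a configuration list
#'
#' The configuration mirrors the bundled YAML schema: `patches` is a list of
#' `{id, cx, cy, diameter, resource_g}` records, `channels` a list of
#' `{id, from, to, width}` records (optionally `subzone_breaks`, two axial
#' fractions splitting the channel into the a|b|c subzones; equal thirds by
#' default), `arena` a polygon as a list of `[x, y]` vertices, and
#' `wall_margin` the kinematic wall-exclusion margin in metres (default 0.01).
#'
#' @param config A named list (e.g. from [read_maze_config()]).
#' @return An object of class `maze_geometry`.
#' @seealso [default_maze()], [locate_points()]
#' @export
build_maze <- function(config) {
  if (is.null(config$patches) || length(config$patches) < 2) {
    stop("maze config must declare at least 2 patches")
  }
  if (is.null(config$channels) || length(config$channels) < 1) {
    stop("maze config must declare at least 1 channel")
  }
  pl <- config$patches
  patches <- data.frame(
    id = vapply(pl, function(p) as.character(p$id), character(1)),
    cx = vapply(pl, function(p) as.numeric(p$cx), numeric(1)),
    cy = vapply(pl, function(p) as.numeric(p$cy), numeric(1)),
    diameter = vapply(pl, function(p) as.numeric(p$diameter), numeric(1)),
    resource_g = vapply(pl, function(p) {
      if (is.null(p$resource_g)) 0 else as.numeric(p$resource_g)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(patches$diameter) | patches$diameter <= 0
  if (any(bad)) {
    stop("patch diameters must be > 0: ", paste(patches$id[bad], collapse = ", "))
  }
  if (anyDuplicated(patches$id)) stop("duplicate patch ids")
  if (any(patches$resource_g < 0)) stop("resource_g must be >= 0")
  n <- nrow(patches)
  overlaps <- character(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt((patches$cx[i] - patches$cx[j])^2 + (patches$cy[i] - patches$cy[j])^2)
    if (d < (patches$diameter[i] + patches$diameter[j]) / 2 - 1e-12) {
      overlaps <- c(overlaps, sprintf("%s/%s", patches$id[i], patches$id[j]))
    }
  }
  if (length(overlaps)) {
    stop("overlapping patches: ", paste(overlaps, collapse = ", "))
  }
  channels <- lapply(config$channels, .build_channel, patches = patches)
  ids <- vapply(channels, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate channel ids")
  names(channels) <- ids
  arena <- config$arena
  if (is.null(arena)) {
    # bounding box of patches + channels, padded by one patch radius
    xs <- c(patches$cx - patches$diameter / 2, patches$cx + patches$diameter / 2)
    ys <- c(patches$cy - patches$diameter / 2, patches$cy + patches$diameter / 2)
    arena <- rbind(c(min(xs), min(ys)), c(max(xs), min(ys)),
                   c(max(xs), max(ys)), c(min(xs), max(ys)))
  } else {
    arena <- do.call(rbind, lapply(arena, as.numeric))
    if (ncol(arena) != 2 || nrow(arena) < 3 || any(!is.finite(arena))) {
      stop("malformed arena polygon")
    }
  }
  wm <- config$wall_margin
  if (is.null(wm)) wm <- 0.01
  structure(list(patches = patches, channels = channels, arena = arena,
                 wall_margin = as.numeric(wm)),
            class = "maze_geometry")
}

#' Read a maze configuration file (YAML)
#'
#' @param path Path to a YAML maze configuration.
#' @return The parsed configuration list (pass to [build_maze()]).
#' @export
read_maze_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("units", "patches", "channels", "arena", "wall_margin")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown maze config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$units) && !identical(cfg$units, "m")) {
    stop("maze config units must be metres ('m')")
  }
  cfg
}

#' Write a maze configuration file (YAML)
#'
#' Inverse of [read_maze_config()]: a written config read back and passed to
#' [build_maze()] reproduces the same geometry.
#'
#' @param maze A `maze_geometry` object.
#' @param path Output path.
#' @export
write_maze_config <- function(maze, path) {
  p <- maze$patches
  cfg <- list(
    units = "m",
    wall_margin = maze$wall_margin,
    arena = lapply(seq_len(nrow(maze$arena)), function(i) as.numeric(maze$arena[i, ])),
    patches = lapply(seq_len(nrow(p)), function(i) {
      list(id = p$id[i], cx = p$cx[i], cy = p$cy[i],
           diameter = p$diameter[i], resource_g = p$resource_g[i])
    }),
    channels = lapply(maze$channels, function(ch) {
      list(id = ch$id, from = ch$from, to = ch$to, width = ch$width,
           subzone_breaks = ch$subzone_breaks)
    })
  )
  names(cfg$channels) <- NULL
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' The bundled six-patch trapezoid maze
#'
#' A 70/40/70-cm isosceles trapezoid arena holding six 13-cm circular patches
#' connected by 2.5-cm-wide channels. Two patches carry leaf resource (1 g and
#' 0.5 g DW), four are empty. Patch positions and the channel network are this
#' package's own layout choice within the stated outline.
#'
#' @return A `maze_geometry` object.
#' @export
default_maze <- function() {
  path <- system.file("extdata", "maze_default.yaml", package = "mazetrack")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "maze_default.yaml")
  build_maze(read_maze_config(path))
}

#' Locate points in the maze
#'
#' Vectorised point-in-zone query. Every point receives exactly one label:
#' a patch, a channel subzone (a, b or c, oriented from the channel's `from`
#' patch), or `outside`. Precedence on boundaries is patch > subzone > outside;
#' subzone boundaries along the channel axis are half-open, the boundary
#' belonging to the subzone nearer the `from` patch.
#'
#' @param maze A `maze_geometry`.
#' @param x,y Coordinates in metres (equal-length vectors).
#' @return A data frame with columns `kind` ("patch"/"subzone"/"outside"),
#'   `patch_id`, `channel_id`, `subzone`, and a compact string `label`.
#' @export
locate_points <- function(maze, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite coordinates")
  n <- length(x)
  kind <- rep("outside", n)
  patch_id <- rep(NA_character_, n)
  channel_id <- rep(NA_character_, n)
  subzone <- rep(NA_character_, n)
  # channels first; patches applied last so patch precedence wins
  for (ch in maze$channels) {
    dx <- x - ch$p0[1]; dy <- y - ch$p0[2]
    u <- dx * ch$axis[1] + dy * ch$axis[2]
    v <- dx * ch$perp[1] + dy * ch$perp[2]
    inside <- u >= 0 & u <= ch$length & abs(v) <= ch$width / 2
    if (any(inside)) {
      idx <- which(inside & kind == "outside")
      if (length(idx)) {
        fi <- u[idx] / ch$length
        kind[idx] <- "subzone"
        channel_id[idx] <- ch$id
        subzone[idx] <- ifelse(fi < ch$subzone_breaks[1], "a",
                               ifelse(fi < ch$subzone_breaks[2], "b", "c"))
      }
    }
  }
  p <- maze$patches
  for (i in seq_len(nrow(p))) {
    r2 <- (p$diameter[i] / 2)^2
    inp <- (x - p$cx[i])^2 + (y - p$cy[i])^2 <= r2
    if (any(inp)) {
      kind[inp] <- "patch"
      patch_id[inp] <- p$id[i]
      channel_id[inp] <- NA_character_
      subzone[inp] <- NA_character_
    }
  }
  label <- ifelse(kind == "patch", paste0("patch:", patch_id),
                  ifelse(kind == "subzone", paste0(channel_id, ":", subzone),
                         "outside"))
  data.frame(kind = kind, patch_id = patch_id, channel_id = channel_id,
             subzone = subzone, label = label, stringsAsFactors = FALSE)
}

#' Locate a single point
#'
#' @param point Numeric length-2 vector `c(x, y)` in metres.
#' @param maze A `maze_geometry`.
#' @return A one-row data frame as in [locate_points()].
#' @export
locate <- function(point, maze) {
  locate_points(maze, point[1], point[2])
}

# shoelace polygon area (used by print and by validation tests)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @export
print.maze_geometry <- function(x, ...) {
  p <- x$patches
  parea <- sum(patch_area(p$diameter))
  carea <- sum(vapply(x$channels, function(ch) ch$length * ch$width, numeric(1)))
  cat(sprintf("maze_geometry: %d patches, %d channels\n", nrow(p), length(x$channels)))
  cat(sprintf("  patch area total %.4f m^2, channel area total %.4f m^2 (sum %.4f m^2)\n",
              parea, carea, parea + carea))
  cat(sprintf("  resource patches: %s\n",
              paste(p$id[p$resource_g > 0], collapse = ", ")))
  invisible(x)
}

#' @export
plot.maze_geometry <- function(x, ...) {
  plot(x$arena[, 1], x$arena[, 2], type = "n", asp = 1,
       xlab = "x [m]", ylab = "y [m]", ...)
  graphics::polygon(x$arena, border = "grey40")
  th <- seq(0, 2 * pi, length.out = 120)
  for (i in seq_len(nrow(x$patches))) {
    r <- x$patches$diameter[i] / 2
    graphics::polygon(x$patches$cx[i] + r * cos(th), x$patches$cy[i] + r * sin(th),
                      border = if (x$patches$resource_g[i] > 0) "darkgreen" else "grey30")
    graphics::text(x$patches$cx[i], x$patches$cy[i], x$patches$id[i])
  }
  for (ch in x$channels) graphics::polygon(ch$polygon, border = "steelblue")
  invisible(x)
}
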