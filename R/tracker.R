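# Silhouette tracking: a single dark animal on a bright NIR-backlit field.
# Frames are 8-bit grayscale matrices (values 0-255) laid out [row, col] with
# row 1 at the top of the image; stacks are [row, col, frame] arrays.

#' Acquisition configuration
#'
#' @param frame_rate Frames per second (default 25).
#' @param frame_size `c(width, height)` in pixels (default 1280 x 1024).
#' @param calibration Metres per pixel. The default maps the frame width onto
#'   the 0.70-m arena width of the bundled maze.
#' @param detection_threshold Minimum background-minus-frame intensity
#'   difference (8-bit units) for a pixel to count as animal.
#' @param blob_size_limits `c(min, max)` blob area in px².
#' @param max_link_jump Maximum plausible displacement between consecutive
#'   frames, in metres.
#' @param max_gap Longest run of missed detections bridged by interpolation.
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(frame_rate = 25, frame_size = c(1280, 1024),
                               calibration = 0.70 / frame_size[1],
                               detection_threshold = 20,
                               blob_size_limits = c(4, 5000),
                               max_link_jump = 0.02, max_gap = 5) {
  stopifnot(frame_rate > 0, calibration > 0,
            blob_size_limits[1] < blob_size_limits[2], max_gap >= 0)
  structure(list(frame_rate = frame_rate, frame_size = frame_size,
                 calibration = calibration,
                 detection_threshold = detection_threshold,
                 blob_size_limits = blob_size_limits,
                 max_link_jump = max_link_jump, max_gap = max_gap),
            class = "acquisition_config")
}

# pixel-centre <-> metre mapping (y axis up; row 1 = top of image)
px_to_m <- function(x_px, y_px, nrow_img, calibration) {
  list(x = (x_px - 0.5) * calibration,
       y = (nrow_img - y_px + 0.5) * calibration)
}
m_to_px <- function(x_m, y_m, nrow_img, calibration) {
  list(x = x_m / calibration + 0.5,
       y = nrow_img - y_m / calibration + 0.5)
}

#' Read an image stack
#'
#' Accepts a directory of PNG frames (sorted by file name; zero-padded numeric
#' names recommended) or a single multi-page TIFF. Frames are converted to
#' 8-bit grayscale.
#'
#' @param path Directory of `.png` files or a `.tif`/`.tiff` file.
#' @return Numeric array `[row, col, frame]` with values in 0–255.
#' @export
read_frames <- function(path) {
  to_gray <- function(img) {
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                            c(1, 2), mean)
    img * 255
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames found in ", path)
    frames <- lapply(files, function(f) to_gray(png::readPNG(f)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray)
  } else {
    stop("path must be a directory of PNGs or a multi-page TIFF")
  }
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("frames have inconsistent sizes")
  }
  array(unlist(frames, use.names = FALSE), dim = c(d, length(frames)))
}

#' Estimate the static background
#'
#' Per-pixel temporal median of the stack. The median is robust to the animal
#' passing through: a pixel is occupied in only a minority of frames, so the
#' recovered plate is the clean background.
#'
#' @param stack Array `[row, col, frame]` with at least 3 frames.
#' @return Background matrix `[row, col]`.
#' @export
estimate_background <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 3) stop("need an image stack of at least 3 frames")
  apply(stack, c(1, 2), stats::median)
}

#' Detect the animal in one frame
#'
#' One-sided background subtraction: pixels where `background - frame`
#' exceeds the detection threshold (the backlit animal is darker than the
#' field) are grouped into connected components; components within the blob
#' size limits are returned with intensity-weighted (sub-pixel) centroids.
#' An empty result is valid — low-contrast (translucent) animals fall below
#' the detection limit.
#'
#' @param frame,background Matrices of equal size (0–255).
#' @param config An `acquisition_config`.
#' @return Data frame `x_px`, `y_px` (image coordinates, row 1 = top),
#'   `area_px`.
#' @export
detect_animal <- function(frame, background, config) {
  if (!identical(dim(frame), dim(background))) {
    stop("frame and background sizes differ")
  }
  diffimg <- background - frame
  mask <- diffimg > config$detection_threshold
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0), area_px = numeric(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask * 1)
  labv <- as.integer(lab)
  sel <- labv > 0L
  labs <- labv[sel]
  w <- pmax(diffimg[sel], 0)
  rows <- row(frame)[sel]
  cols <- col(frame)[sel]
  area <- tabulate(labs)
  wsum <- as.numeric(rowsum(w, labs))
  cx <- as.numeric(rowsum(w * cols, labs)) / wsum
  cy <- as.numeric(rowsum(w * rows, labs)) / wsum
  keep <- area >= config$blob_size_limits[1] & area <= config$blob_size_limits[2]
  data.frame(x_px = cx[keep], y_px = cy[keep], area_px = area[keep])
}

#' Link per-frame detections into a trajectory
#'
#' Single-animal nearest-neighbour linking: each frame keeps the detection
#' nearest to the last confirmed position, rejecting implausible jumps larger
#' than `max_link_jump`; frames without an accepted detection are marked
#' undetected. Before the first detection the track is undetected. Positions
#' are converted from pixels to metres via the calibration.
#'
#' @param detections List of per-frame data frames from [detect_animal()].
#' @param config An `acquisition_config`.
#' @param nrow_img Image height in pixels (rows).
#' @param t0 Time of the first frame (s).
#' @return A `trajectory` (gaps not yet interpolated; see [fill_gaps()]).
#' @export
link_detections <- function(detections, config, nrow_img, t0 = 0) {
  n <- length(detections)
  if (n == 0 || all(vapply(detections, nrow, integer(1)) == 0)) {
    stop("no animal detected in any frame")
  }
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); det <- rep(FALSE, n)
  last <- NULL
  jump_px <- config$max_link_jump / config$calibration
  for (i in seq_len(n)) {
    d <- detections[[i]]
    if (nrow(d) == 0) next
    if (is.null(last)) {
      k <- which.max(d$area_px)   # first confirmation: the largest blob
    } else {
      dist <- sqrt((d$x_px - last[1])^2 + (d$y_px - last[2])^2)
      k <- which.min(dist)
      if (dist[k] > jump_px) next
    }
    last <- c(d$x_px[k], d$y_px[k])
    p <- px_to_m(d$x_px[k], d$y_px[k], nrow_img, config$calibration)
    x[i] <- p$x; y[i] <- p$y; det[i] <- TRUE
  }
  trajectory(t0 + (seq_len(n) - 1) / config$frame_rate, x, y,
             detected = det, interpolated = FALSE,
             frame_rate = config$frame_rate, calibration = config$calibration)
}

#' Fill short detection gaps by linear interpolation
#'
#' Runs of at most `max_gap` consecutive undetected samples flanked by
#' detections are filled linearly and flagged `interpolated`; longer runs are
#' left undetected.
#'
#' @param traj A `trajectory`.
#' @param max_gap Maximum bridgeable run length in frames.
#' @return A `trajectory`.
#' @export
fill_gaps <- function(traj, max_gap) {
  det <- traj$detected
  n <- length(det)
  out <- traj
  r <- rle(det)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (r$values[k] || r$lengths[k] > max_gap) next
    i0 <- starts[k] - 1; i1 <- ends[k] + 1
    if (i0 < 1 || i1 > n) next           # gap touches an end: cannot bridge
    idx <- starts[k]:ends[k]
    f <- (traj$t[idx] - traj$t[i0]) / (traj$t[i1] - traj$t[i0])
    out$x[idx] <- traj$x[i0] + f * (traj$x[i1] - traj$x[i0])
    out$y[idx] <- traj$y[i0] + f * (traj$y[i1] - traj$y[i0])
    out$interpolated[idx] <- TRUE
  }
  out
}

#' Track an image stack end to end
#'
#' Background estimation, per-frame detection, linking, and gap filling.
#'
#' @param stack Array `[row, col, frame]`.
#' @param config An `acquisition_config`.
#' @param t0 Time of the first frame (s).
#' @param background Optional precomputed background plate.
#' @return List `trajectory` (a `trajectory`) and `qc` (detection rate and a
#'   gap-length histogram).
#' @export
track_stack <- function(stack, config = acquisition_config(), t0 = 0,
                        background = NULL) {
  if (is.null(background)) background <- estimate_background(stack)
  n <- dim(stack)[3]
  dets <- lapply(seq_len(n), function(i) {
    detect_animal(stack[, , i], background, config)
  })
  traj <- link_detections(dets, config, nrow_img = dim(stack)[1], t0 = t0)
  rate <- mean(traj$detected)
  r <- rle(traj$detected)
  gaps <- r$lengths[!r$values]
  traj <- fill_gaps(traj, config$max_gap)
  list(trajectory = traj,
       qc = list(detection_rate = rate,
                 gap_histogram = if (length(gaps)) table(gaps) else table(integer(0))))
}
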