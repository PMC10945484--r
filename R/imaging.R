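# Synthetic droplet-pair image rendering and image-based geometry
# extraction.
#
# Coordinate convention: image origin at the top-left pixel, x = column,
# y = row, pixel centers at integer grid coordinates; pixel (i, j) has
# centre (x, y) = ((j - 1) * pixel_size, (i - 1) * pixel_size) um.
# Rendering uses a linear anti-aliased edge whose intensity passes
# through half of the disk brightness exactly on the true circle, so the
# half-level iso-contour recovers the geometry to sub-pixel accuracy.

#' Construct an image frame
#'
#' @param intensity Numeric matrix (rows x cols), finite.
#' @param pixel_size Pixel size (um/px), > 0.
#' @param timestamp Acquisition time (s).
#' @param truth Optional ground-truth [droplet_pair_state()] attribute.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(intensity, pixel_size, timestamp = 0,
                        truth = NULL) {
  if (!is.matrix(intensity) || length(intensity) == 0L ||
      any(!is.finite(intensity)))
    stop("intensity must be a non-empty finite matrix", call. = FALSE)
  stopif_not_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopif_not_scalar(timestamp, "timestamp")
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 timestamp = timestamp, truth = truth),
            class = "image_frame")
}

#' Render a droplet pair as a synthetic microscopy frame
#'
#' Draws two overlapping bright disks on a dark background with a linear
#' anti-aliased edge (one pixel wide by default).  The pair is centred in
#' the frame with the centre-centre axis horizontal, droplet 1 on the
#' left.  Ground truth is carried in the frame's `truth` field.
#'
#' @param state A [droplet_pair_state()]; its centre distance `d` must be
#'   available (it is, whenever `rc > 0`).
#' @param pixel_size Pixel size (um/px).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param edge_width Anti-aliasing edge width (px).
#' @param timestamp Frame time (s).
#' @return An `image_frame`.
#' @export
render_droplet_image <- function(state, pixel_size = 1,
                                 image_shape = c(256, 256),
                                 edge_width = 1, timestamp = 0) {
  stopifnot(inherits(state, "droplet_pair_state"))
  if (is.na(state$d))
    stop("state needs a centre distance d to be rendered", call. = FALSE)
  rows <- image_shape[1L]; cols <- image_shape[2L]
  W <- (cols - 1) * pixel_size
  H <- (rows - 1) * pixel_size
  xm <- W / 2; ym <- H / 2
  c1 <- c(xm - state$d / 2, ym)
  c2 <- c(xm + state$d / 2, ym)
  margin <- edge_width * pixel_size
  if (c1[1L] - state$R1 < -margin / 2 || c2[1L] + state$R2 > W + margin / 2 ||
      ym - max(state$R1, state$R2) < -margin / 2 ||
      ym + max(state$R1, state$R2) > H + margin / 2)
    stop("droplet pair does not fit inside the frame", call. = FALSE)

  x <- (seq_len(cols) - 1) * pixel_size
  y <- (seq_len(rows) - 1) * pixel_size
  xg <- matrix(x, nrow = rows, ncol = cols, byrow = TRUE)
  yg <- matrix(y, nrow = rows, ncol = cols)
  ew <- edge_width * pixel_size
  disk <- function(cc, R) {
    dist <- sqrt((xg - cc[1L])^2 + (yg - cc[2L])^2)
    pmin(pmax((R - dist) / ew + 0.5, 0), 1)
  }
  img <- pmax(disk(c1, state$R1), disk(c2, state$R2))
  image_frame(img, pixel_size, timestamp, truth = state)
}

# Sub-pixel iso-contour points of `img` at `level`: linear interpolation
# along horizontal and vertical pixel-neighbour pairs that straddle the
# level.  Returns a 2-column matrix of (x, y) in um.
contour_points <- function(img, pixel_size, level) {
  rows <- nrow(img); cols <- ncol(img)
  pts <- list()
  # horizontal neighbours
  a <- img[, -cols, drop = FALSE]; b <- img[, -1L, drop = FALSE]
  hit <- (a - level) * (b - level) < 0
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    fa <- a[hit]; fb <- b[hit]
    frac <- (level - fa) / (fb - fa)
    pts[[1L]] <- cbind(x = (idx[, 2L] - 1 + frac) * pixel_size,
                       y = (idx[, 1L] - 1) * pixel_size)
  }
  # vertical neighbours
  a <- img[-rows, , drop = FALSE]; b <- img[-1L, , drop = FALSE]
  hit <- (a - level) * (b - level) < 0
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    fa <- a[hit]; fb <- b[hit]
    frac <- (level - fa) / (fb - fa)
    pts[[2L]] <- cbind(x = (idx[, 2L] - 1) * pixel_size,
                       y = (idx[, 1L] - 1 + frac) * pixel_size)
  }
  do.call(rbind, pts)
}

# Kasa algebraic circle fit; returns list(center, R, rms).
kasa_circle_fit <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  sol <- stats::lm.fit(A, x^2 + y^2)$coefficients
  ctr <- sol[1:2]
  R <- sqrt(sol[3L] + sum(ctr^2))
  d <- sqrt((x - ctr[1L])^2 + (y - ctr[2L])^2)
  list(center = unname(ctr), R = unname(R),
       rms = sqrt(mean((d - R)^2)))
}

#' Fit the droplet-pair geometry in an image frame
#'
#' Extracts the half-level iso-contour of the bright region (level
#' midway between the frame minimum and maximum, hence invariant under
#' global intensity scaling), splits the contour points between the two
#' droplet arcs by alternating circle fitting and residual-based
#' reassignment, and reports least-squares circles for both droplets.
#' The contact radius follows from [contact_radius_from_centers()].
#'
#' @param frame An [image_frame()] containing exactly two overlapping or
#'   touching quasi-circular bright regions.
#' @param max_residual Detection-quality gate: maximum rms circle residual
#'   in pixels before the frame is rejected.
#' @return A [droplet_pair_state()] (droplet 1 = leftmost centre), with a
#'   `fit` attribute carrying centres (um), per-circle rms residuals (um)
#'   and point counts.
#' @export
fit_droplet_pair <- function(frame, max_residual = 1.5) {
  stopifnot(inherits(frame, "image_frame"))
  img <- frame$intensity
  lo <- min(img); hi <- max(img)
  if (hi - lo <= .Machine$double.eps)
    stop("droplet detection failed: found 0 candidate circles ",
         "(blank frame)", call. = FALSE)
  level <- (lo + hi) / 2
  pts <- contour_points(img, frame$pixel_size, level)
  if (is.null(pts) || nrow(pts) < 10L)
    stop("droplet detection failed: found 0 candidate circles ",
         "(no usable contour)", call. = FALSE)

  # split along the principal axis of the contour cloud
  ctr <- colMeans(pts)
  pc <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1L]
  proj <- (pts[, 1L] - ctr[1L]) * pc[1L] + (pts[, 2L] - ctr[2L]) * pc[2L]
  grp <- proj > stats::median(proj)

  fits <- NULL
  for (it in seq_len(25L)) {
    if (sum(grp) < 5L || sum(!grp) < 5L)
      stop("droplet detection failed: found 1 candidate circle",
           call. = FALSE)
    f1 <- kasa_circle_fit(pts[!grp, , drop = FALSE])
    f2 <- kasa_circle_fit(pts[grp, , drop = FALSE])
    r1 <- abs(sqrt((pts[, 1L] - f1$center[1L])^2 +
                     (pts[, 2L] - f1$center[2L])^2) - f1$R)
    r2 <- abs(sqrt((pts[, 1L] - f2$center[1L])^2 +
                     (pts[, 2L] - f2$center[2L])^2) - f2$R)
    grp_new <- r2 < r1
    fits <- list(f1, f2)
    if (all(grp_new == grp)) break
    grp <- grp_new
  }
  f1 <- fits[[1L]]; f2 <- fits[[2L]]
  d <- sqrt(sum((f1$center - f2$center)^2))
  if (d <= abs(f1$R - f2$R) ||
      (d < frame$pixel_size && abs(f1$R - f2$R) < frame$pixel_size))
    stop("droplet detection failed: found 1 candidate circle ",
         "(fits coincide)", call. = FALSE)
  if (max(f1$rms, f2$rms) > max_residual * frame$pixel_size)
    stop("droplet detection failed: contour is not two circles ",
         "(rms residual ", signif(max(f1$rms, f2$rms), 4), " um)",
         call. = FALSE)
  if (f1$center[1L] > f2$center[1L] ||
      (f1$center[1L] == f2$center[1L] && f1$center[2L] > f2$center[2L])) {
    tmp <- f1; f1 <- f2; f2 <- tmp
  }
  rc <- if (d >= f1$R + f2$R) 0 else contact_radius_from_centers(f1$R, f2$R, d)

  st <- droplet_pair_state(f1$R, f2$R, rc,
                           d = if (rc > 0) d else NULL)
  attr(st, "fit") <- list(centers = rbind(f1$center, f2$center),
                          residual_rms = c(f1$rms, f2$rms),
                          n_points = nrow(pts))
  st
}

#' Track a droplet pair across frames
#'
#' Fits each frame with [fit_droplet_pair()] and preserves droplet
#' identity across frames by nearest-centre matching.  Frames whose
#' centre movements are large enough to make the assignment ambiguous
#' (combined movement at least the previous centre separation) raise a
#' tracking error.
#'
#' @param frames List of [image_frame()] objects with strictly increasing
#'   timestamps, length >= 2.
#' @return A `dib_trajectory` data frame (`time_s`, `R1_um`, `R2_um`,
#'   `rc_um`).
#' @export
track_trajectory <- function(frames) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 frames", call. = FALSE)
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (is.unsorted(ts, strictly = TRUE))
    stop("frame timestamps must be strictly increasing", call. = FALSE)

  rows <- vector("list", length(frames))
  prev_centers <- NULL
  for (k in seq_along(frames)) {
    st <- fit_droplet_pair(frames[[k]])
    fit <- attr(st, "fit")
    cen <- fit$centers
    R <- c(st$R1, st$R2)
    if (!is.null(prev_centers)) {
      cost_id <- sqrt(sum((cen[1L, ] - prev_centers[1L, ])^2)) +
        sqrt(sum((cen[2L, ] - prev_centers[2L, ])^2))
      cost_sw <- sqrt(sum((cen[2L, ] - prev_centers[1L, ])^2)) +
        sqrt(sum((cen[1L, ] - prev_centers[2L, ])^2))
      if (cost_sw < cost_id) {
        cen <- cen[2:1, , drop = FALSE]
        R <- R[2:1]
        cost_id <- cost_sw
      }
      sep <- sqrt(sum((prev_centers[1L, ] - prev_centers[2L, ])^2))
      if (cost_id >= sep)
        stop("tracking ambiguity at frame ", k,
             ": centre movements (", signif(cost_id, 4),
             " um) reach the centre separation (", signif(sep, 4), " um)",
             call. = FALSE)
    }
    prev_centers <- cen
    rows[[k]] <- data.frame(time_s = ts[k], R1_um = R[1L], R2_um = R[2L],
                            rc_um = st$rc)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dib_trajectory", "data.frame")
  out
}
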