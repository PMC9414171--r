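#' @title Stage-camera misalignment calibration
#' @description A manually installed camera is rotated by a small unknown
#'   angle relative to the XY stage axes, so image displacements and stage
#'   displacements disagree and targets moved "to the centre" land off-centre.
#'   Two overlapping frames taken along a +x stage step are registered by
#'   robust translation matching (mosaic construction); the step's apparent
#'   image direction gives the misalignment angle `theta = arctan(dy/dx)`,
#'   and a 2 x 2 rotation maps image displacements to stage displacements.
#' @name stage_cal
NULL

# --- internal: robust translation registration --------------------------

fft_xcorr_peak <- function(a, b) {
  # circular cross-correlation via FFT, zero-padded to avoid wraparound;
  # returns the integer shift t maximizing sum a(x) * b(x + t)
  h <- nrow(a); w <- ncol(a)
  H <- stats::nextn(2 * h); W <- stats::nextn(2 * w)
  A <- matrix(0, H, W); B <- matrix(0, H, W)
  A[1:h, 1:w] <- a - mean(a)
  B[1:h, 1:w] <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  k <- which.max(cc)
  ky <- (k - 1) %% H; kx <- (k - 1) %/% H
  if (ky > H / 2) ky <- ky - H
  if (kx > W / 2) kx <- kx - W
  c(kx, ky)
}

harris_keypoints <- function(m, n_max = 120, margin = 12, block = 9) {
  sm <- smooth_gauss(m, 1)
  h <- nrow(sm); w <- ncol(sm)
  ix <- matrix(0, h, w); iy <- matrix(0, h, w)
  ix[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2
  iy[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2
  xx <- smooth_gauss(ix * ix, 2); yy <- smooth_gauss(iy * iy, 2)
  xy <- smooth_gauss(ix * iy, 2)
  score <- (xx * yy - xy * xy) - 0.04 * (xx + yy)^2
  # block-wise non-max suppression
  pts <- list()
  for (by in seq(margin + 1, h - margin - block, by = block)) {
    for (bx in seq(margin + 1, w - margin - block, by = block)) {
      sub <- score[by:(by + block - 1), bx:(bx + block - 1)]
      k <- which.max(sub)
      pts[[length(pts) + 1L]] <-
        c(bx + (k - 1) %/% block - 1, by + (k - 1) %% block - 1, max(sub))
    }
  }
  pts <- do.call(rbind, pts)
  pts <- pts[pts[, 3] > 0, , drop = FALSE]
  if (nrow(pts) == 0) return(pts[, 1:2, drop = FALSE])
  pts <- pts[order(pts[, 3], decreasing = TRUE), , drop = FALSE]
  pts[seq_len(min(n_max, nrow(pts))), 1:2, drop = FALSE]
}

zncc <- function(p, q) {
  p <- p - mean(p); q <- q - mean(q)
  d <- sqrt(sum(p * p) * sum(q * q))
  if (d < 1e-12) return(0)
  sum(p * q) / d
}

# SSD between a and b at integer shift t over the overlap region
overlap_ssd <- function(a, b, tx, ty) {
  h <- nrow(a); w <- ncol(a)
  ax0 <- max(0, -tx); ay0 <- max(0, -ty)
  cw <- w - abs(tx); ch <- h - abs(ty)
  if (cw < 8 || ch < 8) return(Inf)
  asub <- a[(ay0 + 1):(ay0 + ch), (ax0 + 1):(ax0 + cw)]
  bsub <- b[(ay0 + ty + 1):(ay0 + ty + ch), (ax0 + tx + 1):(ax0 + tx + cw)]
  mean((asub - bsub)^2)
}

#' Register two overlapping frames (translation model)
#'
#' Corner-like keypoints are extracted from the first frame, matched into the
#' second by normalized cross-correlation of local patches around an initial
#' FFT cross-correlation estimate, and filtered by consensus on a pure
#' translation model (RANSAC-style inlier vote); the consensus shift is
#' refined to sub-pixel precision by a parabolic fit of the overlap SSD.
#' The returned shift is the image motion of scene content from `frame_a`
#' to `frame_b`.
#'
#' @param frame_a,frame_b [gray_image] frames of identical size.
#' @param min_inliers minimal consensus size (default 3).
#' @param patch half-size of the matching patch in pixels.
#' @param search half-size of the local search window around the initial
#'   estimate.
#' @return a `mosaic_shift`: list with `dx_px`, `dy_px`, `n_inliers`,
#'   `inlier_rms_px`.
#' @export
register_pair <- function(frame_a, frame_b, min_inliers = 3, patch = 6,
                          search = 3) {
  if (!all(dim(frame_a) == dim(frame_b))) stop("frames must have equal size")
  a <- as_plain_matrix(frame_a); b <- as_plain_matrix(frame_b)
  h <- nrow(a); w <- ncol(a)
  t0 <- fft_xcorr_peak(a, b)
  kp <- harris_keypoints(a)
  if (nrow(kp) < min_inliers) {
    stop("insufficient overlap or texture: too few keypoints")
  }
  disp <- matrix(NA_real_, 0, 2)
  for (i in seq_len(nrow(kp))) {
    px <- kp[i, 1]; py <- kp[i, 2]
    if (px - patch < 0 || py - patch < 0 ||
        px + patch > w - 1 || py + patch > h - 1) next
    pa <- a[(py - patch + 1):(py + patch + 1),
            (px - patch + 1):(px + patch + 1)]
    best <- c(NA, NA); best_s <- -Inf
    for (dv in -search:search) {
      for (du in -search:search) {
        qx <- px + t0[1] + du; qy <- py + t0[2] + dv
        if (qx - patch < 0 || qy - patch < 0 ||
            qx + patch > w - 1 || qy + patch > h - 1) next
        qb <- b[(qy - patch + 1):(qy + patch + 1),
                (qx - patch + 1):(qx + patch + 1)]
        s <- zncc(pa, qb)
        if (s > best_s) { best_s <- s; best <- c(qx - px, qy - py) }
      }
    }
    if (is.finite(best_s) && best_s >= 0.6) disp <- rbind(disp, best)
  }
  if (nrow(disp) < min_inliers) {
    stop("insufficient overlap or texture: too few keypoint matches")
  }
  # consensus on the translation model: largest set within 1.5 px of a member
  votes <- vapply(seq_len(nrow(disp)), function(i) {
    sum(abs(disp[, 1] - disp[i, 1]) <= 1.5 & abs(disp[, 2] - disp[i, 2]) <= 1.5)
  }, 1L)
  c0 <- disp[which.max(votes), ]
  inl <- abs(disp[, 1] - c0[1]) <= 1.5 & abs(disp[, 2] - c0[2]) <= 1.5
  if (sum(inl) < min_inliers) {
    stop("insufficient overlap or texture: no translation consensus")
  }
  t_int <- round(c(stats::median(disp[inl, 1]), stats::median(disp[inl, 2])))
  # sub-pixel refinement: parabolic fit of the overlap SSD around t_int
  S <- matrix(Inf, 3, 3)
  for (j in -1:1) for (i in -1:1) {
    S[j + 2, i + 2] <- overlap_ssd(a, b, t_int[1] + i, t_int[2] + j)
  }
  para <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (!is.finite(den) || den <= 0) 0 else {
      d <- 0.5 * (m1 - p1) / den
      max(-0.5, min(0.5, d))
    }
  }
  dx <- t_int[1] + para(S[2, 1], S[2, 2], S[2, 3])
  dy <- t_int[2] + para(S[1, 2], S[2, 2], S[3, 2])
  rms <- sqrt(mean((disp[inl, 1] - dx)^2 + (disp[inl, 2] - dy)^2))
  structure(list(dx_px = dx, dy_px = dy, n_inliers = sum(inl),
                 inlier_rms_px = rms),
            class = "mosaic_shift")
}

#' @export
print.mosaic_shift <- function(x, ...) {
  cat(sprintf("<mosaic shift (%.3f, %.3f) px, %d inliers, RMS %.2f px>\n",
              x$dx_px, x$dy_px, x$n_inliers, x$inlier_rms_px))
  invisible(x)
}

#' Misalignment angle from a mosaic shift
#'
#' `theta = arctan(dy / dx)` for a stage step along +x: the apparent image
#' direction of the step is the stage-to-image rotation angle.
#'
#' @param shift a [register_pair] result, or any list with `dx_px`, `dy_px`.
#' @return a `stage_calibration`: list with `theta_rad` and `source_shift`.
#' @export
misalignment_angle <- function(shift) {
  if (shift$dx_px <= 0) {
    stop("dx must be positive: the calibration stage step is along +x")
  }
  structure(list(theta_rad = atan(shift$dy_px / shift$dx_px),
                 source_shift = shift),
            class = "stage_calibration")
}

#' Build a calibration from a known angle
#'
#' @param theta_rad rotation angle in radians, in (-pi, pi]; mosaic-estimated
#'   angles always lie in (-pi/2, pi/2).
#' @return a `stage_calibration`.
#' @export
stage_calibration <- function(theta_rad) {
  stopifnot(is.finite(theta_rad), theta_rad > -pi, theta_rad <= pi)
  structure(list(theta_rad = theta_rad, source_shift = NULL),
            class = "stage_calibration")
}

#' @export
print.stage_calibration <- function(x, ...) {
  cat(sprintf("<stage calibration: theta = %.4f deg>\n",
              x$theta_rad * 180 / pi))
  invisible(x)
}

#' Rotate an image displacement into stage coordinates
#'
#' Applies the misalignment rotation `[[cos, -sin], [sin, cos]]` (positive
#' theta counterclockwise in the y-down raster frame) to a displacement:
#' the homogeneous-form mapping between image and stage displacement.
#'
#' @param displacement_img numeric `c(dx, dy)` image displacement.
#' @param cal a `stage_calibration`.
#' @return numeric `c(dx, dy)` stage displacement.
#' @export
image_to_stage <- function(displacement_img, cal) {
  th <- cal$theta_rad
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  as.numeric(R %*% as.numeric(displacement_img))
}

#' Invert a calibration
#'
#' The mosaic measures the stage-to-image rotation; commanding the stage to
#' realize a desired image displacement uses the inverse rotation. This
#' returns the calibration with the angle negated.
#'
#' @param cal a `stage_calibration`.
#' @return the inverted `stage_calibration`.
#' @export
invert_calibration <- function(cal) {
  structure(list(theta_rad = -cal$theta_rad, source_shift = cal$source_shift),
            class = "stage_calibration")
}

#' Estimate calibration from two frames
#'
#' Convenience wrapper: [register_pair] then [misalignment_angle].
#'
#' @param frame_a,frame_b overlapping [gray_image] frames along a +x stage
#'   step.
#' @param ... passed to [register_pair].
#' @return a `stage_calibration`.
#' @export
estimate_calibration <- function(frame_a, frame_b, ...) {
  misalignment_angle(register_pair(frame_a, frame_b, ...))
}
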