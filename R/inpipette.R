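#' @title In-pipette oocyte tracking and the stop-flow guard
#' @description Once aspirated, the oocyte travels down the pipette lumen
#'   with the medium; if it passes a left limit position it is about to be
#'   lost in the tubing, so the pump must stop immediately. The lumen is
#'   located from the two near-horizontal dark wall bands via a Hough line
#'   transform; circle detection restricted to the band between the walls
#'   tracks the oocyte position each frame.
#' @name inpipette
NULL

# Hough transform for near-horizontal lines on a set of edge pixels.
# Parameterization rho = y cos(phi) - x sin(phi); for |phi| small, the line
# is y = tan(phi) x + rho / cos(phi). Returns c(phi_deg, rho) of the peak.
hough_line <- function(xs, ys, angle_tol_deg = 5, angle_step = 0.25,
                       rho_step = 1) {
  phis <- seq(-angle_tol_deg, angle_tol_deg, by = angle_step) * pi / 180
  best <- NULL; best_votes <- -1L
  for (phi in phis) {
    rho <- ys * cos(phi) - xs * sin(phi)
    tab <- table(round(rho / rho_step))
    k <- which.max(tab)
    if (tab[k] > best_votes) {
      best_votes <- as.integer(tab[k])
      best <- c(phi, as.numeric(names(tab)[k]) * rho_step)
    }
  }
  list(phi = best[1], rho = best[2], votes = best_votes)
}

# least-squares refinement of y = m x + c on pixels near the Hough line
refine_line <- function(xs, ys, phi, rho, band = 1.5) {
  d <- ys * cos(phi) - xs * sin(phi) - rho
  keep <- abs(d) <= band
  if (sum(keep) < 2) return(c(m = tan(phi), c = rho / cos(phi)))
  fit <- stats::lm.fit(cbind(1, xs[keep]), ys[keep])
  c(m = unname(fit$coefficients[2]), c = unname(fit$coefficients[1]))
}

line_y_at <- function(line, x) line["m"] * x + line["c"]

#' Locate the pipette lumen between the wall lines
#'
#' The smoothed frame is thresholded to the dark wall bands; the inner edge
#' pixels of the two wall components are each fitted by a Hough line
#' transform restricted to near-horizontal angles (then refined by least
#' squares). The ROI is the band strictly between the two lines, from the
#' left image edge to the rightmost wall column (the tip).
#'
#' @param image a [gray_image] showing both wall bands.
#' @param angle_tol_deg angular tolerance around horizontal (default 5).
#' @param blur_sigma smoothing sigma.
#' @param min_area_px2 minimal wall component area.
#' @param margin_px rows excluded below/above the wall lines inside the ROI.
#' @return a `lumen_roi`: list with `top_line`, `bottom_line` (named vectors
#'   `m`, `c` of `y = m x + c`), `tip_x_px`, and `roi_rect` `c(x, y, w, h)`.
#' @export
locate_lumen <- function(image, angle_tol_deg = 5, blur_sigma = 1.5,
                         min_area_px2 = 200, margin_px = 3) {
  m <- as_plain_matrix(image)
  sm <- smooth_gauss(m, blur_sigma)
  mask <- wall_mask(sm)
  if (!any(mask) || all(mask)) stop("no lumen: wall bands not found")
  mask <- morph_open_square(mask, 3L, 1L)
  labels <- label_components(mask)
  st <- component_stats(labels)
  st <- st[st$area >= min_area_px2, , drop = FALSE]
  if (nrow(st) >= 2) {
    aspect <- (st$xmax - st$xmin + 1) / (st$ymax - st$ymin + 1)
    st2 <- st[aspect >= 2, , drop = FALSE]
    if (nrow(st2) >= 2) st <- st2
  }
  if (nrow(st) < 2) stop("no lumen: fewer than two wall bands detected")
  st <- st[order(st$area, decreasing = TRUE)[1:2], ]
  st <- st[order(st$cy), ]
  fit_inner <- function(id, side) {
    bnd <- component_boundary(labels, id)
    # inner edge: for the top wall its lowest pixels per column, for the
    # bottom wall its highest pixels per column
    f <- if (side == "top") tapply(bnd$y, bnd$x, max)
         else tapply(bnd$y, bnd$x, min)
    xs <- as.numeric(names(f)); ys <- as.numeric(f)
    hl <- hough_line(xs, ys, angle_tol_deg = angle_tol_deg)
    refine_line(xs, ys, hl$phi, hl$rho)
  }
  top <- fit_inner(st$id[1], "top")
  bot <- fit_inner(st$id[2], "bottom")
  w <- ncol(m); h <- nrow(m)
  y_t <- line_y_at(top, c(0, w - 1)); y_b <- line_y_at(bot, c(0, w - 1))
  if (any(y_t >= y_b)) stop("malformed walls: lines cross inside the image")
  tip_x <- max(st$xmax)
  y0 <- ceiling(max(y_t) + margin_px)
  y1 <- floor(min(y_b) - margin_px)
  if (y1 <= y0) stop("malformed walls: no interior band between the lines")
  roi <- c(0, y0, min(w, tip_x + 1), y1 - y0 + 1)
  structure(list(top_line = top, bottom_line = bot, tip_x_px = tip_x,
                 roi_rect = roi),
            class = "lumen_roi")
}

#' @export
print.lumen_roi <- function(x, ...) {
  cat(sprintf("<lumen: top y=%.2f%+.4fx, bottom y=%.2f%+.4fx, tip x=%d, roi [%d %d %d %d]>\n",
              x$top_line["c"], x$top_line["m"], x$bottom_line["c"],
              x$bottom_line["m"], x$tip_x_px, x$roi_rect[1], x$roi_rect[2],
              x$roi_rect[3], x$roi_rect[4]))
  invisible(x)
}

#' Default left limit position
#'
#' 40% of the lumen length from the tip: `tip_x - 0.4 tip_x`.
#'
#' @param lumen a `lumen_roi`.
#' @param fraction fraction of the lumen length measured from the tip.
#' @return x position in pixels.
#' @export
default_left_limit <- function(lumen, fraction = 0.4) {
  lumen$tip_x_px * (1 - fraction)
}

#' Track the oocyte inside the lumen
#'
#' Circle detection (the oocyte segmentation pipeline) restricted to the
#' lumen ROI; the oocyte position is the leftmost detected oocyte-sized
#' centre. The stop-flow signal is raised exactly when an oocyte is present
#' and its centre lies left of the limit.
#'
#' @param image a [gray_image].
#' @param lumen a `lumen_roi` from [locate_lumen].
#' @param left_limit_px stop-flow limit x position (default:
#'   [default_left_limit]).
#' @param oocyte_radius_um minimal oocyte radius (um) for a detection to
#'   count as the oocyte.
#' @param ... passed to [segment_cells].
#' @return a `track_state`: list with `oocyte_x_px` (`NA` when absent),
#'   `left_limit_px`, `stop_flow`, `detections` (contour data.frame in
#'   full-image coordinates).
#' @export
track_lumen <- function(image, lumen, left_limit_px = default_left_limit(lumen),
                        oocyte_radius_um = 25, ...) {
  roi <- lumen$roi_rect
  sub <- crop_roi(image, roi)
  det <- segment_cells(sub, ...)
  ps <- pixel_size_um(image)
  if (nrow(det)) {
    det$cx_px <- det$cx_px + roi[1]
    det$cy_px <- det$cy_px + roi[2]
    det <- det[det$r_px * ps >= oocyte_radius_um, , drop = FALSE]
  }
  if (nrow(det)) {
    x <- min(det$cx_px)
    structure(list(oocyte_x_px = x, left_limit_px = left_limit_px,
                   stop_flow = x < left_limit_px, detections = det),
              class = "track_state")
  } else {
    structure(list(oocyte_x_px = NA_real_, left_limit_px = left_limit_px,
                   stop_flow = FALSE, detections = det),
              class = "track_state")
  }
}

#' @export
print.track_state <- function(x, ...) {
  cat(sprintf("<track: oocyte %s, limit %.1f px, stop_flow=%s>\n",
              if (is.na(x$oocyte_x_px)) "absent"
              else sprintf("at x=%.1f px", x$oocyte_x_px),
              x$left_limit_px, x$stop_flow))
  invisible(x)
}

#' Simulate an in-pipette aspiration frame sequence
#'
#' Renders a pipette with an oocyte inside the lumen drifting leftward at a
#' constant speed — the situation the stop-flow guard monitors. Ground
#' truth records the true oocyte centre per frame.
#'
#' @param n_frames number of frames.
#' @param drift_px_per_frame leftward drift per frame.
#' @param entry_x_px oocyte centre x in frame 1.
#' @param tip_x_px,tip_y_px pipette tip position.
#' @param width_px,height_px frame size.
#' @param oocyte_radius_um oocyte radius (um).
#' @param inner_diameter_um lumen diameter (um).
#' @param noise_sd additive noise sd.
#' @param seed RNG seed.
#' @param pixel_size_um micrometres per pixel.
#' @return list with `frames` (list of [gray_image]), `truth` (data.frame
#'   `frame`, `x_px` of true centres), and the scene parameters.
#' @export
aspiration_sequence <- function(n_frames = 20, drift_px_per_frame = 5,
                                entry_x_px = 262.5, tip_x_px = 300,
                                tip_y_px = 100, width_px = 360,
                                height_px = 200, oocyte_radius_um = 40,
                                inner_diameter_um = 125, noise_sd = 3,
                                seed = 1L, pixel_size_um = 1.0) {
  ps <- pixel_size_um
  xs <- entry_x_px - drift_px_per_frame * (seq_len(n_frames) - 1)
  frames <- lapply(seq_len(n_frames), function(k) {
    render_aspiration_frame(xs[k], tip_x_px, tip_y_px, width_px, height_px,
                            oocyte_radius_um, inner_diameter_um, noise_sd,
                            seed + k, ps)
  })
  list(frames = frames,
       truth = data.frame(frame = seq_len(n_frames), x_px = xs),
       tip_x_px = tip_x_px, tip_y_px = tip_y_px,
       drift_px_per_frame = drift_px_per_frame)
}

# single in-pipette frame: oocyte at x inside the lumen; shared by
# aspiration_sequence and the session simulator (lazy rendering)
render_aspiration_frame <- function(x_px, tip_x_px, tip_y_px, width_px,
                                    height_px, oocyte_radius_um,
                                    inner_diameter_um, noise_sd, seed, ps) {
  sp <- scene_spec(width_px, height_px, pixel_size_um = ps,
                   background_level = 60, noise_sd = noise_sd,
                   oocytes = list(oocyte_spec(
                     center_um = c(x_px * ps, tip_y_px * ps),
                     radius_um = oocyte_radius_um,
                     zona_thickness_um = 0, n_holes = 0)),
                   pipette = pipette_spec(
                     tip_um = c(tip_x_px * ps, tip_y_px * ps),
                     inner_diameter_um = inner_diameter_um),
                   rng_seed = seed)
  render_scene(sp, .clip = TRUE)$image
}

#' Run the stop-flow guard over a frame sequence
#'
#' Processes frames in order and stops at the first raised stop-flow signal,
#' as the online pump guard would.
#'
#' @param frames list of [gray_image] frames.
#' @param lumen a `lumen_roi`.
#' @param left_limit_px stop-flow limit.
#' @param ... passed to [track_lumen].
#' @return list with `fired` (logical), `frame_index` (first stop frame or
#'   `NA`), `states` (list of `track_state` up to and including the stop).
#' @export
run_stop_flow_guard <- function(frames, lumen,
                                left_limit_px = default_left_limit(lumen),
                                ...) {
  states <- list()
  for (k in seq_along(frames)) {
    st <- track_lumen(frames[[k]], lumen, left_limit_px = left_limit_px, ...)
    states[[k]] <- st
    if (st$stop_flow) {
      return(list(fired = TRUE, frame_index = k, states = states))
    }
  }
  list(fired = FALSE, frame_index = NA_integer_, states = states)
}
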