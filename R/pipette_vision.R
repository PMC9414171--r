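#' @title Micropipette tip identification and contact detection
#' @description Locates the micropipette tip as the midpoint of the rightmost
#'   points of the two dark wall edges (Gaussian smoothing, thresholding,
#'   morphological opening, contour detection), and declares substrate
#'   contact from the lateral tip displacement across a descent image
#'   sequence.
#' @name pipette_vision
NULL

#' Default region of interest for tip detection
#'
#' A 230 x 200 pixel window centred in the frame (clipped to the frame),
#' the working ROI size used around an approximately known tip position.
#'
#' @param image a [gray_image].
#' @return rectangle `c(x, y, w, h)` in 0-based pixels.
#' @export
default_tip_roi <- function(image) {
  w <- min(230L, ncol(image)); h <- min(200L, nrow(image))
  c(floor((ncol(image) - w) / 2), floor((nrow(image) - h) / 2), w, h)
}

#' Detect the micropipette tip
#'
#' Pipeline: Gaussian low-pass filter -> threshold (Otsu by default; the
#' pipette walls are the dark class) -> morphological erosion then dilation
#' with a 3 x 3 square element to remove small objects -> connected-component
#' contours of the top and bottom wall edges -> point A = rightmost point of
#' the top edge, point B = rightmost point of the bottom edge, tip = midpoint
#' of A and B.
#'
#' @param image a [gray_image].
#' @param roi optional rectangle `c(x, y, w, h)`; `NULL` processes the whole
#'   frame (see [default_tip_roi] for the windowed default).
#' @param blur_sigma Gaussian sigma in pixels.
#' @param threshold fixed binarization level in `[0, 255]`, or `NULL` for Otsu.
#' @param min_area_px2 wall components smaller than this are discarded.
#' @param min_aspect wall components must be at least this wide relative to
#'   their height (pipette walls are elongated).
#' @param max_tip_gap_px maximal allowed difference between the x coordinates
#'   of A and B before the detection is declared malformed.
#' @return a `pipette_tip_fix`: list with `top_edge`, `bottom_edge`
#'   (data.frames of x, y), `point_A`, `point_B`, `tip_px` — all in full-image
#'   0-based pixel coordinates.
#' @export
detect_tip <- function(image, roi = NULL, blur_sigma = 1.5, threshold = NULL,
                       min_area_px2 = 60, min_aspect = 2,
                       max_tip_gap_px = 20) {
  work <- if (is.null(roi)) image else crop_roi(image, roi)
  off <- if (is.null(roi)) c(0, 0) else roi[1:2]
  m <- as_plain_matrix(work)
  sm <- smooth_gauss(m, blur_sigma)
  # walls are darker than background; two-stage Otsu isolates the dark class
  # even when bright cells dominate the histogram
  mask <- if (is.null(threshold)) wall_mask(sm) else sm < threshold
  if (!any(mask) || all(mask)) stop("no pipette found in the image")
  mask <- morph_open_square(mask, 3L, 1L)
  labels <- label_components(mask)
  st <- component_stats(labels)
  st <- st[st$area >= min_area_px2, , drop = FALSE]
  if (nrow(st)) {
    aspect <- (st$xmax - st$xmin + 1) / (st$ymax - st$ymin + 1)
    st <- st[aspect >= min_aspect, , drop = FALSE]
  }
  if (nrow(st) < 2) stop("no pipette found in the image (need two wall edges)")
  st <- st[order(st$area, decreasing = TRUE)[1:2], ]
  st <- st[order(st$cy), ]         # top wall first
  top <- component_boundary(labels, st$id[1])
  bot <- component_boundary(labels, st$id[2])
  rightmost <- function(edge) {
    xm <- max(edge$x)
    c(xm, mean(edge$y[edge$x == xm]))
  }
  A <- rightmost(top); B <- rightmost(bot)
  if (A[2] > B[2]) stop("malformed pipette: top edge below bottom edge")
  if (abs(A[1] - B[1]) > max_tip_gap_px) {
    stop(sprintf("malformed pipette: rightmost wall points %d px apart in x (max %d)",
                 round(abs(A[1] - B[1])), round(max_tip_gap_px)))
  }
  shift <- function(e) data.frame(x = e$x + off[1], y = e$y + off[2])
  A <- A + off; B <- B + off
  structure(list(top_edge = shift(top), bottom_edge = shift(bot),
                 point_A = A, point_B = B,
                 tip_px = (A + B) / 2),
            class = "pipette_tip_fix")
}

#' @export
print.pipette_tip_fix <- function(x, ...) {
  cat(sprintf("<pipette tip at (%.1f, %.1f) px; A=(%.0f, %.1f), B=(%.0f, %.1f)>\n",
              x$tip_px[1], x$tip_px[2], x$point_A[1], x$point_A[2],
              x$point_B[1], x$point_B[2]))
  invisible(x)
}

#' Detect substrate contact from a descent image sequence
#'
#' Tracks the tip across frames and declares contact at the first frame whose
#' tip displacement from the frame-1 position exceeds `threshold_px` — the
#' lateral slip/deflection a descending pipette shows on touching the dish
#' substrate, against an otherwise unchanged background.
#'
#' @param frames list of [gray_image] frames (at least 2), in descent order.
#' @param roi optional rectangle passed to [detect_tip].
#' @param threshold_px displacement threshold in pixels (default 3).
#' @param ... further arguments passed to [detect_tip].
#' @return a `contact_event`: list with `contact` (logical), `frame_index`
#'   (1-based first contact frame, `NA` when no contact), `tip_track`
#'   (n x 2 matrix of tip positions), `displacement_px` (displacement at the
#'   contact frame, or the maximum observed when there is no contact).
#' @export
detect_contact <- function(frames, roi = NULL, threshold_px = 3, ...) {
  if (length(frames) < 2) stop("at least 2 frames are required")
  track <- matrix(NA_real_, length(frames), 2)
  for (k in seq_along(frames)) {
    fix <- tryCatch(detect_tip(frames[[k]], roi = roi, ...),
                    error = function(e) NULL)
    if (is.null(fix)) {
      if (k == 1) stop("tip not detectable in frame 1")
      stop(sprintf("tip lost in frame %d", k))
    }
    track[k, ] <- fix$tip_px
  }
  disp <- sqrt((track[, 1] - track[1, 1])^2 + (track[, 2] - track[1, 2])^2)
  hit <- which(disp > threshold_px)
  if (length(hit)) {
    structure(list(contact = TRUE, frame_index = hit[1], tip_track = track,
                   displacement_px = disp[hit[1]]),
              class = "contact_event")
  } else {
    structure(list(contact = FALSE, frame_index = NA_integer_,
                   tip_track = track, displacement_px = max(disp)),
              class = "contact_event")
  }
}

#' @export
print.contact_event <- function(x, ...) {
  if (x$contact) {
    cat(sprintf("<contact at frame %d, displacement %.2f px>\n",
                x$frame_index, x$displacement_px))
  } else {
    cat(sprintf("<no contact; max displacement %.2f px over %d frames>\n",
                x$displacement_px, nrow(x$tip_track)))
  }
  invisible(x)
}
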