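#' @title Oocyte and cumulus cell recognition
#' @description Segments bright circular cells from a grayscale frame
#'   (Gaussian smoothing, Otsu thresholding, morphological closing, hole
#'   filling, contour extraction, least-squares circle fitting), separates
#'   oocytes from cumulus cells by size, applies the zona-pellucida
#'   attachment rule `d <= R + r + s`, and computes the combined
#'   oocyte-plus-cumulus mass from sphere volumes.
#' @name cell_vision
NULL

#' Least-squares (Kåsa) circle fit
#'
#' Algebraic fit minimizing `sum((x^2 + y^2 + D x + E y + F)^2)`, the
#' linearization of the radial error. Exact on noiseless circles; for three
#' points it returns the circumcircle.
#'
#' @param points matrix or data.frame with columns x, y (at least 3 points,
#'   not collinear).
#' @return a `circle_contour`: list with `center_px` (x, y), `radius_px`,
#'   `fit_residual` (RMS of radial distances minus the radius), `n_points`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fit_circle(cbind(10 + 5 * cos(th), 10 + 5 * sin(th)))
#' @export
fit_circle <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) < 2) stop("points must have x and y columns")
  p <- p[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  n <- nrow(p)
  if (n < 3) stop("degenerate input: at least 3 points are required")
  x <- p[, 1]; y <- p[, 2]
  X <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  XtX <- crossprod(X)
  # collinear points make the normal matrix singular
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10) {
    stop("degenerate input: points are collinear within tolerance")
  }
  beta <- solve(XtX, crossprod(X, rhs))
  D <- beta[1]; E <- beta[2]; FF <- beta[3]
  cx <- -D / 2; cy <- -E / 2
  r2 <- cx^2 + cy^2 - FF
  if (r2 <= 0) stop("degenerate input: no real circle fits these points")
  r <- sqrt(r2)
  resid <- sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - r)^2))
  structure(list(center_px = c(cx, cy), radius_px = r,
                 fit_residual = resid, n_points = n),
            class = "circle_contour")
}

#' @export
print.circle_contour <- function(x, ...) {
  cat(sprintf("<circle: center (%.2f, %.2f) px, radius %.2f px, RMS %.3f px, %d pts>\n",
              x$center_px[1], x$center_px[2], x$radius_px, x$fit_residual,
              x$n_points))
  invisible(x)
}

#' Segment circular cells in a frame
#'
#' Pipeline: Gaussian low-pass -> Otsu threshold (bright foreground) ->
#' morphological closing -> hole filling -> contour extraction per connected
#' component -> Kåsa circle fit. With `fill_holes = FALSE` the interior holes
#' survive thresholding and their boundaries are returned as additional
#' contours — the failure mode the filling step exists to prevent.
#'
#' Fitted radii are increased by half a pixel to refer the boundary-pixel
#' centres back to the intensity edge.
#'
#' @param image a [gray_image].
#' @param min_area_px2 components (and holes) smaller than this are dropped.
#' @param blur_sigma Gaussian smoothing sigma in pixels.
#' @param close_radius_px disc radius of the morphological closing.
#' @param fill_holes fill interior holes before contour extraction
#'   (default `TRUE`).
#' @return data.frame with one row per contour: `cx_px`, `cy_px`, `r_px`,
#'   `area_px2`, `fit_residual`, `is_hole`. Empty on a blank image.
#' @export
segment_cells <- function(image, min_area_px2 = 40, blur_sigma = 1.5,
                          close_radius_px = 2, fill_holes = TRUE) {
  m <- as_plain_matrix(image)
  empty <- data.frame(cx_px = numeric(), cy_px = numeric(), r_px = numeric(),
                      area_px2 = numeric(), fit_residual = numeric(),
                      is_hole = logical())
  if (max(m) - min(m) < 1e-8) return(empty)
  sm <- smooth_gauss(m, blur_sigma)
  mask <- sm > otsu_level(sm)
  if (!any(mask) || all(mask)) return(empty)
  mask <- morph_close(mask, close_radius_px)
  filled <- fill_mask_holes(mask)
  work <- if (fill_holes) filled else mask
  labels <- label_components(work)
  st <- component_stats(labels)
  bnds <- component_boundaries(labels)
  rows <- list()
  for (i in seq_len(nrow(st))) {
    if (st$area[i] < min_area_px2) next
    bnd <- bnds[[st$id[i]]]
    fit <- tryCatch(fit_circle(bnd), error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <-
      data.frame(cx_px = fit$center_px[1], cy_px = fit$center_px[2],
                 r_px = fit$radius_px + 0.5, area_px2 = st$area[i],
                 fit_residual = fit$fit_residual, is_hole = FALSE)
  }
  if (!fill_holes) {
    holes <- filled & !mask
    hl <- label_components(holes)
    hst <- component_stats(hl)
    hbnds <- component_boundaries(hl)
    for (i in seq_len(nrow(hst))) {
      if (hst$area[i] < min_area_px2) next
      bnd <- hbnds[[hst$id[i]]]
      fit <- tryCatch(fit_circle(bnd), error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <-
        data.frame(cx_px = fit$center_px[1], cy_px = fit$center_px[2],
                   r_px = fit$radius_px, area_px2 = hst$area[i],
                   fit_residual = fit$fit_residual, is_hole = TRUE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Classify contours into oocytes and cumulus cells
#'
#' Contours with fitted radius at or above `oocyte_radius_um` are oocytes,
#' smaller ones cumulus. Each cumulus is assigned to the nearest oocyte for
#' which the zona-pellucida rule `d <= R + r + s` holds (with a tolerance of
#' one pixel to absorb rasterization error); ties go to the smaller centre
#' distance, then to the lower oocyte index. Cumulus satisfying the rule for
#' no oocyte are reported as dispersed and are never promoted to oocytes.
#'
#' @param contours data.frame from [segment_cells].
#' @param pixel_size_um micrometres per pixel.
#' @param s_um zona pellucida thickness in micrometres (default 8).
#' Contours whose circle-fit residual exceeds `max_residual_px` are not
#' circles (touching debris clumps, fragments) and are returned separately
#' as rejects rather than being forced into either class.
#'
#' @param oocyte_radius_um size threshold separating oocytes from cumulus
#'   (default 25 um, between typical cumulus ~10 um and oocyte ~40 um radii).
#' @param tol_um attachment tolerance; defaults to one pixel's worth of um.
#' @param max_residual_px circularity gate: maximal RMS circle-fit residual
#'   for a contour to be classified at all.
#' @return a `cell_detections` list: `oocytes` — list of per-oocyte records
#'   (`contour`, `R_um`, `cumulus` data.frame with `r_um`, `d_um`,
#'   `attached`); `dispersed` — data.frame of unassigned cumulus;
#'   `rejected` — non-circular contours; plus the parameters used.
#' @export
classify_cells <- function(contours, pixel_size_um = 1.0, s_um = 8,
                           oocyte_radius_um = 25,
                           tol_um = pixel_size_um,
                           max_residual_px = 3) {
  ps <- pixel_size_um
  ct <- contours[!contours$is_hole, , drop = FALSE]
  rejected <- ct[ct$fit_residual > max_residual_px, , drop = FALSE]
  ct <- ct[ct$fit_residual <= max_residual_px, , drop = FALSE]
  is_oo <- ct$r_px * ps >= oocyte_radius_um
  oo <- ct[is_oo, , drop = FALSE]
  cu <- ct[!is_oo, , drop = FALSE]
  oo_list <- lapply(seq_len(nrow(oo)), function(i) {
    list(contour = oo[i, ], R_um = oo$r_px[i] * ps,
         cumulus = data.frame(cx_px = numeric(), cy_px = numeric(),
                              r_px = numeric(), r_um = numeric(),
                              d_um = numeric(), attached = logical()))
  })
  dispersed <- cu[0, , drop = FALSE]
  for (j in seq_len(nrow(cu))) {
    r_um <- cu$r_px[j] * ps
    best <- NA_integer_; best_d <- Inf
    for (i in seq_len(nrow(oo))) {
      d_um <- sqrt((cu$cx_px[j] - oo$cx_px[i])^2 +
                   (cu$cy_px[j] - oo$cy_px[i])^2) * ps
      if (d_um <= oo$r_px[i] * ps + r_um + s_um + tol_um &&
          d_um < best_d) {
        best <- i; best_d <- d_um
      }
    }
    if (is.na(best)) {
      dispersed <- rbind(dispersed, cu[j, , drop = FALSE])
    } else {
      rec <- cbind(cu[j, c("cx_px", "cy_px", "r_px")],
                   data.frame(r_um = r_um, d_um = best_d, attached = TRUE))
      oo_list[[best]]$cumulus <- rbind(oo_list[[best]]$cumulus, rec)
    }
  }
  structure(list(oocytes = oo_list, dispersed = dispersed,
                 rejected = rejected, pixel_size_um = ps, s_um = s_um,
                 oocyte_radius_um = oocyte_radius_um, tol_um = tol_um,
                 max_residual_px = max_residual_px),
            class = "cell_detections")
}

#' @export
print.cell_detections <- function(x, ...) {
  cat(sprintf("<cell detections: %d oocyte(s), %d attached cumulus, %d dispersed>\n",
              length(x$oocytes),
              sum(vapply(x$oocytes, function(o) nrow(o$cumulus), 1L)),
              nrow(x$dispersed)))
  invisible(x)
}

#' Combined oocyte and cumulus mass
#'
#' `M + m = (4/3) pi rho0 (R^3 + sum r^3)` from sphere volumes, with radii in
#' micrometres converted to metres. The single-radius form is recovered for
#' one cumulus cell; `r_mode = "effective"` instead treats the mean cumulus
#' radius as one effective cell.
#'
#' @param R_um oocyte radius in micrometres (>= 0).
#' @param r_um_list numeric vector of cumulus radii in micrometres (may be
#'   empty).
#' @param rho0_kg_m3 cell density in kg/m^3 (> 0), default 1050.
#' @param r_mode `"sum"` (default) adds every cumulus volume; `"effective"`
#'   uses the cube of the mean radius.
#' @return a `cell_mass` list with `combined_mass_kg` and `rho0_kg_m3`.
#' @examples
#' combined_mass(40, numeric(), 1000)  # ~2.68e-10 kg
#' @export
combined_mass <- function(R_um, r_um_list = numeric(), rho0_kg_m3 = 1050,
                          r_mode = c("sum", "effective")) {
  r_mode <- match.arg(r_mode)
  if (R_um < 0 || any(r_um_list < 0)) stop("radii must be non-negative")
  if (rho0_kg_m3 <= 0) stop("rho0 must be positive")
  r3 <- if (length(r_um_list) == 0) 0
        else if (r_mode == "sum") sum((r_um_list * 1e-6)^3)
        else (mean(r_um_list) * 1e-6)^3
  m <- (4 / 3) * pi * rho0_kg_m3 * ((R_um * 1e-6)^3 + r3)
  structure(list(combined_mass_kg = m, rho0_kg_m3 = rho0_kg_m3),
            class = "cell_mass")
}
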