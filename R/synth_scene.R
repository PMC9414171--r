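#' @title Synthetic microscopy scene generation
#' @description Renders bright-field-like scenes of oocytes, cumulus cells and
#'   a micropipette with exact ground truth, so every vision routine in the
#'   package can be exercised against known geometry. Cells are rendered
#'   brighter than the background and pipette walls darker (one fixed polarity
#'   throughout the package); edges are anti-aliased over one pixel so circle
#'   centres and radii are meaningful at sub-pixel resolution.
#' @name synth_scene
NULL

# run code under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Oocyte specification for scene rendering
#'
#' @param center_um centre `c(x, y)` in micrometres.
#' @param radius_um oocyte radius R in micrometres (> 0).
#' @param zona_thickness_um zona pellucida thickness s in micrometres
#'   (default 8, the textbook mouse value).
#' @param n_holes number of darker interior blobs, emulating the intensity
#'   variation of the ooplasm that fragments naive thresholding.
#' @param cumulus list of `list(center_um = c(x, y), radius_um = r)` cumulus
#'   cells attached to (or near) this oocyte; radii must be positive and
#'   smaller than the oocyte radius.
#' @return an `oocyte_spec` list.
#' @export
oocyte_spec <- function(center_um, radius_um, zona_thickness_um = 8,
                        n_holes = 0, cumulus = list()) {
  stopifnot(length(center_um) == 2L, radius_um > 0, zona_thickness_um >= 0,
            n_holes >= 0)
  for (c_ in cumulus) {
    stopifnot(length(c_$center_um) == 2L)
    if (!(c_$radius_um > 0 && c_$radius_um < radius_um)) {
      stop("cumulus radii must be positive and smaller than the oocyte radius")
    }
  }
  structure(list(center_um = as.numeric(center_um),
                 radius_um = radius_um,
                 zona_thickness_um = zona_thickness_um,
                 n_holes = as.integer(n_holes),
                 cumulus = cumulus),
            class = "oocyte_spec")
}

#' Micropipette specification for scene rendering
#'
#' The pipette is horizontal with the tip pointing toward +x; the two wall
#' bands converge at the tip, which sits on the lumen axis at the rightmost
#' wall column (the geometry the tip detector assumes).
#'
#' @param tip_um tip position `c(x, y)` in micrometres (lumen axis at the
#'   rightmost wall column).
#' @param inner_diameter_um lumen diameter in micrometres (default 125, a
#'   standard denudation pipette bore).
#' @param wall_thickness_um wall band thickness at the tip, micrometres.
#' @param taper_angle_deg outer-wall taper: walls thicken at this angle going
#'   away from the tip.
#' @return a `pipette_spec` list.
#' @export
pipette_spec <- function(tip_um, inner_diameter_um = 125,
                         wall_thickness_um = 12, taper_angle_deg = 2) {
  stopifnot(length(tip_um) == 2L, inner_diameter_um > 0,
            wall_thickness_um > 0, taper_angle_deg >= 0)
  structure(list(tip_um = as.numeric(tip_um),
                 inner_diameter_um = inner_diameter_um,
                 wall_thickness_um = wall_thickness_um,
                 taper_angle_deg = taper_angle_deg),
            class = "pipette_spec")
}

#' Scene specification
#'
#' @param width_px,height_px image size in pixels (> 0).
#' @param pixel_size_um micrometres per pixel (default 1, so pixel and
#'   micrometre coordinates coincide).
#' @param background_level background intensity in `[0, 255]`.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (clipped to `[0, 255]` after addition).
#' @param oocytes list of [oocyte_spec] objects.
#' @param dispersed_cumulus list of `list(center_um, radius_um)` free cumulus
#'   cells not associated with any oocyte (detached debris).
#' @param pipette optional [pipette_spec].
#' @param rng_seed integer seed; rendering is bit-reproducible given the seed.
#' @param noise_seed separate seed for the noise field (defaults to
#'   `rng_seed`); frame pairs use it to redraw the sensor noise while the
#'   scene content stays put.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(width_px, height_px, pixel_size_um = 1.0,
                       background_level = 60, noise_sd = 0,
                       oocytes = list(), dispersed_cumulus = list(),
                       pipette = NULL, rng_seed = 1L, noise_seed = rng_seed) {
  stopifnot(width_px > 0, height_px > 0, pixel_size_um > 0,
            background_level >= 0, background_level <= 255, noise_sd >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 oocytes = oocytes,
                 dispersed_cumulus = dispersed_cumulus,
                 pipette = pipette,
                 rng_seed = as.integer(rng_seed),
                 noise_seed = as.integer(noise_seed)),
            class = "scene_spec")
}

# intensity palette; cells bright, pipette walls dark, zona near background so
# thresholding separates the oocyte disc from attached cumulus
scene_levels <- function(bg) {
  list(cell = min(255, bg + 110),
       zona = bg + 6,
       hole = bg,
       wall = max(0, bg - 40))
}

# blend an anti-aliased disc into img (matrix, 0-based px coords)
blend_disk <- function(img, cx, cy, r, level, soft = 1) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(0L, floor(cx - r - 2)); x1 <- min(w - 1L, ceiling(cx + r + 2))
  y0 <- max(0L, floor(cy - r - 2)); y1 <- min(h - 1L, ceiling(cy + r + 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov <- pmin(1, pmax(0, 0.5 + (r - d) / soft))
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  img[ys + 1L, xs + 1L] <- sub * (1 - cov) + level * cov
  img
}

# blend an annulus [r_in, r_out]
blend_annulus <- function(img, cx, cy, r_in, r_out, level, soft = 1) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(0L, floor(cx - r_out - 2)); x1 <- min(w - 1L, ceiling(cx + r_out + 2))
  y0 <- max(0L, floor(cy - r_out - 2)); y1 <- min(h - 1L, ceiling(cy + r_out + 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov_out <- pmin(1, pmax(0, 0.5 + (r_out - d) / soft))
  cov_in  <- pmin(1, pmax(0, 0.5 + (r_in  - d) / soft))
  cov <- cov_out - cov_in
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  img[ys + 1L, xs + 1L] <- sub * (1 - cov) + level * cov
  img
}

# blend the two pipette wall bands; all arguments in px
blend_pipette <- function(img, tip_x, tip_y, inner_d, wall, taper_deg, level) {
  h <- nrow(img); w <- ncol(img)
  x1 <- min(w - 1L, ceiling(tip_x + 1))
  if (x1 < 0) return(img)
  xs <- 0:x1; ys <- 0:(h - 1L)
  off <- pmax(0, tip_x - xs) * tan(taper_deg * pi / 180)
  # horizontal soft cut at the tip column
  xcov <- pmin(1, pmax(0, 0.5 + (tip_x - xs)))
  Y <- matrix(ys, length(ys), length(xs))
  for (side in c(-1, 1)) {
    yin  <- tip_y + side * inner_d / 2                 # inner edge (fixed)
    yout <- outer(rep(1, length(ys)), off) * side + yin + side * wall
    Yin <- matrix(yin, length(ys), length(xs))
    lo <- pmin(Yin, yout); hi <- pmax(Yin, yout)
    cov <- pmin(1, pmax(0, 0.5 + (Y - lo))) * pmin(1, pmax(0, 0.5 + (hi - Y)))
    cov <- cov * matrix(xcov, length(ys), length(xs), byrow = TRUE)
    sub <- img[, xs + 1L, drop = FALSE]
    img[, xs + 1L] <- sub * (1 - cov) + level * cov
  }
  img
}

check_bounds <- function(name, cx, cy, r, w_um, h_um) {
  if (cx - r < 0 || cy - r < 0 || cx + r > w_um || cy + r > h_um) {
    stop(sprintf("%s at (%.1f, %.1f) um with extent %.1f um lies outside the image bounds",
                 name, cx, cy, r))
  }
}

#' Render a synthetic scene with ground truth
#'
#' Deterministic given `spec$rng_seed`: identical specs render bit-identical
#' images. Oocytes are drawn as bright discs with a near-background zona
#' annulus of thickness s, optional darker interior holes, and attached
#' cumulus discs; the pipette as two dark converging wall bands ending at the
#' tip; Gaussian noise of sd `noise_sd` is added last and clipped.
#'
#' @param spec a [scene_spec].
#' @param .clip if `TRUE`, objects may extend beyond the frame (used when
#'   rendering shifted frame pairs); by default an out-of-bounds object is an
#'   error naming the object.
#' @return `list(image = gray_image, truth = ground truth list)`. The truth
#'   holds per-oocyte and per-cumulus centres/radii in both um and px,
#'   attachment flags, and the pipette tip and lumen edges in px.
#' @export
render_scene <- function(spec, .clip = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  ps <- spec$pixel_size_um
  w <- spec$width_px; h <- spec$height_px
  w_um <- w * ps; h_um <- h * ps
  lv <- scene_levels(spec$background_level)
  img <- matrix(spec$background_level, h, w)

  oo_tab <- list(); cu_tab <- list(); pip <- NULL
  with_seed(spec$rng_seed, {
    for (i in seq_along(spec$oocytes)) {
      oo <- spec$oocytes[[i]]
      cx <- oo$center_um[1]; cy <- oo$center_um[2]
      R <- oo$radius_um; s <- oo$zona_thickness_um
      if (!.clip) check_bounds(sprintf("oocyte %d", i), cx, cy, R + s, w_um, h_um)
      img <- blend_annulus(img, cx / ps, cy / ps, R / ps, (R + s) / ps, lv$zona)
      img <- blend_disk(img, cx / ps, cy / ps, R / ps, lv$cell)
      if (oo$n_holes > 0) {
        ang <- stats::runif(oo$n_holes, 0, 2 * pi)
        rad <- stats::runif(oo$n_holes, 0.15, 0.6) * R
        hr  <- stats::runif(oo$n_holes, 0.08, 0.14) * R
        for (k in seq_len(oo$n_holes)) {
          img <- blend_disk(img, (cx + rad[k] * cos(ang[k])) / ps,
                            (cy + rad[k] * sin(ang[k])) / ps,
                            hr[k] / ps, lv$hole)
        }
      }
      oo_tab[[i]] <- data.frame(id = i, cx_um = cx, cy_um = cy, r_um = R,
                                s_um = s, cx_px = cx / ps, cy_px = cy / ps,
                                r_px = R / ps)
      for (j in seq_along(oo$cumulus)) {
        cc <- oo$cumulus[[j]]
        ccx <- cc$center_um[1]; ccy <- cc$center_um[2]; r <- cc$radius_um
        if (!.clip) check_bounds(sprintf("cumulus %d of oocyte %d", j, i),
                                 ccx, ccy, r, w_um, h_um)
        img <- blend_disk(img, ccx / ps, ccy / ps, r / ps, lv$cell)
        d <- sqrt((ccx - cx)^2 + (ccy - cy)^2)
        cu_tab[[length(cu_tab) + 1L]] <-
          data.frame(oocyte_id = i, cx_um = ccx, cy_um = ccy, r_um = r,
                     cx_px = ccx / ps, cy_px = ccy / ps, r_px = r / ps,
                     attached = d <= oo$radius_um + r + oo$zona_thickness_um)
      }
    }
    for (j in seq_along(spec$dispersed_cumulus)) {
      cc <- spec$dispersed_cumulus[[j]]
      ccx <- cc$center_um[1]; ccy <- cc$center_um[2]; r <- cc$radius_um
      if (!.clip) check_bounds(sprintf("dispersed cumulus %d", j),
                               ccx, ccy, r, w_um, h_um)
      img <- blend_disk(img, ccx / ps, ccy / ps, r / ps, lv$cell)
      cu_tab[[length(cu_tab) + 1L]] <-
        data.frame(oocyte_id = NA_integer_, cx_um = ccx, cy_um = ccy, r_um = r,
                   cx_px = ccx / ps, cy_px = ccy / ps, r_px = r / ps,
                   attached = FALSE)
    }
    if (!is.null(spec$pipette)) {
      pp <- spec$pipette
      tx <- pp$tip_um[1] / ps; ty <- pp$tip_um[2] / ps
      if (!.clip && (tx < 0 || ty < 0 || tx > w - 1 || ty > h - 1)) {
        stop("pipette tip lies outside the image bounds")
      }
      img <- blend_pipette(img, tx, ty, pp$inner_diameter_um / ps,
                           pp$wall_thickness_um / ps, pp$taper_angle_deg,
                           lv$wall)
      pip <- list(tip_px = c(tx, ty), tip_um = pp$tip_um,
                  lumen_top_px = ty - pp$inner_diameter_um / (2 * ps),
                  lumen_bottom_px = ty + pp$inner_diameter_um / (2 * ps))
    }
  })
  if (spec$noise_sd > 0) {
    ns <- if (is.null(spec$noise_seed)) spec$rng_seed else spec$noise_seed
    img <- img + with_seed(ns, matrix(stats::rnorm(w * h, 0, spec$noise_sd),
                                      h, w))
  }

  truth <- list(
    oocytes = if (length(oo_tab)) do.call(rbind, oo_tab) else
      data.frame(id = integer(), cx_um = numeric(), cy_um = numeric(),
                 r_um = numeric(), s_um = numeric(), cx_px = numeric(),
                 cy_px = numeric(), r_px = numeric()),
    cumulus = if (length(cu_tab)) do.call(rbind, cu_tab) else
      data.frame(oocyte_id = integer(), cx_um = numeric(), cy_um = numeric(),
                 r_um = numeric(), cx_px = numeric(), cy_px = numeric(),
                 r_px = numeric(), attached = logical()),
    pipette = pip,
    pixel_size_um = ps)
  list(image = gray_image(img, pixel_size_um = ps), truth = truth)
}

#' Render two frames separated by a stage step seen through a rotated camera
#'
#' The second frame shows the same scene translated by `R(angle_deg) %*%
#' shift_px`: a stage step of `shift_px` whose image-frame displacement is
#' rotated by the camera misalignment. The exact applied displacement is
#' stored in the ground truth (`truth$shift_applied_px`). The two frames get
#' independent noise realizations (seeds `rng_seed` and `rng_seed + 1`), as
#' two camera exposures would.
#'
#' @param spec a [scene_spec] describing the first frame.
#' @param shift_px stage step `c(dx, dy)` in pixels.
#' @param angle_deg camera misalignment angle in degrees (counterclockwise in
#'   the y-down raster frame).
#' @return `list(frame_a, frame_b, truth)`; frames are [gray_image]s.
#' @export
render_shifted_pair <- function(spec, shift_px, angle_deg = 0) {
  stopifnot(inherits(spec, "scene_spec"), length(shift_px) == 2L)
  th <- angle_deg * pi / 180
  t_px <- c(cos(th) * shift_px[1] - sin(th) * shift_px[2],
            sin(th) * shift_px[1] + cos(th) * shift_px[2])
  ov <- (spec$width_px - abs(t_px[1])) * (spec$height_px - abs(t_px[2])) /
    (spec$width_px * spec$height_px)
  if (!is.finite(ov) || ov < 0.3) {
    stop(sprintf("shift leaves %.0f%% overlap; at least 30%% is required",
                 100 * max(0, ov)))
  }
  a <- render_scene(spec, .clip = TRUE)
  spec_b <- spec
  t_um <- t_px * spec$pixel_size_um
  spec_b$oocytes <- lapply(spec$oocytes, function(oo) {
    oo$center_um <- oo$center_um + t_um
    oo$cumulus <- lapply(oo$cumulus, function(cc) {
      cc$center_um <- cc$center_um + t_um; cc
    })
    oo
  })
  spec_b$dispersed_cumulus <- lapply(spec$dispersed_cumulus, function(cc) {
    cc$center_um <- cc$center_um + t_um; cc
  })
  if (!is.null(spec$pipette)) {
    spec_b$pipette$tip_um <- spec$pipette$tip_um + t_um
  }
  spec_b$noise_seed <- spec$rng_seed + 1L
  b <- render_scene(spec_b, .clip = TRUE)
  truth <- a$truth
  truth$shift_applied_px <- t_px
  truth$stage_step_px <- as.numeric(shift_px)
  truth$angle_deg <- angle_deg
  list(frame_a = a$image, frame_b = b$image, truth = truth)
}

#' Random cumulus-oocyte-complex scene
#'
#' Draws a scene with `n_oocytes` non-overlapping cumulus-oocyte complexes
#' and optional dispersed cumulus, under one seed. Default geometry: oocyte
#' radii 35-45 um, cumulus radii 5-15 um, zona 8 um, attached cumulus placed
#' so that the attachment rule `d <= R + r + s` holds with the cumulus disc
#' overlapping only the zona annulus.
#'
#' @param n_oocytes number of oocytes.
#' @param n_cumulus_range integer range of attached cumulus per oocyte.
#' @param n_dispersed number of free cumulus cells.
#' @param n_holes_range integer range of interior holes per oocyte.
#' @param width_px,height_px frame size.
#' @param noise_sd additive noise sd.
#' @param pipette optional [pipette_spec] passed through.
#' @param seed integer RNG seed.
#' @param pixel_size_um micrometres per pixel.
#' @return a [scene_spec].
#' @export
random_scene_spec <- function(n_oocytes = 3, n_cumulus_range = c(2, 6),
                              n_dispersed = 0, n_holes_range = c(3, 6),
                              width_px = 560, height_px = 420, noise_sd = 5,
                              pipette = NULL, seed = 1L, pixel_size_um = 1.0) {
  ps <- pixel_size_um
  with_seed(seed, {
    R <- stats::runif(n_oocytes, 35, 45)
    s <- rep(8, n_oocytes)
    margin <- (R + s + 2 * 15) / ps + 2      # complex extent in px (cumulus
                                             # centre at most R+s+r, plus r)
    centers <- matrix(NA_real_, 0, 2)
    for (i in seq_len(n_oocytes)) {
      ok <- FALSE
      for (try in 1:2000) {
        cx <- stats::runif(1, margin[i], width_px - margin[i])
        cy <- stats::runif(1, margin[i], height_px - margin[i])
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                margin[i] + margin[seq_len(i - 1)])) {
          centers <- rbind(centers, c(cx, cy)); ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place oocytes without overlap; enlarge the frame")
    }
    oocytes <- lapply(seq_len(n_oocytes), function(i) {
      n_c <- sample(seq(n_cumulus_range[1], n_cumulus_range[2]), 1)
      ang <- stats::runif(1, 0, 2 * pi) +
        seq(0, 2 * pi, length.out = n_c + 1)[seq_len(n_c)]
      cum <- lapply(seq_len(n_c), function(j) {
        r <- stats::runif(1, 5, 15)
        d <- R[i] + s[i] + stats::runif(1, 0.8, 0.98) * r
        list(center_um = c(centers[i, 1] * ps + d * cos(ang[j]),
                           centers[i, 2] * ps + d * sin(ang[j])),
             radius_um = r)
      })
      oocyte_spec(center_um = centers[i, ] * ps, radius_um = R[i],
                  zona_thickness_um = s[i],
                  n_holes = sample(seq(n_holes_range[1], n_holes_range[2]), 1),
                  cumulus = cum)
    })
    disp <- list()
    if (n_dispersed > 0) {
      for (j in seq_len(n_dispersed)) {
        for (try in 1:500) {
          r <- stats::runif(1, 5, 15)
          cx <- stats::runif(1, r + 2, width_px - r - 2)
          cy <- stats::runif(1, r + 2, height_px - r - 2)
          if (nrow(centers) == 0 ||
              all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                  margin + r / ps + 2)) {
            disp[[j]] <- list(center_um = c(cx, cy) * ps, radius_um = r)
            break
          }
        }
      }
      disp <- Filter(Negate(is.null), disp)
    }
    scene_spec(width_px, height_px, pixel_size_um = ps,
               background_level = 60, noise_sd = noise_sd,
               oocytes = oocytes, dispersed_cumulus = disp,
               pipette = pipette, rng_seed = seed)
  })
}

#' Write scene ground truth as JSON
#'
#' One JSON document per scene: oocyte and cumulus tables (um and px),
#' pipette tip and lumen edges, pixel size, and any registration metadata.
#'
#' @param truth ground truth list from [render_scene] / [render_shifted_pair].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read scene ground truth from JSON
#'
#' @param path a `.json` path written by [write_ground_truth].
#' @return the ground truth list (tables as data frames).
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
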