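#' @title Simulated denudation session
#' @description Runs the four-well denudation protocol end to end against a
#'   virtual stage, pump and camera over synthetic scenes: substrate contact
#'   detection, tip positioning, automated stage-camera calibration,
#'   per-oocyte centring, flow-rate selection inside the admissible window,
#'   aspiration with the in-pipette stop-flow guard, and cumulus detachment
#'   bookkeeping, with the enzymatic-exposure clock enforced.
#' @name orchestrator
NULL

#' Denudation protocol configuration
#'
#' Defaults follow the four-well layout and timings of the automated
#' denudation workflow: Q1 holds 100 uL hyaluronidase, Q2-Q4 hold 80 uL M2
#' medium; the tip is parked 25 um above the substrate and 150 um left of
#' the field centre, transfers run 55 um above the dish top, and no oocyte
#' may stay in the enzyme longer than 40 s.
#'
#' @param wells data.frame of well labels, media and volumes.
#' @param tip_height_above_substrate_um tip working height, um.
#' @param tip_x_offset_um tip offset left of the field centre, um.
#' @param transfer_height_um transfer height above the dish top, um.
#' @param max_enzyme_s maximal hyaluronidase exposure per oocyte, seconds.
#' @param cycles_per_well aspiration/deposition cycles per M2 well.
#' @param flow_policy operating-point fraction inside the flow window.
#' @param pickup_s time to aspirate one oocyte in Q1, seconds.
#' @param cycle_s duration of one denudation cycle in an M2 well, seconds.
#' @param tracking enable the in-pipette stop-flow guard.
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(wells = data.frame(
                              label = c("Q1", "Q2", "Q3", "Q4"),
                              medium = c("hyaluronidase", "M2", "M2", "M2"),
                              volume_uL = c(100, 80, 80, 80)),
                            tip_height_above_substrate_um = 25,
                            tip_x_offset_um = 150,
                            transfer_height_um = 55,
                            max_enzyme_s = 40,
                            cycles_per_well = 3,
                            flow_policy = 0.5,
                            pickup_s = 1.5,
                            cycle_s = 5,
                            tracking = TRUE) {
  stopifnot(all(wells$volume_uL > 0), tip_height_above_substrate_um > 0,
            transfer_height_um > 0, max_enzyme_s > 0, cycles_per_well >= 1,
            flow_policy >= 0, flow_policy <= 1, pickup_s > 0, cycle_s > 0)
  structure(list(wells = wells,
                 tip_height_above_substrate_um = tip_height_above_substrate_um,
                 tip_x_offset_um = tip_x_offset_um,
                 transfer_height_um = transfer_height_um,
                 max_enzyme_s = max_enzyme_s,
                 cycles_per_well = cycles_per_well,
                 flow_policy = flow_policy,
                 pickup_s = pickup_s, cycle_s = cycle_s,
                 tracking = tracking),
            class = "protocol_config")
}

#' Virtual hardware description
#'
#' The camera is rotated by a hidden misalignment angle: a commanded stage
#' displacement `u` appears in the image as `R(theta) u` (raster frame,
#' y down). The stage quantizes moves to its resolution.
#'
#' @param stage_misalignment_deg hidden camera-stage misalignment, degrees.
#' @param stage_resolution_um stage step resolution, um (default 1).
#' @param travel_mm stage travel range, mm (default 60).
#' @param pixel_size_um camera scale, um per pixel.
#' @param frame_width_px,frame_height_px camera frame size.
#' @return a `virtual_hardware` list.
#' @export
virtual_hardware <- function(stage_misalignment_deg = 2,
                             stage_resolution_um = 1,
                             travel_mm = 60,
                             pixel_size_um = 1,
                             frame_width_px = 520,
                             frame_height_px = 390) {
  stopifnot(stage_resolution_um > 0, travel_mm > 0, pixel_size_um > 0)
  structure(list(stage_misalignment_deg = stage_misalignment_deg,
                 stage_resolution_um = stage_resolution_um,
                 travel_mm = travel_mm,
                 pixel_size_um = pixel_size_um,
                 frame_width_px = frame_width_px,
                 frame_height_px = frame_height_px),
            class = "virtual_hardware")
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

#' Calibrate the virtual stage from a rendered mosaic pair
#'
#' Renders two overlapping frames of a textured scene separated by a +x
#' stage step seen through the hidden camera rotation, registers them and
#' estimates the misalignment angle.
#'
#' @param hw a [virtual_hardware].
#' @param seed RNG seed for the scene.
#' @param step_px stage step in pixels.
#' @return a `stage_calibration`.
#' @export
calibrate_virtual_stage <- function(hw, seed = 1L, step_px = 120) {
  spec <- random_scene_spec(n_oocytes = 3, n_dispersed = 10,
                            width_px = hw$frame_width_px,
                            height_px = hw$frame_height_px,
                            noise_sd = 5, seed = seed,
                            pixel_size_um = hw$pixel_size_um)
  pair <- render_shifted_pair(spec, c(step_px, 0),
                              angle_deg = hw$stage_misalignment_deg)
  estimate_calibration(pair$frame_a, pair$frame_b)
}

# centring move of a target seen at image offset v_um (from the field
# centre): returns the residual position after the move, in um
centering_residual <- function(v_um, hw, cal = NULL) {
  theta <- hw$stage_misalignment_deg * pi / 180
  want <- -v_um                       # desired image motion
  u <- if (is.null(cal)) want
       else image_to_stage(want, invert_calibration(cal))
  u_q <- round(u / hw$stage_resolution_um) * hw$stage_resolution_um
  v_um + as.numeric(rot2(theta) %*% u_q)
}

#' Stage-positioning trial
#'
#' Places `n_targets` random targets up to `max_offset_um` off-centre and
#' moves each to the field centre, either with the calibrated transform
#' (misalignment estimated from a rendered mosaic pair) or with the raw
#' image displacement; residual X/Y errors are measured after the move under
#' stage quantization.
#'
#' @param n_targets number of targets (>= 1).
#' @param hw a [virtual_hardware].
#' @param calibrated use the mosaic-estimated calibration (default `TRUE`).
#' @param seed RNG seed.
#' @param max_offset_um maximal target offset from centre, um.
#' @param cal optional pre-computed `stage_calibration` (skips the mosaic).
#' @return data.frame with `x_error_um`, `y_error_um`, `offset_um` per
#'   target; the estimated angle is attached as attribute `theta_est_deg`.
#' @export
positioning_trial <- function(n_targets = 50, hw = virtual_hardware(),
                              calibrated = TRUE, seed = 1L,
                              max_offset_um = 700, cal = NULL) {
  stopifnot(n_targets >= 1)
  if (calibrated && is.null(cal)) {
    cal <- calibrate_virtual_stage(hw, seed = seed)
  }
  res <- with_seed(seed + 10000L, {
    ang <- stats::runif(n_targets, 0, 2 * pi)
    rad <- stats::runif(n_targets, 0, max_offset_um)
    t(vapply(seq_len(n_targets), function(i) {
      v <- rad[i] * c(cos(ang[i]), sin(ang[i]))
      r <- centering_residual(v, hw, cal = if (calibrated) cal else NULL)
      c(r[1], r[2], rad[i])
    }, numeric(3)))
  })
  out <- data.frame(x_error_um = res[, 1], y_error_um = res[, 2],
                    offset_um = res[, 3])
  attr(out, "theta_est_deg") <-
    if (calibrated) cal$theta_rad * 180 / pi else NA_real_
  out
}

#' Random well map of cumulus-oocyte complexes
#'
#' A scene specification covering a whole well: oocyte complexes scattered
#' with wide separation over a square region much larger than one camera
#' frame. Local camera views of it are rendered on demand during a session.
#'
#' @param n_oocytes number of oocytes.
#' @param well_um side length of the populated region, um.
#' @param seed RNG seed.
#' @param n_cumulus_range attached cumulus count range per oocyte.
#' @param pixel_size_um camera scale.
#' @return a [scene_spec] (not intended for whole-frame rendering).
#' @export
random_well_spec <- function(n_oocytes = 20, well_um = 4000, seed = 1L,
                             n_cumulus_range = c(2, 6), pixel_size_um = 1) {
  with_seed(seed, {
    pos <- matrix(NA_real_, 0, 2)
    while (nrow(pos) < n_oocytes) {
      p <- stats::runif(2, 200, well_um - 200)
      if (nrow(pos) == 0 ||
          all(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2) > 220)) {
        pos <- rbind(pos, p)
      }
    }
    oocytes <- lapply(seq_len(n_oocytes), function(i) {
      R <- stats::runif(1, 35, 45); s <- 8
      n_c <- sample(seq(n_cumulus_range[1], n_cumulus_range[2]), 1)
      ang <- stats::runif(1, 0, 2 * pi) +
        seq(0, 2 * pi, length.out = n_c + 1)[seq_len(n_c)]
      cum <- lapply(seq_len(n_c), function(j) {
        r <- stats::runif(1, 5, 15)
        d <- R + s + stats::runif(1, 0.8, 0.98) * r
        list(center_um = pos[i, ] + d * c(cos(ang[j]), sin(ang[j])),
             radius_um = r)
      })
      oocyte_spec(center_um = pos[i, ], radius_um = R, zona_thickness_um = s,
                  n_holes = sample(3:6, 1), cumulus = cum)
    })
    scene_spec(ceiling(well_um / pixel_size_um),
               ceiling(well_um / pixel_size_um),
               pixel_size_um = pixel_size_um, background_level = 60,
               noise_sd = 5, oocytes = oocytes, rng_seed = seed)
  })
}

# render the local camera view of one complex: the oocyte (with its current
# cumulus) placed at the frame centre plus a residual offset
render_local_view <- function(oo, offset_um, hw, noise_sd = 5, seed = 1L) {
  w <- 420L; h <- 320L
  ps <- hw$pixel_size_um
  ctr <- c(w, h) / 2 * ps + offset_um
  shift <- ctr - oo$center_um
  oo2 <- oo
  oo2$center_um <- oo$center_um + shift
  oo2$cumulus <- lapply(oo$cumulus, function(cc) {
    cc$center_um <- cc$center_um + shift; cc
  })
  sp <- scene_spec(w, h, pixel_size_um = ps, background_level = 60,
                   noise_sd = noise_sd, oocytes = list(oo2),
                   rng_seed = seed)
  render_scene(sp, .clip = TRUE)
}

#' Run a simulated denudation session
#'
#' Executes the full protocol on a well map: substrate contact detection
#' from a rendered descent sequence, tip localization, automated stage
#' calibration, then per oocyte: centring via the calibrated stage,
#' oocyte/cumulus recognition on a local camera view, flow-window selection,
#' and one tracked aspiration per well transfer (Q1 to Q2, Q2 to Q3, Q3 to
#' Q4) with the stop-flow guard when tracking is enabled. Attached cumulus
#' detach in the M2 wells when the fluid shear at the operating rate exceeds
#' their adhesion force. Each oocyte ends in exactly one state: recovered in
#' Q4 or lost inside the pipette.
#'
#' @param scene a well map [scene_spec] (see [random_well_spec]).
#' @param protocol a [protocol_config].
#' @param hw a [virtual_hardware].
#' @param seed integer seed; identical inputs give identical reports.
#' @return a `session_report` (see Details).
#' @details The report lists `n_oocytes`, `n_recovered`, `n_fully_denuded`,
#'   `yield_rate`, `denudation_efficiency`, per-oocyte enzyme exposure and
#'   states, stop-flow event count, per-move positioning errors, the true
#'   and estimated misalignment angles, and the contact-detection frame.
#' @export
run_session <- function(scene, protocol = protocol_config(),
                        hw = virtual_hardware(), seed = 1L) {
  n <- length(scene$oocytes)
  oo_states <- lapply(scene$oocytes, function(oo) {
    list(spec = oo, lost = FALSE, n_cumulus0 = length(oo$cumulus))
  })
  report <- list(n_oocytes = n, n_recovered = 0L, n_fully_denuded = 0L,
                 yield_rate = NA_real_, denudation_efficiency = NA_real_,
                 exposure_s = numeric(0), schedule_ok = TRUE,
                 stop_flow_events = 0L, positioning_errors = data.frame(),
                 lost = integer(0), theta_true_deg = hw$stage_misalignment_deg,
                 theta_est_deg = NA_real_, contact_frame = NA_integer_,
                 Q_op_uL_min = numeric(0), oocytes = data.frame())
  class(report) <- "session_report"
  if (n == 0) {
    report$yield_rate <- NaN; report$denudation_efficiency <- NaN
    return(report)
  }

  # substrate contact detection from a synthetic descent sequence: the tip
  # slips laterally on touching the dish at a known frame
  contact_true <- 6L
  descent <- lapply(1:9, function(k) {
    dx <- if (k >= contact_true) 6 else 0
    sp <- scene_spec(230, 200, pixel_size_um = hw$pixel_size_um,
                     background_level = 60, noise_sd = 2,
                     pipette = pipette_spec(
                       tip_um = c((150 + dx) * hw$pixel_size_um,
                                  100 * hw$pixel_size_um)),
                     rng_seed = seed + 500L + k)
    render_scene(sp, .clip = TRUE)$image
  })
  ev <- detect_contact(descent, threshold_px = 3)
  report$contact_frame <- ev$frame_index

  cal <- calibrate_virtual_stage(hw, seed = seed)
  report$theta_est_deg <- cal$theta_rad * 180 / pi

  n_wells <- nrow(protocol$wells)
  tip_x <- 300; tip_y <- 100
  limit <- 0.6 * tip_x
  lumen <- NULL
  pe <- vector("list", n); qop <- rep(NA_real_, n)
  exposure <- protocol$pickup_s * seq_len(n)
  report$schedule_ok <- all(exposure <= protocol$max_enzyme_s)

  for (i in seq_len(n)) {
    st <- oo_states[[i]]

    # centring via the calibrated stage
    off <- with_seed(seed + 2000L + i, {
      a <- stats::runif(1, 0, 2 * pi); r <- stats::runif(1, 50, 400)
      r * c(cos(a), sin(a))
    })
    resid <- centering_residual(off, hw, cal = cal)
    pe[[i]] <- data.frame(oocyte = i, x_error_um = resid[1],
                          y_error_um = resid[2])

    # recognition on the local camera view (residual off-centre)
    lv <- render_local_view(st$spec, resid, hw, seed = seed + 3000L + i)
    det <- classify_cells(segment_cells(lv$image),
                          pixel_size_um = hw$pixel_size_um)
    if (length(det$oocytes) >= 1) {
      sizes <- vapply(det$oocytes, function(o) o$R_um, 0)
      best <- det$oocytes[[which.max(sizes)]]
      R_est <- best$R_um
      r_est <- if (nrow(best$cumulus)) best$cumulus$r_um else numeric(0)
    } else {
      # recognition miss: fall back to the true geometry
      R_est <- st$spec$radius_um
      r_est <- vapply(st$spec$cumulus, function(cc) cc$radius_um, 0)
    }

    p_i <- flow_params(R_um = R_est,
                       r_um = if (length(r_est)) max(r_est) else 0,
                       s_travel_um = protocol$tip_x_offset_um)
    win <- flow_window(p_i)
    if (!win$feasible) {
      stop(sprintf(paste0("session aborted: infeasible flow window for ",
                          "oocyte %d (R=%.1f um, r=%.1f um, mu_s=%.2f, ",
                          "Fmx=%.2e N)"),
                   i, R_est, if (length(r_est)) max(r_est) else 0,
                   p_i$mu_s, p_i$Fmx_N))
    }
    Q_op <- safe_rate(win, protocol$flow_policy)
    qop[i] <- flow_to_uL_min(Q_op)

    # well transfers with aspiration; guard active when tracking
    for (w in seq_len(n_wells - 1L)) {
      if (st$lost) break
      drift <- with_seed(seed + 4000L + i * 10L + w,
                         stats::runif(1, 4, 9))
      entry_u <- with_seed(seed + 6000L + i * 10L + w,
                           stats::runif(1, 1.5, 3.5))
      entry <- limit + 45 + entry_u
      if (protocol$tracking) {
        # frames rendered lazily: the guard stops the pump and the sequence
        fired <- FALSE
        for (k in 1:30) {
          x_k <- entry - drift * (k - 1)
          fr <- render_aspiration_frame(x_k, tip_x, tip_y, 360L, 200L,
                                        40, 125, 3,
                                        seed + 7000L + i * 100L +
                                          w * 31L + k,
                                        hw$pixel_size_um)
          if (is.null(lumen)) lumen <- locate_lumen(fr)
          ts <- track_lumen(fr, lumen, left_limit_px = limit)
          if (ts$stop_flow) { fired <- TRUE; break }
          if (x_k < limit - 30) break  # guard failed; oocyte runs deep
        }
        if (fired) {
          report$stop_flow_events <- report$stop_flow_events + 1L
        } else {
          st$lost <- TRUE   # guard never fired: oocyte drifted out of view
        }
      } else {
        # open-loop pump timing from the nominal drift speed, stopping a
        # safety margin short of the limit; fast oocytes overshoot
        n_open <- 6L
        final_x <- entry - drift * n_open
        if (final_x < limit) st$lost <- TRUE
      }
      # cumulus detachment during the cycles in the M2 well just entered
      if (!st$lost && protocol$wells$medium[w + 1L] == "M2" &&
          length(st$spec$cumulus)) {
        for (cyc in seq_len(protocol$cycles_per_well)) {
          keep <- vapply(st$spec$cumulus, function(cc) {
            pc <- flow_params(R_um = R_est, r_um = cc$radius_um,
                              s_travel_um = protocol$tip_x_offset_um)
            shear_force(Q_op, pc) < adhesion_force(pc)
          }, logical(1))
          st$spec$cumulus <- st$spec$cumulus[keep]
        }
      }
    }
    oo_states[[i]] <- st
  }

  rec <- !vapply(oo_states, function(s) s$lost, logical(1))
  den <- rec & vapply(oo_states, function(s) length(s$spec$cumulus) == 0,
                      logical(1))
  report$n_recovered <- sum(rec)
  report$n_fully_denuded <- sum(den)
  report$yield_rate <- report$n_recovered / n
  report$denudation_efficiency <- report$n_fully_denuded / n
  report$exposure_s <- exposure
  report$positioning_errors <- do.call(rbind, pe)
  report$lost <- which(!rec)
  report$Q_op_uL_min <- qop
  report$oocytes <- data.frame(
    id = seq_len(n), recovered = rec, fully_denuded = den,
    n_cumulus_initial = vapply(oo_states, function(s) s$n_cumulus0, 0L),
    n_cumulus_left = vapply(oo_states,
                            function(s) length(s$spec$cumulus), 0L))
  report
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<denudation session: %d oocytes, %d recovered (yield %.1f%%), %d fully denuded (efficiency %.1f%%)>\n",
              x$n_oocytes, x$n_recovered, 100 * x$yield_rate,
              x$n_fully_denuded, 100 * x$denudation_efficiency))
  if (x$n_oocytes > 0) {
    cat(sprintf("  theta: true %.2f deg, estimated %.3f deg; stop-flow events: %d; lost: %d\n",
                x$theta_true_deg, x$theta_est_deg, x$stop_flow_events,
                length(x$lost)))
    cat(sprintf("  enzyme exposure: max %.1f s (limit ok: %s)\n",
                max(x$exposure_s), x$schedule_ok))
  }
  invisible(x)
}
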