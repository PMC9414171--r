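# shared fixture builders (everything is generated in code at test time)

# one oocyte with holes, centred in a small frame
one_oocyte_spec <- function(n_holes = 0, noise_sd = 0, seed = 1L,
                            R = 45, width = 160, height = 160) {
  scene_spec(width, height, background_level = 60, noise_sd = noise_sd,
             oocytes = list(oocyte_spec(center_um = c(width / 2, height / 2),
                                        radius_um = R, n_holes = n_holes)),
             rng_seed = seed)
}

# pipette-only frame with the tip at a known position
pipette_scene <- function(tip = c(160, 100), noise_sd = 3, seed = 1L,
                          width = 230, height = 200) {
  scene_spec(width, height, background_level = 60, noise_sd = noise_sd,
             pipette = pipette_spec(tip_um = tip), rng_seed = seed)
}

# scene with dispersed cumulus only (no oocytes)
cumulus_only_spec <- function(n = 8, seed = 1L, width = 260, height = 200) {
  random_scene_spec(n_oocytes = 0, n_dispersed = n, width_px = width,
                    height_px = height, noise_sd = 5, seed = seed)
}

# closed-form circumcircle of three points (independent oracle)
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# coarse-to-fine grid search minimizing the true geometric circle objective
# sum (dist - r)^2; independent of the algebraic fit it checks
grid_circle_fit <- function(pts) {
  obj <- function(cx, cy) {
    d <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    r <- mean(d)
    sum((d - r)^2)
  }
  c0 <- colMeans(pts)
  span <- 3
  for (step in c(0.25, 0.05, 0.01)) {
    xs <- seq(c0[1] - span, c0[1] + span, by = step)
    ys <- seq(c0[2] - span, c0[2] + span, by = step)
    vals <- outer(xs, ys, Vectorize(function(x, y) obj(x, y)))
    k <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    c0 <- c(xs[k[1]], ys[k[2]])
    span <- step * 2
  }
  d <- sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2)
  list(center = c0, radius = mean(d))
}

# random draw of valid flow parameters (denominator constraint enforced)
random_flow_params <- function() {
  repeat {
    p <- try(flow_params(tip_diameter_um = runif(1, 80, 200),
                         R_um = runif(1, 20, 55),
                         r_um = runif(1, 2, 20),
                         s_travel_um = runif(1, 80, 500),
                         rho_kg_m3 = runif(1, 990, 1060),
                         rho0_kg_m3 = runif(1, 1020, 1100),
                         Cd = runif(1, 0.5, 2),
                         mu = runif(1, 0.05, 0.5),
                         mu_s = runif(1, 0.1, 1),
                         Fmx_N = 10^runif(1, -8, -6)), silent = TRUE)
    if (inherits(p, "try-error")) next
    den <- 3 * p$rho_kg_m3 * p$Cd * p$A_m2 * p$s_travel_m -
      4 * pi * p$rho0_kg_m3 * (p$R_m^3 + p$r_m^3)
    if (den > 0) return(p)
  }
}
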