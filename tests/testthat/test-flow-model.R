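test_that("drag force is quadratic in the flow rate", {
  p <- flow_params()
  expect_equal(drag_force(0, p), 0)
  expect_equal(drag_force(2e-11, p) / drag_force(1e-11, p), 4)
  # direct substitution at the standard 125 um tip
  A <- pi * (62.5e-6)^2
  p2 <- flow_params(tip_diameter_um = 125, rho_kg_m3 = 1000, Cd = 1)
  expect_equal(drag_force(1e-11, p2), 1000 * (1e-11)^2 * 1 / (2 * A),
               tolerance = 1e-12)
})

test_that("the massless limit reduces shear to drag", {
  p <- flow_params()
  p$R_m <- 1e-30; p$r_m <- 0   # vanishing cell volume
  Q <- seq(0, 5e-10, length.out = 7)
  expect_equal(shear_force(Q, p), drag_force(Q, p), tolerance = 1e-9)
})

test_that("at rest with no friction there is no shear", {
  p <- flow_params(mu = 1e-30)
  expect_lt(abs(shear_force(0, p)), 1e-20)
})

test_that("the closed-form shear equals the term-wise force balance", {
  set.seed(10)
  for (i in 1:50) {
    p <- random_flow_params()
    Q <- runif(1, 0, 5e-10)
    Mm <- combined_mass(p$R_m * 1e6, p$r_m * 1e6,
                        p$rho0_kg_m3)$combined_mass_kg
    acc <- Q^2 / (2 * p$s_travel_m * p$A_m2^2)
    Ff <- Mm * p$g_m_s2 * p$mu
    oracle <- drag_force(Q, p) - Mm * acc - Ff
    expect_equal(shear_force(Q, p), oracle, tolerance = 1e-9)
  }
})

test_that("window roots satisfy their defining force identities", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_flow_params()
    w <- flow_window(p)
    adh <- adhesion_force(p)
    expect_lt(abs(shear_force(w$Q_min_m3_s, p) - adh) / adh, 1e-9)
    expect_lt(abs(shear_force(w$Q_max_m3_s, p) - p$Fmx_N) / p$Fmx_N, 1e-9)
  }
})

test_that("closed-form roots match numeric root finding", {
  set.seed(12)
  for (i in 1:20) {
    p <- random_flow_params()
    w <- flow_window(p)
    hi <- 10 * max(w$Q_min_m3_s, w$Q_max_m3_s)
    root <- function(target) {
      stats::uniroot(function(q) shear_force(q, p) - target,
                     c(0, hi), tol = 1e-18)$root
    }
    expect_equal(w$Q_min_m3_s, root(adhesion_force(p)), tolerance = 1e-6)
    expect_equal(w$Q_max_m3_s, root(p$Fmx_N), tolerance = 1e-6)
  }
})

test_that("without cumulus the lower bound drops the r terms", {
  p <- flow_params(r_um = 0)
  w <- flow_window(p)
  A <- p$A_m2; s <- p$s_travel_m
  den <- 3 * p$rho_kg_m3 * p$Cd * A * s - 4 * pi * p$rho0_kg_m3 * p$R_m^3
  expect_equal(w$Q_min_m3_s,
               sqrt(8 * pi * A^2 * s * p$rho0_kg_m3 * p$g_m_s2 * p$mu *
                      p$R_m^3 / den), tolerance = 1e-12)
  expect_true(w$feasible)
})

test_that("the window responds monotonically to its limits", {
  base <- flow_params()
  q_at <- function(Fmx) flow_window(flow_params(Fmx_N = Fmx))$Q_max_m3_s
  fx <- c(1e-8, 1e-7, 1e-6, 1e-5)
  expect_true(all(diff(vapply(fx, q_at, 0)) > 0))
  qmin_at <- function(mu_s) flow_window(flow_params(mu_s = mu_s))$Q_min_m3_s
  expect_true(all(diff(vapply(c(0.1, 0.3, 0.6, 0.9), qmin_at, 0)) > 0))
  # shear strictly increases beyond Q_min while drag dominates
  w <- flow_window(base)
  Q <- seq(w$Q_min_m3_s, 5 * w$Q_max_m3_s, length.out = 50)
  expect_true(all(diff(shear_force(Q, base)) > 0))
})

test_that("infeasible windows are flagged, not raised", {
  # huge sticky cumulus vs tiny physiological limit
  p <- flow_params(r_um = 30, mu_s = 5, Fmx_N = 1e-12)
  w <- flow_window(p)
  expect_false(w$feasible)
  expect_error(safe_rate(w), "infeasible")
  # feasibility is exactly m*g*mu_s <= Fmx
  m <- (4 / 3) * pi * p$rho0_kg_m3 * p$r_m^3
  expect_equal(w$feasible, m * p$g_m_s2 * p$mu_s <= p$Fmx_N)
})

test_that("a non-positive denominator is an error", {
  expect_error(flow_window(flow_params(tip_diameter_um = 40, R_um = 60,
                                       s_travel_um = 50)),
               "drag cannot dominate")
})

test_that("the operating policy interpolates the window linearly", {
  p <- flow_params()
  w <- flow_window(p)
  expect_equal(safe_rate(p, 0), w$Q_min_m3_s)
  expect_equal(safe_rate(p, 1), w$Q_max_m3_s)
  expect_equal(safe_rate(p, 0.5), (w$Q_min_m3_s + w$Q_max_m3_s) / 2)
})

test_that("unit scaling is dimensionally consistent", {
  p <- flow_params()
  # all lengths x10: A x100, volumes x1000
  p10 <- flow_params(tip_diameter_um = 1250, R_um = 400, r_um = 100,
                     s_travel_um = 1500)
  Q <- 1e-11
  expect_equal(drag_force(Q, p10), drag_force(Q, p) / 100, tolerance = 1e-9)
  expect_equal(adhesion_force(p10), adhesion_force(p) * 1000,
               tolerance = 1e-9)
})

test_that("pump unit conversion is exact", {
  expect_equal(flow_from_uL_min(60), 1e-9)
  expect_equal(flow_to_uL_min(flow_from_uL_min(7.25)), 7.25,
               tolerance = 1e-12)
})
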