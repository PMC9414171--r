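#' @title Aspiration-flow dynamics and the admissible flow-rate window
#' @description During micropipette aspiration the flow drags the
#'   cumulus-oocyte complex toward the tip; the fluid shear force available
#'   to strip cumulus cells is the drag minus the inertial and frictional
#'   reactions of the complex. Denudation requires the shear to exceed the
#'   cumulus adhesion force `m g mu_s` while staying below the physiological
#'   shear limit `F_mx` that would damage the oocyte; solving both
#'   constraints for the pump flow rate Q yields a closed-form admissible
#'   window `[Q_min, Q_max]`.
#' @name flow_model
NULL

#' Flow model parameters
#'
#' All quantities are stored in SI units; the constructor accepts the
#' geometric lengths in micrometres for convenience. The cross-sectional
#' area defaults to `pi (d/2)^2` from the tip diameter.
#'
#' The density and coefficient defaults are physically plausible working
#' values for M2 medium and mouse oocytes — the window identities hold for
#' any valid parameter set, so no result of this module depends on them.
#'
#' @param tip_diameter_um pipette tip (lumen) diameter, default 125 um.
#' @param R_um oocyte radius, default 40 um.
#' @param r_um effective cumulus radius, default 10 um (may be 0).
#' @param s_travel_um initial oocyte-to-tip travel distance s, default 150 um
#'   (the protocol's tip offset from the field centre).
#' @param rho_kg_m3 medium density, default 1005 (M2 medium, near water).
#' @param rho0_kg_m3 cell density, default 1050.
#' @param Cd drag coefficient, dimensionless, default 1.
#' @param mu friction coefficient oocyte-cumulus, default 0.1.
#' @param mu_s adhesion coefficient cumulus-oocyte, default 0.3.
#' @param g_m_s2 gravitational acceleration, default 9.81.
#' @param Fmx_N physiological shear limit in newtons, default 1e-7.
#' @param A_m2 pipette cross-sectional area; overrides `tip_diameter_um`.
#' @return a `flow_params` list (SI fields `A_m2`, `R_m`, `r_m`,
#'   `s_travel_m`, `rho_kg_m3`, `rho0_kg_m3`, `Cd`, `mu`, `mu_s`, `g_m_s2`,
#'   `Fmx_N`).
#' @export
flow_params <- function(tip_diameter_um = 125, R_um = 40, r_um = 10,
                        s_travel_um = 150, rho_kg_m3 = 1005,
                        rho0_kg_m3 = 1050, Cd = 1.0, mu = 0.1, mu_s = 0.3,
                        g_m_s2 = 9.81, Fmx_N = 1e-7, A_m2 = NULL) {
  if (is.null(A_m2)) A_m2 <- pi * (tip_diameter_um * 1e-6 / 2)^2
  p <- list(A_m2 = A_m2, R_m = R_um * 1e-6, r_m = r_um * 1e-6,
            s_travel_m = s_travel_um * 1e-6, rho_kg_m3 = rho_kg_m3,
            rho0_kg_m3 = rho0_kg_m3, Cd = Cd, mu = mu, mu_s = mu_s,
            g_m_s2 = g_m_s2, Fmx_N = Fmx_N)
  with(p, stopifnot(A_m2 > 0, R_m > 0, r_m >= 0, s_travel_m > 0,
                    rho_kg_m3 > 0, rho0_kg_m3 > 0, Cd > 0, mu > 0,
                    mu_s > 0, g_m_s2 > 0, Fmx_N > 0))
  structure(p, class = "flow_params")
}

#' Drag force of the aspiration flow
#'
#' `F_d = rho Q^2 C_d / (2 A)`: the dynamic pressure of the mean lumen
#' velocity `Q / A` times the drag coefficient, acting over the lumen area.
#'
#' @param Q flow rate(s) in m^3/s (>= 0); vectorized.
#' @param p a [flow_params].
#' @return drag force(s) in newtons.
#' @export
drag_force <- function(Q, p) {
  stopifnot(all(Q >= 0))
  p$rho_kg_m3 * Q^2 * p$Cd / (2 * p$A_m2)
}

# combined oocyte + cumulus mass from the SI radii
complex_mass <- function(p) {
  (4 / 3) * pi * p$rho0_kg_m3 * (p$R_m^3 + p$r_m^3)
}

#' Cumulus adhesion force
#'
#' `m g mu_s` with `m = (4/3) pi rho0 r^3`, the cumulus mass: the force the
#' fluid shear must exceed to strip the cumulus from the oocyte.
#'
#' @param p a [flow_params].
#' @return adhesion force in newtons.
#' @export
adhesion_force <- function(p) {
  (4 / 3) * pi * p$rho0_kg_m3 * p$r_m^3 * p$g_m_s2 * p$mu_s
}

#' Fluid shear force on the cumulus-oocyte complex
#'
#' Newton balance of the complex under drag, constant-acceleration inertia
#' over the travel distance s, and friction:
#' `F_s = rho C_d Q^2 / (2A) - (2/3) pi rho0 (Q^2 / (A^2 s) + 2 g mu)
#' (R^3 + r^3)`.
#'
#' @param Q flow rate(s) in m^3/s (>= 0); vectorized.
#' @param p a [flow_params].
#' @return shear force(s) in newtons (may be negative below the stall rate).
#' @export
shear_force <- function(Q, p) {
  stopifnot(all(Q >= 0))
  drag_force(Q, p) -
    (2 / 3) * pi * p$rho0_kg_m3 *
    (Q^2 / (p$A_m2^2 * p$s_travel_m) + 2 * p$g_m_s2 * p$mu) *
    (p$R_m^3 + p$r_m^3)
}

#' Admissible flow-rate window
#'
#' Solves `m g mu_s <= F_s(Q) <= F_mx` for Q in closed form:
#' \deqn{Q_{min} = \sqrt{\frac{8\pi A^2 s \rho_0 g (\mu R^3 + \mu r^3 +
#'   \mu_s r^3)}{3 \rho C_d A s - 4 \pi \rho_0 (R^3 + r^3)}}}
#' \deqn{Q_{max} = \sqrt{\frac{2 A^2 s (4\pi\rho_0 g \mu R^3 +
#'   4\pi\rho_0 g \mu r^3 + 3 F_{mx})}{3 \rho C_d A s -
#'   4 \pi \rho_0 (R^3 + r^3)}}}
#' The window is feasible iff `Q_min <= Q_max`, equivalently
#' `m g mu_s <= F_mx`. An infeasible window is returned with
#' `feasible = FALSE`, not raised as an error; a non-positive denominator
#' (drag unable to dominate inertia plus friction) is an error.
#'
#' @param p a [flow_params].
#' @return a `flow_window`: list with `Q_min_m3_s`, `Q_max_m3_s`, `feasible`.
#' @export
flow_window <- function(p) {
  A <- p$A_m2; s <- p$s_travel_m; R3 <- p$R_m^3; r3 <- p$r_m^3
  den <- 3 * p$rho_kg_m3 * p$Cd * A * s - 4 * pi * p$rho0_kg_m3 * (R3 + r3)
  if (den <= 0) {
    stop("drag cannot dominate inertia and friction: ",
         "3*rho*Cd*A*s - 4*pi*rho0*(R^3+r^3) <= 0")
  }
  g <- p$g_m_s2; rho0 <- p$rho0_kg_m3
  Qmin <- sqrt(8 * pi * A^2 * s * rho0 * g *
                 (p$mu * R3 + p$mu * r3 + p$mu_s * r3) / den)
  Qmax <- sqrt(2 * A^2 * s *
                 (4 * pi * rho0 * g * p$mu * R3 +
                  4 * pi * rho0 * g * p$mu * r3 + 3 * p$Fmx_N) / den)
  structure(list(Q_min_m3_s = Qmin, Q_max_m3_s = Qmax,
                 feasible = Qmin <= Qmax),
            class = "flow_window")
}

#' @export
print.flow_window <- function(x, ...) {
  cat(sprintf("<flow window: [%.3f, %.3f] uL/min, %s>\n",
              flow_to_uL_min(x$Q_min_m3_s), flow_to_uL_min(x$Q_max_m3_s),
              if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}

#' Operating flow rate inside the admissible window
#'
#' `Q = Q_min + policy (Q_max - Q_min)`: a linear operating-point policy,
#' 0 = gentlest rate that still strips cumulus, 1 = the physiological limit.
#'
#' @param p a [flow_params] or a [flow_window].
#' @param policy fraction in `[0, 1]`, default 0.5.
#' @return flow rate in m^3/s.
#' @export
safe_rate <- function(p, policy = 0.5) {
  stopifnot(policy >= 0, policy <= 1)
  win <- if (inherits(p, "flow_window")) p else flow_window(p)
  if (!win$feasible) {
    stop("infeasible flow window: cumulus adhesion exceeds the ",
         "physiological shear limit (m*g*mu_s > F_mx)")
  }
  win$Q_min_m3_s + policy * (win$Q_max_m3_s - win$Q_min_m3_s)
}

#' Flow rate unit conversions
#'
#' Pumps are programmed in uL/min; the model works in m^3/s.
#' `1 uL/min = 1e-9 / 60 m^3/s` exactly.
#'
#' @param Q flow rate in m^3/s.
#' @return flow rate in uL/min.
#' @export
flow_to_uL_min <- function(Q) Q / (1e-9 / 60)

#' @rdname flow_to_uL_min
#' @param Q_uL_min flow rate in uL/min.
#' @return flow rate in m^3/s.
#' @export
flow_from_uL_min <- function(Q_uL_min) Q_uL_min * (1e-9 / 60)
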