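#' Lumped pressure-flow surrogate of the main pulmonary artery junction
#'
#' Nonlinear lumped model fulfilling the macro-domain contract at the two
#' 1D/macro interfaces: given an inlet flow and outlet pressures it returns
#' the inlet pressure and outlet flows. Each branch obeys
#' `P_in - P_i = a_i Q_i + b_i Q_i |Q_i|`, a convex, strictly increasing
#' pressure-flow curve dominated at physiological flows by the
#' flow-dependent (quadratic) term, as in 3D simulations of the major
#' arteries. The linear coefficients derive from Poiseuille resistance of
#' cylinders with the measured branch areas; the quadratic coefficients are
#' `b_i = K rho_b / (2 A_i^2)` (dynamic-pressure / minor-loss form).
#'
#' @param lpa_area,rpa_area,mpa_area Branch cross-sectional areas (m^2).
#' @param lpa_length,rpa_length,mpa_length Effective branch lengths (m).
#' @param K Minor-loss coefficient of the quadratic term.
#' @param scale Common multiplier on the Poiseuille linear coefficients.
#' @param fluid [fluid_properties()].
#' @return A `macro_surrogate` object usable with [macro_solve()].
#' @export
macro_surrogate <- function(lpa_area = 3.77e-4, rpa_area = 3.54e-4,
                            mpa_area = 7.72e-4,
                            lpa_length = 0.03, rpa_length = 0.03,
                            mpa_length = 0.05,
                            K = 1, scale = 1, fluid = fluid_properties()) {
  stopifnot(K >= 0, scale >= 0)
  areas <- c(LPA = lpa_area, RPA = rpa_area)
  lens <- c(LPA = lpa_length, RPA = rpa_length)
  d <- sqrt(4 * areas / pi)
  a <- scale * 128 * fluid$mu * lens / (pi * d^4)
  b <- K * fluid$rho_b / (2 * areas^2)
  d_mpa <- sqrt(4 * mpa_area / pi)
  a_mpa <- scale * 128 * fluid$mu * mpa_length / (pi * d_mpa^4)
  structure(list(a = a, b = b, a_mpa = a_mpa, areas = areas,
                 mpa_area = mpa_area, d = d, d_mpa = d_mpa,
                 K = K, scale = scale, fluid = fluid),
            class = "macro_surrogate")
}

# Branch flow for a given driving pressure difference (vectorized, signed).
branch_flow <- function(dP, a, b) {
  s <- sign(dP); ad <- abs(dP)
  ifelse(b > 0, s * (-a + sqrt(a^2 + 4 * b * ad)) / (2 * b), s * ad / a)
}

#' Solve the macro surrogate
#'
#' Finds the junction pressure such that the branch flows, each satisfying its
#' convex pressure-flow law against its prescribed outlet pressure, sum to the
#' inlet flow (monotone scalar root bracketed and solved to 1e-9 Pa). The MPA
#' segment adds its linear drop upstream of the junction.
#'
#' @param macro A `macro_surrogate`.
#' @param Q_in Inlet (cardiac output) flow (m^3/s).
#' @param P_out Named numeric vector of outlet pressures, names `LPA`, `RPA`
#'   (or `left`/`right`, mapped in that order).
#' @param ... Unused.
#' @return List with `P_in` (Pa, at the MPA inlet), `P_junction`, `Q_out`
#'   (named, m^3/s) and a `sawss` record from [sawss_poiseuille()].
#' @export
macro_solve <- function(macro, Q_in, P_out, ...) UseMethod("macro_solve")

#' @export
macro_solve.macro_surrogate <- function(macro, Q_in, P_out, ...) {
  stopifnot(Q_in >= 0, length(P_out) == 2)
  P_out <- unname(P_out)
  resid <- function(Pj) sum(branch_flow(Pj - P_out, macro$a, macro$b)) - Q_in
  lo <- min(P_out)
  span <- max(1, diff(range(P_out)), macro$a[1] * Q_in + macro$b[1] * Q_in^2)
  hi <- lo + span
  for (k in 1:60) {
    if (resid(hi) >= 0) break
    span <- span * 2; hi <- lo + span
  }
  if (resid(hi) < 0) stop("macro surrogate root not bracketed")
  Pj <- stats::uniroot(resid, c(lo, hi), tol = 1e-9)$root
  Q <- branch_flow(Pj - P_out, macro$a, macro$b)
  names(Q) <- c("LPA", "RPA")
  P_in <- Pj + macro$a_mpa * Q_in
  tau <- c(MPA = sawss_poiseuille(Q_in, macro$d_mpa, macro$fluid$mu),
           LPA = sawss_poiseuille(Q[1], macro$d[1], macro$fluid$mu),
           RPA = sawss_poiseuille(Q[2], macro$d[2], macro$fluid$mu))
  w <- c(macro$mpa_area, macro$areas)
  sawss <- list(tau_Pa = tau, tau_dyne_cm2 = tau * 10,
                area_weighted_Pa = sum(tau * w) / sum(w))
  list(P_in = P_in, P_junction = Pj, Q_out = Q, sawss = sawss)
}

#' Two linear resistors as a macro stand-in
#'
#' Minimal linear macro model (`P_in - P_i = R_i Q_i`) used for verification
#' against monolithic resistor-network solutions.
#'
#' @param R Named numeric vector of two branch resistances (Pa s/m^3).
#' @return A `linear_macro` object.
#' @export
linear_macro <- function(R = c(LPA = 1e7, RPA = 1e7)) {
  structure(list(R = unname(R)), class = "linear_macro")
}

#' @export
macro_solve.linear_macro <- function(macro, Q_in, P_out, ...) {
  P_out <- unname(P_out)
  g <- 1 / macro$R
  Pj <- (Q_in + sum(g * P_out)) / sum(g)
  Q <- g * (Pj - P_out)
  names(Q) <- c("LPA", "RPA")
  list(P_in = Pj, P_junction = Pj, Q_out = Q, sawss = NULL)
}

#' Poiseuille wall-shear-stress analogue
#'
#' Explicit tube approximation `tau = 32 mu Q / (pi D^3)` of the spatially
#' averaged wall shear stress in a major artery. This is a deliberately
#' simple analogue of the surface-averaged CFD quantity and is not comparable
#' in magnitude to values from a resolved 3D flow field.
#'
#' @param Q Flow (m^3/s).
#' @param D Diameter (m).
#' @param mu Blood viscosity (Pa s).
#' @return Shear stress (Pa); multiply by 10 for dyne/cm^2.
#' @export
sawss_poiseuille <- function(Q, D, mu = 0.0035) {
  if (any(D <= 0)) stop("diameter must be positive")
  32 * mu * Q / (pi * D^3)
}

# Equal-pressure LPA flow fraction (%) of a surrogate at a given inlet flow.
macro_lpa_fraction <- function(macro, Q_in = 4.8 / 6e4) {
  sol <- macro_solve(macro, Q_in, c(LPA = 0, RPA = 0))
  100 * sol$Q_out[["LPA"]] / Q_in
}

#' Calibrate the macro surrogate
#'
#' Two-point calibration at a reference cardiac output with equal outlet
#' pressures: the mix between the linear (Poiseuille-derived) and quadratic
#' (flow-dependent) branch terms is root-found so the LPA receives the target
#' share of flow, and the overall impedance is scaled so the junction-to-
#' outlet pressure drop matches `dP_target`. Because both coefficient
#' families scale as the inverse squared branch area, the split depends only
#' on the linear/quadratic mix while the drop sets the magnitude.
#'
#' @param Q_ref Reference inlet flow (m^3/s); default 4.8 L/min.
#' @param lpa_target Target LPA flow percentage at equal outlet pressures.
#' @param dP_target Junction-to-outlet pressure drop at `Q_ref` (Pa).
#' @param ... Passed to [macro_surrogate()] (areas, lengths, fluid).
#' @return A calibrated `macro_surrogate`.
#' @export
calibrate_macro <- function(Q_ref = 4.8 / 6e4, lpa_target = 52.85,
                            dP_target = 300, ...) {
  drop_at <- function(m) {
    sol <- macro_solve(m, Q_ref, c(LPA = 0, RPA = 0))
    sol$P_junction
  }
  build <- function(theta) {
    # theta in (0,1): fraction of dP_target carried by the linear term
    m0 <- macro_surrogate(K = 0, scale = 1, ...)
    mq <- macro_surrogate(K = 1, scale = 0, ...)
    s <- theta * dP_target / drop_at(m0)
    K <- (1 - theta) * dP_target / drop_at(mq)
    macro_surrogate(K = K, scale = s, ...)
  }
  fr <- function(theta) macro_lpa_fraction(build(theta), Q_ref) - lpa_target
  f0 <- fr(1e-6); f1 <- fr(1 - 1e-6)
  if (sign(f0) == sign(f1)) {
    theta <- if (abs(f0) < abs(f1)) 1e-6 else 1 - 1e-6
  } else {
    theta <- stats::uniroot(fr, c(1e-6, 1 - 1e-6), tol = 1e-8)$root
  }
  m <- build(theta)
  # rescale once more so the total drop is exact after the mix is fixed
  adj <- dP_target / drop_at(m)
  m <- macro_surrogate(K = m$K * adj, scale = m$scale * adj, ...)
  m$calibration <- list(Q_ref = Q_ref, lpa_target = lpa_target,
                        dP_target = dP_target, theta = theta,
                        lpa_fraction = macro_lpa_fraction(m, Q_ref))
  m
}
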