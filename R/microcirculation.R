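#' Capillary sheet height
#'
#' Piecewise-linear recruitment law for the height of a capillary sheet as a
#' function of transmural pressure (blood minus alveolar pressure): collapsed
#' below zero, linearly compliant up to the upper recruitment pressure `PCU`,
#' and saturated at `Hmax` above it. Continuous and non-decreasing.
#'
#' @param Ptm Transmural pressure (Pa); vectorized.
#' @param params A [capillary_sheet_params()] object.
#' @return Sheet height (m).
#' @export
sheet_height <- function(Ptm, params = capillary_sheet_params()) {
  h <- params$H0 + params$alpha_c * Ptm
  h[Ptm < 0] <- 0
  pmin(h, params$Hmax)
}

# Antiderivative F(P) = integral_0^P H(p)^3 dp of the cubed sheet height.
# Collapsed region contributes nothing, the compliant region integrates to a
# quartic, and the saturated region is linear in P.
sheet_height3_antideriv <- function(P, params) {
  H0 <- params$H0; ac <- params$alpha_c; Hmax <- params$Hmax; PCU <- params$PCU
  Pc <- pmin(pmax(P, 0), PCU)
  Fv <- ((H0 + ac * Pc)^4 - H0^4) / (4 * ac)
  sat <- P > PCU
  if (any(sat)) Fv[sat] <- Fv[sat] + Hmax^3 * (P[sat] - PCU)
  Fv
}

#' Capillary sheet flow
#'
#' Flow through one capillary sheet between arteriolar and venular transmural
#' pressures, `Q = SA/(mu_c f l_c^2) * integral of H^3 dPtm`, evaluated with
#' zone-wise closed forms. Both pressures below zero (zone 1) gives no flow;
#' a negative venular pressure clamps the lower limit to zero (zone 2,
#' waterfall); both positive is zone 3. Antisymmetric under exchange of the
#' two pressures.
#'
#' @param Ptm_art Arteriolar transmural pressure (Pa); vectorized.
#' @param Ptm_ven Venular transmural pressure (Pa); vectorized.
#' @param params A [capillary_sheet_params()] object.
#' @return Volumetric flow (m^3/s).
#' @export
sheet_flow <- function(Ptm_art, Ptm_ven, params = capillary_sheet_params()) {
  params$k * (sheet_height3_antideriv(Ptm_art, params) -
                sheet_height3_antideriv(Ptm_ven, params))
}

#' Build the intra-acinar ladder template
#'
#' The acinus is a 9-generation symmetric series-parallel ("ladder") network:
#' arteriolar and venular chains joined at every generation by a capillary
#' sheet. Generation i of the chain carries `2^i` parallel vessels whose
#' diameters and lengths shrink geometrically from the feeding terminal
#' vessel. Gravity is neglected inside the acinus and the chain segments are
#' treated as rigid.
#'
#' @param d_art Diameter of the terminal artery feeding the acinus (m).
#' @param d_ven Diameter of the terminal vein draining it (m).
#' @param cap A [capillary_sheet_params()] object (per-sheet area already set).
#' @param mu Blood viscosity in arterioles/venules (Pa s).
#' @param n_gen Number of generations (rungs).
#' @param diam_ratio Per-generation diameter ratio.
#' @param len_ratio Per-generation length ratio.
#' @param L1 Length of a generation-1 vessel (m).
#' @param alveolar_pressure Air pressure surrounding the sheets (Pa).
#' @return A `ladder_acinus` list with per-generation chain resistances
#'   `R_art`, `R_ven` (Pa s/m^3) and the sheet parameters.
#' @export
ladder_acinus <- function(d_art, d_ven, cap = capillary_sheet_params(),
                          mu = 0.0035, n_gen = 9, diam_ratio = 0.8,
                          len_ratio = 0.8, L1 = 0.4e-3,
                          alveolar_pressure = 0) {
  stopifnot(d_art > 0, d_ven > 0, n_gen >= 1)
  gen <- seq_len(n_gen)
  n_par <- 2^gen
  L <- L1 * len_ratio^(gen - 1)
  Da <- d_art * diam_ratio^gen
  Dv <- d_ven * diam_ratio^gen
  structure(list(
    n_gen = n_gen, cap = cap, mu = mu,
    L = L, D_art = Da, D_ven = Dv, n_parallel = n_par,
    R_art = 128 * mu * L / (pi * Da^4 * n_par),
    R_ven = 128 * mu * L / (pi * Dv^4 * n_par),
    alveolar_pressure = alveolar_pressure,
    g_floor = 1e-18
  ), class = "ladder_acinus")
}

# Distension factors of the compliant ladder chain segments: resistances are
# divided by (1 + alpha Ptm)^4, Ptm relative to alveolar pressure, with the
# same diameter floor as the extra-acinar compliance law. P_art/P_ven are
# rung blood pressures (matrices n x n_gen) from the previous iterate; NULL
# gives a rigid chain.
ladder_distension <- function(ladder, P_art, P_ven, alpha, floor_frac = 0.1,
                              ceiling_frac = 2) {
  if (is.null(P_art) || is.null(alpha) || alpha == 0)
    return(list(art = NULL, ven = NULL))
  f <- function(P) pmin(pmax(1 + alpha * (P - ladder$alveolar_pressure),
                             floor_frac), ceiling_frac)^4
  list(art = f(P_art), ven = f(P_ven))
}

# Series-parallel reduction of the ladder. gs: sheet conductances (matrix
# n_cases x n_gen); dist: optional distension factors multiplying chain
# conductances. Returns the equivalent conductance T_i of the sub-ladder from
# rung i outward, as a list of vectors (T[[n_gen+1]] = 0).
ladder_reduce <- function(ladder, gs, dist = list(art = NULL, ven = NULL)) {
  ng <- ladder$n_gen
  Tn <- vector("list", ng + 1L)
  Tn[[ng + 1L]] <- rep(0, nrow(gs))
  for (i in ng:1) {
    Ra <- if (is.null(dist$art)) ladder$R_art[i] else ladder$R_art[i] / dist$art[, i]
    Rv <- if (is.null(dist$ven)) ladder$R_ven[i] else ladder$R_ven[i] / dist$ven[, i]
    Tn[[i]] <- 1 / (Ra + 1 / (gs[, i] + Tn[[i + 1L]]) + Rv)
  }
  Tn
}

# Forward sweep recovering internal rung pressures and flows given terminal
# pressures P_in / P_out (vectors) and the reduction list Tn.
ladder_sweep <- function(ladder, gs, Tn, P_in, P_out,
                         dist = list(art = NULL, ven = NULL)) {
  ng <- ladder$n_gen
  n <- length(P_in)
  a <- matrix(0, n, ng); v <- matrix(0, n, ng); qs <- matrix(0, n, ng)
  ap <- P_in; vp <- P_out
  Qi <- Tn[[1L]] * (P_in - P_out)
  Q_total <- Qi
  for (i in seq_len(ng)) {
    Ra <- if (is.null(dist$art)) ladder$R_art[i] else ladder$R_art[i] / dist$art[, i]
    Rv <- if (is.null(dist$ven)) ladder$R_ven[i] else ladder$R_ven[i] / dist$ven[, i]
    a[, i] <- ap - Qi * Ra
    v[, i] <- vp + Qi * Rv
    qs[, i] <- gs[, i] * (a[, i] - v[, i])
    Qi <- Tn[[i + 1L]] * (a[, i] - v[, i])
    ap <- a[, i]; vp <- v[, i]
  }
  list(Q_total = Q_total, P_art = a, P_ven = v, Q_sheet = qs)
}

# Secant conductance of each sheet from the closed-form flow; near-equal
# pressures fall back to the local derivative k*H^3.
sheet_secant_conductance <- function(Pa, Pv, cap, g_floor) {
  dP <- Pa - Pv
  q <- sheet_flow(Pa, Pv, cap)
  g <- ifelse(abs(dP) > 1e-9, q / dP, cap$k * sheet_height((Pa + Pv) / 2, cap)^3)
  pmax(g, g_floor)
}

#' Solve one ladder acinus
#'
#' Kirchhoff solution of the series-parallel acinar ladder with rigid
#' Poiseuille chain segments and nonlinear sheet conductances, by damped
#' fixed-point iteration on the sheet secant conductances with an exact chain
#' reduction at each step. A zone-1 acinus (alveolar pressure at or above both
#' boundary blood pressures) carries exactly zero flow.
#'
#' @param P_in Arteriolar inlet blood pressure (Pa).
#' @param P_out Venular outlet blood pressure (Pa).
#' @param P_alv Alveolar pressure (Pa); defaults to the template's value.
#' @param ladder A [ladder_acinus()] template.
#' @param tol Convergence tolerance on rung pressures (Pa).
#' @param max_iter Iteration cap.
#' @param damping Fixed-point damping factor.
#' @param alpha Compliance of the chain segments (1/Pa); 0 gives a rigid
#'   chain, the network solver passes the vessel compliance constant.
#' @return List with `Q_total` (m^3/s), per-rung `sheet_flows`, a `pressures`
#'   tibble, `converged`, `iterations` and the final `residual` (Pa).
#' @export
solve_ladder <- function(P_in, P_out, P_alv = ladder$alveolar_pressure,
                         ladder, tol = 1e-8, max_iter = 200, damping = 0.5,
                         alpha = 0) {
  ng <- ladder$n_gen
  if (P_in <= P_alv && P_out <= P_alv) {
    # all sheets collapsed: no flow, chain pressures equilibrate to the ends
    return(list(Q_total = 0, sheet_flows = rep(0, ng),
                pressures = tibble::tibble(generation = seq_len(ng),
                                           P_art = P_in, P_ven = P_out),
                converged = TRUE, iterations = 0L, residual = 0))
  }
  Pm <- (P_in + P_out) / 2
  gs <- matrix(sheet_secant_conductance(rep(Pm - P_alv, ng), rep(Pm - P_alv, ng) - 1,
                                        ladder$cap, ladder$g_floor),
               nrow = 1)
  prev <- NULL
  Pa_r <- NULL; Pv_r <- NULL
  converged <- FALSE; it <- 0L; resid <- Inf
  while (it < max_iter) {
    it <- it + 1L
    dist <- ladder_distension(ladder, Pa_r, Pv_r, alpha)
    Tn <- ladder_reduce(ladder, gs, dist)
    sw <- ladder_sweep(ladder, gs, Tn, P_in, P_out, dist)
    Pa_r <- sw$P_art; Pv_r <- sw$P_ven
    pr <- cbind(sw$P_art, sw$P_ven)
    if (!is.null(prev)) {
      resid <- max(abs(pr - prev))
      if (resid < tol) { converged <- TRUE; prev <- pr; break }
    }
    prev <- pr
    gs_new <- sheet_secant_conductance(sw$P_art[1, ] - P_alv, sw$P_ven[1, ] - P_alv,
                                       ladder$cap, ladder$g_floor)
    gs <- gs + damping * (rbind(gs_new) - gs)
  }
  dist <- ladder_distension(ladder, Pa_r, Pv_r, alpha)
  Tn <- ladder_reduce(ladder, gs, dist)
  sw <- ladder_sweep(ladder, gs, Tn, P_in, P_out, dist)
  if (!converged && resid > 1e-4)
    warning("ladder iteration did not converge; residual ", signif(resid, 3), " Pa")
  list(Q_total = unname(sw$Q_total[1]), sheet_flows = unname(sw$Q_sheet[1, ]),
       pressures = tibble::tibble(generation = seq_len(ng),
                                  P_art = unname(sw$P_art[1, ]),
                                  P_ven = unname(sw$P_ven[1, ])),
       converged = converged, iterations = it, residual = resid)
}
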