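#' Blood properties
#'
#' Container for the fluid constants entering the modified Poiseuille relation:
#' dynamic viscosity `mu` (Pa s) and density `rho_b` (kg/m^3). Defaults are the
#' population-average values used throughout the package.
#'
#' @param mu Blood viscosity (Pa s).
#' @param rho_b Blood density (kg/m^3).
#' @return A `fluid_properties` list.
#' @export
fluid_properties <- function(mu = 0.0035, rho_b = 1050) {
  stopifnot(mu > 0, rho_b > 0)
  structure(list(mu = mu, rho_b = rho_b), class = "fluid_properties")
}

#' Linear vessel compliance law
#'
#' Vessel diameters respond linearly to transmural pressure,
#' `D = D0 * (1 + alpha * Ptm)`, floored at `floor_frac * D0` so collapsing
#' vessels never produce a degenerate resistance and capped at
#' `ceiling_frac * D0`, the validity range of the linear law (converged
#' physiological states sit well below the cap).
#'
#' @param alpha Compliance constant (1/Pa).
#' @param floor_frac Smallest allowed diameter as a fraction of `D0`.
#' @param ceiling_frac Largest allowed diameter as a fraction of `D0`.
#' @return A `compliance_law` list.
#' @export
compliance_law <- function(alpha = 1.49e-4, floor_frac = 0.1,
                           ceiling_frac = 2) {
  stopifnot(alpha >= 0, floor_frac > 0, floor_frac <= 1, ceiling_frac >= 1)
  structure(list(alpha = alpha, floor_frac = floor_frac,
                 ceiling_frac = ceiling_frac), class = "compliance_law")
}

#' Capillary sheet parameters
#'
#' Parameters of the sheet-flow description of the pulmonary capillary bed.
#' The sheet height H follows a piecewise-linear law in transmural pressure:
#' collapsed (H = 0) below zero, compliant `H = H0 + alpha_c * Ptm` up to the
#' upper recruitment pressure `PCU = (Hmax - H0) / alpha_c`, and saturated at
#' `Hmax` beyond. `SA_total` is the whole-lung capillary surface area; the
#' per-sheet area defaults to an equal split over `n_acini * n_sheets` sheets.
#'
#' @param H0 Unstrained sheet height (m).
#' @param Hmax Maximum sheet height (m).
#' @param alpha_c Sheet compliance (m/Pa).
#' @param mu_c Capillary blood viscosity (Pa s).
#' @param f Dimensionless numerical factor of the sheet-flow relation.
#' @param l_c Mean arteriole-to-venule path length within a sheet (m).
#' @param SA_total Total capillary surface area of both lungs (m^2).
#' @param n_acini Number of acinar units sharing `SA_total`.
#' @param n_sheets Sheets (ladder rungs) per acinus.
#' @param SA_sheet Surface area of a single sheet (m^2); computed when `NULL`.
#' @return A `capillary_sheet_params` list, including derived `PCU` and the
#'   conductance prefactor `k = SA_sheet / (mu_c * f * l_c^2)`.
#' @export
capillary_sheet_params <- function(H0 = 3.5e-6, Hmax = 7.7e-6, alpha_c = 1.3e-9,
                                   mu_c = 0.0019, f = 21.6, l_c = 1186e-6,
                                   SA_total = 65.4, n_acini = 30676, n_sheets = 9,
                                   SA_sheet = NULL) {
  stopifnot(H0 > 0, Hmax > H0, alpha_c > 0, mu_c > 0, f > 0, l_c > 0, SA_total > 0)
  if (is.null(SA_sheet)) SA_sheet <- SA_total / (n_acini * n_sheets)
  structure(list(
    H0 = H0, Hmax = Hmax, alpha_c = alpha_c, mu_c = mu_c, f = f, l_c = l_c,
    SA_total = SA_total, n_acini = n_acini, n_sheets = n_sheets,
    SA_sheet = SA_sheet,
    PCU = (Hmax - H0) / alpha_c,
    k = SA_sheet / (mu_c * f * l_c^2)
  ), class = "capillary_sheet_params")
}

#' Tree growth parameters
#'
#' Controls of the volume-filling branching algorithm: each new branch extends
#' `length_fraction` of the distance from its parent tip to the centroid of the
#' seed subset it claims, its angle to the parent is clamped at
#' `branch_angle_limit`, and branch lengths never fall below
#' `min_branch_length`.
#'
#' @param length_fraction Fraction of tip-to-centroid distance used as branch
#'   length (0 < value < 1).
#' @param branch_angle_limit Maximum branching angle from the parent (degrees).
#' @param min_branch_length Shortest admissible branch (m).
#' @return A `tree_growth_params` list.
#' @export
tree_growth_params <- function(length_fraction = 0.4, branch_angle_limit = 60,
                               min_branch_length = 1.2e-3) {
  stopifnot(length_fraction > 0, length_fraction < 1,
            branch_angle_limit > 0, min_branch_length > 0)
  structure(list(length_fraction = length_fraction,
                 branch_angle_limit = branch_angle_limit,
                 min_branch_length = min_branch_length),
            class = "tree_growth_params")
}

#' Posture and gravity context
#'
#' Defines the gravity vector in anatomical coordinates (+x toward the
#' subject's right, +y ventral, +z cranial). Heights are computed by projecting
#' positions onto the upward direction (-gravity), referenced to the most
#' dependent network node.
#'
#' @param name One of `"zero_g"`, `"supine"`, `"prone"`, `"upright"`,
#'   `"right_lateral"`.
#' @param g Gravitational acceleration magnitude (m/s^2); forced to 0 for
#'   `"zero_g"`.
#' @return A `posture_context` with unit gravity `direction`.
#' @export
posture <- function(name = c("zero_g", "supine", "prone", "upright", "right_lateral"),
                    g = 9.81) {
  name <- match.arg(name)
  dir <- switch(name,
    zero_g        = c(0, 0, -1),
    supine        = c(0, -1, 0),
    prone         = c(0, 1, 0),
    upright       = c(0, 0, -1),
    right_lateral = c(1, 0, 0)
  )
  if (name == "zero_g") g <- 0
  structure(list(name = name, g = g, direction = dir / sqrt(sum(dir^2))),
            class = "posture_context")
}

#' Node heights above the most dependent point
#'
#' Projects positions onto the upward (-gravity) axis. With zero gravity the
#' nominal direction is still used so heights remain defined for plotting.
#'
#' @param xyz Numeric matrix (n x 3) of positions (m).
#' @param posture A [posture()] context.
#' @return Heights (m), minimum 0.
#' @export
node_heights <- function(xyz, posture) {
  h <- -as.numeric(xyz %*% posture$direction)
  h - min(h)
}
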