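#' Boundary conditions for a network solve
#'
#' Flow is prescribed at the arterial inlet (uncoupled runs) or at the two
#' macro interfaces (coupled runs); a single pressure outlet closes the
#' venous side. Extra-vascular pressure is alveolar pressure for vessels with
#' `D0` below 200 um and a linearly height-dependent elastic recoil
#' (tethering) pressure for larger vessels; the negative recoil slope makes
#' tethering strongest in the non-dependent lung, and it scales with the
#' gravity magnitude so it vanishes at zero g.
#'
#' @param inflow Named numeric vector of inflows (m^3/s), names are node ids;
#'   or a single unnamed value applied at the network inlet node.
#' @param outlet_pressure Venous outlet pressure (Pa).
#' @param alveolar_pressure Alveolar pressure (Pa).
#' @param recoil_ref Recoil pressure at mid-height (Pa).
#' @param recoil_slope Recoil change per metre of height (Pa/m) at 1 g.
#' @return A `boundary_conditions` list.
#' @export
boundary_conditions <- function(inflow, outlet_pressure = 666,
                                alveolar_pressure = 0,
                                recoil_ref = -500, recoil_slope = -981) {
  stopifnot(all(inflow >= 0))
  structure(list(inflow = inflow, outlet_pressure = outlet_pressure,
                 alveolar_pressure = alveolar_pressure,
                 recoil_ref = recoil_ref, recoil_slope = recoil_slope),
            class = "boundary_conditions")
}

#' Solver iteration controls
#'
#' @param tol_p Convergence tolerance on nodal pressures (Pa).
#' @param tol_d Convergence tolerance on relative diameter change.
#' @param damping Fixed-point damping factor for diameter and sheet updates.
#' @param max_iter Outer iteration cap.
#' @param acinus_floor Regularizing conductance (m^3 s^-1 Pa^-1) added to each
#'   acinar connector so fully collapsed beds never disconnect the system.
#' @return A `solver_control` list.
#' @export
solver_control <- function(tol_p = 1e-4, tol_d = 1e-6, damping = 0.5,
                           max_iter = 500, acinus_floor = 1e-15) {
  structure(list(tol_p = tol_p, tol_d = tol_d, damping = damping,
                 max_iter = max_iter, acinus_floor = acinus_floor),
            class = "solver_control")
}

#' Pressure drop along a vessel element
#'
#' Modified Poiseuille relation with a hydrostatic term,
#' `dP = 128 mu L Q / (pi D^4) + rho_b g L cos(theta)`, where `theta` is the
#' angle between the element direction (from -> to) and the upward vertical,
#' so that a vessel carrying flow upward incurs a positive hydrostatic drop
#' and one descending into dependent tissue gains pressure. The hydrostatic
#' term applies only to extra-acinar vessels (types `"artery"`, `"vein"`);
#' it is dropped for intra-acinar elements where the resistive term
#' dominates.
#'
#' @param element Data frame of elements with columns `L`, `D` (or `D0`),
#'   `cos_theta` and `type`.
#' @param Q Flow per element (m^3/s).
#' @param fluid [fluid_properties()].
#' @param posture [posture()].
#' @return Pressure drop (Pa), vectorized over rows.
#' @export
element_pressure_drop <- function(element, Q, fluid = fluid_properties(),
                                  posture = pulmoperf::posture("zero_g")) {
  D <- if ("D" %in% names(element)) element$D else element$D0
  if (any(D <= 0)) stop("element diameter must be positive")
  visc <- 128 * fluid$mu * element$L * Q / (pi * D^4)
  hydro <- ifelse(element$type %in% c("artery", "vein"),
                  fluid$rho_b * posture$g * element$L * element$cos_theta, 0)
  visc + hydro
}

#' Compliant diameter update
#'
#' Linear transmural-pressure law `D = D0 (1 + alpha Ptm)`, floored at
#' `floor_frac * D0`.
#'
#' @param element Data frame with column `D0`.
#' @param Ptm Transmural pressure per element (Pa).
#' @param law [compliance_law()].
#' @return Updated diameters (m).
#' @export
update_diameter <- function(element, Ptm, law = compliance_law()) {
  ceil <- law$ceiling_frac %||% 2
  pmin(pmax(element$D0 * (1 + law$alpha * Ptm), law$floor_frac * element$D0),
       ceil * element$D0)
}

#' Extra-vascular pressure of an element
#'
#' Vessels under 200 um diameter feel alveolar pressure; larger vessels feel
#' local elastic recoil, linear in gravitational height about the mid-height
#' reference and scaled by gravity so the gradient vanishes at zero g.
#'
#' @param element Data frame with column `D0`.
#' @param posture [posture()].
#' @param height Element mid-point height (m).
#' @param bcs [boundary_conditions()].
#' @param h_mid Reference mid-height (m); default is the mean of the height range.
#' @return Extra-vascular pressure (Pa) per element.
#' @export
extravascular_pressure <- function(element, posture, height,
                                   bcs = boundary_conditions(0), h_mid = NULL) {
  if (is.null(h_mid)) h_mid <- mean(range(height))
  slope <- bcs$recoil_slope * posture$g / 9.81
  ifelse(element$D0 < 200e-6, bcs$alveolar_pressure,
         bcs$recoil_ref + slope * (height - h_mid))
}

# Assemble and solve the nodal conservation system for fixed conductances.
# f/t: node indices; g: element conductances; hyd: hydrostatic source (Pa);
# dirichlet: (node index, value); src: named inflow by node index.
solve_nodal_system <- function(nn, f, t, g, hyd, dirichlet_node, dirichlet_val, src) {
  # nodes not incident to any element (e.g. central stubs excluded in coupled
  # mode) are left out of the system and reported as NA
  present <- sort(unique(c(f, t)))
  unk <- setdiff(present, dirichlet_node)
  map <- integer(nn); map[unk] <- seq_along(unk)
  i <- c(f, t, f, t); j <- c(f, t, t, f); x <- c(g, g, -g, -g)
  keep <- map[i] > 0 & map[j] > 0
  A <- Matrix::sparseMatrix(i = map[i[keep]], j = map[j[keep]], x = x[keep],
                            dims = c(length(unk), length(unk)))
  b <- numeric(length(unk))
  if (length(src)) b[map[as.integer(names(src))]] <- unname(src)
  gh <- g * hyd
  b_f <- tapply(gh, f, sum); b_t <- tapply(gh, t, sum)
  idx_f <- as.integer(names(b_f)); idx_t <- as.integer(names(b_t))
  kf <- map[idx_f] > 0; kt <- map[idx_t] > 0
  b[map[idx_f[kf]]] <- b[map[idx_f[kf]]] + b_f[kf]
  b[map[idx_t[kt]]] <- b[map[idx_t[kt]]] - b_t[kt]
  # Dirichlet elimination
  touch_f <- t == dirichlet_node
  touch_t <- f == dirichlet_node
  if (any(touch_f)) {
    bf <- tapply(g[touch_f] * dirichlet_val, f[touch_f], sum)
    b[map[as.integer(names(bf))]] <- b[map[as.integer(names(bf))]] + bf
  }
  if (any(touch_t)) {
    bt <- tapply(g[touch_t] * dirichlet_val, t[touch_t], sum)
    b[map[as.integer(names(bt))]] <- b[map[as.integer(names(bt))]] + bt
  }
  p_unk <- as.numeric(Matrix::solve(Matrix::forceSymmetric(A), b))
  P <- rep(NA_real_, nn)
  P[unk] <- p_unk
  P[dirichlet_node] <- dirichlet_val
  P
}

#' Steady-state solution of the 1D circulation
#'
#' Fixed-point outer loop: with diameters and capillary sheet conductances
#' frozen, nodal flow-conservation equations form a sparse symmetric linear
#' system in pressures (hydrostatic heads enter as source terms); the solve
#' then updates transmural pressures, compliant diameters and the acinar
#' ladder secant conductances (each acinus reduced exactly by series-parallel
#' elimination), with damping, until nodal pressures and diameters settle.
#'
#' @param network A `vessel_network`.
#' @param bcs [boundary_conditions()]; a single unnamed inflow is applied at
#'   the inlet node, a named vector at the named nodes (coupled mode: central
#'   arterial elements upstream of the interfaces are excluded).
#' @param posture [posture()].
#' @param fluid [fluid_properties()].
#' @param law [compliance_law()].
#' @param control [solver_control()].
#' @param state0 Optional previous `network_state` used to warm-start the
#'   nonlinear iteration.
#' @return A `network_state`: nodal pressures, element flows and diameters,
#'   per-acinus flows with heights, ladder internals and diagnostics.
#' @export
solve_network <- function(network, bcs, posture, fluid = fluid_properties(),
                          law = compliance_law(), control = solver_control(),
                          state0 = NULL) {
  el <- network$elements
  coupled <- !is.null(names(bcs$inflow)) &&
    setequal(names(bcs$inflow), as.character(unname(network$interface_nodes)))
  if (coupled) {
    drop_ids <- el$id[el$central & el$type == "artery"]
    el <- el[!(el$id %in% drop_ids), ]
  }
  nodes <- network$nodes
  nn <- nrow(nodes)
  node_idx <- function(ids) match(ids, nodes$id)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  h <- -as.numeric(xyz %*% posture$direction)
  h <- h - min(h)
  f <- node_idx(el$from); t <- node_idx(el$to)
  extra <- el$type %in% c("artery", "vein")
  # hydrostatic head: at zero flow P_from - P_to = rho g (h_to - h_from),
  # i.e. pressure rises toward the dependent (low) end of a vessel
  hyd <- ifelse(extra, fluid$rho_b * posture$g * (h[t] - h[f]), 0)
  h_elem <- (h[f] + h[t]) / 2
  Pe <- extravascular_pressure(el, posture, h_elem, bcs, h_mid = mean(range(h)))

  acin <- network$acini
  has_ac <- !is.null(acin) && nrow(acin) > 0
  if (has_ac) {
    ladder <- network$ladder
    ai <- match(acin$element, el$id)
    a_art <- node_idx(acin$node_art); a_ven <- node_idx(acin$node_ven)
    P_alv <- bcs$alveolar_pressure
  }

  # inflow sources
  src <- bcs$inflow
  if (is.null(names(src))) {
    names(src) <- as.character(node_idx(network$inlet_node))
  } else {
    names(src) <- as.character(node_idx(as.integer(names(src))))
  }
  out_idx <- node_idx(network$outlet_node)

  # warm start
  D <- if (!is.null(state0)) state0$internal$D else el$D0
  if (length(D) != nrow(el)) D <- el$D0
  if (has_ac) {
    gs <- if (!is.null(state0) && !is.null(state0$internal$gs)) state0$internal$gs else
      matrix(ladder$cap$k * sheet_height(500, ladder$cap)^3, nrow(acin), ladder$n_gen)
    Pa_rung <- if (!is.null(state0)) state0$internal$Pa_rung else NULL
    Pv_rung <- if (!is.null(state0)) state0$internal$Pv_rung else NULL
  }

  P_prev <- NULL
  converged <- FALSE
  it <- 0L
  max_dp <- Inf; max_dd <- Inf
  while (it < control$max_iter) {
    it <- it + 1L
    g_el <- pi * D^4 / (128 * fluid$mu * el$L)
    if (has_ac) {
      dist <- ladder_distension(ladder, Pa_rung, Pv_rung, law$alpha,
                              law$floor_frac, law$ceiling_frac %||% 2)
      Tn <- ladder_reduce(ladder, gs, dist)
      g_el[ai] <- Tn[[1L]] + control$acinus_floor
    }
    P <- solve_nodal_system(nn, f, t, g_el, hyd, out_idx, bcs$outlet_pressure, src)
    if (has_ac) {
      sw <- ladder_sweep(ladder, gs, Tn, P[a_art], P[a_ven], dist)
      Pa_rung <- sw$P_art; Pv_rung <- sw$P_ven
      gs_new <- sheet_secant_conductance(sw$P_art - P_alv, sw$P_ven - P_alv,
                                         ladder$cap, ladder$g_floor)
      dim(gs_new) <- dim(gs)
      gs <- gs + control$damping * (gs_new - gs)
    }
    Ptm <- (P[f] + P[t]) / 2 - Pe
    D_new <- ifelse(extra, update_diameter(el, Ptm, law), D)
    max_dd <- max(abs(D_new - D) / el$D0)
    D <- D + control$damping * (D_new - D)
    if (!is.null(P_prev)) {
      max_dp <- max(abs(P - P_prev), na.rm = TRUE)
      if (max_dp < control$tol_p && max_dd < control$tol_d) { converged <- TRUE; break }
    }
    P_prev <- P
  }
  # final consistent solve with converged conductances
  g_el <- pi * D^4 / (128 * fluid$mu * el$L)
  if (has_ac) {
    dist <- ladder_distension(ladder, Pa_rung, Pv_rung, law$alpha,
                              law$floor_frac, law$ceiling_frac %||% 2)
    Tn <- ladder_reduce(ladder, gs, dist)
    g_el[ai] <- Tn[[1L]] + control$acinus_floor
  }
  P <- solve_nodal_system(nn, f, t, g_el, hyd, out_idx, bcs$outlet_pressure, src)
  Q <- g_el * (P[f] - P[t] - hyd)
  if (has_ac) sw <- ladder_sweep(ladder, gs, Tn, P[a_art], P[a_ven], dist)

  el_out <- el
  el_out$flow <- Q
  el_out$diameter <- D
  el_out$dP <- P[f] - P[t]
  state <- structure(list(
    nodes = tibble::tibble(id = nodes$id, pressure = P, height = h),
    elements = tibble::as_tibble(el_out),
    acini = if (has_ac) dplyr::mutate(acin, flow = Q[ai], height = h[a_art],
                                      P_art = P[a_art], P_ven = P[a_ven]) else NULL,
    ladder_state = if (has_ac) list(P_art = sw$P_art, P_ven = sw$P_ven,
                                    Q_sheet = sw$Q_sheet) else NULL,
    interface_pressures = if (!anyNA(network$interface_nodes))
      stats::setNames(P[node_idx(network$interface_nodes)],
                      names(network$interface_nodes)) else NULL,
    inlet_pressure = if (!is.na(network$inlet_node) && !coupled)
      P[node_idx(network$inlet_node)] else NA_real_,
    total_inflow = sum(bcs$inflow),
    posture = posture$name,
    converged = converged, iterations = it,
    max_dp = max_dp, max_dd = max_dd,
    internal = list(D = D, gs = if (has_ac) gs else NULL,
                    Pa_rung = if (has_ac) Pa_rung else NULL,
                    Pv_rung = if (has_ac) Pv_rung else NULL, P = P),
    bcs = bcs
  ), class = "network_state")
  if (!converged)
    warning("network solve did not converge in ", control$max_iter,
            " iterations (max |dP| = ", signif(max_dp, 3), " Pa)")
  state
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> posture:", x$posture,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  inflow:", signif(x$total_inflow * 6e4, 4), "L/min;",
      "outer iterations:", x$iterations, "\n")
  if (!is.null(x$acini))
    cat("  acini:", nrow(x$acini), "; total acinar flow:",
        signif(sum(x$acini$flow) * 6e4, 4), "L/min\n")
  invisible(x)
}

#' Tidy a solved network state
#'
#' Returns the per-element results (flow, diameter, pressure drop) as a tibble.
#' @param x A `network_state`.
#' @param ... Unused.
#' @method tidy network_state
#' @export
tidy.network_state <- function(x, ...) {
  x$elements
}

#' One-row summary of a solved network state
#'
#' @param x A `network_state`.
#' @param ... Unused.
#' @method glance network_state
#' @export
glance.network_state <- function(x, ...) {
  tibble::tibble(
    posture = x$posture,
    inflow_L_min = x$total_inflow * 6e4,
    inlet_pressure_Pa = x$inlet_pressure,
    n_acini = if (is.null(x$acini)) 0L else nrow(x$acini),
    acinar_flow_L_min = if (is.null(x$acini)) NA_real_ else sum(x$acini$flow) * 6e4,
    converged = x$converged,
    iterations = x$iterations
  )
}
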