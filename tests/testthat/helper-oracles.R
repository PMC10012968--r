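# Independent oracles used across the suite.

# Adaptive-quadrature oracle for the capillary sheet flow: numerically
# integrates H(Ptm)^3 between the two transmural pressures, splitting at the
# recruitment kinks so the quadrature sees smooth pieces.
sheet_flow_quadrature <- function(Ptm_art, Ptm_ven, params) {
  kinks <- c(0, params$PCU)
  integrand <- function(p) sheet_height(p, params)^3
  lo <- min(Ptm_ven, Ptm_art); hi <- max(Ptm_ven, Ptm_art)
  pts <- sort(unique(c(lo, hi, kinks[kinks > lo & kinks < hi])))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    total <- total + stats::integrate(integrand, pts[i], pts[i + 1],
                                      rel.tol = 1e-12, abs.tol = 0)$value
  }
  sign(Ptm_art - Ptm_ven) * params$k * total
}

# Dense nodal solve of an arbitrary linear conductance network:
# elements (from, to, g, hyd), sources by node, one Dirichlet node.
# Conservation rows assembled from scratch with base R only.
dense_network_solve <- function(nn, from, to, g, hyd = rep(0, length(g)),
                                src = numeric(nn), dirichlet_node, dirichlet_val) {
  A <- matrix(0, nn, nn)
  b <- src
  for (e in seq_along(from)) {
    f <- from[e]; t <- to[e]
    A[f, f] <- A[f, f] + g[e]; A[t, t] <- A[t, t] + g[e]
    A[f, t] <- A[f, t] - g[e]; A[t, f] <- A[t, f] - g[e]
    b[f] <- b[f] + g[e] * hyd[e]
    b[t] <- b[t] - g[e] * hyd[e]
  }
  unk <- setdiff(seq_len(nn), dirichlet_node)
  bb <- b[unk] - A[unk, dirichlet_node, drop = FALSE] %*% dirichlet_val
  P <- numeric(nn)
  P[unk] <- solve(A[unk, unk], bb)
  P[dirichlet_node] <- dirichlet_val
  P
}

# Hand-built toy circulation: two interface nodes, one linear resistor per
# lung to a shared venous node, then an outlet resistor. Used for coupling
# correctness checks against a monolithic solve.
make_linear_toy <- function(R_left = 2e6, R_right = 1.5e6, R_out = 5e5) {
  nodes <- tibble::tibble(id = 1:4,
                          x = c(-0.02, 0.02, 0, 0),
                          y = c(0, 0, 0, 0),
                          z = c(0.1, 0.1, 0.05, 0.02))
  # diameters chosen to realize the requested Poiseuille resistances
  mu <- 0.0035
  d_for <- function(R, L) (128 * mu * L / (pi * R))^(1 / 4)
  L <- c(0.05, 0.05, 0.03)
  elements <- tibble::tibble(
    id = 1:3, from = c(1L, 2L, 3L), to = c(3L, 3L, 4L), type = "artery",
    L = L, D0 = d_for(c(R_left, R_right, R_out), L),
    order = NA_integer_, generation = 0L, lung = c("left", "right", NA),
    central = FALSE, parent = NA_integer_, seed = NA_integer_
  )
  vessel_network(nodes, elements, inlet_node = NA_integer_, outlet_node = 4L,
                 interface_nodes = c(left = 1L, right = 2L))
}

rigid_law <- function() compliance_law(alpha = 0)

# Small but complete anatomic network shared across test files.
small_net <- local({
  net <- NULL
  function(n = 150, seed = 7) {
    if (is.null(net)) net <<- build_pulmonary_network(n_acini = n, seed = seed)
    net
  }
})
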