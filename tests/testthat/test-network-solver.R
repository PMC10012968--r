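fluid <- fluid_properties()

test_that("element pressure drop matches hand arithmetic", {
  el <- tibble::tibble(L = 0.01, D = 0.001, type = "artery", cos_theta = 0)
  expect_equal(element_pressure_drop(el, 0, fluid, posture("upright")), 0)
  expect_equal(element_pressure_drop(el, 1e-6, fluid, posture("upright")),
               1426.0, tolerance = 1e-3)
  el$cos_theta <- 1
  expect_equal(element_pressure_drop(el, 0, fluid, posture("upright")),
               103.0, tolerance = 1e-3)
  # hydrostatic term absent for intra-acinar elements
  el$type <- "arteriole"
  expect_equal(element_pressure_drop(el, 0, fluid, posture("upright")), 0)
  el$D <- -1
  expect_error(element_pressure_drop(el, 0, fluid, posture("upright")), "positive")
})

test_that("compliant diameter update is linear with a floor", {
  el <- tibble::tibble(D0 = 2e-3)
  law <- compliance_law()
  expect_equal(update_diameter(el, 0, law), 2e-3)
  expect_equal(update_diameter(el, 1000, law), 1.149 * 2e-3)
  expect_equal(update_diameter(el, -1e6, law), 0.1 * 2e-3)
})

test_that("extra-vascular pressure switches at 200 um and is linear in height", {
  bcs <- boundary_conditions(0, alveolar_pressure = 0, recoil_ref = -500,
                             recoil_slope = -981)
  up <- posture("upright")
  small <- tibble::tibble(D0 = 100e-6)
  big <- tibble::tibble(D0 = 1e-3)
  expect_equal(extravascular_pressure(small, up, 0.1, bcs, h_mid = 0.1), 0)
  expect_equal(extravascular_pressure(big, up, 0.1, bcs, h_mid = 0.1), -500)
  p1 <- extravascular_pressure(big, up, 0.15, bcs, h_mid = 0.1)
  p2 <- extravascular_pressure(big, up, 0.05, bcs, h_mid = 0.1)
  expect_equal(p1 - p2, -981 * 0.1)
  # the recoil gradient vanishes without gravity
  expect_equal(extravascular_pressure(big, posture("zero_g"), 0.15, bcs, h_mid = 0.1),
               -500)
})

test_that("a single rigid tube recovers the Poiseuille closed form", {
  nodes <- tibble::tibble(id = 1:2, x = 0, y = 0, z = c(0, 0))
  el <- tibble::tibble(id = 1L, from = 1L, to = 2L, type = "artery",
                       L = 0.02, D0 = 2e-3, order = 1L, generation = 0L,
                       lung = NA_character_, central = FALSE,
                       parent = NA_integer_, seed = NA_integer_)
  net <- vessel_network(nodes, el, inlet_node = 1L, outlet_node = 2L)
  Q <- 2e-6
  st <- solve_network(net, boundary_conditions(Q, outlet_pressure = 500),
                      posture("zero_g"), law = rigid_law())
  R <- 128 * fluid$mu * 0.02 / (pi * (2e-3)^4)
  expect_equal(st$inlet_pressure, 500 + R * Q, tolerance = 1e-8)
  expect_equal(st$elements$flow, Q, tolerance = 1e-12)
})

test_that("a symmetric rigid bifurcation splits flow exactly in half", {
  nodes <- tibble::tibble(id = 1:4, x = c(0, 0, -0.01, 0.01), y = 0,
                          z = c(0.04, 0.02, 0, 0))
  el <- tibble::tibble(id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                       type = "artery", L = c(0.02, 0.022, 0.022), D0 = 2e-3,
                       order = NA_integer_, generation = 0L, lung = NA_character_,
                       central = FALSE, parent = NA_integer_, seed = NA_integer_)
  # join the daughters back so a single outlet exists
  el2 <- tibble::tibble(id = 4:5, from = c(3L, 4L), to = c(5L, 5L), type = "vein",
                        L = 0.022, D0 = 2e-3, order = NA_integer_, generation = 0L,
                        lung = NA_character_, central = FALSE,
                        parent = NA_integer_, seed = NA_integer_)
  nodes <- dplyr::bind_rows(nodes, tibble::tibble(id = 5L, x = 0, y = 0, z = -0.02))
  net <- vessel_network(nodes, dplyr::bind_rows(el, el2),
                        inlet_node = 1L, outlet_node = 5L)
  st <- solve_network(net, boundary_conditions(4e-6), posture("zero_g"),
                      law = rigid_law())
  q <- st$elements$flow
  expect_equal(q[2], q[3], tolerance = 1e-12)
  expect_equal(q[2], 2e-6, tolerance = 1e-10)
})

test_that("full network conserves mass at nodes and globally", {
  net <- small_net()
  Q <- 4.8 / 6e4
  st <- solve_network(net, boundary_conditions(Q), posture("supine"))
  expect_true(st$converged)
  expect_equal(sum(st$acini$flow), Q, tolerance = 1e-8)
  # nodal conservation: net element flow at every interior node ~ 0
  el <- st$elements
  div <- tapply(c(-el$flow, el$flow), c(el$from, el$to), sum)
  interior <- setdiff(as.integer(names(div)),
                      c(net$inlet_node, net$outlet_node))
  expect_lt(max(abs(div[as.character(interior)])), 1e-10 * Q)
})

test_that("zero gravity wipes out posture dependence", {
  net <- small_net()
  bcs <- boundary_conditions(4.8 / 6e4)
  st1 <- solve_network(net, bcs, posture("zero_g"))
  p2 <- posture("supine"); p2$g <- 0  # supine axis, no gravity
  st2 <- solve_network(net, bcs, p2)
  expect_equal(st1$nodes$pressure, st2$nodes$pressure, tolerance = 1e-6)
  expect_equal(st1$acini$flow, st2$acini$flow, tolerance = 1e-9)
})

test_that("total pressure drop increases with cardiac output", {
  net <- small_net()
  pin <- vapply(c(3, 4.8, 6.5) / 6e4, function(q) {
    solve_network(net, boundary_conditions(q), posture("zero_g"))$inlet_pressure
  }, numeric(1))
  expect_true(all(diff(pin) > 0))
})

test_that("rigid, saturated network equals a single dense linear solve", {
  net <- build_pulmonary_network(n_acini = 40, seed = 13, diameter_cv = 0)
  Q <- 40 * 8e-9
  # strongly negative alveolar pressure saturates every sheet (H = Hmax)
  bcs <- boundary_conditions(Q, outlet_pressure = 600, alveolar_pressure = -1e6,
                             recoil_ref = 0, recoil_slope = 0)
  st <- solve_network(net, bcs, posture("zero_g"), law = rigid_law())

  # oracle: expand each acinus into its 18-node ladder with constant sheet
  # conductance k*Hmax^3, assemble the whole linear system densely
  el <- net$elements
  lad <- net$ladder
  nn0 <- nrow(net$nodes)
  extra <- el$type != "acinus"
  from <- el$from[extra]; to <- el$to[extra]
  g <- pi * el$D0[extra]^4 / (128 * fluid$mu * el$L[extra])
  nn <- nn0
  gs_const <- lad$cap$k * lad$cap$Hmax^3
  for (i in seq_len(nrow(net$acini))) {
    arts <- nn + 1:9; vens <- nn + 10:18; nn <- nn + 18L
    from <- c(from, c(net$acini$node_art[i], arts[1:8]),
              vens, c(net$acini$node_ven[i], vens[1:8]))
    to <- c(to, arts, arts, vens)
    g <- c(g, 1 / lad$R_art, rep(gs_const, 9), 1 / lad$R_ven)
  }
  src <- numeric(nn)
  src[net$inlet_node] <- Q
  P_ref <- dense_network_solve(nn, from, to, g, src = src,
                               dirichlet_node = net$outlet_node,
                               dirichlet_val = 600)
  expect_equal(st$nodes$pressure[net$inlet_node], P_ref[net$inlet_node],
               tolerance = 1e-6)
  expect_equal(st$acini$P_art, P_ref[net$acini$node_art], tolerance = 1e-5)
})
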