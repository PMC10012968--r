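test_that("lung shapes split volume as requested and reject bad input", {
  sh <- generate_lung_shapes(6.8e-3, 0.525)
  expect_equal(sh$right$volume, 3.57e-3, tolerance = 0.005)
  expect_equal(sh$right$volume / (sh$left$volume + sh$right$volume), 0.525,
               tolerance = 1e-10)
  expect_equal(shape_volume(sh$right), sh$right$volume, tolerance = 1e-12)

  even <- generate_lung_shapes(4e-3, 0.5)
  expect_equal(even$left$semi, even$right$semi)
  expect_equal(even$left$volume, even$right$volume)

  expect_error(generate_lung_shapes(-1, 0.5), "positive")
  expect_error(generate_lung_shapes(4e-3, 1.2), "right_fraction")
})

test_that("lung shapes do not overlap", {
  sh <- generate_lung_shapes()
  expect_gt(sh$right$center[1] - sh$right$semi[1],
            sh$left$center[1] + sh$left$semi[1])
})

test_that("membership test agrees with analytic volume under Monte Carlo", {
  sh <- generate_lung_shapes()$right
  set.seed(42)
  n <- 2e5
  lo <- sh$center - c(sh$semi[1], sh$semi[2], 0)
  hi <- sh$center + sh$semi
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  box <- prod(hi - lo)
  mc_vol <- box * mean(in_lung_shape(sh, pts))
  expect_equal(mc_vol, shape_volume(sh), tolerance = 0.01)
})

test_that("acinar seeding is counted, interior, quasi-uniform and deterministic", {
  sh <- generate_lung_shapes()$left
  s1 <- seed_acini(sh, 300, seed = 11)
  expect_equal(nrow(s1$points), 300)
  expect_true(all(in_lung_shape(sh, s1$points)))

  d <- as.matrix(dist(s1$points))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.5)

  s2 <- seed_acini(sh, 300, seed = 11)
  expect_identical(s1$points, s2$points)
  s3 <- seed_acini(sh, 300, seed = 12)
  expect_false(identical(s1$points, s3$points))
})

test_that("a single seed grows a single branch toward that point", {
  tmpl <- central_arterial_template()
  sh <- generate_lung_shapes()$left
  seeds <- seed_acini(sh, 1, seed = 3)
  net <- grow_volume_filling_tree(tmpl, seeds, tree_growth_params())
  new_el <- net$elements[!net$elements$central, ]
  expect_equal(nrow(new_el), 1L)
  tip <- as.numeric(net$nodes[match(new_el$to, net$nodes$id), c("x", "y", "z")])
  start <- as.numeric(net$nodes[match(new_el$from, net$nodes$id), c("x", "y", "z")])
  v1 <- tip - start; v2 <- seeds$points[1, ] - start
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  expect_gt(cosang, 0.999)  # branch points at the seed
})

test_that("volume-filling growth closes one terminal per seed, inside the shape", {
  tmpl <- central_arterial_template()
  sh <- generate_lung_shapes()$right
  n <- 120
  seeds <- seed_acini(sh, n, seed = 5)
  params <- tree_growth_params()
  net <- grow_volume_filling_tree(tmpl, seeds, params)
  el <- net$elements[!net$elements$central, ]
  term <- el[!(el$to %in% el$from), ]
  expect_equal(nrow(term), n)

  tp <- as.matrix(net$nodes[match(term$to, net$nodes$id), c("x", "y", "z")])
  expect_true(all(in_lung_shape(sh, tp)))

  # space filling at realistic seeding density: nearly every seed lies
  # within 2 cm of some terminal
  dense <- seed_acini(sh, 600, seed = 6)
  net2 <- grow_volume_filling_tree(tmpl, dense, params)
  el2 <- net2$elements[!net2$elements$central, ]
  tp2 <- as.matrix(net2$nodes[match(el2$to[!(el2$to %in% el2$from)],
                                    net2$nodes$id), c("x", "y", "z")])
  d2 <- outer(rowSums(dense$points^2), rowSums(tp2^2), "+") -
    2 * dense$points %*% t(tp2)
  expect_gt(mean(sqrt(pmax(apply(d2, 1, min), 0)) < 0.02), 0.99)

  # branching angle limit holds for internal branches
  pos <- function(ids) as.matrix(net$nodes[match(ids, net$nodes$id), c("x", "y", "z")])
  internal <- el[el$to %in% el$from, ]
  par_idx <- match(internal$parent, net$elements$id)
  pe <- net$elements[par_idx, ]
  u <- pos(internal$to) - pos(internal$from)
  v <- pos(internal$from) - pos(pe$from)
  cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  expect_true(all(cosang >= cos(params$branch_angle_limit * pi / 180) - 1e-9))

  # element lengths equal node distances and respect the minimum
  expect_equal(el$L, sqrt(rowSums((pos(el$to) - pos(el$from))^2)), tolerance = 1e-12)
})

test_that("identical seeds give byte-identical networks", {
  n1 <- build_pulmonary_network(n_acini = 60, seed = 21)
  n2 <- build_pulmonary_network(n_acini = 60, seed = 21)
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$elements, n2$elements)
})

test_that("Strahler radii follow the diameter ratio and stay monotone", {
  # two-level symmetric hand tree
  nodes <- tibble::tibble(id = 1:4, x = c(0, 0, -0.01, 0.01),
                          y = 0, z = c(0, -0.02, -0.04, -0.04))
  elements <- tibble::tibble(
    id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L), type = "artery",
    L = 0.02, D0 = 1e-3, order = NA_integer_, generation = 1L,
    lung = "left", central = FALSE, parent = c(NA, 1L, 1L), seed = NA_integer_)
  tree <- vessel_network(nodes, elements)
  tree <- assign_strahler_radii(tree, 0.02, 1.52, element_ids = 1:3)
  expect_equal(tree$elements$order, c(2L, 1L, 1L))
  expect_equal(tree$elements$D0, c(0.02, 0.02 / 1.52, 0.02 / 1.52))

  # single element keeps the inlet diameter
  one <- vessel_network(nodes[1:2, ], elements[1, ])
  one <- assign_strahler_radii(one, 0.015, 1.52, element_ids = 1L)
  expect_equal(one$elements$D0, 0.015)

  # a non-tree subset is rejected
  cyc <- elements
  cyc$to[3] <- 3L  # duplicate node use -> not a tree
  bad <- vessel_network(nodes, cyc)
  expect_error(assign_strahler_radii(bad, 0.02, 1.52, element_ids = 1:3),
               "not a tree")

  # generated tree: mean log-diameter regression on order recovers the ratio,
  # and diameters never increase from root to leaf despite scatter
  net <- small_net()
  art <- net$elements[net$elements$type == "artery" & !net$elements$central, ]
  mld <- tapply(log(art$D0), art$order, mean)
  fit <- stats::lm(mld ~ as.numeric(names(mld)))
  expect_equal(unname(exp(stats::coef(fit)[2])), 1.52, tolerance = 0.05)
  par_D <- art$D0[match(art$parent, art$id)]
  expect_true(all(art$D0 <= par_D + 1e-15, na.rm = TRUE))
})

test_that("venous mirror preserves topology and applies the venous ratio", {
  tmpl <- central_arterial_template()
  sh <- generate_lung_shapes()$left
  seeds <- seed_acini(sh, 80, seed = 9)
  net <- grow_volume_filling_tree(tmpl, seeds, tree_growth_params())
  ids <- net$elements$id[!net$elements$central]
  net <- assign_strahler_radii(net, 0.0219, 1.52, element_ids = ids)
  ven <- mirror_venous_network(net, ratio = 1.56, art_ratio = 1.52)

  mirrored <- ven$elements[!ven$elements$central, ]
  expect_equal(nrow(mirrored), length(ids))
  expect_true(all(mirrored$type == "vein"))

  # terminals co-located with arterial terminals
  a_el <- net$elements[!net$elements$central, ]
  a_term <- a_el$to[!(a_el$to %in% a_el$from)]
  v_term <- setdiff(ven$elements$from, ven$elements$to)
  pa <- as.matrix(net$nodes[match(a_term, net$nodes$id), c("x", "y", "z")])
  pv <- as.matrix(ven$nodes[match(v_term, ven$nodes$id), c("x", "y", "z")])
  expect_equal(sort(pa[, 1]), sort(pv[, 1]), tolerance = 1e-12)
  expect_equal(sort(pa[, 3]), sort(pv[, 3]), tolerance = 1e-12)

  # diameters follow root_D * 1.56^(order - omax) (no scatter here);
  # mirrored rows are aligned with the arterial rows
  omax <- max(mirrored$order)
  rootD <- a_el$D0[which(mirrored$order == omax)[1]]
  expect_equal(mirrored$D0, rootD * 1.56^(mirrored$order - omax), tolerance = 1e-9)
})

test_that("the full circulation is closed, connected, and one acinus per terminal", {
  net <- small_net()
  expect_equal(nrow(net$acini), 150)
  expect_equal(sum(net$elements$type == "acinus"), 150)

  # BFS from an interface node must reach the venous outlet
  adj <- split(c(net$elements$to, net$elements$from),
               c(net$elements$from, net$elements$to))
  seen <- new.env()
  queue <- unname(net$interface_nodes[1])
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    key <- as.character(v)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    queue <- c(queue, adj[[key]])
  }
  expect_true(!is.null(seen[[as.character(net$outlet_node)]]))

  # mismatched terminals are rejected
  tmpl <- central_arterial_template()
  sh <- generate_lung_shapes()$left
  seeds <- seed_acini(sh, 20, seed = 2)
  art <- grow_volume_filling_tree(tmpl, seeds, tree_growth_params())
  ids <- art$elements$id[!art$elements$central]
  art <- assign_strahler_radii(art, 0.02, 1.52, element_ids = ids)
  ven <- mirror_venous_network(art)
  ven$nodes$x <- ven$nodes$x + 0.001  # break co-location
  expect_error(build_full_circulation(art, ven, small_net()$ladder), "unmatched")
})
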