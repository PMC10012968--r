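#' Vessel network container
#'
#' Assembles nodes, elements and designated boundary nodes into a
#' `vessel_network`. Elements store their centerline length `L`, unstrained
#' diameter `D0`, a `type` (artery, vein or acinus connector), Strahler
#' `order`, `generation`, owning `lung`, a `central` flag for the
#' main/left/right pulmonary trunk vessels, and the `parent` element id.
#'
#' @param nodes Tibble with columns `id, x, y, z` (SI metres).
#' @param elements Tibble with columns
#'   `id, from, to, type, L, D0, order, generation, lung, central, parent`.
#' @param inlet_node,outlet_node Node ids of the arterial inlet and venous
#'   outlet (NA when absent).
#' @param interface_nodes Named integer vector (`left`, `right`) of 1D/macro
#'   interface nodes.
#' @param acini Tibble of acinar units (`id, element, node_art, node_ven,
#'   x, y, z, lung`) or `NULL`.
#' @param ladder A [ladder_acinus()] template shared by all acini, or `NULL`.
#' @param meta Free-form list of provenance (seed, counts, shapes).
#' @return A `vessel_network` object.
#' @export
vessel_network <- function(nodes, elements, inlet_node = NA_integer_,
                           outlet_node = NA_integer_,
                           interface_nodes = c(left = NA_integer_, right = NA_integer_),
                           acini = NULL, ladder = NULL, meta = list()) {
  nodes <- tibble::as_tibble(nodes)
  elements <- tibble::as_tibble(elements)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)),
            all(c("id", "from", "to", "type", "L", "D0") %in% names(elements)))
  if (nrow(elements) && any(elements$L <= 0)) stop("element lengths must be positive")
  if (nrow(elements) && any(elements$D0 <= 0)) stop("element diameters must be positive")
  structure(list(nodes = nodes, elements = elements, inlet_node = inlet_node,
                 outlet_node = outlet_node, interface_nodes = interface_nodes,
                 acini = acini, ladder = ladder, meta = meta),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network>\n")
  cat("  nodes:    ", nrow(x$nodes), "\n")
  cat("  elements: ", nrow(x$elements), " (",
      paste(names(table(x$elements$type)), table(x$elements$type),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  acini:    ", if (is.null(x$acini)) 0 else nrow(x$acini), "\n")
  invisible(x)
}

node_xyz <- function(net, ids) {
  idx <- match(ids, net$nodes$id)
  cbind(net$nodes$x[idx], net$nodes$y[idx], net$nodes$z[idx])
}

#' Generate synthetic left and right lung shapes
#'
#' Stand-in for imaging-derived lobe surfaces: each lung is the upper half of
#' an ellipsoid (clipped at its basal plane), convex, with the right lung
#' occupying `right_fraction` of the total volume. The two shapes are
#' laterally separated (mediastinal gap) and the right lung is displaced
#' slightly dorsally, the left slightly ventrally, so that the volume of
#' dependent tissue differs between postures.
#'
#' @param total_volume Combined lung volume (m^3).
#' @param right_fraction Fraction of volume in the right lung (0-1).
#' @param depth Half ventro-dorsal semi-axis b (m).
#' @param height Cranio-caudal semi-axis c (m); the half-ellipsoid spans
#'   `[0, height]` in z.
#' @param dv_offset Dorso-ventral displacement of the lung centres (m);
#'   right lung moves dorsal by this amount, left ventral.
#' @return List with `left` and `right` `lung_shape` objects.
#' @export
generate_lung_shapes <- function(total_volume = 4.0e-3, right_fraction = 0.525,
                                 depth = 0.075, height = 0.24, dv_offset = 0.008) {
  if (total_volume <= 0) stop("total_volume must be positive")
  if (right_fraction <= 0 || right_fraction >= 1) stop("right_fraction must be in (0,1)")
  mk <- function(side, vol, sgn_x, cy) {
    a <- vol / ((2 / 3) * pi * depth * height)
    center <- c(sgn_x * (0.013 + a), cy, 0)
    structure(list(side = side, center = center, semi = c(a, depth, height),
                   volume = vol), class = "lung_shape")
  }
  list(left  = mk("left",  total_volume * (1 - right_fraction), -1, +dv_offset),
       right = mk("right", total_volume * right_fraction,       +1, -dv_offset))
}

#' Analytic volume of a lung shape
#' @param shape A `lung_shape`.
#' @return Volume (m^3) of the half-ellipsoid.
#' @export
shape_volume <- function(shape) {
  (2 / 3) * pi * prod(shape$semi)
}

#' Membership test for a lung shape
#'
#' @param shape A `lung_shape`.
#' @param pts Numeric matrix (n x 3) of positions.
#' @return Logical vector: inside the clipped half-ellipsoid.
#' @export
in_lung_shape <- function(shape, pts) {
  pts <- rbind(pts)
  dx <- sweep(pts, 2, shape$center)
  r2 <- (dx[, 1] / shape$semi[1])^2 + (dx[, 2] / shape$semi[2])^2 +
    (dx[, 3] / shape$semi[3])^2
  r2 <= 1 & pts[, 3] >= shape$center[3]
}

#' Seed acinar locations inside a lung shape
#'
#' Quasi-uniform seeds: a cubic grid at the spacing implied by the target
#' count, jittered by at most `jitter` of the spacing, clipped to the shape.
#' The grid is densified until at least `n` interior points exist, then
#' exactly `n` are retained (random thinning, seeded).
#'
#' @param shape A `lung_shape`.
#' @param n Number of seeds requested.
#' @param jitter Jitter amplitude as a fraction of grid spacing.
#' @param seed RNG seed; identical seeds give identical point sets.
#' @return A `seed_point_set`: list with `points` (n x 3 matrix) and `shape`.
#' @export
seed_acini <- function(shape, n, jitter = 0.2, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  s <- (shape_volume(shape) / n)^(1 / 3)
  lo <- shape$center - c(shape$semi[1], shape$semi[2], 0)
  hi <- shape$center + shape$semi
  repeat {
    gx <- seq(lo[1] + s / 2, hi[1], by = s)
    gy <- seq(lo[2] + s / 2, hi[2], by = s)
    gz <- seq(lo[3] + s / 2, hi[3], by = s)
    g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    g <- g + matrix(stats::runif(length(g), -jitter * s, jitter * s), ncol = 3)
    keep <- in_lung_shape(shape, g)
    if (sum(keep) >= n) break
    s <- s * 0.93  # densify
  }
  pts <- g[keep, , drop = FALSE]
  pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
  structure(list(points = unname(pts), shape = shape), class = "seed_point_set")
}

# -- internal growth machinery -------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Split a seed subset by the plane containing the parent direction and the
# subset centroid; degenerate configurations fall back to a median split
# along the axis of largest spread (guaranteed non-empty halves).
split_seed_subset <- function(pts, tip, dir) {
  ctr <- colMeans(pts)
  nrm <- cross3(dir, ctr - tip)
  nn <- sqrt(sum(nrm^2))
  if (nn > 1e-12) {
    side <- as.numeric(sweep(pts, 2, ctr) %*% (nrm / nn)) > 0
    if (any(side) && any(!side)) return(list(which(side), which(!side)))
  }
  spread <- apply(pts, 2, function(v) diff(range(v)))
  ax <- which.max(spread)
  ord <- order(pts[, ax])
  half <- length(ord) %/% 2L
  list(ord[seq_len(half)], ord[-seq_len(half)])
}

# Grow a bifurcating volume-filling tree from one tip into a seed cloud.
# Returns new nodes/elements in local numbering; local node 0 is the root tip.
grow_tree_core <- function(root_pos, root_dir, seeds, params) {
  n <- nrow(seeds)
  cap_nodes <- 4L * n + 8L
  npos <- matrix(NA_real_, cap_nodes, 3)
  efrom <- integer(cap_nodes); eto <- integer(cap_nodes)
  eparent <- integer(cap_nodes); egen <- integer(cap_nodes)
  eseed <- rep(NA_integer_, cap_nodes)  # seed index for terminal elements
  nn <- 0L; ne <- 0L
  cos_lim <- cos(params$branch_angle_limit * pi / 180)
  lf <- params$length_fraction; min_len <- params$min_branch_length

  add_branch <- function(tip_node, tip_pos, dir, subset, parent_elem, gen) {
    # returns list(node, pos, dir) of the created branch end, or NULL (pruned)
    k <- length(subset)
    target <- if (k == 1L) seeds[subset, ] else colMeans(seeds[subset, , drop = FALSE])
    vec <- target - tip_pos
    d <- sqrt(sum(vec^2))
    if (d < 1e-9) return(NULL)
    u <- vec / d
    if (k > 1L) {
      ca <- sum(u * dir)
      if (ca < cos_lim) {  # clamp branching angle toward the parent direction
        w <- u - ca * dir
        nw <- sqrt(sum(w^2))
        if (nw > 1e-12) u <- cos_lim * dir + sqrt(1 - cos_lim^2) * (w / nw)
      }
    }
    len <- max(lf * d, min_len)
    if (k == 1L) len <- min(len, d)  # terminal branches close on their seed
    pos <- tip_pos + u * len
    nn <<- nn + 1L; npos[nn, ] <<- pos
    ne <<- ne + 1L
    efrom[ne] <<- tip_node; eto[ne] <<- nn
    eparent[ne] <<- parent_elem; egen[ne] <<- gen
    eseed[ne] <<- if (k == 1L) subset else NA_integer_
    list(node = nn, pos = pos, dir = u, elem = ne)
  }

  stack <- list(list(node = 0L, pos = root_pos, dir = root_dir,
                     subset = seq_len(n), parent = 0L, gen = 0L))
  pruned <- 0L
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sub <- cur$subset
    if (length(sub) == 1L) {
      br <- add_branch(cur$node, cur$pos, cur$dir, sub, cur$parent, cur$gen + 1L)
      if (is.null(br)) pruned <- pruned + 1L
      next
    }
    halves <- split_seed_subset(seeds[sub, , drop = FALSE], cur$pos, cur$dir)
    for (h in halves) {
      if (!length(h)) { pruned <- pruned + length(h); next }
      br <- add_branch(cur$node, cur$pos, cur$dir, sub[h], cur$parent, cur$gen + 1L)
      if (is.null(br)) { pruned <- pruned + length(h); next }
      # singleton subsets close immediately with their terminal branch
      if (length(h) > 1L)
        stack[[length(stack) + 1L]] <- list(node = br$node, pos = br$pos,
                                            dir = br$dir, subset = sub[h],
                                            parent = br$elem, gen = cur$gen + 1L)
    }
  }
  sel <- seq_len(ne)
  list(nodes = npos[seq_len(nn), , drop = FALSE],
       from = efrom[sel], to = eto[sel], parent = eparent[sel], gen = egen[sel],
       seed = eseed[sel], pruned = pruned)
}

#' Grow a volume-filling branching tree
#'
#' Recursive bisection growth into a cloud of acinar seed points: the seed
#' subset of each active tip is split by the plane containing the parent
#' direction and the subset centroid, and a branch grows toward each
#' sub-centroid covering `length_fraction` of the distance, with the
#' branching angle clamped and a minimum branch length enforced. Subsets of
#' one seed close with a terminal branch toward that seed. Growth starts from
#' the terminal of `initial_tree` nearest the seed cloud.
#'
#' @param initial_tree A `vessel_network` with at least one terminal element
#'   near the seeded shape (e.g. [central_arterial_template()]).
#' @param seeds A [seed_acini()] point set.
#' @param params [tree_growth_params()].
#' @param rng_seed Unused source of randomness kept for interface stability;
#'   growth is deterministic given its inputs.
#' @return The network extended with the grown elements (type `"artery"`,
#'   `lung` set from the seed shape side).
#' @export
grow_volume_filling_tree <- function(initial_tree, seeds, params = tree_growth_params(),
                                     rng_seed = 1L) {
  net <- initial_tree
  term <- setdiff(net$elements$to, net$elements$from)
  tpos <- node_xyz(net, term)
  ctr <- colMeans(seeds$points)
  d2 <- rowSums(sweep(tpos, 2, ctr)^2)
  root_node <- term[which.min(d2)]
  root_elem <- net$elements$id[net$elements$to == root_node]
  rp <- as.numeric(node_xyz(net, root_node))
  fp <- as.numeric(node_xyz(net, net$elements$from[net$elements$id == root_elem]))
  root_dir <- (rp - fp) / sqrt(sum((rp - fp)^2))

  gr <- grow_tree_core(rp, root_dir, seeds$points, params)
  n_new <- nrow(gr$nodes)
  node_off <- max(net$nodes$id)
  elem_off <- max(net$elements$id)
  map_node <- function(i) ifelse(i == 0L, root_node, i + node_off)
  new_nodes <- tibble::tibble(id = seq_len(n_new) + node_off,
                              x = gr$nodes[, 1], y = gr$nodes[, 2], z = gr$nodes[, 3])
  from_ids <- map_node(gr$from)
  to_ids <- gr$to + node_off
  fpos <- rbind(gr$nodes, rp)[ifelse(gr$from == 0L, n_new + 1L, gr$from), , drop = FALSE]
  tpos2 <- gr$nodes[gr$to, , drop = FALSE]
  L <- as.numeric(sqrt(rowSums((tpos2 - fpos)^2)))
  new_elems <- tibble::tibble(
    id = seq_along(gr$from) + elem_off,
    from = from_ids, to = to_ids, type = "artery",
    L = L, D0 = 1e-3,  # placeholder until Strahler radii are assigned
    order = NA_integer_,
    generation = gr$gen,
    lung = seeds$shape$side,
    central = FALSE,
    parent = ifelse(gr$parent == 0L, root_elem, gr$parent + elem_off),
    seed = gr$seed
  )
  if (!"seed" %in% names(net$elements)) net$elements$seed <- NA_integer_
  net$nodes <- dplyr::bind_rows(net$nodes, new_nodes)
  net$elements <- dplyr::bind_rows(net$elements, new_elems)
  net$meta$pruned <- (net$meta$pruned %||% 0L) + gr$pruned
  net
}

# Strahler orders for a set of elements linked by parent ids (leaf -> root).
strahler_orders <- function(ids, parent) {
  ne <- length(ids)
  ord <- integer(ne)
  idx_of <- match(parent, ids)           # NA for subtree roots
  kids <- split(seq_len(ne), factor(idx_of, levels = seq_len(ne)))
  for (i in rev(seq_len(ne))) {          # creation order: parents precede children
    ch <- kids[[i]]
    if (!length(ch)) { ord[i] <- 1L } else {
      m <- max(ord[ch])
      ord[i] <- m + as.integer(sum(ord[ch] == m) >= 2L)
    }
  }
  ord
}

#' Assign diameters by Strahler order
#'
#' Computes Strahler orders leaf-to-root over a (sub)tree of elements and sets
#' unstrained diameters `D0(order) = inlet_diameter * ratio^(order - max_order)`,
#' so diameters are non-increasing from root to leaf along every path.
#'
#' @param tree A `vessel_network`.
#' @param inlet_diameter Diameter of the highest-order (root) element (m).
#' @param ratio Strahler diameter ratio (> 1).
#' @param element_ids Elements forming the tree to process (default: all
#'   non-central elements). Elements whose parent lies outside the subset are
#'   treated as subtree roots.
#' @param diameter_cv Within-order lognormal diameter scatter (coefficient of
#'   variation); 0 (default) gives the exact order formula. Scatter is
#'   mean-preserving, skips subtree roots, and children are clamped to their
#'   parent diameter so monotonicity holds.
#' @param rng_seed Seed for the scatter draws.
#' @param max_order Reference order carrying `inlet_diameter`; defaults to the
#'   subtree's own maximum. Supplying a common value across subtrees anchors
#'   them at the same anatomical level.
#' @return The network with `order` and `D0` filled in for the subset.
#' @export
assign_strahler_radii <- function(tree, inlet_diameter, ratio,
                                  element_ids = NULL, diameter_cv = 0,
                                  rng_seed = 1L, max_order = NULL) {
  stopifnot(ratio > 1, inlet_diameter > 0, diameter_cv >= 0)
  el <- tree$elements
  if (is.null(element_ids)) element_ids <- el$id[!el$central]
  sel <- match(element_ids, el$id)
  if (length(unique(c(el$from[sel], el$to[sel]))) != length(sel) + 1L)
    stop("element subset is not a tree (cycle or disconnection detected)")
  ord <- strahler_orders(el$id[sel], el$parent[sel])
  if (is.null(max_order)) max_order <- max(ord)
  D <- inlet_diameter * ratio^(ord - max_order)
  if (diameter_cv > 0) {
    set.seed(rng_seed)
    sig <- sqrt(log(1 + diameter_cv^2))
    fac <- exp(stats::rnorm(length(sel), -sig^2 / 2, sig))
    parent_idx <- match(el$parent[sel], el$id[sel])   # NA at subtree roots
    fac[is.na(parent_idx)] <- 1
    D <- D * fac
    for (i in seq_along(sel)) {                       # parents precede children
      p <- parent_idx[i]
      if (!is.na(p)) D[i] <- min(D[i], D[p])
    }
  }
  el$order[sel] <- ord
  el$D0[sel] <- D
  tree$elements <- el
  tree
}

#' Mirror an arterial network into a venous one
#'
#' The venous structure follows the arterial one: identical topology and node
#' positions, reversed flow direction (terminal to root), and diameters
#' re-derived from the same Strahler orders with the venous diameter ratio.
#' Non-central arterial elements are mirrored per lung; the venous subtree
#' roots (at the hila) are then joined by main-vein trunks to a single venous
#' outlet node placed at `outlet_pos`.
#'
#' @param arterial A `vessel_network` with Strahler orders assigned.
#' @param ratio Venous Strahler diameter ratio.
#' @param art_ratio Arterial ratio the mirrored diameters are rescaled from,
#'   so any within-order scatter of the arterial tree carries over.
#' @param inlet_diameters Named vector (`left`, `right`): venous root
#'   diameters; defaults to the arterial root diameters of each lung.
#' @param outlet_pos Position of the venous outlet (left atrium); default sits
#'   between and slightly caudal to the interface nodes.
#' @return A `vessel_network` of type-`"vein"` elements with `outlet_node` set.
#' @export
mirror_venous_network <- function(arterial, ratio = 1.56, art_ratio = 1.52,
                                  inlet_diameters = NULL, outlet_pos = NULL) {
  el <- arterial$elements[!arterial$elements$central, ]
  used <- sort(unique(c(el$from, el$to)))
  pos <- node_xyz(arterial, used)
  nodes <- tibble::tibble(id = seq_along(used), x = pos[, 1], y = pos[, 2], z = pos[, 3])
  remap <- function(i) match(i, used)
  new_el <- tibble::tibble(
    id = seq_len(nrow(el)),
    from = remap(el$to), to = remap(el$from),  # reversed: terminal -> root
    type = "vein", L = el$L, D0 = el$D0, order = el$order,
    generation = el$generation, lung = el$lung, central = FALSE,
    parent = match(el$parent, el$id), seed = el$seed
  )
  omax_all <- max(new_el$order)
  for (lg in unique(new_el$lung)) {
    sel <- which(new_el$lung == lg)
    omax <- omax_all
    venD <- el$D0[sel] * (ratio / art_ratio)^(new_el$order[sel] - omax)
    root_row <- sel[is.na(new_el$parent[sel])][1]
    if (!is.null(inlet_diameters))
      venD <- venD * inlet_diameters[[lg]] / el$D0[root_row]
    new_el$D0[sel] <- venD
  }
  # venous subtree roots: elements whose parent is outside the mirrored set
  roots <- which(is.na(new_el$parent))
  root_nodes <- new_el$to[roots]
  if (is.null(outlet_pos)) {
    rp <- as.matrix(nodes[match(root_nodes, nodes$id), c("x", "y", "z")])
    outlet_pos <- colMeans(rp) + c(0, -0.005, -0.035)
  }
  out_id <- nrow(nodes) + 1L
  nodes <- dplyr::bind_rows(nodes, tibble::tibble(id = out_id, x = outlet_pos[1],
                                                  y = outlet_pos[2], z = outlet_pos[3]))
  mains <- tibble::tibble(
    id = nrow(new_el) + seq_along(root_nodes),
    from = root_nodes, to = out_id, type = "vein",
    L = sqrt(rowSums(sweep(as.matrix(nodes[match(root_nodes, nodes$id),
                                           c("x", "y", "z")]), 2, outlet_pos)^2)),
    D0 = new_el$D0[roots] * ratio, order = max(new_el$order, na.rm = TRUE) + 1L,
    generation = 0L, lung = new_el$lung[roots], central = TRUE,
    parent = NA_integer_, seed = NA_integer_
  )
  vessel_network(nodes, dplyr::bind_rows(new_el, mains),
                 outlet_node = out_id,
                 meta = list(mirrored_from = "arterial"))
}

#' Central arterial template
#'
#' Fixed initial tree for growth: the main pulmonary artery splitting into
#' left and right pulmonary artery stubs whose cross-sectional areas match the
#' macro-model branches. The stub ends are the 1D/macro interface nodes,
#' placed at the hila (60% of cranio-caudal lung height, ventral of centre).
#'
#' @param mpa_area,lpa_area,rpa_area Cross-sectional areas (m^2).
#' @param hilum_left,hilum_right,inlet_pos,junction_pos Positions (m).
#' @return A `vessel_network` of the three central elements.
#' @export
central_arterial_template <- function(mpa_area = 7.72e-4, lpa_area = 3.77e-4,
                                      rpa_area = 3.54e-4,
                                      hilum_left = c(-0.042, 0.005, 0.15),
                                      hilum_right = c(0.045, 0.005, 0.15),
                                      inlet_pos = c(0, 0.03, 0.11),
                                      junction_pos = c(0, 0.02, 0.14)) {
  d <- function(a) sqrt(4 * a / pi)
  nodes <- tibble::tibble(
    id = 1:4,
    x = c(inlet_pos[1], junction_pos[1], hilum_left[1], hilum_right[1]),
    y = c(inlet_pos[2], junction_pos[2], hilum_left[2], hilum_right[2]),
    z = c(inlet_pos[3], junction_pos[3], hilum_left[3], hilum_right[3])
  )
  len <- function(i, j) sqrt(sum((as.numeric(nodes[i, 2:4]) - as.numeric(nodes[j, 2:4]))^2))
  elements <- tibble::tibble(
    id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L), type = "artery",
    L = c(len(1, 2), len(2, 3), len(2, 4)),
    D0 = c(d(mpa_area), d(lpa_area), d(rpa_area)),
    order = NA_integer_, generation = 0L,
    lung = c(NA, "left", "right"), central = TRUE,
    parent = c(NA_integer_, 1L, 1L), seed = NA_integer_
  )
  vessel_network(nodes, elements, inlet_node = 1L,
                 interface_nodes = c(left = 3L, right = 4L))
}

#' Close the circulation through ladder acini
#'
#' Joins each terminal arterial element to the co-located venous terminal
#' through one acinus connector element, merging the arterial and venous
#' networks into a single closed circulation from the inlet/interface nodes to
#' the venous outlet. Terminals are matched by position; any unmatched
#' terminal is an error.
#'
#' @param arterial Full arterial `vessel_network` (central + grown trees).
#' @param venous Venous network from [mirror_venous_network()].
#' @param ladder_template A [ladder_acinus()] shared by all acini.
#' @return A connected `vessel_network` with `acini` populated.
#' @export
build_full_circulation <- function(arterial, venous, ladder_template) {
  a_el <- arterial$elements
  term_a <- a_el[!(a_el$to %in% a_el$from), ]
  v_el <- venous$elements
  term_v_nodes <- setdiff(v_el$from, v_el$to)
  pa <- node_xyz(arterial, term_a$to)
  pv <- node_xyz(venous, term_v_nodes)
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9), round(m[, 3], 9))
  idx <- match(key(pa), key(pv))
  if (anyNA(idx)) stop("unmatched arterial/venous terminals: ", sum(is.na(idx)))
  off_n <- max(arterial$nodes$id)
  off_e <- max(a_el$id)
  v_nodes <- venous$nodes
  v_nodes$id <- v_nodes$id + off_n
  v_el2 <- v_el
  v_el2$id <- v_el2$id + off_e
  v_el2$from <- v_el2$from + off_n
  v_el2$to <- v_el2$to + off_n
  v_el2$parent <- v_el2$parent + off_e
  n_ac <- nrow(term_a)
  ac_el <- tibble::tibble(
    id = max(v_el2$id) + seq_len(n_ac),
    from = term_a$to, to = term_v_nodes[idx] + off_n,
    type = "acinus", L = 1e-3, D0 = 1e-4,  # nominal; resistance comes from the ladder
    order = 0L, generation = NA_integer_, lung = term_a$lung,
    central = FALSE, parent = NA_integer_, seed = NA_integer_
  )
  acini <- tibble::tibble(
    id = seq_len(n_ac), element = ac_el$id,
    node_art = ac_el$from, node_ven = ac_el$to,
    x = pa[, 1], y = pa[, 2], z = pa[, 3], lung = term_a$lung
  )
  vessel_network(
    dplyr::bind_rows(arterial$nodes, v_nodes),
    dplyr::bind_rows(a_el, v_el2, ac_el),
    inlet_node = arterial$inlet_node,
    outlet_node = venous$outlet_node + off_n,
    interface_nodes = arterial$interface_nodes,
    acini = acini, ladder = ladder_template,
    meta = c(arterial$meta, list(n_acini = n_ac))
  )
}

#' Build a complete synthetic pulmonary circulation
#'
#' End-to-end geometry pipeline: synthetic lung shapes, quasi-uniform acinar
#' seeds split between lungs in proportion to volume, volume-filling arterial
#' trees grown from the left/right pulmonary artery stubs, Strahler diameters
#' (arterial ratio 1.52, venous 1.56), a mirrored venous network, and ladder
#' acini closing the circulation. The per-sheet capillary surface area is the
#' whole-lung total divided equally over `n_acini * 9` sheets.
#'
#' @param n_acini Total number of acinar units.
#' @param total_volume,right_fraction Lung volumes, see [generate_lung_shapes()].
#' @param growth [tree_growth_params()].
#' @param cap Capillary parameters; `SA_sheet` is recomputed for `n_acini`.
#' @param fluid [fluid_properties()].
#' @param strahler_ratio_art,strahler_ratio_ven Diameter ratios.
#' @param diameter_cv Within-order diameter scatter of the generated trees
#'   (see [assign_strahler_radii()]); morphometrically typical default.
#' @param seed RNG seed controlling seeding (and hence the whole geometry).
#' @param alveolar_pressure Alveolar pressure handed to the ladder template (Pa).
#' @return A closed `vessel_network` ready for [solve_network()].
#' @export
build_pulmonary_network <- function(n_acini = 10000, total_volume = 4.0e-3,
                                    right_fraction = 0.525,
                                    growth = tree_growth_params(),
                                    cap = capillary_sheet_params(),
                                    fluid = fluid_properties(),
                                    strahler_ratio_art = 1.52,
                                    strahler_ratio_ven = 1.56,
                                    diameter_cv = 0.15,
                                    seed = 1L, alveolar_pressure = 0) {
  shapes <- generate_lung_shapes(total_volume, right_fraction)
  n_r <- round(n_acini * right_fraction)
  n_l <- n_acini - n_r
  seeds_l <- seed_acini(shapes$left, n_l, seed = seed)
  seeds_r <- seed_acini(shapes$right, n_r, seed = seed + 1L)

  net <- central_arterial_template()
  lpa_d <- net$elements$D0[2]; rpa_d <- net$elements$D0[3]
  net <- grow_volume_filling_tree(net, seeds_l, growth)
  net <- grow_volume_filling_tree(net, seeds_r, growth)
  el <- net$elements
  ids_l <- el$id[!el$central & el$lung == "left"]
  ids_r <- el$id[!el$central & el$lung == "right"]
  # anchor both lungs at a common reference order (LPA and RPA sit at the
  # same anatomical level), so leaf diameters are consistent across lungs
  omax <- max(strahler_orders(ids_l, el$parent[match(ids_l, el$id)]),
              strahler_orders(ids_r, el$parent[match(ids_r, el$id)]))
  net <- assign_strahler_radii(net, lpa_d, strahler_ratio_art,
                               element_ids = ids_l, max_order = omax,
                               diameter_cv = diameter_cv, rng_seed = seed + 2L)
  net <- assign_strahler_radii(net, rpa_d, strahler_ratio_art,
                               element_ids = ids_r, max_order = omax,
                               diameter_cv = diameter_cv, rng_seed = seed + 3L)
  ven <- mirror_venous_network(net, ratio = strahler_ratio_ven,
                               art_ratio = strahler_ratio_art)
  cap_n <- capillary_sheet_params(H0 = cap$H0, Hmax = cap$Hmax, alpha_c = cap$alpha_c,
                                  mu_c = cap$mu_c, f = cap$f, l_c = cap$l_c,
                                  SA_total = cap$SA_total, n_acini = n_acini,
                                  n_sheets = cap$n_sheets)
  leaf_art <- stats::median(net$elements$D0[!net$elements$central &
                                              net$elements$order == 1], na.rm = TRUE)
  leaf_ven <- stats::median(ven$elements$D0[ven$elements$order == 1], na.rm = TRUE)
  ladder <- ladder_acinus(leaf_art, leaf_ven, cap_n, mu = fluid$mu,
                          alveolar_pressure = alveolar_pressure)
  full <- build_full_circulation(net, ven, ladder)
  full$meta$seed <- seed
  full$meta$total_volume <- total_volume
  full$meta$right_fraction <- right_fraction
  full$meta$shapes <- shapes
  full
}
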