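#' Write a network to plain-text CSV tables
#'
#' Two files in SI units with 0-based ids: `nodes.csv` (`id,x,y,z`) and
#' `elements.csv` (`id,node_in,node_out,type,D0,order`).
#'
#' @param network A `vessel_network`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_network_csv <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- file.path(dir, "nodes.csv")
  ef <- file.path(dir, "elements.csv")
  nd <- network$nodes
  utils::write.csv(data.frame(id = nd$id - 1L, x = nd$x, y = nd$y, z = nd$z),
                   nf, row.names = FALSE)
  el <- network$elements
  utils::write.csv(data.frame(id = el$id - 1L, node_in = el$from - 1L,
                              node_out = el$to - 1L, type = el$type,
                              D0 = el$D0, order = el$order),
                   ef, row.names = FALSE)
  invisible(c(nodes = nf, elements = ef))
}

#' Read a network written by [write_network_csv()]
#'
#' Reconstructs a minimal `vessel_network` (geometry and diameters; element
#' lengths recomputed from node positions).
#'
#' @param dir Directory holding `nodes.csv` and `elements.csv`.
#' @return A `vessel_network`.
#' @export
read_network_csv <- function(dir) {
  nd <- utils::read.csv(file.path(dir, "nodes.csv"))
  el <- utils::read.csv(file.path(dir, "elements.csv"))
  nodes <- tibble::tibble(id = nd$id + 1L, x = nd$x, y = nd$y, z = nd$z)
  f <- match(el$node_in + 1L, nodes$id); t <- match(el$node_out + 1L, nodes$id)
  L <- sqrt((nodes$x[f] - nodes$x[t])^2 + (nodes$y[f] - nodes$y[t])^2 +
              (nodes$z[f] - nodes$z[t])^2)
  elements <- tibble::tibble(
    id = el$id + 1L, from = el$node_in + 1L, to = el$node_out + 1L,
    type = el$type, L = pmax(L, 1e-9), D0 = el$D0,
    order = el$order, generation = NA_integer_, lung = NA_character_,
    central = FALSE, parent = NA_integer_, seed = NA_integer_
  )
  vessel_network(nodes, elements)
}

#' Export a network (and optional solution) as VTK PolyData
#'
#' Legacy ASCII VTK: nodes as POINTS, elements as two-point LINES, diameters
#' (and, when a state is given, flows and pressure drops) as CELL_DATA and
#' nodal pressures as POINT_DATA. Loads in standard VTK viewers.
#'
#' @param network A `vessel_network`.
#' @param file Output path.
#' @param state Optional `network_state` matching the network.
#' @return Invisibly, `file`.
#' @export
export_vtk <- function(network, file, state = NULL) {
  nd <- network$nodes; el <- network$elements
  if (!is.null(state)) {
    if (nrow(state$elements) != nrow(el) || nrow(state$nodes) != nrow(nd))
      stop("state does not match network (size mismatch)")
  }
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("pulmoperf vascular network")
  w("ASCII")
  w("DATASET POLYDATA")
  w("POINTS ", nrow(nd), " float")
  writeLines(paste(format(nd$x, digits = 9), format(nd$y, digits = 9),
                   format(nd$z, digits = 9)), con)
  idx <- function(ids) match(ids, nd$id) - 1L
  w("LINES ", nrow(el), " ", 3L * nrow(el))
  writeLines(paste(2L, idx(el$from), idx(el$to)), con)
  w("CELL_DATA ", nrow(el))
  w("SCALARS diameter float 1")
  w("LOOKUP_TABLE default")
  dia <- if (!is.null(state)) state$elements$diameter else el$D0
  writeLines(format(dia, digits = 9), con)
  if (!is.null(state)) {
    w("SCALARS flow float 1")
    w("LOOKUP_TABLE default")
    writeLines(format(state$elements$flow, digits = 9), con)
    w("POINT_DATA ", nrow(nd))
    w("SCALARS pressure float 1")
    w("LOOKUP_TABLE default")
    writeLines(format(state$nodes$pressure, digits = 9), con)
  }
  invisible(file)
}

#' Re-parse a VTK PolyData file written by [export_vtk()]
#'
#' Minimal reader used to verify round-trips: returns points, line
#' connectivity (0-based) and the scalar arrays.
#'
#' @param file Path to the VTK file.
#' @return List with `points`, `lines`, and named `cell_data` / `point_data`.
#' @export
read_vtk_polydata <- function(file) {
  ln <- readLines(file)
  grab <- function(pat) grep(pat, ln)[1]
  np <- as.integer(strsplit(ln[grab("^POINTS")], " +")[[1]][2])
  pts <- do.call(rbind, lapply(strsplit(ln[grab("^POINTS") + seq_len(np)], " +"),
                               function(s) as.numeric(s[s != ""])))
  nl <- as.integer(strsplit(ln[grab("^LINES")], " +")[[1]][2])
  lines <- do.call(rbind, lapply(strsplit(ln[grab("^LINES") + seq_len(nl)], " +"),
                                 function(s) as.integer(s[s != ""])[2:3]))
  read_scalars <- function(start, n) {
    out <- list()
    i <- start
    while (!is.na(i) && i <= length(ln)) {
      if (grepl("^SCALARS", ln[i])) {
        nm <- strsplit(ln[i], " +")[[1]][2]
        vals <- as.numeric(ln[i + 1L + seq_len(n)])
        out[[nm]] <- vals
        i <- i + 1L + n
      } else if (grepl("^(CELL|POINT)_DATA", ln[i])) break
      i <- i + 1L
    }
    out
  }
  cd_at <- grab("^CELL_DATA"); pd_at <- grab("^POINT_DATA")
  list(points = pts, lines = lines,
       cell_data = if (!is.na(cd_at)) read_scalars(cd_at + 1L, nl) else list(),
       point_data = if (!is.na(pd_at)) read_scalars(pd_at + 1L, np) else list())
}

#' Interface exchange record
#'
#' Structured record exchanged between the macro and 1D domains at each
#' coupling half-step; serialized as JSON so an external CFD solver can stand
#' in for the built-in surrogate without code changes.
#'
#' @param iteration Coupling iteration index.
#' @param inlet_flow_m3s Inlet flow (m^3/s).
#' @param inlet_pressure_Pa Inlet pressure (Pa).
#' @param outlet List of outlets, each a list with `id`, `pressure_Pa`,
#'   `flow_m3s`.
#' @return An `exchange_record`.
#' @export
exchange_record <- function(iteration, inlet_flow_m3s, inlet_pressure_Pa, outlet) {
  rec <- list(iteration = as.integer(iteration),
              inlet_flow_m3s = inlet_flow_m3s,
              inlet_pressure_Pa = inlet_pressure_Pa,
              outlet = outlet)
  validate_exchange(rec)
  structure(rec, class = "exchange_record")
}

validate_exchange <- function(rec) {
  need <- c("iteration", "inlet_flow_m3s", "inlet_pressure_Pa", "outlet")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("exchange record missing field '", miss[1], "'")
  for (o in rec$outlet) {
    miss <- setdiff(c("id", "pressure_Pa", "flow_m3s"), names(o))
    if (length(miss)) stop("exchange record outlet missing field '", miss[1], "'")
  }
  invisible(rec)
}

#' Write an exchange record as JSON
#'
#' Floats are serialized at full precision so a write-then-read round trip is
#' bit-exact.
#'
#' @param rec An [exchange_record()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_exchange <- function(rec, file) {
  validate_exchange(rec)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(unclass(rec), file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' Read an exchange record
#'
#' @param file JSON path written by [write_exchange()].
#' @return An `exchange_record`.
#' @export
read_exchange <- function(file) {
  rec <- tryCatch(jsonlite::read_json(file),
                  error = function(e) stop("malformed exchange file '", file,
                                           "': ", conditionMessage(e)))
  validate_exchange(rec)
  structure(rec, class = "exchange_record")
}
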