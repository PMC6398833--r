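#' Unstructured quadrilateral mesh
#'
#' Lightweight container for 4-node quadrilateral meshes shared by the solid
#' parts and the Eulerian fluid grid. Node coordinates are in cm; element
#' connectivity is counter-clockwise. Boundary edges are extracted on demand
#' and carry tags (inlet, outlet, lateral, leaflet_surface_upper, ...).
#'
#' @param nodes numeric matrix (n x 2) of node coordinates.
#' @param elems integer matrix (E x 4), counter-clockwise connectivity.
#' @param part character vector (length E) of part tags.
#' @param edge_tags optional data.frame with columns `n1`, `n2`, `tag`.
#' @return object of class `quad_mesh`.
#' @export
quad_mesh <- function(nodes, elems, part = rep("body", nrow(elems)),
                      edge_tags = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  stopifnot(ncol(nodes) == 2L, ncol(elems) == 4L,
            length(part) == nrow(elems))
  m <- list(nodes = nodes, elems = elems, part = as.character(part),
            edge_tags = edge_tags)
  class(m) <- "quad_mesh"
  m
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat("quad_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "elements\n")
  tb <- table(x$part)
  for (p in names(tb)) cat("  part", p, ":", tb[[p]], "elements\n")
  invisible(x)
}

#' Element Jacobians at the four corners
#'
#' Returns the minimum corner Jacobian of each element (positive for a valid
#' counter-clockwise quadrilateral, corner-wise).
#'
#' @param mesh a `quad_mesh`.
#' @return numeric vector of length E.
#' @export
mesh_min_corner_jacobian <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  x <- matrix(nd[el, 1L], ncol = 4L)
  y <- matrix(nd[el, 2L], ncol = 4L)
  jac_at <- function(a, b, c) {
    # cross product of the two edges leaving corner a
    (x[, b] - x[, a]) * (y[, c] - y[, a]) - (x[, c] - x[, a]) * (y[, b] - y[, a])
  }
  j1 <- jac_at(1L, 2L, 4L); j2 <- jac_at(2L, 3L, 1L)
  j3 <- jac_at(3L, 4L, 2L); j4 <- jac_at(4L, 1L, 3L)
  pmin(j1, pmin(j2, pmin(j3, j4))) / 4
}

#' Element areas (shoelace)
#' @param mesh a `quad_mesh`.
#' @return numeric vector of element areas.
#' @export
mesh_element_areas <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  x <- matrix(nd[el, 1L], ncol = 4L)
  y <- matrix(nd[el, 2L], ncol = 4L)
  0.5 * abs((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
            (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
            (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
            (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

#' Mean edge length of a mesh
#' @param mesh a `quad_mesh`.
#' @return scalar mean length over all element edges.
#' @export
mesh_mean_edge_length <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  tot <- 0
  for (k in 1:4) {
    a <- el[, k]; b <- el[, if (k == 4L) 1L else k + 1L]
    tot <- tot + sum(sqrt(rowSums((nd[a, , drop = FALSE] - nd[b, , drop = FALSE])^2)))
  }
  tot / (4 * nrow(el))
}

#' Boundary edges of a mesh (or of one part)
#'
#' Boundary edges are those appearing in exactly one element. Returned in the
#' element's counter-clockwise orientation so that the outward normal is the
#' edge direction rotated by -90 degrees.
#'
#' @param mesh a `quad_mesh`.
#' @param part optional part tag; restrict to elements of that part.
#' @return data.frame with columns `n1`, `n2`, `elem`.
#' @export
mesh_boundary_edges <- function(mesh, part = NULL) {
  el <- mesh$elems
  keep <- if (is.null(part)) seq_len(nrow(el)) else which(mesh$part %in% part)
  el <- el[keep, , drop = FALSE]
  e1 <- cbind(el[, 1], el[, 2]); e2 <- cbind(el[, 2], el[, 3])
  e3 <- cbind(el[, 3], el[, 4]); e4 <- cbind(el[, 4], el[, 1])
  edges <- rbind(e1, e2, e3, e4)
  eid <- rep(keep, 4L)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  dup <- key %in% key[duplicated(key)]
  data.frame(n1 = edges[!dup, 1], n2 = edges[!dup, 2], elem = eid[!dup])
}

#' Trace boundary edges into closed loops
#'
#' @param edges data.frame from [mesh_boundary_edges()].
#' @return list of integer vectors, each a closed loop of node ids (first not
#'   repeated at the end).
#' @export
mesh_boundary_loops <- function(edges) {
  nxt <- split(seq_len(nrow(edges)), edges$n1)
  used <- rep(FALSE, nrow(edges))
  loops <- list()
  for (start in seq_len(nrow(edges))) {
    if (used[start]) next
    loop <- integer(0)
    i <- start
    repeat {
      used[i] <- TRUE
      loop <- c(loop, edges$n1[i])
      cands <- nxt[[as.character(edges$n2[i])]]
      cands <- cands[!used[cands]]
      if (length(cands) == 0L) break
      i <- cands[1L]
    }
    if (edges$n2[i] != loop[1L]) stop("open boundary loop: solid boundary must be closed")
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Merge meshes, deduplicating coincident nodes
#'
#' @param meshes list of `quad_mesh` objects.
#' @param tol coincidence tolerance in cm.
#' @return a single `quad_mesh`.
#' @export
mesh_merge <- function(meshes, tol = 1e-9) {
  nodes <- do.call(rbind, lapply(meshes, `[[`, "nodes"))
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$nodes), 1L)))
  elems <- do.call(rbind, Map(function(m, o) m$elems + o,
                              meshes, offs[-length(offs)]))
  part <- unlist(lapply(meshes, `[[`, "part"))
  key <- paste(round(nodes[, 1] / tol), round(nodes[, 2] / tol))
  uid <- match(key, key)            # first occurrence index
  keep <- sort(unique(uid))
  remap <- integer(nrow(nodes)); remap[keep] <- seq_along(keep)
  elems <- matrix(remap[uid[elems]], ncol = 4L)
  out <- quad_mesh(nodes[keep, , drop = FALSE], elems, part)
  # map each input mesh's local node ids to merged ids
  glob <- remap[uid]
  attr(out, "node_maps") <- Map(function(a, b) glob[(a + 1L):b],
                                offs[-length(offs)], offs[-1L])
  out
}

#' Structured quadrilateral block mesh from a curvilinear map
#'
#' @param fx,fy vectorized functions of (s, t) on the unit square returning x
#'   and y coordinates.
#' @param ns,nt number of cells in the s and t directions.
#' @param part part tag for all elements.
#' @return a `quad_mesh`; nodes are ordered t-major then s.
#' @export
mesh_block <- function(fx, fy, ns, nt, part = "body") {
  s <- rep(seq(0, 1, length.out = ns + 1L), times = nt + 1L)
  t <- rep(seq(0, 1, length.out = nt + 1L), each = ns + 1L)
  nodes <- cbind(fx(s, t), fy(s, t))
  nid <- function(i, j) (j - 1L) * (ns + 1L) + i   # i in 1..ns+1, j in 1..nt+1
  i <- rep(seq_len(ns), times = nt)
  j <- rep(seq_len(nt), each = ns)
  elems <- cbind(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
  m <- quad_mesh(nodes, elems, rep(part, nrow(elems)))
  if (any(mesh_min_corner_jacobian(m) <= 0)) {
    # flip orientation if the map is left-handed
    m$elems <- m$elems[, c(1L, 4L, 3L, 2L)]
    if (any(mesh_min_corner_jacobian(m) <= 0))
      stop("mesh error: degenerate block for part ", part)
  }
  m
}

#' Write a mesh (optionally with nodal fields) to legacy-VTK ASCII
#'
#' Minimal ASCII writer for 2D quad meshes; z is written as 0. Fields are
#' point-data scalars or 2-vectors (padded to 3D).
#'
#' @param mesh a `quad_mesh`.
#' @param file output path.
#' @param point_data named list of numeric vectors (length n) or matrices
#'   (n x 2).
#' @return the file path, invisibly.
#' @export
write_vtk_quad <- function(mesh, file, point_data = list()) {
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "venofsi mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", e, 5L * e), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
                     mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(rep("9", e), con)
  writeLines(sprintf("CELL_DATA %d", e), con)
  writeLines(c("SCALARS part int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.integer(factor(mesh$part))), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.17g %.17g 0", v[, 1], v[, 2]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.17g", v), con)
      }
    }
  }
  invisible(file)
}

#' Read a legacy-VTK ASCII quad mesh written by [write_vtk_quad()]
#'
#' @param file path to a `.vtk` file.
#' @return list with `mesh` (a `quad_mesh`) and `point_data` (named list).
#' @export
read_vtk_quad <- function(file) {
  ln <- readLines(file)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  pts <- do.call(rbind, lapply(strsplit(ln[(ip + 1):(ip + n)], " +"), as.numeric))
  ic <- grep("^CELLS", ln)[1]
  e <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cells <- do.call(rbind, lapply(strsplit(ln[(ic + 1):(ic + e)], " +"), as.numeric))
  elems <- cells[, 2:5, drop = FALSE] + 1L
  part <- rep("body", e)
  isc <- grep("^SCALARS part", ln)
  if (length(isc)) part <- as.character(ln[(isc[1] + 2):(isc[1] + 1 + e)])
  pd <- list()
  ipd <- grep("^POINT_DATA", ln)
  if (length(ipd)) {
    k <- ipd[1] + 1L
    while (k <= length(ln)) {
      if (grepl("^SCALARS", ln[k])) {
        nm <- strsplit(ln[k], " +")[[1]][2]
        pd[[nm]] <- as.numeric(ln[(k + 2):(k + 1 + n)])
        k <- k + 2L + n
      } else if (grepl("^VECTORS", ln[k])) {
        nm <- strsplit(ln[k], " +")[[1]][2]
        vv <- do.call(rbind, lapply(strsplit(ln[(k + 1):(k + n)], " +"), as.numeric))
        pd[[nm]] <- vv[, 1:2, drop = FALSE]
        k <- k + 1L + n
      } else k <- k + 1L
    }
  }
  list(mesh = quad_mesh(pts[, 1:2, drop = FALSE], elems, part), point_data = pd)
}
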