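#' Signed volumes of linear tetrahedra
#'
#' @param nodes numeric matrix (n x 3) of node coordinates in mm.
#' @param tets integer matrix (m x 4) of 1-based node indices.
#' @return numeric vector of signed volumes (mm^3); positive for
#'   right-handed connectivity.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  # det([a; b; d]) / 6, expanded by cofactors
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
    a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
    a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Construct a finite element mesh object
#'
#' Container for a linear-tetrahedral mesh with named node sets, element
#' region sets, an optional fracture node-pair registry, contact pairs and
#' equal-displacement tie pairs.
#'
#' @param nodes n x 3 coordinate matrix (mm).
#' @param tets m x 4 connectivity (1-based). Reordered internally so that all
#'   signed volumes are positive.
#' @param node_sets named list of integer vectors.
#' @param element_sets named list of integer vectors; must partition the
#'   elements (each element in exactly one region).
#' @param fracture_pairs data frame with columns `a` (anterior node), `b`
#'   (posterior node), `g0` (undeformed pair distance, mm), `nx`, `ny`, `nz`
#'   (unit pair normal pointing a -> b), or NULL.
#' @param contact_pairs data frame with the same columns plus `set`, used by
#'   the contact solver; defaults to the fracture pairs.
#' @param tie_pairs data frame with columns `a`, `b`: DOF-wise
#'   equal-displacement constraints (screw sites), or NULL.
#' @param info free-form list of provenance/metadata.
#' @return object of class `fem_mesh`.
#' @export
fem_mesh <- function(nodes, tets, node_sets = list(), element_sets = list(),
                     fracture_pairs = NULL, contact_pairs = NULL,
                     tie_pairs = NULL, info = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4)
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) { # swap two nodes to restore right-handed orientation
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
    v[neg] <- -v[neg]
  }
  if (any(v <= 0)) stop("mesh contains degenerate (zero-volume) tetrahedra")
  if (length(element_sets)) {
    idx <- sort(unlist(element_sets, use.names = FALSE))
    if (length(idx) != nrow(tets) || any(idx != seq_len(nrow(tets))))
      stop("element_sets must partition the elements")
  }
  structure(list(nodes = nodes, tets = tets, node_sets = node_sets,
                 element_sets = element_sets, fracture_pairs = fracture_pairs,
                 contact_pairs = if (is.null(contact_pairs)) fracture_pairs else contact_pairs,
                 tie_pairs = tie_pairs, info = info),
            class = "fem_mesh")
}

#' Total mesh volume
#' @param mesh a `fem_mesh`.
#' @param sets optional character vector of element-set names to restrict to.
#' @return total volume in mm^3.
#' @export
mesh_volume <- function(mesh, sets = NULL) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  if (is.null(sets)) return(sum(v))
  sum(v[unlist(mesh$element_sets[sets], use.names = FALSE)])
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat("<fem_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets), " tets\n", sep = "")
  cat("  element sets:", paste(names(x$element_sets), collapse = ", "), "\n")
  cat("  node sets:   ", length(x$node_sets), "\n")
  if (!is.null(x$fracture_pairs))
    cat("  fracture:    ", nrow(x$fracture_pairs), " node pairs, gap ",
        format(x$fracture_pairs$g0[1]), " mm\n", sep = "")
  invisible(x)
}

# Nodes used by elements of the given region sets.
region_nodes <- function(mesh, sets) {
  els <- unlist(mesh$element_sets[intersect(sets, names(mesh$element_sets))],
                use.names = FALSE)
  sort(unique(as.vector(mesh$tets[els, ])))
}

#' Structured box mesh of linear tetrahedra
#'
#' Axis-aligned box split into a hex lattice, each hex split into six
#' tetrahedra (Kuhn split, conforming across shared faces). Used for the
#' verification suite (patch tests, cantilever beams, contact blocks) and as
#' a minimal example mesh.
#'
#' @param lx,ly,lz box dimensions (mm).
#' @param nx,ny,nz number of cells per direction.
#' @param origin coordinate of the corner node.
#' @return a `fem_mesh` with element set `solid` and node sets for the six
#'   faces (`xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`).
#' @export
box_mesh <- function(lx, ly, lz, nx = 2, ny = 2, nz = 2, origin = c(0, 0, 0)) {
  xs <- seq(0, lx, length.out = nx + 1) + origin[1]
  ys <- seq(0, ly, length.out = ny + 1) + origin[2]
  zs <- seq(0, lz, length.out = nz + 1) + origin[3]
  nid <- array(seq_len((nx + 1) * (ny + 1) * (nz + 1)),
               dim = c(nx + 1, ny + 1, nz + 1))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  tets <- matrix(0L, 6 * nx * ny * nz, 4)
  k <- 0L
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    hex <- hex_corner_ids(nid, ix, iy, iz)
    tets[k + 1:6, ] <- kuhn_split(hex)
    k <- k + 6L
  }
  face <- function(test) which(test)
  tol <- 1e-9
  ns <- list(
    xmin = face(abs(nodes[, 1] - origin[1]) < tol),
    xmax = face(abs(nodes[, 1] - (origin[1] + lx)) < tol),
    ymin = face(abs(nodes[, 2] - origin[2]) < tol),
    ymax = face(abs(nodes[, 2] - (origin[2] + ly)) < tol),
    zmin = face(abs(nodes[, 3] - origin[3]) < tol),
    zmax = face(abs(nodes[, 3] - (origin[3] + lz)) < tol))
  fem_mesh(nodes, tets, node_sets = ns,
           element_sets = list(solid = seq_len(nrow(tets))))
}

# 8 corner ids of lattice cell (ix,iy,iz), in (i,j,k)-bit order:
# index = 1 + i + 2j + 4k over local axes x,y,z.
hex_corner_ids <- function(nid, ix, iy, iz) {
  c(nid[ix, iy, iz],     nid[ix + 1, iy, iz],
    nid[ix, iy + 1, iz], nid[ix + 1, iy + 1, iz],
    nid[ix, iy, iz + 1],     nid[ix + 1, iy, iz + 1],
    nid[ix, iy + 1, iz + 1], nid[ix + 1, iy + 1, iz + 1])
}

# Kuhn (6-tet) split of a hex given corners in bit order; identical local
# orientation in every cell makes face diagonals conform between neighbours.
kuhn_split <- function(h) {
  paths <- list(c(1, 2), c(2, 3), c(1, 3), c(3, 2), c(2, 1), c(3, 1))
  bit <- c(1L, 2L, 4L)
  out <- matrix(0L, 6, 4)
  for (p in seq_along(paths)) {
    axes <- c(paths[[p]], setdiff(1:3, paths[[p]]))
    idx <- c(0L, cumsum(bit[axes]))
    out[p, ] <- h[idx + 1L]
  }
  out
}
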