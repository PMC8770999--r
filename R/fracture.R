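#' Cut a planar angle fracture into the mandible mesh
#'
#' Realizes the fracture as a conforming planar cut on the cross-section
#' (station) plane of the swept lattice nearest the requested plane within
#' the angle region: the nodes on that plane are duplicated into an anterior
#' and a posterior face, each face is displaced half the gap width into its
#' own fragment (a slab of material `gap_width` thick is removed), and a
#' registry of matched anterior/posterior node pairs at exactly `gap_width`
#' separation is recorded for the contact solver and the interfragmentary
#' displacement statistic.
#'
#' @param mesh an intact `fem_mesh` from [build_mandible()].
#' @param frac a [fracture_spec()].
#' @return the fractured mesh, with node sets `fracture_face_anterior` /
#'   `fracture_face_posterior` and a populated `fracture_pairs` registry
#'   (pair normals point anterior -> posterior, along the sweep tangent).
#' @export
cut_fracture <- function(mesh, frac) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(frac, "fracture_spec"))
  if (!is.null(mesh$fracture_pairs))
    stop("cut_fracture: mesh already contains a fracture")
  info <- mesh$info
  if (is.null(info$stations))
    stop("cut_fracture: mesh carries no sweep-station metadata")
  st <- info$stations
  meta <- info$meta
  side_code <- if (frac$side == "left") "L" else "R"
  sgn <- if (frac$side == "left") 1 else -1   # x mirrors for the right side

  # candidate stations: the angle region around the gonial corner
  ic <- st$corner
  cand <- max(ic - 2L, 1L):min(ic + 2L, st$S - 1L)
  centers <- st$center[cand + 1L, , drop = FALSE]
  centers[, 1] <- sgn * centers[, 1]  # left half is built at negative x
  point <- if (is.null(frac$plane_point)) centers[match(ic, cand), ]
           else as.numeric(frac$plane_point)
  d <- sqrt(rowSums((centers - matrix(point, nrow(centers), 3,
                                      byrow = TRUE))^2))
  if (min(d) > max(st$arc, na.rm = TRUE) / 4)
    stop("cut_fracture: plane_point misses the angle region of the ",
         frac$side, " side")
  s_cut <- cand[which.min(d)]
  tang <- st$tangent[s_cut + 1L, ]
  if (frac$side == "right") tang[1] <- -tang[1]
  if (!is.null(frac$plane_normal) &&
      abs(sum(frac$plane_normal * tang)) < cos(pi / 4))
    stop("cut_fracture: plane_normal deviates more than 45 degrees from the ",
         "local sweep tangent; no conforming cut plane available")

  gap <- frac$gap_width
  seg_len <- sqrt(sum((st$center[s_cut + 1L, ] - st$center[s_cut, ])^2))
  seg_len <- min(seg_len,
                 sqrt(sum((st$center[s_cut + 2L, ] - st$center[s_cut + 1L, ])^2)))
  if (gap >= 0.5 * seg_len)
    stop("cut_fracture: gap_width (", gap, " mm) too wide for the local ",
         "element size (", round(seg_len, 2), " mm); would invert elements")

  cut <- which(meta$side == side_code & meta$station == s_cut)
  if (!length(cut)) stop("cut_fracture: no nodes on the cut plane")

  # classify elements: posterior = any element whose node stations (on this
  # side) exceed the cut station
  nodes <- mesh$nodes
  tets <- mesh$tets
  stn <- meta$station
  stn[meta$side != side_code] <- -1L
  el_max <- pmax(stn[tets[, 1]], stn[tets[, 2]], stn[tets[, 3]], stn[tets[, 4]])
  in_cut <- matrix(tets %in% cut, ncol = 4)
  touches <- rowSums(in_cut) > 0
  posterior_el <- touches & el_max > s_cut

  n0 <- nrow(nodes)
  dup <- seq_len(length(cut)) + n0
  dup_of <- setNames(dup, cut)
  # re-point posterior elements at the duplicated face
  pt <- tets[posterior_el, , drop = FALSE]
  remap <- seq_len(n0)
  remap[cut] <- dup
  tets[posterior_el, ] <- matrix(remap[pt], ncol = 4)

  # separate the faces by the gap along the plane normal
  normal <- tang / sqrt(sum(tang^2))
  new_nodes <- nodes[cut, , drop = FALSE] +
    matrix(normal * (gap / 2), length(cut), 3, byrow = TRUE)
  nodes[cut, ] <- nodes[cut, , drop = FALSE] -
    matrix(normal * (gap / 2), length(cut), 3, byrow = TRUE)
  nodes <- rbind(nodes, new_nodes)

  meta_dup <- meta[cut, ]
  meta_dup$dup <- "posterior"
  meta <- rbind(meta, meta_dup)

  pairs <- data.frame(a = cut, b = dup,
                      g0 = sqrt(rowSums((nodes[dup, , drop = FALSE] -
                                         nodes[cut, , drop = FALSE])^2)),
                      nx = normal[1], ny = normal[2], nz = normal[3],
                      set = "fracture", stringsAsFactors = FALSE)

  ns <- lapply(mesh$node_sets, function(ids) {
    hit <- ids %in% cut
    if (any(hit)) c(ids, unname(dup_of[as.character(ids[hit])])) else ids
  })
  ns$fracture_face_anterior <- cut
  ns$fracture_face_posterior <- dup
  ns$fracture_zone <- c(cut, dup)

  info$meta <- meta
  info$fracture <- list(side = frac$side, station = s_cut, gap = gap,
                        point = point, normal = normal)
  fem_mesh(nodes, tets, node_sets = ns, element_sets = mesh$element_sets,
           fracture_pairs = pairs, contact_pairs = pairs,
           tie_pairs = mesh$tie_pairs, info = info)
}
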