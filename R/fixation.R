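# Miniplate fixation hardware: thin plate strips meshed as their own tet
# regions, connected to the bone by screw-site equal-displacement ties and
# by frictional plate-bone contact pairs.

# Straight plate box meshed as a hex strip split into tets.
plate_strip <- function(center, e_a, e_w, e_t, len, wid, thk, n_a) {
  as_ <- seq(-len / 2, len / 2, length.out = n_a + 1)
  ws <- c(-wid / 2, wid / 2)
  ts <- c(-thk / 2, thk / 2)
  g <- expand.grid(ia = seq_len(n_a + 1), iw = 1:2, it = 1:2)
  pos <- matrix(center, nrow(g), 3, byrow = TRUE) +
    outer(as_[g$ia], e_a) + outer(ws[g$iw], e_w) + outer(ts[g$it], e_t)
  nid <- array(seq_len(nrow(g)), dim = c(n_a + 1, 2, 2))
  tets <- matrix(0L, 0, 4)
  for (ia in seq_len(n_a))
    tets <- rbind(tets, kuhn_split(hex_corner_ids(nid, ia, 1, 1)))
  list(nodes = pos, tets = tets, nid = nid,
       axial = as_[g$ia], trans = ts[g$it])
}

#' Attach miniplate fixation to a fractured mandible
#'
#' Champy fixation places one plate on the superior border of the angle;
#' biplanar fixation adds a second plate on the inferolateral surface. Each
#' plate is a straight strip of the stated dimensions spanning the fracture
#' perpendicular to its plane, offset a small standoff from the bone
#' surface. Screw sites pair plate-hole nodes with the underlying cortical
#' nodes as equal-displacement ties (screw threads are not meshed); the
#' remaining plate underside is paired with the bone as frictional contact.
#'
#' @param mesh a fractured `fem_mesh` (see [cut_fracture()]).
#' @param fix a [fixation_spec()].
#' @return the plated mesh with element sets `plate_1` (and `plate_2`),
#'   screw-site node sets, a `plate_construct` node set, and a
#'   `bone_implant_interface` node set (bone nodes tied to screws or paired
#'   with a plate).
#' @export
attach_fixation <- function(mesh, fix) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(fix, "fixation_spec"))
  if (fix$technique == "none")
    stop("attach_fixation: technique 'none' attaches no hardware")
  if (is.null(mesh$fracture_pairs))
    stop("attach_fixation: mesh contains no fracture to span")
  info <- mesh$info
  fr <- info$fracture
  st <- info$stations
  g <- info$grid
  meta <- info$meta
  side_code <- if (fr$side == "left") "L" else "R"
  mir <- function(v) if (fr$side == "right") v * c(-1, 1, 1) else v

  s_cut <- fr$station
  d1 <- mir(st$d1[s_cut + 1L, ])
  d2 <- mir(st$d2[s_cut + 1L, ])
  e_a <- fr$normal / sqrt(sum(fr$normal^2))

  on_cut <- meta$side == side_code & meta$station == s_cut
  iv_top <- max(meta$iv[on_cut])
  cut_top <- which(on_cut & meta$iv == iv_top)
  cut_lat <- which(on_cut & meta$iu == g$n_u &
                     meta$iv <= max(1L, g$n_v %/% 3L))

  placements <- list(plate_1 = list(
    center = colMeans(mesh$nodes[cut_top, , drop = FALSE]) +
      d2 * (fix$standoff + fix$plate_thickness / 2),
    e_t = d2))
  if (fix$technique == "biplanar") {
    placements$plate_2 <- list(
      center = colMeans(mesh$nodes[cut_lat, , drop = FALSE]) +
        d1 * (fix$standoff + fix$plate_thickness / 2),
      e_t = d1)
  }

  nodes <- mesh$nodes
  tets <- mesh$tets
  es <- mesh$element_sets
  ns <- mesh$node_sets
  ties <- mesh$tie_pairs
  cpairs <- mesh$contact_pairs
  bone_n <- nrow(nodes)               # plates attach only to existing bone
  iface <- integer(0)
  plate_nodes_all <- integer(0)
  plate_frames <- list()
  n_a <- max(8L, as.integer(round(fix$plate_length / 2.6)))
  screw_ax <- seq(-0.35, 0.35, length.out = fix$screws_per_plate) *
    fix$plate_length

  for (pk in names(placements)) {
    pl <- placements[[pk]]
    e_t <- pl$e_t
    e_w <- cross3(e_t, e_a)
    e_w <- e_w / sqrt(sum(e_w^2))
    # the plate must straddle the fracture plane
    ax0 <- sum((pl$center - fr$point) * e_a)
    if (abs(ax0) > 0.25 * fix$plate_length)
      stop("attach_fixation: plate '", pk, "' does not span the fracture ",
           "plane at the chosen location")
    strip <- plate_strip(pl$center, e_a, e_w, e_t, fix$plate_length,
                         fix$plate_width, fix$plate_thickness, n_a)
    ids <- nrow(nodes) + seq_len(nrow(strip$nodes))
    nodes <- rbind(nodes, strip$nodes)
    es[[pk]] <- nrow(tets) + seq_len(nrow(strip$tets))
    tets <- rbind(tets, strip$tets + (ids[1] - 1L))
    meta <- rbind(meta, data.frame(
      station = rep(NA_integer_, length(ids)), iu = NA_integer_,
      iv = NA_integer_, side = side_code, dup = pk))
    plate_nodes_all <- c(plate_nodes_all, ids)
    plate_frames[[pk]] <- list(center = pl$center, e_a = e_a, e_w = e_w,
                               e_t = e_t,
                               dims = c(fix$plate_length, fix$plate_width,
                                        fix$plate_thickness))

    inner <- ids[strip$trans < 0]            # plate underside nodes
    inner_ax <- strip$axial[strip$trans < 0] # axial position in plate frame
    # nearest bone node for every underside node
    bone_idx <- nearest_nodes(nodes[inner, , drop = FALSE],
                              nodes[seq_len(bone_n), , drop = FALSE])
    gap0 <- rowSums((nodes[inner, , drop = FALSE] -
                     nodes[bone_idx, , drop = FALSE]) *
                      matrix(e_t, length(inner), 3, byrow = TRUE))
    if (any(gap0 > fix$screw_diameter))
      stop("attach_fixation: plate '", pk, "' stands too far off the bone ",
           "surface at the chosen location")

    screwed <- rep(FALSE, length(inner))
    for (k in seq_along(screw_ax)) {
      selk <- which(abs(inner_ax - screw_ax[k]) <= fix$screw_diameter / 2)
      if (!length(selk))
        stop("attach_fixation: no plate-hole nodes at screw site ", k,
             " of '", pk, "'")
      screwed[selk] <- TRUE
      ties <- rbind(ties, data.frame(a = inner[selk], b = bone_idx[selk]))
      ns[[paste0("screw_site_", pk, "_", k)]] <- sort(unique(bone_idx[selk]))
      iface <- c(iface, bone_idx[selk])
    }
    # each fragment must hold at least one screw
    sides <- sign(screw_ax + ax0)    # screw position relative to the plane
    if (!any(sides < 0) || !any(sides > 0))
      stop("attach_fixation: plate '", pk, "' lacks a screw on one fragment")
    # remaining underside in frictional contact with the bone
    free <- which(!screwed)
    if (length(free)) {
      cpairs <- rbind(cpairs, data.frame(
        a = bone_idx[free], b = inner[free], g0 = pmax(gap0[free], 1e-6),
        nx = e_t[1], ny = e_t[2], nz = e_t[3],
        set = paste0(pk, "_bone"), stringsAsFactors = FALSE))
      iface <- c(iface, bone_idx[free])
    }
  }

  ns$plate_construct <- plate_nodes_all
  ns$bone_implant_interface <- sort(unique(iface))
  # plate placement elevates the soft tissue over its footprint: bone nodes
  # under a plate or screw no longer receive direct muscle traction
  for (mn in MUSCLE_NAMES) for (sd in c("left", "right")) {
    key <- paste0(mn, "_", sd)
    if (!is.null(ns[[key]])) {
      left_over <- setdiff(ns[[key]], ns$bone_implant_interface)
      if (length(left_over)) ns[[key]] <- left_over
    }
  }
  info$meta <- meta
  info$plates <- plate_frames
  info$fixation <- fix
  fem_mesh(nodes, tets, node_sets = ns, element_sets = es,
           fracture_pairs = mesh$fracture_pairs, contact_pairs = cpairs,
           tie_pairs = ties, info = info)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Index of the nearest row of `pool` for each row of `pts` (chunked
# brute-force; pools here are small enough that this is cheap).
nearest_nodes <- function(pts, pool, chunk = 256L) {
  out <- integer(nrow(pts))
  px <- pool[, 1]; py <- pool[, 2]; pz <- pool[, 3]
  for (i0 in seq(1, nrow(pts), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(pts))
    d2 <- outer(pts[i0:i1, 1], px, "-")^2 +
      outer(pts[i0:i1, 2], py, "-")^2 +
      outer(pts[i0:i1, 3], pz, "-")^2
    out[i0:i1] <- max.col(-d2, ties.method = "first")
  }
  out
}
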