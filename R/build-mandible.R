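# Swept-lattice mandible generator.
#
# The solid is a rectangular cross-section swept along a piecewise path:
# semicircular anterior arch (in the occlusal plane), straight corpus on each
# side, a mitered 90-degree gonial corner, and a vertical ramus ending in the
# condyle. Stations are cross-section planes along the path; hex cells between
# consecutive stations are split into six tetrahedra (Kuhn split) so all
# region interfaces conform (shared nodes realize the tie constraints between
# cortical shell, trabecular core and tooth blocks).

# Station table for the left half-path (symphysis -> condyle). The stations
# adjacent to the mitered gonial corner must clear the elbow (the 45-degree
# corner section spans +/- h/2 along its diagonal), so the corpus covers
# y in [0, L - g_c] and the ramus z in [g_c, H] with g_c slightly beyond h/2.
mandible_stations <- function(spec) {
  R <- spec$arch_radius; L <- spec$corpus_length; H <- spec$ramus_height
  h <- spec$corpus_section_height
  n_ah <- spec$n_arch_segments %/% 2L
  dth <- (pi / 2) / n_ah
  s_t <- R * dth
  g_c <- h / 2 + s_t / 2            # elbow clearance at the corner
  if (L <= g_c + s_t || H <= g_c + s_t)
    stop("mandible_spec: corpus_length and ramus_height must exceed the ",
         "gonial elbow size (about corpus_section_height/2) by at least one ",
         "station spacing")
  n_c <- max(2L, as.integer(round((L - g_c) / s_t)))
  n_r <- max(2L, as.integer(round((H - g_c) / s_t)) + 1L)
  ic <- n_ah + n_c + 1L              # 0-based corner station index
  S <- ic + n_r
  center <- matrix(0, S + 1, 3)
  tang <- d1 <- d2 <- matrix(0, S + 1, 3)
  u_scale <- v_scale <- rep(1, S + 1)
  region <- character(S + 1)
  arc <- rep(NA_real_, S + 1)
  for (k in 0:n_ah) {
    th <- k * dth
    i <- k + 1
    center[i, ] <- c(-R * sin(th), R * cos(th), 0)
    tang[i, ] <- c(-cos(th), -sin(th), 0)
    d1[i, ] <- c(-sin(th), cos(th), 0)
    d2[i, ] <- c(0, 0, 1)
    region[i] <- "arch"
    arc[i] <- k * R * dth
    # miter widening where the discrete sweep turns in-plane
    u_scale[i] <- if (k < n_ah) 1 / cos(dth / 2) else 1 / cos(dth / 4)
  }
  for (j in 1:n_c) {
    i <- n_ah + j + 1
    center[i, ] <- c(-R, -j * (L - g_c) / n_c, 0)
    tang[i, ] <- c(0, -1, 0)
    d1[i, ] <- c(-1, 0, 0)
    d2[i, ] <- c(0, 0, 1)
    region[i] <- "corpus"
    arc[i] <- R * pi / 2 + j * (L - g_c) / n_c
  }
  i <- ic + 1
  center[i, ] <- c(-R, -L, 0)
  tang[i, ] <- c(0, -1, 1) / sqrt(2)
  d1[i, ] <- c(-1, 0, 0)
  d2[i, ] <- c(0, 1, 1) / sqrt(2)
  v_scale[i] <- sqrt(2)  # 45-degree miter at the gonial corner
  region[i] <- "corner"
  arc[i] <- R * pi / 2 + L
  zs <- seq(g_c, H, length.out = n_r)
  for (j in 1:n_r) {
    i <- ic + j + 1
    center[i, ] <- c(-R, -L, zs[j])
    tang[i, ] <- c(0, 0, 1)
    d1[i, ] <- c(-1, 0, 0)
    d2[i, ] <- c(0, 1, 0)
    region[i] <- "ramus"
  }
  list(center = center, tangent = tang, d1 = d1, d2 = d2,
       u_scale = u_scale, v_scale = v_scale, region = region, arc = arc,
       n_ah = n_ah, n_c = n_c, n_r = n_r, S = S, corner = ic,
       hemi_arc = R * pi / 2 + L)
}

#' Build the idealized mandible mesh
#'
#' Generates the intact (unfractured) mandible: a conforming linear-tet mesh
#' with cortical shell, trabecular core and tooth blocks, plus the node sets
#' used by the loading module (left/right condyles, bite points on the
#' chewing teeth, and one insertion patch per masticatory muscle per side).
#' The mesh is exactly mirror-symmetric about the midsagittal plane and fully
#' deterministic for a fixed spec.
#'
#' @param spec a [mandible_spec()].
#' @return a `fem_mesh` with element sets `cortical`, `trabecular`, `teeth`.
#' @export
build_mandible <- function(spec) {
  stopifnot(inherits(spec, "mandible_spec"))
  st <- mandible_stations(spec)
  w <- spec$corpus_section_width; h <- spec$corpus_section_height
  n_u <- spec$elements_per_section
  a <- w / n_u
  n_v <- max(2L, as.integer(round(h / a)))
  tc <- spec$cortical_thickness
  S <- st$S

  # --- tooth segments along the hemi-arch ------------------------------------
  # eligible segments: arch + corpus (both bounding stations unmitered)
  n_alv <- st$n_ah + st$n_c
  seg_mid <- (st$arc[1:n_alv] + st$arc[2:(n_alv + 1)]) / 2 / st$hemi_arc
  tooth_seg <- integer(0)
  if (length(spec$tooth_positions)) {
    tooth_seg <- vapply(spec$tooth_positions,
                        function(p) which.min(abs(seg_mid - p)), integer(1))
    if (anyDuplicated(tooth_seg))
      stop("mandible_spec: discretization too coarse to host all ",
           "tooth_positions as distinct tooth blocks; increase ",
           "n_arch_segments or thin tooth_positions")
  }
  iu_t0 <- n_u %/% 4L                 # tooth block spans the central columns
  iu_t1 <- n_u - iu_t0
  tooth_stations <- sort(unique(c(tooth_seg, tooth_seg + 1L))) - 1L  # 0-based

  # --- half-mesh nodes -------------------------------------------------------
  id <- array(NA_integer_, dim = c(S + 1, n_u + 1, n_v + 2))
  coords <- matrix(0, 0, 3)
  meta <- list(station = integer(0), iu = integer(0), iv = integer(0))
  nid <- 0L
  add_nodes <- function(s, ius, ivs, pos) {
    k <- nrow(pos)
    id[cbind(s + 1L, ius + 1L, ivs + 1L)] <<- nid + seq_len(k)
    coords <<- rbind(coords, pos)
    meta$station <<- c(meta$station, rep.int(s, k))
    meta$iu <<- c(meta$iu, ius)
    meta$iv <<- c(meta$iv, ivs)
    nid <<- nid + k
  }
  us <- seq(-w / 2, w / 2, length.out = n_u + 1)
  vs <- seq(-h / 2, h / 2, length.out = n_v + 1)
  for (s in 0:S) {
    g <- expand.grid(iu = 0:n_u, iv = 0:n_v)
    uu <- us[g$iu + 1] * st$u_scale[s + 1]
    vv <- vs[g$iv + 1] * st$v_scale[s + 1]
    pos <- matrix(st$center[s + 1, ], nrow(g), 3, byrow = TRUE) +
      outer(uu, st$d1[s + 1, ]) + outer(vv, st$d2[s + 1, ])
    add_nodes(s, g$iu, g$iv, pos)
    if (s %in% tooth_stations) {     # occlusal tooth layer, one cell high
      ius <- iu_t0:iu_t1
      uu <- us[ius + 1] * st$u_scale[s + 1]
      pos <- matrix(st$center[s + 1, ], length(ius), 3, byrow = TRUE) +
        outer(uu, st$d1[s + 1, ]) +
        matrix((h / 2 + a) * st$d2[s + 1, ], length(ius), 3, byrow = TRUE)
      add_nodes(s, ius, rep.int(n_v + 1L, length(ius)), pos)
    }
  }

  # --- half-mesh hexes -> tets ----------------------------------------------
  tets <- vector("list", S)
  region <- vector("list", S)
  d_edge <- function(uc, vc) pmin(w / 2 - abs(uc), h / 2 - abs(vc))
  for (s in 1:S) {                    # segment s between stations s-1 and s
    cells <- expand.grid(cu = 1:n_u, cv = 1:n_v)
    seg_tets <- matrix(0L, 0, 4)
    seg_reg <- character(0)
    hexes <- cbind(
      id[cbind(s, cells$cu, cells$cv)],         id[cbind(s + 1L, cells$cu, cells$cv)],
      id[cbind(s, cells$cu + 1L, cells$cv)],    id[cbind(s + 1L, cells$cu + 1L, cells$cv)],
      id[cbind(s, cells$cu, cells$cv + 1L)],    id[cbind(s + 1L, cells$cu, cells$cv + 1L)],
      id[cbind(s, cells$cu + 1L, cells$cv + 1L)], id[cbind(s + 1L, cells$cu + 1L, cells$cv + 1L)])
    uc <- (us[cells$cu] + us[cells$cu + 1]) / 2
    vc <- (vs[cells$cv] + vs[cells$cv + 1]) / 2
    reg <- ifelse(d_edge(uc, vc) < tc, "cortical", "trabecular")
    for (r in seq_len(nrow(hexes))) {
      seg_tets <- rbind(seg_tets, kuhn_split(hexes[r, ]))
      seg_reg <- c(seg_reg, rep(reg[r], 6))
    }
    if (s %in% tooth_seg) {           # tooth block cells on top
      cu <- (iu_t0 + 1L):iu_t1
      hexes <- cbind(
        id[cbind(s, cu, n_v + 1L)],      id[cbind(s + 1L, cu, n_v + 1L)],
        id[cbind(s, cu + 1L, n_v + 1L)], id[cbind(s + 1L, cu + 1L, n_v + 1L)],
        id[cbind(s, cu, n_v + 2L)],      id[cbind(s + 1L, cu, n_v + 2L)],
        id[cbind(s, cu + 1L, n_v + 2L)], id[cbind(s + 1L, cu + 1L, n_v + 2L)])
      hexes <- matrix(hexes, ncol = 8)
      for (r in seq_len(nrow(hexes))) {
        seg_tets <- rbind(seg_tets, kuhn_split(hexes[r, ]))
        seg_reg <- c(seg_reg, rep("teeth", 6))
      }
    }
    tets[[s]] <- seg_tets
    region[[s]] <- seg_reg
  }
  tets <- do.call(rbind, tets)
  regionv <- unlist(region)

  # --- mirror to the full mandible ------------------------------------------
  # Station 0 lies exactly in the midsagittal plane; its nodes are shared.
  nh <- nrow(coords)
  mid <- meta$station == 0L
  rmap <- integer(nh)
  rmap[mid] <- which(mid)
  new_ids <- nh + seq_len(sum(!mid))
  rmap[!mid] <- new_ids
  rcoords <- coords[!mid, , drop = FALSE]
  rcoords[, 1] <- -rcoords[, 1]
  nodes <- rbind(coords, rcoords)
  rtets <- matrix(rmap[tets], ncol = 4)
  all_tets <- rbind(tets, rtets)
  all_region <- c(regionv, regionv)
  side <- c(ifelse(mid, "M", "L"), rep("R", sum(!mid)))
  meta_full <- data.frame(
    station = c(meta$station, meta$station[!mid]),
    iu = c(meta$iu, meta$iu[!mid]),
    iv = c(meta$iv, meta$iv[!mid]),
    side = side, dup = "", stringsAsFactors = FALSE)

  # --- node sets -------------------------------------------------------------
  sel <- function(sides, stations, ius = NULL, ivs = NULL) {
    keep <- meta_full$side %in% sides & meta_full$station %in% stations
    if (!is.null(ius)) keep <- keep & meta_full$iu %in% ius
    if (!is.null(ivs)) keep <- keep & meta_full$iv %in% ivs
    which(keep)
  }
  ic <- st$corner
  ram_hi <- (ic + st$n_r %/% 2L):(S - 1L)
  # masseteric sling / pterygoid insertion: the angle and lower ramus,
  # predominantly posterior to the angle-fracture line below M3
  angle_st <- max(ic - 1L, 1L):min(ic + 3L, S - 1L)
  bite_seg <- tooth_seg[seq_len(min(3L, length(tooth_seg)))]
  bite_st <- sort(unique(c(bite_seg - 1L, bite_seg)))
  # articular facet: the posterior part of the ramus end cap (the condyle
  # contacts the fossa over a small patch, leaving the fragment free to
  # rotate about it)
  cond_iv <- 0:(g_nv3 <- max(1L, n_v %/% 3L))
  ns <- list(
    condyle_left = sel("L", S, ivs = cond_iv),
    condyle_right = sel("R", S, ivs = cond_iv),
    bite_left = sel(c("L", "M"), bite_st, ivs = n_v + 1L),
    bite_right = sel(c("R", "M"), bite_st, ivs = n_v + 1L),
    superficial_masseter_left = sel("L", angle_st, ius = n_u, ivs = 0:n_v),
    superficial_masseter_right = sel("R", angle_st, ius = n_u, ivs = 0:n_v),
    deep_masseter_left = sel("L", ram_hi, ius = n_u),
    deep_masseter_right = sel("R", ram_hi, ius = n_u),
    medial_pterygoid_left = sel("L", angle_st, ius = 0L, ivs = 0:n_v),
    medial_pterygoid_right = sel("R", angle_st, ius = 0L, ivs = 0:n_v),
    anterior_temporalis_left = sel("L", ram_hi, ivs = n_v),
    anterior_temporalis_right = sel("R", ram_hi, ivs = n_v),
    posterior_temporalis_left = sel("L", ram_hi, ivs = 0L),
    posterior_temporalis_right = sel("R", ram_hi, ivs = 0L))
  empty <- names(ns)[vapply(ns, length, 1L) == 0]
  if (length(empty))
    stop("mandible_spec: discretization too coarse to host node set(s) ",
         paste(empty, collapse = ", "),
         "; increase n_arch_segments or elements_per_section")

  es <- split(seq_len(nrow(all_tets)), factor(all_region,
              levels = c("cortical", "trabecular", "teeth")))
  es <- es[vapply(es, length, 1L) > 0]

  fem_mesh(nodes, all_tets, node_sets = ns, element_sets = es,
           info = list(spec = spec, stations = st, meta = meta_full,
                       grid = list(n_u = n_u, n_v = n_v, cell = a,
                                   tooth_seg = tooth_seg,
                                   iu_t0 = iu_t0, iu_t1 = iu_t1)))
}

#' Analytic volume of the idealized mandible solid
#'
#' Closed form for the swept solid the mesh discretizes: cross-section area
#' times centerline length (the mitered corner contributes exactly
#' width x height x ramus/corpus lengths), plus the tooth blocks. The meshed
#' volume approaches this under arch refinement (chordal deficit only).
#'
#' @param spec a [mandible_spec()].
#' @return volume in mm^3.
#' @export
mandible_analytic_volume <- function(spec) {
  st <- mandible_stations(spec)
  w <- spec$corpus_section_width; h <- spec$corpus_section_height
  n_u <- spec$elements_per_section
  a <- w / n_u
  iu_t0 <- n_u %/% 4L
  tooth_w <- (n_u - 2L * iu_t0) * a
  n_alv <- st$n_ah + st$n_c          # tooth-eligible segments
  seg_len <- diff(st$arc[1:(n_alv + 1)])
  seg_mid <- (st$arc[1:n_alv] + st$arc[2:(n_alv + 1)]) / 2 / st$hemi_arc
  tooth_seg <- vapply(spec$tooth_positions,
                      function(p) which.min(abs(seg_mid - p)), integer(1))
  v_teeth <- sum(seg_len[tooth_seg]) * tooth_w * a
  2 * (w * h * (spec$arch_radius * pi / 2 + spec$corpus_length +
                  spec$ramus_height) + v_teeth)
}
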