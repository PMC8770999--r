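# Outcome statistics: principal strain fields, von Mises stress, trimmed
# extremes, interfragmentary displacement, sectional moment profiles and
# strain-difference maps against the unfractured control.

#' Principal values of symmetric 3x3 tensors (vectorized)
#'
#' Closed-form trigonometric eigenvalues of symmetric tensors given as rows
#' `(xx, yy, zz, xy, yz, xz)` (tensor, not engineering, shear components).
#'
#' @param t6 n x 6 matrix.
#' @return n x 3 matrix of eigenvalues in decreasing order.
#' @export
principal_tensor_values <- function(t6) {
  t6 <- rbind(t6)
  q <- (t6[, 1] + t6[, 2] + t6[, 3]) / 3
  p2 <- (t6[, 1] - q)^2 + (t6[, 2] - q)^2 + (t6[, 3] - q)^2 +
    2 * (t6[, 4]^2 + t6[, 5]^2 + t6[, 6]^2)
  p <- sqrt(p2 / 6)
  iso <- p < 1e-300 | p < 1e-14 * pmax(abs(q), 1)
  ps <- ifelse(iso, 1, p)
  bxx <- (t6[, 1] - q) / ps; byy <- (t6[, 2] - q) / ps
  bzz <- (t6[, 3] - q) / ps
  bxy <- t6[, 4] / ps; byz <- t6[, 5] / ps; bxz <- t6[, 6] / ps
  detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out <- cbind(e1, e2, e3)
  out[iso, ] <- q[iso]
  dimnames(out) <- NULL
  out
}

#' Recover the strain field from a solution
#'
#' Constant strain per element from the shape-function gradients; nodal
#' tensors are the volume-weighted averages of the adjacent element tensors
#' (tensors averaged before eigen-decomposition); principal strains
#' reported in microstrain.
#'
#' @param solution a converged `fem_solution`.
#' @param mesh the mesh solved on.
#' @return object of class `strain_field`: `el` (m x 6 tensor components),
#'   `nodal` (n x 6), `eps1`, `eps3` (per node, microstrain).
#' @export
element_strain <- function(solution, mesh) {
  if (!isTRUE(solution$converged))
    stop("element_strain: solution did not converge")
  sg <- shape_gradients(mesh$nodes, mesh$tets)
  G <- sg$G; V <- sg$V
  u <- solution$u
  tets <- mesh$tets
  m <- nrow(tets)
  comp <- matrix(0, m, 6)
  colnames(comp) <- c("xx", "yy", "zz", "xy", "yz", "xz")
  gu <- function(i, j) {
    out <- numeric(m)
    for (a in 1:4) out <- out + u[tets[, a], i] * G[, a, j]
    out
  }
  comp[, 1] <- gu(1, 1)
  comp[, 2] <- gu(2, 2)
  comp[, 3] <- gu(3, 3)
  comp[, 4] <- (gu(1, 2) + gu(2, 1)) / 2
  comp[, 5] <- (gu(2, 3) + gu(3, 2)) / 2
  comp[, 6] <- (gu(1, 3) + gu(3, 1)) / 2
  nodal <- nodal_average(comp, tets, V, nrow(mesh$nodes))
  pv <- principal_tensor_values(nodal)
  structure(list(el = comp, nodal = nodal, V = V,
                 eps1 = pv[, 1] * 1e6, eps3 = pv[, 3] * 1e6),
            class = "strain_field")
}

# Volume-weighted nodal average of per-element quantities.
nodal_average <- function(el_vals, tets, V, n) {
  el_vals <- cbind(el_vals)
  idx <- as.vector(tets)
  wt <- rep(V, 4)
  denom <- rowsum(wt, idx)
  num <- rowsum(el_vals[rep(seq_len(nrow(el_vals)), 4), , drop = FALSE] * wt,
                idx)
  out <- matrix(0, n, ncol(el_vals))
  out[as.integer(rownames(num)), ] <- num / as.vector(denom)
  out
}

#' Stress field and von Mises stress
#'
#' Element stresses from the strain field through each region's isotropic
#' elasticity tensor, with nodal volume-weighted averaging of the von Mises
#' scalar.
#'
#' @param strain a `strain_field`.
#' @param system the `fem_system` (provides per-element Lame constants).
#' @param mesh the mesh.
#' @return list with `el` (m x 6 stress components, MPa), `vm_el`,
#'   `vm_nodal` (von Mises, MPa).
#' @export
stress_field <- function(strain, system, mesh) {
  e <- strain$el
  tr <- e[, 1] + e[, 2] + e[, 3]
  lam <- system$lambda; mu <- system$mu
  s <- cbind(lam * tr + 2 * mu * e[, 1],
             lam * tr + 2 * mu * e[, 2],
             lam * tr + 2 * mu * e[, 3],
             2 * mu * e[, 4], 2 * mu * e[, 5], 2 * mu * e[, 6])
  colnames(s) <- colnames(e)
  vm <- von_mises(s)
  list(el = s, vm_el = vm,
       vm_nodal = as.vector(nodal_average(vm, mesh$tets, strain$V,
                                          nrow(mesh$nodes))))
}

#' Von Mises equivalent stress
#'
#' @param s6 n x 6 matrix of stress tensor components
#'   `(xx, yy, zz, xy, yz, xz)` (MPa).
#' @return vector of von Mises stresses (MPa).
#' @export
von_mises <- function(s6) {
  s6 <- rbind(s6)
  sqrt(0.5 * ((s6[, 1] - s6[, 2])^2 + (s6[, 2] - s6[, 3])^2 +
                (s6[, 3] - s6[, 1])^2) +
         3 * (s6[, 4]^2 + s6[, 5]^2 + s6[, 6]^2))
}

#' Largest strains after symmetric tail exclusion
#'
#' Reports the largest and most-negative values remaining after discarding
#' the top and bottom `trim_fraction` of the sorted values (default 5% per
#' tail), excluding modeling artifacts at interface corners. The
#' alternative `"sd"` method excludes values outside two standard deviations
#' of the mean.
#'
#' @param values numeric vector (e.g. nodal principal strains over a region).
#' @param trim_fraction fraction per tail (percentile method).
#' @param method `"percentile"` (sort-and-slice, default) or `"sd"`.
#' @param n_sd standard-deviation multiple for `method = "sd"`.
#' @return list with `largest` (max of retained), `smallest` (min of
#'   retained), `n_used`, `n_total`.
#' @export
trimmed_extreme <- function(values, trim_fraction = 0.05,
                            method = c("percentile", "sd"), n_sd = 2) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (!length(values)) stop("trimmed_extreme: empty value list")
  if (method == "percentile") {
    v <- sort(values)
    k <- floor(length(v) * trim_fraction)
    keep <- v[seq.int(k + 1L, length(v) - k)]
  } else {
    m <- mean(values); s <- sd(values)
    keep <- values[abs(values - m) <= n_sd * s]
    if (!length(keep)) keep <- values
  }
  list(largest = max(keep), smallest = min(keep),
       n_used = length(keep), n_total = length(values))
}

#' Interfragmentary displacement report
#'
#' Percentage change in the distance of every matched fracture node pair
#' between the unloaded and loaded states. Negative values indicate
#' compression (distance shortening), positive values gap widening. The
#' headline statistic is the mode of the per-pair distribution on a 1%-wide
#' histogram (bin center reported; first bin on ties); the mean is also
#' reported.
#'
#' @param solution a converged `fem_solution`.
#' @param mesh the fractured mesh (carries `fracture_pairs`).
#' @param bin_width histogram bin width in percent for the mode.
#' @return object of class `ifd_report`: `pairs` data frame with `pct`,
#'   `mode_pct`, `mean_pct`, `n_pairs`.
#' @export
ifd_report <- function(solution, mesh, bin_width = 1) {
  fp <- mesh$fracture_pairs
  if (is.null(fp) || !nrow(fp)) stop("ifd_report: mesh has no fracture")
  if (!isTRUE(solution$converged))
    stop("ifd_report: solution did not converge")
  xa <- mesh$nodes[fp$a, , drop = FALSE] + solution$u[fp$a, , drop = FALSE]
  xb <- mesh$nodes[fp$b, , drop = FALSE] + solution$u[fp$b, , drop = FALSE]
  d <- sqrt(rowSums((xb - xa)^2))
  pct <- 100 * (d - fp$g0) / fp$g0
  half <- bin_width / 2
  centers <- seq(floor(min(pct) / bin_width) * bin_width,
                 ceiling(max(pct) / bin_width) * bin_width, by = bin_width)
  counts <- vapply(centers,
                   function(cc) sum(pct >= cc - half & pct < cc + half),
                   integer(1))
  structure(list(pairs = data.frame(a = fp$a, b = fp$b, deformed = d,
                                    undeformed = fp$g0, pct = pct),
                 mode_pct = centers[which.max(counts)],
                 mean_pct = mean(pct), n_pairs = nrow(fp),
                 bin_width = bin_width),
            class = "ifd_report")
}

#' @export
print.ifd_report <- function(x, ...) {
  cat("<ifd_report> ", x$n_pairs, " pairs; mode ", x$mode_pct,
      "% (mean ", round(x$mean_pct, 1), "%)\n", sep = "")
  invisible(x)
}

#' Transmitted force and moment across an arbitrary plane
#'
#' Free-body balance: the action transmitted onto the near (negative,
#' "anterior") side of the plane equals minus the sum of external forces and
#' reactions on that side, with the moment taken about the section centroid.
#' Contact, tie and element forces crossing the plane are all captured by
#' the balance.
#'
#' @param solution a converged `fem_solution` (with reactions).
#' @param mesh the mesh.
#' @param loadcase the `load_case` solved.
#' @param point,normal plane definition (mm; unit normal toward the far
#'   side).
#' @param centroid moment reference; default the centroid of nodes within
#'   half a mean edge of the plane.
#' @param side_nodes optional explicit node ids of the near side (overrides
#'   the geometric split).
#' @return list with `force` (3-vector N) and `moment` (3-vector N mm)
#'   transmitted onto the near side.
#' @export
section_moment_plane <- function(solution, mesh, loadcase, point, normal,
                                 centroid = NULL, side_nodes = NULL) {
  sd_ <- as.vector((mesh$nodes - matrix(point, nrow(mesh$nodes), 3,
                                        byrow = TRUE)) %*% normal)
  near <- if (is.null(side_nodes)) which(sd_ <= 1e-9) else side_nodes
  if (!length(near) || length(near) == nrow(mesh$nodes))
    stop("section_moment_plane: plane does not divide the mesh")
  if (is.null(centroid)) {
    onpl <- which(abs(sd_) < 1e-6)
    centroid <- if (length(onpl)) colMeans(mesh$nodes[onpl, , drop = FALSE])
                else point
  }
  ftot <- loadcase$forces[near, , drop = FALSE] +
    solution$reactions[near, , drop = FALSE]
  r <- mesh$nodes[near, , drop = FALSE] -
    matrix(centroid, length(near), 3, byrow = TRUE)
  force <- -colSums(ftot)
  moment <- -colSums(cbind(r[, 2] * ftot[, 3] - r[, 3] * ftot[, 2],
                           r[, 3] * ftot[, 1] - r[, 1] * ftot[, 3],
                           r[, 1] * ftot[, 2] - r[, 2] * ftot[, 1]))
  list(force = force, moment = moment, centroid = centroid)
}

#' Sectional moment profile along the corpus
#'
#' Moments transmitted across cross-section (station) planes of the swept
#' mandible on the fracture side, about each section centroid, in local
#' axes: `Mx` = sagittal bending (about the mediolateral axis), `My` =
#' anteroposterior twisting (about the sweep tangent), `Mz` = transverse
#' bending (about the vertical axis). Reported in N m.
#'
#' @param solution a converged `fem_solution`.
#' @param mesh the mandible mesh.
#' @param loadcase the solved `load_case`.
#' @param stations integer station indices along the arch/corpus (default:
#'   every station from the first arch station to the gonial corner on the
#'   profiled side).
#' @param side which hemimandible to profile; defaults to the fracture side
#'   (left for intact meshes).
#' @return data frame with station index, arc position (mm), and `Mx`,
#'   `My`, `Mz` (N m).
#' @export
section_moments <- function(solution, mesh, loadcase, stations = NULL,
                            side = NULL) {
  info <- mesh$info
  if (is.null(info$stations))
    stop("section_moments: mesh carries no sweep-station metadata")
  st <- info$stations
  meta <- info$meta
  if (is.null(side))
    side <- if (!is.null(info$fracture)) info$fracture$side else "left"
  side_code <- if (side == "left") "L" else "R"
  sgn <- if (side == "left") 1 else -1
  ok <- which(st$region %in% c("arch", "corpus", "corner")) - 1L
  ok <- setdiff(ok, 0L)
  if (is.null(stations)) stations <- ok
  if (!all(stations %in% ok))
    stop("section_moments: station outside the arch/corpus of the profiled",
         " side")
  frs <- info$fracture$station
  out <- data.frame(station = stations, arc = st$arc[stations + 1L],
                    Mx = 0, My = 0, Mz = 0)
  n <- nrow(mesh$nodes)
  for (r in seq_along(stations)) {
    s <- stations[r]
    point <- st$center[s + 1L, ] * c(sgn, 1, 1)
    tangent <- st$tangent[s + 1L, ] * c(sgn, 1, 1)
    post <- meta$side == side_code &
      (!is.na(meta$station) &
         (meta$station > s | (meta$station == s & meta$dup == "posterior")))
    hw <- is.na(meta$station)       # hardware: classify geometrically
    if (any(hw)) {
      sdist <- as.vector((mesh$nodes[hw, , drop = FALSE] -
                          matrix(point, sum(hw), 3, byrow = TRUE)) %*% tangent)
      post[which(hw)[sdist > 0]] <- TRUE
    }
    near <- which(!post)
    sec <- which(meta$side == side_code & !is.na(meta$station) &
                   meta$station == s)
    centroid <- colMeans(mesh$nodes[sec, , drop = FALSE])
    sm <- section_moment_plane(solution, mesh, loadcase, point, tangent,
                               centroid = centroid, side_nodes = near)
    e_y <- tangent
    e_x <- cross3(e_y, c(0, 0, 1))
    nex <- sqrt(sum(e_x^2))
    e_x <- e_x / nex
    e_z <- cross3(e_x, e_y)
    out$Mx[r] <- sum(sm$moment * e_x) / 1000
    out$My[r] <- sum(sm$moment * e_y) / 1000
    out$Mz[r] <- sum(sm$moment * e_z) / 1000
  }
  out
}

#' Strain-difference map against the unfractured control
#'
#' Matches every bone node of the control model to the nearest bone node of
#' the treatment model in undeformed coordinates (hardware excluded) and
#' reports the principal-strain differences treatment minus control.
#'
#' @param treatment,control `strain_field`s of the two models.
#' @param treatment_mesh,control_mesh the corresponding meshes.
#' @param max_dist error threshold (mm) on the nearest-neighbor distance.
#' @return object of class `difference_map`: data frame with control node,
#'   matched treatment node, distance, `de1`, `de3` (microstrain);
#'   attributes `mean_abs_de1`, `mean_abs_de3`.
#' @export
strain_difference_map <- function(treatment, control, treatment_mesh,
                                  control_mesh, max_dist = 2) {
  bone <- c("cortical", "trabecular", "teeth")
  tn <- region_nodes(treatment_mesh, bone)
  cn <- region_nodes(control_mesh, bone)
  idx <- nearest_nodes(control_mesh$nodes[cn, , drop = FALSE],
                       treatment_mesh$nodes[tn, , drop = FALSE])
  tmatch <- tn[idx]
  d <- sqrt(rowSums((control_mesh$nodes[cn, , drop = FALSE] -
                     treatment_mesh$nodes[tmatch, , drop = FALSE])^2))
  if (max(d) > max_dist)
    stop("strain_difference_map: nearest-neighbor distance ",
         signif(max(d), 3), " mm exceeds max_dist; meshes incompatible")
  map <- data.frame(control_node = cn, treatment_node = tmatch, dist = d,
                    de1 = treatment$eps1[tmatch] - control$eps1[cn],
                    de3 = treatment$eps3[tmatch] - control$eps3[cn])
  structure(map, class = c("difference_map", "data.frame"),
            mean_abs_de1 = mean(abs(map$de1)),
            mean_abs_de3 = mean(abs(map$de3)))
}

#' Trimmed principal-strain extremes by region
#'
#' Table-style summary of the largest maximum (eps1) and most negative
#' minimum (eps3) principal strains over named node sets after tail
#' trimming.
#'
#' @param strain a `strain_field`.
#' @param mesh the mesh.
#' @param sets character vector of node-set names.
#' @param trim_fraction,method passed to [trimmed_extreme()].
#' @return data frame with one row per region: `largest_eps1`,
#'   `largest_eps3` (most negative), `n_nodes`.
#' @export
region_strain_extremes <- function(strain, mesh, sets, trim_fraction = 0.05,
                                   method = "percentile") {
  rows <- lapply(sets, function(s) {
    ids <- mesh$node_sets[[s]]
    if (is.null(ids) || !length(ids))
      stop("region_strain_extremes: empty node set '", s, "'")
    t1 <- trimmed_extreme(strain$eps1[ids], trim_fraction, method)
    t3 <- trimmed_extreme(strain$eps3[ids], trim_fraction, method)
    data.frame(region = s, largest_eps1 = t1$largest,
               largest_eps3 = t3$smallest, n_nodes = length(ids))
  })
  do.call(rbind, rows)
}
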