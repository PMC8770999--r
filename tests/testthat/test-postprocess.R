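# Strain recovery, principal values, trimmed extremes, IFD, section
# moments, difference maps.

test_that("principal values match a dense eigensolver on random tensors", {
  set.seed(7)
  n <- 1000
  t6 <- matrix(rnorm(6 * n), n, 6)
  pv <- principal_tensor_values(t6)
  # full batch against eigen at 1e-12 of the tensor scale
  emax <- t(apply(t6, 1, function(r) {
    A <- matrix(c(r[1], r[4], r[6], r[4], r[2], r[5], r[6], r[5], r[3]), 3, 3)
    eigen(A, symmetric = TRUE, only.values = TRUE)$values
  }))
  expect_lt(max(abs(pv - emax)), 1e-12 * max(abs(emax)))
  expect_true(all(pv[, 1] >= pv[, 2] & pv[, 2] >= pv[, 3]))
  # degenerate isotropic tensor
  expect_equal(principal_tensor_values(rbind(c(2, 2, 2, 0, 0, 0)))[1, ],
               c(2, 2, 2))
})

test_that("uniaxial and shear fields recover the textbook principal strains", {
  mesh <- box_mesh(4, 4, 4, 2, 2, 2)
  sys <- assemble_stiffness(mesh, test_materials())
  impose <- function(A) {
    bnodes <- seq_len(nrow(mesh$nodes))
    lc <- load_case(mesh, constraints = data.frame(
      node = rep(bnodes, each = 3), dof = rep(1:3, length(bnodes)),
      value = as.vector(t(mesh$nodes %*% A))))
    solve_contact(sys, lc)
  }
  # uniaxial 1e-3
  sf <- element_strain(impose(diag(c(1e-3, 0, 0))), mesh)
  expect_equal(unname(sf$eps1), rep(1000, nrow(mesh$nodes)),
               tolerance = 1e-9)
  expect_lt(max(abs(sf$eps3)), 1e-4)   # microstrain; zero up to eigen noise
  # pure engineering shear gamma = 2e-3: eps1 = +1000, eps3 = -1000
  A <- matrix(c(0, 2e-3, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  sf <- element_strain(impose(A), mesh)
  expect_equal(unname(sf$eps1), rep(1000, nrow(mesh$nodes)),
               tolerance = 1e-9)
  expect_equal(unname(sf$eps3), rep(-1000, nrow(mesh$nodes)),
               tolerance = 1e-9)
})

test_that("von Mises stress matches closed forms", {
  expect_equal(von_mises(rbind(c(100, 0, 0, 0, 0, 0)))[1], 100)
  expect_equal(von_mises(rbind(c(50, 50, 50, 0, 0, 0)))[1], 0)
  expect_equal(von_mises(rbind(c(0, 0, 0, 10, 0, 0)))[1], 10 * sqrt(3))
  # stress field consistency: uniaxial strain, nu = 0 gives sigma = E eps
  mesh <- box_mesh(4, 4, 4, 1, 1, 1)
  sys <- assemble_stiffness(mesh, test_materials(E = 10000, nu = 0))
  bnodes <- seq_len(nrow(mesh$nodes))
  lc <- load_case(mesh, constraints = data.frame(
    node = rep(bnodes, each = 3), dof = rep(1:3, length(bnodes)),
    value = as.vector(t(mesh$nodes %*% diag(c(1e-3, 0, 0))))))
  sol <- solve_contact(sys, lc)
  st <- stress_field(element_strain(sol, mesh), sys, mesh)
  expect_equal(unname(st$el[, 1]), rep(10, nrow(mesh$tets)),
               tolerance = 1e-9)
  expect_equal(unname(st$vm_nodal), rep(10, nrow(mesh$nodes)),
               tolerance = 1e-9)
})

test_that("trimmed extremes follow the sort-and-slice convention", {
  r <- trimmed_extreme(1:100, 0.05)
  expect_equal(r$largest, 95)
  expect_equal(r$smallest, 6)
  expect_equal(trimmed_extreme(rep(3.5, 40), 0.05)$largest, 3.5)
  expect_equal(trimmed_extreme(rep(3.5, 40), 0.2)$largest, 3.5)
  # large-sample comparison with an independent oracle
  set.seed(11)
  x <- rnorm(1e4, mean = 2, sd = 5)
  r <- trimmed_extreme(x, 0.05)
  xs <- sort(x)
  keep <- xs[(floor(1e4 * 0.05) + 1):(1e4 - floor(1e4 * 0.05))]
  expect_identical(r$largest, max(keep))
  expect_identical(r$smallest, min(keep))
  expect_lt(r$largest, max(x))
  # two-standard-deviation variant
  r2 <- trimmed_extreme(x, method = "sd")
  expect_identical(r2$largest, max(x[abs(x - mean(x)) <= 2 * sd(x)]))
  expect_error(trimmed_extreme(numeric(0)), "empty")
})

test_that("IFD percentages match hand computation on constructed fields", {
  mesh <- small_fractured()
  fp <- mesh$fracture_pairs
  n <- nrow(mesh$nodes)
  fake_sol <- function(u) structure(list(u = u, converged = TRUE),
                                    class = "fem_solution")
  # zero displacement: all pairs 0 %, mode 0
  r0 <- ifd_report(fake_sol(matrix(0, n, 3)), mesh)
  expect_true(all(r0$pairs$pct == 0))
  expect_equal(r0$mode_pct, 0)
  expect_equal(r0$n_pairs, nrow(fp))
  # uniform closure 0.2 -> 0.1 mm: all pairs -50 %
  u <- matrix(0, n, 3)
  nrm <- c(fp$nx[1], fp$ny[1], fp$nz[1])
  u[fp$b, ] <- matrix(-0.1 * nrm, nrow(fp), 3, byrow = TRUE)
  r <- ifd_report(fake_sol(u), mesh)
  expect_equal(unname(r$pairs$pct), rep(-50, nrow(fp)), tolerance = 1e-9)
  expect_equal(r$mode_pct, -50)
  # linear lateral-bending field: opening varies with the mediolateral
  # coordinate from -80 % to +80 %
  meta <- mesh$info$meta[fp$a, ]
  tcoord <- (meta$iu - min(meta$iu)) / (max(meta$iu) - min(meta$iu))
  open_mm <- 0.2 * (1.6 * tcoord - 0.8)
  u <- matrix(0, n, 3)
  u[fp$b, ] <- open_mm %o% nrm
  r <- ifd_report(fake_sol(u), mesh)
  expect_equal(unname(r$pairs$pct), unname(100 * open_mm / 0.2),
               tolerance = 1e-9)
  expect_lt(min(r$pairs$pct), -79)
  expect_gt(max(r$pairs$pct), 79)
})

test_that("section moments reproduce the cantilever closed form", {
  cant <- cantilever_deflection(40, 4, 4)
  P <- 10
  # stations 30 and 60 mm from the support; moment arm is to the tip load
  for (xc in c(30, 60)) {
    sm <- section_moment_plane(cant$sol, cant$mesh, cant$lc,
                               point = c(xc, 5, 5), normal = c(1, 0, 0))
    arm <- 100 - xc
    expect_equal(abs(sm$moment[2]) / 1000, P * arm / 1000,
                 tolerance = 0.02)
    expect_equal(sm$force[3], -P, tolerance = 1e-6)
  }
  # a cut just inside the support carries the full support moment P*L
  sm0 <- section_moment_plane(cant$sol, cant$mesh, cant$lc,
                              point = c(2.5, 5, 5), normal = c(1, 0, 0))
  expect_equal(abs(sm0$moment[2]), P * 97.5, tolerance = 1e-6 * P * 100)
})

test_that("mandible moment profile is zero without load and flags bad stations", {
  mesh <- small_mandible()
  n <- nrow(mesh$nodes)
  sol0 <- structure(list(u = matrix(0, n, 3), converged = TRUE,
                         reactions = matrix(0, n, 3)),
                    class = "fem_solution")
  lc0 <- load_case(mesh)
  mp <- section_moments(sol0, mesh, lc0, side = "left")
  expect_true(all(abs(as.matrix(mp[, c("Mx", "My", "Mz")])) < 1e-12))
  expect_gt(nrow(mp), 5)
  ramus_station <- mesh$info$stations$S - 1L
  expect_error(section_moments(sol0, mesh, lc0, stations = ramus_station),
               "outside the arch/corpus")
})

test_that("difference maps are geometric, not index-based", {
  mesh <- small_mandible()
  sys <- assemble_stiffness(mesh, default_materials())
  cfg <- chew_config("left")
  lc <- assemble_loadcase(cfg, default_muscles(mesh, cfg$emg_table), mesh)
  sol <- solve_contact(sys, lc)
  sf <- element_strain(sol, mesh)
  # identical inputs: all-zero map
  dm <- strain_difference_map(sf, sf, mesh, mesh)
  expect_true(all(dm$de1 == 0) && all(dm$de3 == 0))
  # uniform +100 ue offset
  sf2 <- sf
  sf2$eps1 <- sf$eps1 + 100
  dm2 <- strain_difference_map(sf2, sf, mesh, mesh)
  expect_equal(unname(dm2$de1), rep(100, nrow(dm2)))
  expect_equal(attr(dm2, "mean_abs_de1"), 100)
  # node-order permutation of the treatment mesh leaves the map unchanged
  set.seed(3)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  pmesh <- mesh
  pmesh$nodes <- mesh$nodes[perm, , drop = FALSE]
  pmesh$tets <- matrix(inv[mesh$tets], ncol = 4)
  pmesh$node_sets <- lapply(mesh$node_sets, function(s) inv[s])
  psf <- sf
  psf$eps1 <- sf$eps1[perm]
  psf$eps3 <- sf$eps3[perm]
  dm3 <- strain_difference_map(psf, sf, pmesh, mesh)
  expect_equal(unname(dm3$de1), unname(dm$de1))
  expect_equal(unname(dm3$de3), unname(dm$de3))
  # incompatible geometry is refused
  far <- mesh
  far$nodes <- mesh$nodes + 100
  expect_error(strain_difference_map(sf, sf, far, mesh), "max_dist")
})

test_that("region strain extremes bound the untrimmed extremes", {
  mesh <- small_champy()
  sys <- apply_ties(assemble_stiffness(mesh, default_materials()), mesh)
  cfg <- chew_config("left")
  lc <- assemble_loadcase(cfg, default_muscles(mesh, cfg$emg_table), mesh)
  sol <- solve_contact(sys, lc, contact_params(), mesh$contact_pairs)
  sf <- element_strain(sol, mesh)
  expect_true(all(sf$eps1 >= sf$eps3))
  tab <- region_strain_extremes(sf, mesh,
                                c("plate_construct", "fracture_zone"))
  for (k in seq_len(nrow(tab))) {
    ids <- mesh$node_sets[[tab$region[k]]]
    expect_lte(tab$largest_eps1[k], max(sf$eps1[ids]))
    expect_gte(tab$largest_eps3[k], min(sf$eps3[ids]))
  }
})
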