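# Elastic core: element stiffness, rigid-body modes, patch test, beam
# convergence, ties, reactions.

test_that("element stiffness matches the affine-field energy oracle", {
  set.seed(42)
  for (rep in 1:3) {
    nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) +
      matrix(rnorm(12, 0, 0.1), 4, 3)
    mesh <- fem_mesh(nodes, matrix(1:4, 1, 4),
                     element_sets = list(solid = 1L))
    E <- 10000; nu <- 0.3
    K <- as.matrix(assemble_stiffness(mesh, test_materials(E, nu))$K)
    # oracle: strain energy of the affine displacement interpolant,
    # recovered entry-by-entry through polarization
    energy <- function(uvec) {
      U <- matrix(uvec, 4, 3, byrow = TRUE)
      A <- solve(cbind(1, mesh$nodes), U)
      gradu <- t(A[2:4, ])
      eps <- (gradu + t(gradu)) / 2
      lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
      mu <- E / (2 * (1 + nu))
      V <- tet_volumes(mesh$nodes, mesh$tets)
      V * (lam / 2 * sum(diag(eps))^2 + mu * sum(eps * eps))
    }
    Kor <- matrix(0, 12, 12)
    ei <- function(i) { e <- numeric(12); e[i] <- 1; e }
    for (i in 1:12) for (j in 1:12)
      Kor[i, j] <- energy(ei(i) + ei(j)) - energy(ei(i)) - energy(ei(j))
    expect_lt(max(abs(K - Kor)) / max(abs(Kor)), 1e-10)
    # linearity: doubling E doubles every entry
    K2 <- as.matrix(assemble_stiffness(mesh, test_materials(2 * E, nu))$K)
    expect_lt(max(abs(K2 - 2 * K)) / max(abs(K)), 1e-12)
  }
})

test_that("global stiffness is symmetric with six rigid-body modes", {
  mesh <- box_mesh(10, 10, 10, 2, 2, 2)
  sys <- assemble_stiffness(mesh, test_materials())
  asym <- max(abs(sys$K - Matrix::t(sys$K))) / max(abs(sys$K))
  expect_lt(asym, 1e-9)
  expect_equal(rigid_body_modes(sys), 6)
})

test_that("a disconnected mesh reports more than six zero-energy modes", {
  a <- box_mesh(5, 5, 5, 1, 1, 1)
  b <- box_mesh(5, 5, 5, 1, 1, 1, origin = c(20, 0, 0))
  na <- nrow(a$nodes)
  mesh <- fem_mesh(rbind(a$nodes, b$nodes), rbind(a$tets, b$tets + na),
                   element_sets = list(solid = seq_len(nrow(a$tets) * 2)))
  sys <- assemble_stiffness(mesh, test_materials())
  expect_equal(rigid_body_modes(sys), 12)
})

test_that("missing region material is rejected by name", {
  mesh <- small_mandible()
  expect_error(assemble_stiffness(mesh, test_materials()),
               "no material for region 'cortical'")
})

test_that("patch test: uniform strain is reproduced exactly", {
  mesh <- box_mesh(10, 8, 6, 2, 2, 2)
  sys <- assemble_stiffness(mesh, test_materials())
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                2e-4, -5e-4, 3e-4,
                -1e-4, 3e-4, 4e-4), 3, 3)
  bnodes <- sort(unique(unlist(mesh$node_sets)))
  pres <- mesh$nodes[bnodes, ] %*% A
  lc <- load_case(mesh, constraints = data.frame(
    node = rep(bnodes, each = 3), dof = rep(1:3, length(bnodes)),
    value = as.vector(t(pres))))
  sol <- solve_contact(sys, lc)
  expect_lt(max(abs(sol$u - mesh$nodes %*% A)), 1e-10)
  # every element carries the imposed uniform strain
  sf <- element_strain(sol, mesh)
  epsA <- (A + t(A)) / 2
  target <- c(epsA[1, 1], epsA[2, 2], epsA[3, 3],
              epsA[1, 2], epsA[2, 3], epsA[1, 3])
  expect_lt(max(abs(sweep(sf$el, 2, target))), 1e-10 * max(abs(target)))
})

test_that("cantilever deflection approaches beam theory monotonically", {
  P <- 10; E <- 10000; L <- 100
  exact <- P * L^3 / (3 * E * (10 * 10^3 / 12))
  d <- vapply(list(c(20, 2, 2), c(40, 4, 4), c(60, 6, 6), c(80, 8, 8)),
              function(r) cantilever_deflection(r[1], r[2], r[3])$deflection,
              numeric(1))
  expect_true(all(diff(d) > 0))          # monotone approach from below
  expect_true(all(d < exact))
  expect_lt(abs(d[4] - exact) / exact, 0.10)
})

test_that("energy balance holds for the contact-free linear solve", {
  cant <- cantilever_deflection(40, 4, 4)
  uv <- as.vector(t(cant$sol$u))
  fv <- as.vector(t(cant$lc$forces))
  Wint <- 0.5 * sum(uv * as.vector(cant$sys$K %*% uv))
  Wext <- 0.5 * sum(fv * uv)
  expect_lt(abs(Wint - Wext) / abs(Wext), 1e-9)
})

test_that("tied stacked blocks behave as one merged solid", {
  tied <- stacked_blocks(gap = 0, n = 2, tie = TRUE)
  sys <- apply_ties(assemble_stiffness(tied, test_materials()), tied)
  f <- matrix(0, nrow(tied$nodes), 3)
  top <- tied$node_sets$top
  f[top, 3] <- 5 / length(top)           # pull the top face up
  lc <- load_case(tied, forces = f, constraints = clamp_base(tied))
  sol <- solve_contact(sys, lc)
  # reference: a single 10 x 10 x 20 block with the same lattice
  one <- box_mesh(10, 10, 20, 2, 2, 4)
  sys1 <- assemble_stiffness(one, test_materials())
  f1 <- matrix(0, nrow(one$nodes), 3)
  t1 <- one$node_sets$zmax
  f1[t1, 3] <- 5 / length(t1)
  b1 <- one$node_sets$zmin
  lc1 <- load_case(one, forces = f1, constraints = data.frame(
    node = rep(b1, each = 3), dof = rep(1:3, length(b1)), value = 0))
  sol1 <- solve_contact(sys1, lc1)
  expect_equal(mean(sol$u[top, 3]), mean(sol1$u[t1, 3]), tolerance = 1e-10)
  # control: the same interface untied (compression-only contact) opens
  # under a prescribed pull; the tied interface carries zero jump
  open <- stacked_blocks(gap = 0, n = 2, tie = FALSE)
  syso <- assemble_stiffness(open, test_materials())
  pull <- data.frame(node = rep(top <- open$node_sets$top, each = 3),
                     dof = rep(1:3, length(top)),
                     value = as.vector(t(cbind(0, 0, 0.1)[
                       rep(1, length(top)), ])))
  lco <- load_case(open, constraints = rbind(clamp_base(open), pull))
  solo <- solve_contact(syso, lco, contact_params(), open$contact_pairs)
  jump_open <- solo$u[open$node_sets$upper_face, 3] -
    solo$u[open$node_sets$lower_face, 3]
  expect_gt(min(jump_open), 0.05)        # interface opens
  solt2 <- solve_contact(sys, load_case(tied, constraints = rbind(
    clamp_base(tied), pull)))
  jump_tied <- solt2$u[tied$node_sets$upper_face, 3] -
    solt2$u[tied$node_sets$lower_face, 3]
  expect_lt(max(abs(jump_tied)), 1e-12)
})

test_that("screw-style ties transmit load across a free gap", {
  blocks <- stacked_blocks(gap = 0.2, n = 2, tie = FALSE)
  # tie three non-collinear pairs ('screws'); no contact coupling
  cp <- blocks$contact_pairs
  pick <- cp[c(1, 3, 8), ]
  blocks$tie_pairs <- data.frame(a = pick$a, b = pick$b)
  blocks$contact_pairs <- NULL
  sys <- apply_ties(assemble_stiffness(blocks, test_materials()), blocks)
  # load only fragment 1 (the lower block), laterally
  f <- matrix(0, nrow(blocks$nodes), 3)
  f[blocks$node_sets$lower_face, 1] <- 1
  sol <- solve_contact(sys, load_case(blocks, forces = f,
                                      constraints = clamp_base(blocks)))
  expect_true(sol$converged)
  for (k in seq_len(nrow(pick)))       # tied pairs move together
    expect_equal(sol$u[pick$a[k], ], sol$u[pick$b[k], ], tolerance = 1e-12)
  # fragment 2 displaces although it carries no load
  expect_gt(max(abs(sol$u[blocks$node_sets$top, ])), 1e-6)
})

test_that("reactions balance external loads exactly", {
  cant <- cantilever_deflection(40, 4, 4)
  r <- cant$sol$reactions
  f <- cant$lc$forces
  expect_lt(max(abs(colSums(r) + colSums(f))), 1e-8 * sum(abs(f)))
  expect_lt(cant$sol$residual, 1e-9)
  # zero load gives zero reactions
  mesh <- box_mesh(10, 10, 10, 2, 2, 2)
  sys <- assemble_stiffness(mesh, test_materials())
  base <- mesh$node_sets$zmin
  lc0 <- load_case(mesh, constraints = data.frame(
    node = rep(base, each = 3), dof = rep(1:3, length(base)), value = 0))
  sol0 <- solve_contact(sys, lc0)
  expect_lt(max(abs(sol0$reactions)), 1e-12)
})
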