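# Compression-only frictional penalty contact.

press_case <- function(blocks, dz, shear = 0) {
  # prescribe the top face of the upper block: downward closure dz (mm) and
  # optional tangential displacement along x
  top <- blocks$node_sets$top
  cons <- rbind(clamp_base(blocks),
                data.frame(node = rep(top, each = 3),
                           dof = rep(1:3, length(top)),
                           value = as.vector(t(cbind(shear, 0, -dz)[
                             rep(1, length(top)), ]))))
  load_case(blocks, constraints = cons)
}

test_that("an open gap carries no contact force and matches the free solve", {
  blocks <- stacked_blocks(gap = 0.2, n = 2)
  sys <- assemble_stiffness(blocks, test_materials())
  lc <- press_case(blocks, dz = 0.05)    # closure well short of the gap
  sol <- solve_contact(sys, lc, contact_params(), blocks$contact_pairs)
  expect_true(sol$converged)
  expect_true(all(sol$contact$fn == 0))
  expect_true(all(!sol$contact$active))
  free <- solve_contact(sys, lc, contact_params(), NULL)
  expect_equal(sol$u, free$u, tolerance = 1e-12)
})

test_that("overclosure produces compression-only forces within tolerance", {
  # prescribed 0.3 mm closure over a 0.2 mm gap: the remaining 0.1 mm is
  # shared between column compression of the blocks and spring penetration.
  # With nu = 0 the uniaxial state is exact, so the total interface force
  # follows the 1-D series-stiffness closed form.
  blocks <- stacked_blocks(gap = 0.2, n = 2)
  E <- 1e4
  sys <- assemble_stiffness(blocks, test_materials(E = E, nu = 0))
  cp <- contact_params(penetration_tol = 1e-3)
  sol <- solve_contact(sys, press_case(blocks, dz = 0.3), cp,
                       blocks$contact_pairs)
  expect_true(sol$converged)
  expect_true(all(sol$contact$active))
  expect_true(all(sol$contact$fn > 0))
  expect_lte(sol$penetration, cp$penetration_tol)
  # per-pair penalty law f_n = k_n x overclosure
  expect_equal(sol$contact$fn, sol$kn * pmax(-sol$contact$gap, 0),
               tolerance = 1e-9)
  # series closed form: two 10 mm columns (EA/L each) + the penalty layer
  k_block <- E * 100 / 10
  k_springs <- sum(sol$kn)
  F_exp <- 0.1 / (2 / k_block + 1 / k_springs)
  # small face-warping correction only (uniform-k springs vs tributary
  # areas), well below 0.1% at the default penalty
  expect_equal(sum(sol$contact$fn), F_exp, tolerance = 1e-3)
  # and the reactions at the clamped base balance the interface force
  expect_equal(sum(sol$reactions[blocks$node_sets$base, 3]),
               sum(sol$contact$fn), tolerance = 1e-6)
})

test_that("contact complementarity holds for every pair", {
  blocks <- stacked_blocks(gap = 0.2, n = 2)
  sys <- assemble_stiffness(blocks, test_materials())
  # tilt the press so only part of the face engages: closure + x-shear
  top <- blocks$node_sets$top
  x <- blocks$nodes[top, 1]
  dz <- 0.1 + 0.2 * (x - min(x)) / diff(range(x))   # 0.1 .. 0.3 mm
  cons <- rbind(clamp_base(blocks),
                data.frame(node = rep(top, each = 3),
                           dof = rep(1:3, length(top)),
                           value = as.vector(t(cbind(0, 0, -dz)[
                             seq_along(top), ]))))
  sol <- solve_contact(sys, load_case(blocks, constraints = cons),
                       contact_params(), blocks$contact_pairs)
  expect_true(sol$converged)
  ct <- sol$contact
  expect_true(any(ct$active) && any(!ct$active))
  expect_true(all(ct$fn[ct$active] >= 0))
  expect_true(all(ct$fn[!ct$active] == 0))
  expect_true(all(ct$gap[!ct$active] > -1e-12))
  expect_true(all(ct$gap[ct$active] <= 1e-12))
})

test_that("tangential forces respect the Coulomb bound", {
  blocks <- stacked_blocks(gap = 0.2, n = 2)
  sys <- assemble_stiffness(blocks, test_materials())
  mu <- 0.3
  sol <- solve_contact(sys, press_case(blocks, dz = 0.3, shear = 0.2),
                       contact_params(mu = mu), blocks$contact_pairs)
  expect_true(sol$converged)
  ct <- sol$contact[sol$contact$active, ]
  expect_gt(nrow(ct), 0)
  expect_true(all(ct$ft <= mu * ct$fn + 1e-9))
  expect_true(any(!ct$stick))            # this shear saturates the bound
})

test_that("the high-friction limit approaches the tied interface", {
  blocks <- stacked_blocks(gap = 0, n = 2)
  sysc <- assemble_stiffness(blocks, test_materials())
  lc <- press_case(blocks, dz = 0.1, shear = 0.05)
  solc <- solve_contact(sysc, lc,
                        contact_params(mu = 1e9, normal_penalty = 1e7,
                                       tangential_penalty = 1e7),
                        blocks$contact_pairs)
  tied <- stacked_blocks(gap = 0, n = 2, tie = TRUE)
  syst <- apply_ties(assemble_stiffness(tied, test_materials()), tied)
  solt <- solve_contact(syst, lc)
  expect_true(solc$converged && solt$converged)
  scale <- max(abs(solt$u))
  expect_lt(max(abs(solc$u - solt$u)) / scale, 0.02)
})

test_that("the response varies continuously and monotonically with friction", {
  blocks <- stacked_blocks(gap = 0.2, n = 2)
  sys <- assemble_stiffness(blocks, test_materials())
  lc <- press_case(blocks, dz = 0.3, shear = 0.1)
  slips <- vapply(seq(0.1, 0.5, 0.1), function(mu) {
    sol <- solve_contact(sys, lc, contact_params(mu = mu),
                         blocks$contact_pairs)
    expect_true(sol$converged)
    du <- sol$u[blocks$node_sets$upper_face, 1] -
      sol$u[blocks$node_sets$lower_face, 1]
    mean(du)
  }, numeric(1))
  # relative tangential slip at the interface shrinks as friction grows
  expect_true(all(diff(abs(slips)) <= 1e-12))
  expect_true(all(is.finite(slips)))
})

test_that("non-convergence is reported, not hidden", {
  blocks <- stacked_blocks(gap = 0.2, n = 2)
  sys <- assemble_stiffness(blocks, test_materials())
  cp <- contact_params(max_outer_iters = 1)
  sol <- suppressWarnings(
    solve_contact(sys, press_case(blocks, dz = 0.3), cp,
                  blocks$contact_pairs))
  expect_false(sol$converged)
  expect_equal(sol$iterations, 1L)
  expect_error(element_strain(sol, blocks), "converge")
  expect_error(ifd_report(sol, blocks), "no fracture")
})
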