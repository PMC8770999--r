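# Shared fixtures, built once per test run and cached.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- builder()
  .fix_cache[[key]]
}

# Coarse mandible: ~2k tets, builds in well under a second.
small_spec <- function(...) {
  mandible_spec(n_arch_segments = 8, elements_per_section = 3,
                corpus_length = 30, ramus_height = 24,
                tooth_positions = c(0.45, 0.60, 0.75), ...)
}

small_mandible <- function() cached("small_mandible", function()
  build_mandible(small_spec()))

small_fractured <- function() cached("small_fractured", function()
  cut_fracture(small_mandible(), fracture_spec()))

small_champy <- function() cached("small_champy", function()
  attach_fixation(small_fractured(), fixation_spec("champy")))

small_biplanar <- function() cached("small_biplanar", function()
  attach_fixation(small_fractured(), fixation_spec("biplanar")))

default_mandible <- function() cached("default_mandible", function()
  build_mandible(mandible_spec()))

test_materials <- function(E = 10000, nu = 0.3)
  list(solid = material("solid", E, nu))

# Cantilever fixture: 100 x 10 x 10 mm box, clamped at x = 0, tip load P
# (total, N) downward at x = 100. Returns the solved tip deflection.
cantilever_deflection <- function(nx, ny, nz, P = 10, E = 10000) {
  key <- sprintf("cant_%d_%d_%d_%g_%g", nx, ny, nz, P, E)
  cached(key, function() {
    mesh <- box_mesh(100, 10, 10, nx, ny, nz)
    sys <- assemble_stiffness(mesh, test_materials(E))
    tip <- mesh$node_sets$xmax
    f <- matrix(0, nrow(mesh$nodes), 3)
    f[tip, 3] <- -P / length(tip)
    fixn <- mesh$node_sets$xmin
    lc <- load_case(mesh, forces = f,
                    constraints = data.frame(node = rep(fixn, each = 3),
                                             dof = rep(1:3, length(fixn)),
                                             value = 0))
    sol <- solve_contact(sys, lc)
    list(mesh = mesh, sys = sys, lc = lc, sol = sol,
         deflection = -mean(sol$u[tip, 3]), tip = tip)
  })
}

# Two stacked 10 mm cubes with an interface gap, wired either as contact
# pairs or as tie pairs. Bottom block clamped at its base.
stacked_blocks <- function(gap = 0.2, n = 2, tie = FALSE) {
  lower <- box_mesh(10, 10, 10, n, n, n)
  upper <- box_mesh(10, 10, 10, n, n, n, origin = c(0, 0, 10 + gap))
  nl <- nrow(lower$nodes)
  nodes <- rbind(lower$nodes, upper$nodes)
  tets <- rbind(lower$tets, upper$tets + nl)
  top_of_lower <- lower$node_sets$zmax
  bot_of_upper <- upper$node_sets$zmin + nl
  # match by (x, y)
  ol <- order(round(nodes[top_of_lower, 1], 9), round(nodes[top_of_lower, 2], 9))
  ou <- order(round(nodes[bot_of_upper, 1], 9), round(nodes[bot_of_upper, 2], 9))
  a <- top_of_lower[ol]
  b <- bot_of_upper[ou]
  pairs <- data.frame(a = a, b = b, g0 = gap, nx = 0, ny = 0, nz = 1,
                      set = "interface", stringsAsFactors = FALSE)
  ns <- list(base = lower$node_sets$zmin,
             top = upper$node_sets$zmax + nl,
             lower_face = a, upper_face = b)
  fem_mesh(nodes, tets,
           node_sets = ns,
           element_sets = list(solid = seq_len(nrow(tets))),
           contact_pairs = if (tie) NULL else pairs,
           tie_pairs = if (tie) data.frame(a = a, b = b) else NULL)
}

clamp_base <- function(mesh, extra = NULL) {
  fixn <- mesh$node_sets$base
  cons <- data.frame(node = rep(fixn, each = 3), dof = rep(1:3, length(fixn)),
                     value = 0)
  if (!is.null(extra)) cons <- rbind(cons, extra)
  cons
}
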