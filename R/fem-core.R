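# Static small-strain linear elasticity on linear (constant-strain)
# tetrahedra: vectorized closed-form element stiffness, sparse assembly,
# node-cluster tie constraints, Dirichlet elimination, and an outer
# active-set loop for compression-only frictional penalty contact.

lame_constants <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# Shape-function gradients of all elements: list(G = m x 4 x 3 array of
# grad(N_a), V = element volumes). Closed-form 3x3 inverse, vectorized.
shape_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  a <- e1[, 1]; b <- e1[, 2]; c <- e1[, 3]
  d <- e2[, 1]; e <- e2[, 2]; f <- e2[, 3]
  g <- e3[, 1]; h <- e3[, 2]; i <- e3[, 3]
  det <- a * (e * i - f * h) - d * (b * i - c * h) + g * (b * f - c * e)
  G <- array(0, dim = c(nrow(tets), 4, 3))
  G[, 2, 1] <- (e * i - f * h) / det
  G[, 2, 2] <- (f * g - d * i) / det
  G[, 2, 3] <- (d * h - e * g) / det
  G[, 3, 1] <- (c * h - b * i) / det
  G[, 3, 2] <- (a * i - c * g) / det
  G[, 3, 3] <- (b * g - a * h) / det
  G[, 4, 1] <- (b * f - c * e) / det
  G[, 4, 2] <- (c * d - a * f) / det
  G[, 4, 3] <- (a * e - b * d) / det
  G[, 1, ] <- -(G[, 2, ] + G[, 3, ] + G[, 4, ])
  list(G = G, V = det / 6)
}

#' Assemble the global stiffness matrix
#'
#' Isotropic linear elasticity on constant-strain tetrahedra via the closed
#' form K(ai,bj) = V (lambda Ga_i Gb_j + mu Ga_j Gb_i + mu delta_ij Ga.Gb),
#' assembled as one sparse symmetric matrix over 3 DOFs per node. Before any
#' constraints the matrix of a connected mesh carries exactly six rigid-body
#' modes.
#'
#' @param mesh a `fem_mesh`; every element set must have a material.
#' @param materials named list of [material()]s keyed by element-set name
#'   (see [default_materials()]).
#' @return object of class `fem_system`: sparse `K` (3n x 3n), element
#'   Lame constants, shape gradients and volumes, tie transformation.
#' @export
assemble_stiffness <- function(mesh, materials) {
  m <- nrow(mesh$tets)
  n <- nrow(mesh$nodes)
  lam <- mu <- rep(NA_real_, m)
  el_region <- character(m)
  for (rg in names(mesh$element_sets)) {
    mat <- materials[[rg]]
    if (is.null(mat))
      stop("assemble_stiffness: no material for region '", rg, "'")
    lc <- lame_constants(mat$E, mat$nu)
    idx <- mesh$element_sets[[rg]]
    lam[idx] <- lc$lambda
    mu[idx] <- lc$mu
    el_region[idx] <- rg
  }
  sg <- shape_gradients(mesh$nodes, mesh$tets)
  if (any(sg$V <= 0)) stop("assemble_stiffness: non-positive element volume")
  G <- sg$G; V <- sg$V
  nt <- 144L * m
  ii <- jj <- integer(nt)
  xx <- numeric(nt)
  k <- 0L
  dot <- function(a, b) G[, a, 1] * G[, b, 1] + G[, a, 2] * G[, b, 2] +
    G[, a, 3] * G[, b, 3]
  for (a in 1:4) for (b in 1:4) {
    gg <- dot(a, b)
    ra <- 3L * (mesh$tets[, a] - 1L)
    cb <- 3L * (mesh$tets[, b] - 1L)
    for (i in 1:3) for (j in 1:3) {
      val <- V * (lam * G[, a, i] * G[, b, j] + mu * G[, a, j] * G[, b, i])
      if (i == j) val <- val + V * mu * gg
      ii[k + seq_len(m)] <- ra + i
      jj[k + seq_len(m)] <- cb + j
      xx[k + seq_len(m)] <- val
      k <- k + m
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * n, 3L * n))
  structure(list(K = K, n_nodes = n, lambda = lam, mu = mu,
                 el_region = el_region, G = G, V = V,
                 materials = materials, T = NULL, rep_node = seq_len(n)),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat("<fem_system> ", x$n_nodes, " nodes (", 3 * x$n_nodes, " DOFs), ",
      length(x$V), " elements", if (!is.null(x$T)) ", ties applied", "\n",
      sep = "")
  invisible(x)
}

#' Apply equal-displacement tie constraints
#'
#' Conforming region interfaces already share nodes; the remaining ties are
#' the screw-site pairings between plate-hole nodes and the underlying
#' cortical nodes. Tied node clusters are merged by master-slave elimination
#' through a sparse indicator transformation, keeping the reduced system
#' symmetric.
#'
#' @param system a `fem_system` from [assemble_stiffness()].
#' @param mesh the mesh carrying `tie_pairs` (may be NULL for none).
#' @return the system with the tie transformation attached.
#' @export
apply_ties <- function(system, mesh) {
  tp <- mesh$tie_pairs
  n <- system$n_nodes
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(tp) && nrow(tp)) {
    for (r in seq_len(nrow(tp))) {
      ra <- find(tp$a[r]); rb <- find(tp$b[r])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  rep_node <- vapply(seq_len(n), find, integer(1))
  reps <- sort(unique(rep_node))
  red_of_rep <- integer(n)
  red_of_rep[reps] <- seq_along(reps)
  red_node <- red_of_rep[rep_node]          # node -> reduced cluster index
  full_dof <- seq_len(3L * n)
  red_dof <- 3L * (red_node[(full_dof + 2L) %/% 3L] - 1L) +
    ((full_dof - 1L) %% 3L) + 1L
  T <- Matrix::sparseMatrix(i = full_dof, j = red_dof, x = 1,
                            dims = c(3L * n, 3L * length(reps)))
  system$T <- T
  system$rep_node <- rep_node
  system$red_dof <- red_dof
  system
}

#' Contact solver parameters
#'
#' @param normal_penalty normal spring stiffness per node pair (N/mm); NULL
#'   selects 100 x the mean stiffness diagonal at the contact nodes.
#' @param mu static friction coefficient (Coulomb bound on the tangential
#'   force); default 0.3.
#' @param tangential_penalty stick stiffness (N/mm); NULL matches the normal
#'   penalty.
#' @param penetration_tol maximum admissible residual penetration (mm).
#' @param max_outer_iters cap on active-set iterations.
#' @param convergence_tol relative displacement-change tolerance for the
#'   outer loop.
#' @return object of class `contact_params`.
#' @export
contact_params <- function(normal_penalty = NULL, mu = 0.3,
                           tangential_penalty = NULL, penetration_tol = 1e-3,
                           max_outer_iters = 200L, convergence_tol = 1e-8) {
  stopifnot(mu >= 0, penetration_tol > 0, max_outer_iters >= 1)
  if (!is.null(normal_penalty) && normal_penalty <= 0)
    stop("contact_params: normal_penalty must be > 0")
  structure(list(normal_penalty = normal_penalty, mu = mu,
                 tangential_penalty = tangential_penalty,
                 penetration_tol = penetration_tol,
                 max_outer_iters = as.integer(max_outer_iters),
                 convergence_tol = convergence_tol),
            class = "contact_params")
}

#' Minimal load case constructor
#'
#' Lower-level companion to [assemble_loadcase()] for bespoke analyses
#' (verification problems, patch tests): supply nodal forces and/or
#' displacement constraints directly. Prescribed values may be nonzero.
#'
#' @param mesh the target mesh.
#' @param forces n x 3 matrix of nodal forces (N), or NULL for none.
#' @param constraints data frame with columns `node`, `dof` (1:3), `value`.
#' @return object of class `load_case`.
#' @export
load_case <- function(mesh, forces = NULL, constraints = NULL) {
  n <- nrow(mesh$nodes)
  if (is.null(forces)) forces <- matrix(0, n, 3)
  stopifnot(nrow(forces) == n, ncol(forces) == 3)
  if (is.null(constraints))
    constraints <- data.frame(node = integer(0), dof = integer(0),
                              value = numeric(0))
  structure(list(forces = forces, constraints = constraints,
                 provenance = list()),
            class = "load_case")
}

# Sparse contact-spring stiffness and constant rhs for the current state.
# Sticking pairs carry the full tangential penalty; slipping pairs carry a
# secant tangential stiffness mu*f_n/|s| (radial return), which keeps the
# system symmetric positive definite and makes the outer loop a stable
# fixed-point iteration.
contact_spring_system <- function(pairs, state, kn, ndof) {
  act <- which(state$active)
  rhs <- numeric(ndof)
  if (!length(act))
    return(list(S = NULL, rhs = rhs))
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (p in act) {
    n <- c(pairs$nx[p], pairs$ny[p], pairs$nz[p])
    A <- 3L * (pairs$a[p] - 1L) + 1:3
    B <- 3L * (pairs$b[p] - 1L) + 1:3
    blk <- kn[p] * tcrossprod(n) +
      state$ktan[p] * (diag(3) - tcrossprod(n))
    # blocks: +blk on (A,A) and (B,B), -blk on (B,A) and (A,B)
    ii <- c(ii, rep(c(A, B), each = 3), rep(c(A, B), each = 3))
    jj <- c(jj, rep(A, 6), rep(B, 6))
    xx <- c(xx, blk, -blk, -blk, blk)
    # natural-length offset of the normal spring: pushes the faces apart
    rhs[A] <- rhs[A] + kn[p] * pairs$g0[p] * n
    rhs[B] <- rhs[B] - kn[p] * pairs$g0[p] * n
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  list(S = S, rhs = rhs)
}

# Gap, normal force and tangential state of every pair for displacement u.
contact_state_update <- function(pairs, u, kn, kt, mu) {
  du <- u[pairs$b, , drop = FALSE] - u[pairs$a, , drop = FALSE]
  nrm <- cbind(pairs$nx, pairs$ny, pairs$nz)
  dn <- rowSums(du * nrm)
  gap <- pairs$g0 + dn
  active <- gap <= 0
  fn <- ifelse(active, -kn * gap, 0)
  s <- du - dn * nrm
  smag <- sqrt(rowSums(s^2))
  ft_stick <- kt * smag
  stick <- !active | ft_stick <= mu * fn | smag < 1e-14
  sdir <- s / ifelse(smag > 0, smag, 1)
  ktan <- ifelse(stick, kt, mu * fn / pmax(smag, 1e-300))
  ktan <- pmin(ktan, kt)
  list(active = active, stick = stick, fn = fn, gap = gap,
       slip_mag = smag, slip_dir = sdir, mu_eff = mu, ktan = ktan,
       ft = ifelse(active, pmin(ft_stick, mu * fn), 0))
}

#' Solve the constrained elastic problem with frictional contact
#'
#' Direct sparse symmetric solve with Dirichlet conditions imposed by
#' elimination (exact reactions) and tie clusters merged beforehand.
#' Fracture and plate-bone interfaces are compression-only node-pair penalty
#' springs: an outer active-set loop activates a pair when its normal gap
#' closes, caps the tangential force by the Coulomb bound `mu * f_n`
#' (capped pairs slide with a constant friction force), and iterates until
#' the active/stick sets and displacements are stationary.
#'
#' @param system a `fem_system` (with [apply_ties()] applied if the mesh has
#'   tie pairs).
#' @param loadcase a `load_case`.
#' @param contact [contact_params()].
#' @param pairs contact pair table (`mesh$contact_pairs`), or NULL for a
#'   contact-free solve.
#' @return object of class `fem_solution`: `u` (n x 3 displacements, mm),
#'   `reactions` (n x 3, N, nonzero only on constrained DOFs), `contact`
#'   (per-pair gap/normal/tangential forces), `converged`, `iterations`,
#'   `residual` (relative equilibrium residual on free DOFs).
#' @export
solve_contact <- function(system, loadcase, contact = contact_params(),
                          pairs = NULL) {
  K <- system$K
  n <- system$n_nodes
  ndof <- 3L * n
  T <- system$T
  if (is.null(T)) T <- Matrix::Diagonal(ndof)
  red_dof <- system$red_dof
  if (is.null(red_dof)) red_dof <- seq_len(ndof)
  nred <- ncol(T)

  cons <- loadcase$constraints
  f_full <- as.vector(t(loadcase$forces))
  cdof_full <- 3L * (cons$node - 1L) + cons$dof
  cdof <- red_dof[cdof_full]
  cvals <- cons$value
  agg <- tapply(cvals, cdof, function(v) {
    if (max(v) - min(v) > 1e-12)
      stop("solve_contact: conflicting prescribed values inside a tie cluster")
    v[1]
  })
  cdof_u <- as.integer(names(agg))
  cvals_u <- as.numeric(agg)
  free <- setdiff(seq_len(nred), cdof_u)

  Kr <- Matrix::forceSymmetric(Matrix::crossprod(T, K %*% T))
  fr0 <- as.vector(Matrix::crossprod(T, f_full))

  if (is.null(pairs) || !nrow(pairs)) {
    pairs <- data.frame(a = integer(0), b = integer(0), g0 = numeric(0),
                        nx = numeric(0), ny = numeric(0), nz = numeric(0),
                        set = character(0))
  }
  np <- nrow(pairs)
  kdiag <- Matrix::diag(K)
  kn <- rep(0, np)
  if (np) {
    auto <- 100 * mean(kdiag[c(3 * (pairs$a - 1) + 1, 3 * (pairs$a - 1) + 2,
                               3 * (pairs$a - 1) + 3)])
    kn <- rep(if (is.null(contact$normal_penalty)) auto
              else contact$normal_penalty, np)
  }
  kt <- rep(if (is.null(contact$tangential_penalty)) NA_real_
            else contact$tangential_penalty, np)
  kt[is.na(kt)] <- kn[is.na(kt)]

  state <- list(active = rep(FALSE, np), stick = rep(TRUE, np),
                fn = rep(0, np), gap = pairs$g0,
                slip_mag = rep(0, np), slip_dir = matrix(0, np, 3),
                mu_eff = contact$mu, ktan = kt, ft = rep(0, np))
  applied_state <- state
  u_red_prev <- NULL
  converged <- FALSE
  iters <- 0L
  u <- matrix(0, n, 3)

  solve_once <- function(Kc, fc) {
    if (!length(free)) {            # fully prescribed model
      ur <- numeric(nred)
      ur[cdof_u] <- cvals_u
      return(ur)
    }
    rhs <- fc[free]
    if (length(cdof_u) && any(cvals_u != 0))
      rhs <- rhs - as.vector(Kc[free, cdof_u, drop = FALSE] %*% cvals_u)
    uf <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kc[free, free]),
                             LDL = FALSE)
      as.vector(Matrix::solve(ch, rhs))
    }, error = function(e)
      as.vector(Matrix::solve(Kc[free, free], rhs)))
    ur <- numeric(nred)
    ur[free] <- uf
    ur[cdof_u] <- cvals_u
    ur
  }

  repeat {
    iters <- iters + 1L
    applied_state <- state
    sp <- contact_spring_system(pairs, state, kn, ndof)
    if (is.null(sp$S)) {
      Kc <- Kr
      fc <- fr0
    } else {
      Kc <- Matrix::forceSymmetric(Kr + Matrix::crossprod(T, sp$S %*% T))
      fc <- fr0 + as.vector(Matrix::crossprod(T, sp$rhs))
    }
    ur <- solve_once(Kc, fc)
    u <- matrix(as.vector(T %*% ur), n, 3, byrow = TRUE)
    if (!np) { converged <- TRUE; break }
    new_state <- contact_state_update(pairs, u, kn, kt, contact$mu)
    sets_stable <- identical(new_state$active, state$active) &&
      identical(new_state$stick, state$stick)
    du_rel <- if (is.null(u_red_prev)) Inf
              else max(abs(ur - u_red_prev)) / max(max(abs(ur)), 1e-30)
    state <- new_state
    u_red_prev <- ur
    if (sets_stable && du_rel < max(contact$convergence_tol, 1e-14)) {
      converged <- TRUE
      break
    }
    if (iters >= contact$max_outer_iters) break
  }

  pen <- if (np && any(state$active)) max(0, -min(state$gap[state$active]))
         else 0
  if (converged && np && pen > contact$penetration_tol)
    warning("solve_contact: residual penetration ", signif(pen, 3),
            " mm exceeds penetration_tol")

  sol <- structure(list(u = u, converged = converged, iterations = iters,
                        contact = if (np) cbind(pairs, data.frame(
                          gap = state$gap, fn = state$fn, ft = state$ft,
                          active = state$active, stick = state$stick))
                          else NULL,
                        contact_state = state,
                        applied_state = applied_state, penetration = pen,
                        kn = kn, kt = kt),
                   class = "fem_solution")
  rr <- compute_reactions(sol, system, loadcase, pairs = pairs)
  sol$reactions <- rr$reactions
  sol$residual <- rr$residual
  sol
}

#' @export
print.fem_solution <- function(x, ...) {
  cat("<fem_solution> ", nrow(x$u), " nodes; converged: ", x$converged,
      " (", x$iterations, " iterations)\n", sep = "")
  cat("  max |u| = ", signif(max(abs(x$u)), 4), " mm; residual = ",
      signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

# Full-space internal spring forces of the state that built the last solve,
# evaluated at the solved displacements (exactly the forces the linear
# system applied, so equilibrium closes to solver precision).
contact_internal_forces <- function(pairs, state, u, kn, ndof) {
  f <- numeric(ndof)
  act <- which(state$active)
  for (p in act) {
    n <- c(pairs$nx[p], pairs$ny[p], pairs$nz[p])
    A <- 3L * (pairs$a[p] - 1L) + 1:3
    B <- 3L * (pairs$b[p] - 1L) + 1:3
    du <- u[pairs$b[p], ] - u[pairs$a[p], ]
    gap <- pairs$g0[p] + sum(du * n)
    s <- du - sum(du * n) * n
    Ia <- -kn[p] * gap * n - state$ktan[p] * s
    f[A] <- f[A] + Ia
    f[B] <- f[B] - Ia
  }
  f
}

#' Reaction forces and equilibrium residual
#'
#' Reactions at constrained DOFs recovered from the internal force vector
#' `K u` plus the contact spring forces; global equilibrium (sum of external
#' forces plus reactions) closes to the solver tolerance.
#'
#' @param solution a `fem_solution`.
#' @param system the `fem_system` used for the solve.
#' @param loadcase the `load_case` used for the solve.
#' @param pairs the contact pair table used for the solve (NULL if none).
#' @return list with `reactions` (n x 3 matrix, N) and `residual` (relative
#'   equilibrium residual over free DOFs, tie-cluster summed).
#' @export
compute_reactions <- function(solution, system, loadcase, pairs = NULL) {
  n <- system$n_nodes
  ndof <- 3L * n
  uvec <- as.vector(t(solution$u))
  fint <- as.vector(system$K %*% uvec)
  if (!is.null(pairs) && nrow(pairs) &&
      !is.null(solution$applied_state)) {
    fint <- fint + contact_internal_forces(pairs, solution$applied_state,
                                           solution$u, solution$kn, ndof)
  }
  fext <- as.vector(t(loadcase$forces))
  resid_full <- fint - fext
  cons <- loadcase$constraints
  cdof <- unique(3L * (cons$node - 1L) + cons$dof)
  T <- system$T
  red_dof <- system$red_dof
  if (is.null(T)) {
    red <- resid_full
    cred <- cdof
  } else {
    red <- as.vector(Matrix::crossprod(T, resid_full))
    cred <- unique(red_dof[cdof])
  }
  freer <- setdiff(seq_along(red), cred)
  scale <- max(sum(abs(fext)), max(abs(red[cred]), 0), 1e-30)
  residual <- if (length(freer)) max(abs(red[freer])) / scale else 0
  reac <- numeric(ndof)
  reac[cdof] <- resid_full[cdof]
  list(reactions = matrix(reac, n, 3, byrow = TRUE), residual = residual)
}

#' Count near-rigid-body modes of the unconstrained stiffness
#'
#' Dense eigen-decomposition; intended for small verification meshes. A
#' connected mesh has exactly six zero-energy modes; more indicate a
#' disconnected (or mechanism-bearing) model.
#'
#' @param system a `fem_system`.
#' @param tol relative eigenvalue threshold.
#' @return number of near-zero eigenvalues.
#' @export
rigid_body_modes <- function(system, tol = 1e-9) {
  ev <- eigen(as.matrix(Matrix::forceSymmetric(system$K)),
              symmetric = TRUE, only.values = TRUE)$values
  sum(abs(ev) < tol * max(abs(ev)))
}
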