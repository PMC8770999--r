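# Masticatory loading: muscle forces from EMG x PCSA x specific tension and
# chewing-side displacement boundary conditions.

MUSCLE_NAMES <- c("anterior_temporalis", "posterior_temporalis",
                  "deep_masseter", "superficial_masseter", "medial_pterygoid")

#' Define a masticatory muscle load
#'
#' Total force magnitude is `emg * pcsa * specific_tension` (N, with PCSA in
#' cm^2 and specific tension in N/cm^2); the direction is the unit vector
#' from the insertion-node centroid toward the cranium-side origin anchor;
#' the force is divided equally across the insertion nodes.
#'
#' @param name one of `anterior_temporalis`, `posterior_temporalis`,
#'   `deep_masseter`, `superficial_masseter`, `medial_pterygoid`.
#' @param side `"left"` or `"right"`.
#' @param insertion_set node-set name of the mandibular insertion patch.
#' @param origin_anchor 3-vector (mm), surrogate for the cranial origin
#'   centroid.
#' @param emg mean normalized EMG amplitude in `[0, 1]`.
#' @param pcsa physiological cross-sectional area (cm^2).
#' @param specific_tension muscle specific tension (N/cm^2), default 30.
#' @return object of class `muscle_def`.
#' @export
muscle_def <- function(name, side = c("left", "right"), insertion_set,
                       origin_anchor, emg, pcsa, specific_tension = 30) {
  side <- match.arg(side)
  if (!name %in% MUSCLE_NAMES)
    stop("muscle_def: unknown muscle '", name, "'")
  if (!is.numeric(emg) || emg < 0 || emg > 1)
    stop("muscle_def: emg must lie in [0, 1]")
  if (!is.numeric(pcsa) || pcsa <= 0) stop("muscle_def: pcsa must be > 0")
  origin_anchor <- as.numeric(origin_anchor)
  stopifnot(length(origin_anchor) == 3)
  structure(list(name = name, side = side, insertion_set = insertion_set,
                 origin_anchor = origin_anchor, emg = emg, pcsa = pcsa,
                 specific_tension = specific_tension),
            class = "muscle_def")
}

# Default PCSA placeholders (cm^2) at macaque scale; subject-specific values
# live outside the desk-scale model and are configurable.
DEFAULT_PCSA <- c(anterior_temporalis = 4.5, posterior_temporalis = 2.0,
                  deep_masseter = 1.5, superficial_masseter = 4.0,
                  medial_pterygoid = 2.5)

# Anchor offsets (mm) from the insertion centroid, expressed for the LEFT
# side as (lateral(-x), anterior(+y), superior(+z)); x flips for the right.
ANCHOR_OFFSETS <- rbind(
  anterior_temporalis = c(0, 4, 30),
  posterior_temporalis = c(0, -12, 24),
  deep_masseter = c(-6, 2, 18),     # near-vertical with the lateral pull of
                                    # the zygomatic origin (wishboning driver)
  superficial_masseter = c(-3, 10, 28),
  medial_pterygoid = c(8, 8, 24))

#' Default muscle set for a mandible mesh
#'
#' Builds the ten `muscle_def`s (five muscles x two sides) with origin
#' anchors placed at fixed elevator-line offsets from each insertion-patch
#' centroid, mirrored across the midsagittal plane. EMG amplitudes come from
#' `emg_table` (see [chew_config()]).
#'
#' @param mesh a `fem_mesh` from [build_mandible()] (possibly fractured /
#'   plated).
#' @param emg_table named numeric: entries `"<muscle>_<side>"` in `[0, 1]`.
#' @param pcsa named numeric, PCSA per muscle (cm^2).
#' @param specific_tension N/cm^2.
#' @return list of ten [muscle_def()]s.
#' @export
default_muscles <- function(mesh, emg_table, pcsa = DEFAULT_PCSA,
                            specific_tension = 30) {
  out <- list()
  for (m in MUSCLE_NAMES) for (side in c("left", "right")) {
    set <- paste0(m, "_", side)
    ids <- mesh$node_sets[[set]]
    if (is.null(ids) || !length(ids))
      stop("default_muscles: mesh lacks insertion set '", set, "'")
    cen <- colMeans(mesh$nodes[ids, , drop = FALSE])
    off <- ANCHOR_OFFSETS[m, ]
    if (side == "right") off[1] <- -off[1]
    out[[set]] <- muscle_def(m, side, set, cen + off,
                             emg = unname(emg_table[[set]]), pcsa = pcsa[[m]],
                             specific_tension = specific_tension)
  }
  out
}

#' Chewing configuration
#'
#' Encodes the chewing side, the fracture side and the EMG recruitment table.
#' By default every working-side (chewing-side) muscle is assigned the
#' working amplitude and every balancing-side muscle the balancing amplitude;
#' a full per-muscle table can be supplied instead.
#'
#' @param chew_side,fracture_side `"left"` or `"right"`.
#' @param emg_working,emg_balancing default amplitudes in `[0, 1]`.
#' @param emg_table optional named numeric overriding the two-level default;
#'   must cover all 10 `"<muscle>_<side>"` combinations.
#' @return object of class `chew_config` with derived field `laterality`
#'   (`"ipsilateral"` if chewing on the fracture side).
#' @export
chew_config <- function(chew_side = c("left", "right"),
                        fracture_side = "left",
                        emg_working = 1.0, emg_balancing = 0.6,
                        emg_table = NULL) {
  chew_side <- match.arg(chew_side)
  fracture_side <- match.arg(fracture_side, c("left", "right"))
  keys <- as.vector(outer(MUSCLE_NAMES, c("left", "right"), paste, sep = "_"))
  if (is.null(emg_table)) {
    emg_table <- setNames(ifelse(grepl(paste0("_", chew_side, "$"), keys),
                                 emg_working, emg_balancing), keys)
  }
  if (!all(keys %in% names(emg_table)))
    stop("chew_config: emg_table must cover all 10 muscle-side combinations")
  if (any(emg_table < 0 | emg_table > 1))
    stop("chew_config: emg amplitudes must lie in [0, 1]")
  structure(list(chew_side = chew_side, fracture_side = fracture_side,
                 emg_table = emg_table[keys],
                 laterality = if (chew_side == fracture_side) "ipsilateral"
                              else "contralateral"),
            class = "chew_config")
}

#' Per-node forces for one muscle
#'
#' @param m a [muscle_def()].
#' @param mesh the mesh carrying the insertion node set.
#' @return list with `nodes` (ids), `forces` (k x 3, N) and `total`
#'   (3-vector, N). The rows sum to `total` exactly.
#' @export
muscle_force <- function(m, mesh) {
  ids <- mesh$node_sets[[m$insertion_set]]
  if (is.null(ids) || !length(ids))
    stop("muscle_force: empty insertion set '", m$insertion_set, "'")
  cen <- colMeans(mesh$nodes[ids, , drop = FALSE])
  dirv <- m$origin_anchor - cen
  len <- sqrt(sum(dirv^2))
  if (len < 1e-9)
    stop("muscle_force: origin anchor coincides with insertion centroid")
  total <- (m$emg * m$pcsa * m$specific_tension) * dirv / len
  k <- length(ids)
  list(nodes = ids, forces = matrix(total / k, k, 3, byrow = TRUE),
       total = total)
}

#' Displacement boundary conditions for a chewing side
#'
#' The working (chewing) side condyle is fixed in all directions; the
#' balancing condyle is fixed anteroposteriorly (y) and superoinferiorly (z)
#' but left free to translate mediolaterally (x), admitting lateral
#' wishboning of the corpus; the chewing-side bite nodes (premolar/first
#' molar occlusal surfaces) are fixed in all directions so bite force arises
#' as a reaction. All prescribed values are zero.
#'
#' @param cfg a [chew_config()].
#' @param mesh mesh with `condyle_*` and `bite_*` node sets.
#' @return data frame with columns `node`, `dof` (1 = x, 2 = y, 3 = z),
#'   `value`.
#' @export
build_constraints <- function(cfg, mesh) {
  work <- cfg$chew_side
  bal <- setdiff(c("left", "right"), work)
  need <- c(paste0("condyle_", c(work, bal)), paste0("bite_", work))
  for (s in need)
    if (!length(mesh$node_sets[[s]]))
      stop("build_constraints: empty or missing node set '", s, "'")
  wc <- mesh$node_sets[[paste0("condyle_", work)]]
  bc <- mesh$node_sets[[paste0("condyle_", bal)]]
  bt <- mesh$node_sets[[paste0("bite_", work)]]
  rbind(
    data.frame(node = rep(wc, each = 3), dof = rep(1:3, length(wc)), value = 0),
    data.frame(node = rep(bc, each = 2), dof = rep(2:3, length(bc)), value = 0),
    data.frame(node = rep(bt, each = 3), dof = rep(1:3, length(bt)), value = 0))
}

#' Assemble a solver-ready load case
#'
#' Superposes all muscle nodal forces and attaches the chewing-side
#' displacement constraints. A force applied on a constrained DOF would be
#' inconsistent; such components are zeroed with a warning.
#'
#' @param cfg a [chew_config()].
#' @param muscles list of [muscle_def()]s (see [default_muscles()]).
#' @param mesh the target mesh.
#' @return object of class `load_case`: `forces` (n x 3, N), `constraints`
#'   (data frame), `provenance`.
#' @export
assemble_loadcase <- function(cfg, muscles, mesh) {
  n <- nrow(mesh$nodes)
  f <- matrix(0, n, 3)
  totals <- matrix(0, length(muscles), 3)
  for (i in seq_along(muscles)) {
    mf <- muscle_force(muscles[[i]], mesh)
    f[mf$nodes, ] <- f[mf$nodes, ] + mf$forces
    totals[i, ] <- mf$total
  }
  cons <- build_constraints(cfg, mesh)
  idx <- cbind(cons$node, cons$dof)
  clobbered <- f[idx] != 0
  if (any(clobbered)) {
    warning(sum(clobbered), " muscle force component(s) fell on constrained ",
            "DOFs and were zeroed")
    f[idx] <- 0
  }
  structure(list(forces = f, constraints = cons,
                 provenance = list(config = cfg,
                                   muscle_totals = totals,
                                   muscles = names(muscles))),
            class = "load_case")
}
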