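#' Specification of the idealized mandible geometry
#'
#' Parameterizes a U-shaped swept solid standing in for a CT-derived mandible:
#' a rectangular cross-section (corpus width x height) swept along a
#' semicircular anterior dental arch, straight posterior corpus on each side,
#' and a vertical ramus rising from the gonial corner to a condyle. The
#' cross-section carries a cortical shell around a trabecular core; tooth
#' blocks sit on the occlusal (superior) surface at the given arc positions.
#' The intact mesh is exactly mirror-symmetric about the midsagittal plane
#' (x = 0).
#'
#' @param arch_radius radius of the anterior arch centerline (mm).
#' @param corpus_length straight posterior corpus length per side (mm).
#' @param ramus_height ramus height from gonial corner to condyle (mm).
#' @param corpus_section_width,corpus_section_height cross-section dimensions
#'   (mm): width is mediolateral (bucco-lingual), height superoinferior.
#' @param cortical_thickness cortical shell thickness (mm); must be less than
#'   half the smaller section dimension.
#' @param n_arch_segments number of sweep segments along the full semicircular
#'   arch; even, at least 4. Controls the along-arch resolution; corpus and
#'   ramus stations are spaced to match.
#' @param elements_per_section number of lattice cells across the section
#'   width; the cell size also sets the section-height cell count.
#' @param tooth_positions normalized arc coordinates in (0, 1) of tooth blocks
#'   along the hemi-arch (0 = symphysis, 1 = gonial corner). The first three
#'   (most anterior) teeth are the bite teeth (premolars and first molar).
#' @param seed integer recorded for provenance; the generator itself is
#'   deterministic.
#' @return object of class `mandible_spec`.
#' @export
mandible_spec <- function(arch_radius = 15, corpus_length = 35,
                          ramus_height = 30, corpus_section_width = 8,
                          corpus_section_height = 14, cortical_thickness = 2,
                          n_arch_segments = 24, elements_per_section = 4,
                          tooth_positions = c(0.40, 0.52, 0.64, 0.76, 0.88),
                          seed = 1L) {
  s <- list(arch_radius = arch_radius, corpus_length = corpus_length,
            ramus_height = ramus_height,
            corpus_section_width = corpus_section_width,
            corpus_section_height = corpus_section_height,
            cortical_thickness = cortical_thickness,
            n_arch_segments = as.integer(n_arch_segments),
            elements_per_section = as.integer(elements_per_section),
            tooth_positions = sort(tooth_positions), seed = as.integer(seed))
  lens <- c("arch_radius", "corpus_length", "ramus_height",
            "corpus_section_width", "corpus_section_height",
            "cortical_thickness")
  for (f in lens)
    if (!is.numeric(s[[f]]) || length(s[[f]]) != 1 || s[[f]] <= 0)
      stop("mandible_spec: field '", f, "' must be a positive length (mm)")
  if (s$cortical_thickness >=
      min(s$corpus_section_width, s$corpus_section_height) / 2)
    stop("mandible_spec: field 'cortical_thickness' must be < half the ",
         "smaller section dimension")
  if (s$n_arch_segments < 4)
    stop("mandible_spec: field 'n_arch_segments' must be >= 4")
  if (s$n_arch_segments %% 2 != 0)
    stop("mandible_spec: field 'n_arch_segments' must be even ",
         "(mirror symmetry)")
  if (s$elements_per_section < 2)
    stop("mandible_spec: field 'elements_per_section' must be >= 2")
  if (length(s$tooth_positions) &&
      (any(s$tooth_positions <= 0) || any(s$tooth_positions >= 1)))
    stop("mandible_spec: field 'tooth_positions' must lie in (0, 1)")
  class(s) <- "mandible_spec"
  s
}

#' Specification of the planar angle fracture
#'
#' @param side fracture side, `"left"` (default, matching the modeled case)
#'   or `"right"`.
#' @param plane_point point on the fracture plane (mm); NULL places the cut at
#'   the gonial corner of the chosen side.
#' @param plane_normal unit plane normal; NULL uses the sweep tangent at the
#'   chosen station (anterior fragment on the negative side). The realized cut
#'   follows the nearest conforming cross-section plane within the angle
#'   region.
#' @param gap_width fracture gap (mm); default 0.2.
#' @return object of class `fracture_spec`.
#' @export
fracture_spec <- function(side = c("left", "right"), plane_point = NULL,
                          plane_normal = NULL, gap_width = 0.2) {
  side <- match.arg(side)
  if (!is.null(plane_normal)) {
    n <- as.numeric(plane_normal)
    if (length(n) != 3 || abs(sqrt(sum(n^2)) - 1) > 1e-12)
      stop("fracture_spec: plane_normal must be a unit 3-vector")
    plane_normal <- n
  }
  if (!is.numeric(gap_width) || gap_width <= 0)
    stop("fracture_spec: gap_width must be > 0")
  structure(list(side = side, plane_point = plane_point,
                 plane_normal = plane_normal, gap_width = gap_width),
            class = "fracture_spec")
}

#' Specification of the miniplate fixation hardware
#'
#' Dimensions default to the modeled locking miniplates: 26.1 x 2.5 x 1 mm
#' with 4.2 mm screws. `"champy"` places a single plate on the superior
#' border; `"biplanar"` adds a second plate on the inferolateral surface.
#'
#' @param technique one of `"none"`, `"champy"`, `"biplanar"`.
#' @param plate_length,plate_width,plate_thickness plate dimensions (mm).
#' @param screw_diameter screw diameter (mm); sets the radius used to gather
#'   plate-hole nodes at each screw site.
#' @param screws_per_plate number of screws per plate (even; half per
#'   fragment).
#' @param standoff gap between the plate underside and the bone surface (mm),
#'   bridged by the screw ties and closed by plate-bone contact.
#' @return object of class `fixation_spec`.
#' @export
fixation_spec <- function(technique = c("champy", "biplanar", "none"),
                          plate_length = 26.1, plate_width = 2.5,
                          plate_thickness = 1.0, screw_diameter = 4.2,
                          screws_per_plate = 4L, standoff = 0.1) {
  technique <- match.arg(technique)
  stopifnot(plate_length > 0, plate_width > 0, plate_thickness > 0,
            screw_diameter > 0, screws_per_plate >= 2,
            screws_per_plate %% 2 == 0, standoff >= 0)
  structure(list(technique = technique, plate_length = plate_length,
                 plate_width = plate_width, plate_thickness = plate_thickness,
                 screw_diameter = screw_diameter,
                 screws_per_plate = as.integer(screws_per_plate),
                 standoff = standoff),
            class = "fixation_spec")
}
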