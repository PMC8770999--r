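#' Define an isotropic linear-elastic material
#'
#' @param region element-set name the material applies to.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return object of class `material`.
#' @export
material <- function(region, E, nu) {
  if (!is.numeric(E) || E <= 0) stop("material: E must be > 0 (MPa)")
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    stop("material: nu must lie in [0, 0.5)")
  structure(list(region = region, E = E, nu = nu), class = "material")
}

#' Default material table
#'
#' Teeth and trabecular bone use the modeled isotropic properties
#' (E = 24.5 GPa and 10 GPa, nu = 0.3); titanium-alloy hardware uses
#' E = 105 GPa, nu = 0.36. Cortical bone, modeled heterogeneous/orthotropic
#' in subject-specific work, is replaced here by a configurable isotropic
#' default of E = 17 GPa, nu = 0.3 (a typical mandibular cortical axial
#' modulus).
#'
#' @param cortical_E cortical Young's modulus (MPa).
#' @param cortical_nu cortical Poisson ratio.
#' @return list of [material()] objects keyed by region.
#' @export
default_materials <- function(cortical_E = 17000, cortical_nu = 0.3) {
  mats <- list(
    material("cortical", cortical_E, cortical_nu),
    material("trabecular", 10000, 0.3),
    material("teeth", 24500, 0.3),
    material("plate_1", 105000, 0.36),
    material("plate_2", 105000, 0.36))
  names(mats) <- vapply(mats, `[[`, "", "region")
  mats
}
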