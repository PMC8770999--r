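# End-to-end study pipeline: healthy control + fixation treatments under
# ipsilateral and contralateral chewing, with all outcome statistics.

#' Run the full fixation-comparison pipeline
#'
#' Builds the intact control and the fractured/plated treatment meshes from
#' one geometry spec (identical bone mesh, differing only in fracture and
#' hardware), assembles identical material properties and muscle loadings
#' for each requested chewing side, solves every arm, and computes the
#' outcome statistics: trimmed principal-strain extremes in the plate
#' construct, bone-implant interface and fracture zone; the
#' interfragmentary displacement report; sectional moment profiles; and
#' strain-difference maps against the healthy control on the same chew
#' side.
#'
#' @param config a [run_config()].
#' @param verbose emit per-stage progress messages.
#' @return object of class `report_bundle`: per-arm results under `arms`
#'   (keys like `champy_contralateral`, `healthy_left_chew`), comparison
#'   tables `strain_extremes`, `ifd_table`, `diffmap_table`, provenance
#'   (config, hash, timings, convergence).
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  sp <- config_specs(config)
  hash <- config_hash(config)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t, what) {
    dt <- as.numeric(difftime(Sys.time(), t, units = "secs"))
    timings[[what]] <<- dt
    say("  %-28s %.1f s", what, dt)
  }

  say("building meshes (seed %d, hash %s)", config$seed,
      substr(hash, 1, 8))
  tt <- tic()
  intact <- build_mandible(sp$mandible)
  fractured <- cut_fracture(intact, sp$fracture)
  meshes <- list(healthy = intact)
  for (tech in config$techniques) {
    fx <- do.call(fixation_spec,
                  c(list(technique = tech), config$fixation))
    meshes[[tech]] <- attach_fixation(fractured, fx)
  }
  toc(tt, "mesh generation")

  tt <- tic()
  systems <- lapply(meshes, function(m)
    apply_ties(assemble_stiffness(m, sp$materials), m))
  toc(tt, "stiffness assembly")

  mus_args <- config$muscles
  emg_w <- mus_args$emg_working %||% 1.0
  emg_b <- mus_args$emg_balancing %||% 0.6
  pcsa <- if (!is.null(mus_args$pcsa)) unlist(mus_args$pcsa) else DEFAULT_PCSA
  stension <- mus_args$specific_tension %||% 30
  cpar <- do.call(contact_params, config$contact)

  arms <- list()
  strain_fields <- list()
  solve_arm <- function(name, mesh, system, cfg, contact_pairs) {
    tt <- tic()
    muscles <- default_muscles(mesh, emg_table = cfg$emg_table, pcsa = pcsa,
                               specific_tension = stension)
    lc <- assemble_loadcase(cfg, muscles, mesh)
    sol <- solve_contact(system, lc, cpar, pairs = contact_pairs)
    toc(tt, paste0("solve ", name))
    if (!sol$converged)
      warning("run_pipeline: arm '", name, "' did not converge in ",
              sol$iterations, " iterations")
    list(loadcase = lc, solution = sol)
  }

  for (side in config$chew_sides) {
    cfg <- chew_config(chew_side = side,
                       fracture_side = sp$fracture$side,
                       emg_working = emg_w, emg_balancing = emg_b)
    hname <- paste0("healthy_", side, "_chew")
    h <- solve_arm(hname, intact, systems$healthy, cfg, NULL)
    h$strain <- element_strain(h$solution, intact)
    h$moments <- if (h$solution$converged)
      section_moments(h$solution, intact, h$loadcase,
                      side = sp$fracture$side) else NULL
    arms[[hname]] <- c(h, list(mesh = "healthy", chew_side = side,
                               laterality = NA_character_,
                               converged = h$solution$converged))
    for (tech in config$techniques) {
      aname <- paste0(tech, "_", cfg$laterality)
      mesh <- meshes[[tech]]
      a <- solve_arm(aname, mesh, systems[[tech]], cfg,
                     mesh$contact_pairs)
      if (a$solution$converged) {
        a$strain <- element_strain(a$solution, mesh)
        a$ifd <- ifd_report(a$solution, mesh,
                            bin_width = config$ifd_bin_width)
        a$moments <- section_moments(a$solution, mesh, a$loadcase)
        a$extremes <- region_strain_extremes(
          a$strain, mesh,
          c("plate_construct", "bone_implant_interface", "fracture_zone"),
          trim_fraction = config$trim_fraction)
        a$diffmap <- strain_difference_map(a$strain, h$strain, mesh, intact)
      }
      arms[[aname]] <- c(a, list(mesh = tech, chew_side = side,
                                 laterality = cfg$laterality,
                                 converged = a$solution$converged))
    }
  }

  fixed <- names(arms)[vapply(arms, function(a)
    a$mesh != "healthy" && isTRUE(a$converged), TRUE)]
  strain_tab <- do.call(rbind, lapply(fixed, function(nm) {
    cbind(arm = nm, technique = arms[[nm]]$mesh,
          laterality = arms[[nm]]$laterality, arms[[nm]]$extremes)
  }))
  ifd_tab <- do.call(rbind, lapply(fixed, function(nm) {
    data.frame(arm = nm, technique = arms[[nm]]$mesh,
               laterality = arms[[nm]]$laterality,
               n_pairs = arms[[nm]]$ifd$n_pairs,
               mode_pct = arms[[nm]]$ifd$mode_pct,
               mean_pct = arms[[nm]]$ifd$mean_pct)
  }))
  dm_tab <- do.call(rbind, lapply(fixed, function(nm) {
    data.frame(arm = nm, technique = arms[[nm]]$mesh,
               laterality = arms[[nm]]$laterality,
               mean_abs_de1 = attr(arms[[nm]]$diffmap, "mean_abs_de1"),
               mean_abs_de3 = attr(arms[[nm]]$diffmap, "mean_abs_de3"))
  }))

  bundle <- structure(list(
    arms = arms, meshes = meshes,
    strain_extremes = strain_tab, ifd_table = ifd_tab,
    diffmap_table = dm_tab,
    provenance = list(config = config, hash = hash, timings = timings,
                      package_version = tryCatch(
                        as.character(utils::packageVersion("mandfix")),
                        error = function(e) NA_character_),
                      total_s = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")))),
    class = "report_bundle")
  if (!is.null(config$out_dir)) export_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$arms), " arms; config ",
      substr(x$provenance$hash, 1, 8), "\n", sep = "")
  if (!is.null(x$ifd_table)) {
    cat("interfragmentary displacement (mode %):\n")
    print(x$ifd_table[, c("arm", "n_pairs", "mode_pct", "mean_pct")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Export a report bundle to CSV and VTK files
#'
#' Writes the comparison tables (trimmed strain extremes, IFD, difference
#' maps), per-arm moment profiles and IFD pair maps as CSV, deformed-shape
#' VTK fields (display scale 20x) with principal strains and von Mises
#' stress, and the YAML config with its hash.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if absent).
#' @param vtk also write VTK field exports.
#' @param scale display scale factor for deformed shapes.
#' @return `out_dir`, invisibly.
#' @export
export_bundle <- function(bundle, out_dir, vtk = TRUE, scale = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
  wcsv(bundle$strain_extremes, "strain_extremes.csv")
  wcsv(bundle$ifd_table, "ifd_table.csv")
  wcsv(bundle$diffmap_table, "diffmap_table.csv")
  for (nm in names(bundle$arms)) {
    a <- bundle$arms[[nm]]
    if (!isTRUE(a$converged)) next
    if (!is.null(a$moments))
      wcsv(cbind(arm = nm, a$moments), paste0("moments_", nm, ".csv"))
    if (!is.null(a$ifd))
      wcsv(cbind(arm = nm, a$ifd$pairs), paste0("ifd_pairs_", nm, ".csv"))
    if (!is.null(a$diffmap))
      wcsv(as.data.frame(a$diffmap), paste0("diffmap_", nm, ".csv"))
    if (vtk && !is.null(a$strain)) {
      mesh <- bundle$meshes[[a$mesh]]
      write_vtk(mesh, file.path(out_dir, paste0(nm, ".vtk")),
                point_data = list(eps1_microstrain = a$strain$eps1,
                                  eps3_microstrain = a$strain$eps3),
                displacements = a$solution$u, scale = scale)
    }
  }
  cfg <- bundle$provenance$config
  write_config(cfg, file.path(out_dir, "config.yaml"))
  writeLines(bundle$provenance$hash, file.path(out_dir, "config.md5"))
  invisible(out_dir)
}

#' Friction-coefficient sensitivity sweep
#'
#' Re-solves the fixed arms over a set of static friction coefficients and
#' tabulates the interfragmentary displacement statistics against mu,
#' reusing the meshes and assembled stiffness.
#'
#' @param config a [run_config()].
#' @param mus friction coefficients to sweep.
#' @param verbose progress messages.
#' @return list with `summary` (data frame: mu, technique, laterality, mode
#'   and mean IFD), and `bundles` (per-mu lists of IFD reports).
#' @export
sweep_friction <- function(config = run_config(), mus = seq(0.1, 0.5, 0.1),
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  sp <- config_specs(config)
  intact <- build_mandible(sp$mandible)
  fractured <- cut_fracture(intact, sp$fracture)
  meshes <- list()
  systems <- list()
  for (tech in config$techniques) {
    fx <- do.call(fixation_spec, c(list(technique = tech), config$fixation))
    meshes[[tech]] <- attach_fixation(fractured, fx)
    systems[[tech]] <- apply_ties(assemble_stiffness(meshes[[tech]],
                                                     sp$materials),
                                  meshes[[tech]])
  }
  emg_w <- config$muscles$emg_working %||% 1.0
  emg_b <- config$muscles$emg_balancing %||% 0.6
  rows <- list()
  bundles <- list()
  for (mu in mus) {
    cargs <- config$contact
    cargs$mu <- mu
    cpar <- do.call(contact_params, cargs)
    bkey <- sprintf("mu_%.2f", mu)
    bundles[[bkey]] <- list()
    for (side in config$chew_sides) {
      cfg <- chew_config(chew_side = side, fracture_side = sp$fracture$side,
                         emg_working = emg_w, emg_balancing = emg_b)
      for (tech in config$techniques) {
        mesh <- meshes[[tech]]
        muscles <- default_muscles(mesh, emg_table = cfg$emg_table)
        lc <- assemble_loadcase(cfg, muscles, mesh)
        sol <- solve_contact(systems[[tech]], lc, cpar,
                             pairs = mesh$contact_pairs)
        ifd <- if (sol$converged) ifd_report(sol, mesh) else NULL
        say("mu=%.2f %s %s: mode IFD %s%%", mu, tech, cfg$laterality,
            if (is.null(ifd)) "NA" else ifd$mode_pct)
        rows[[length(rows) + 1L]] <- data.frame(
          mu = mu, technique = tech, chew_side = side,
          laterality = cfg$laterality, converged = sol$converged,
          mode_pct = if (is.null(ifd)) NA_real_ else ifd$mode_pct,
          mean_pct = if (is.null(ifd)) NA_real_ else ifd$mean_pct)
        bundles[[bkey]][[paste0(tech, "_", cfg$laterality)]] <- ifd
      }
    }
  }
  list(summary = do.call(rbind, rows), bundles = bundles)
}
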