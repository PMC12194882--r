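# Config-driven pipeline: one structured file (YAML or JSON) describes the
# path source, capillary spec, support strategy and chip, and the pipeline
# turns it into STL files plus a JSON manifest of every derived quantity.

config_defaults <- function() {
  list(
    seed = 1,
    path = list(source = "hilbert", order = 2, dims = 2, step = 150,
                layers = 1, layer_gap = 80, degree = 3,
                corner_fillet_radius = NULL, file = NULL, units_scale = 1,
                radius = 50, pitch = 100, turns = 2, strands = 1,
                z_offset = NULL),
    capillary = list(ld = 40, pd = 5, ps = 8, wall = 10,
                     side_pore_elongation = 1.5, smoothing_iterations = 1,
                     side_cone_deg = 30),
    supports = list(strategy = "lattice", cell_size = 100,
                    beam_diameter = 10, clearance = 2, margin = 40,
                    polygon_sides = 4, collar_clearance = 0,
                    placement = "equidistant", spacing = 250,
                    rotational_offset = 0, fov_width = 400, overlap = 5,
                    stitch_angle = 15, taper_angle = 15, tip_radius = 10,
                    cone_spacing = 200, pipe_segments = 12),
    chip = list(base_thickness = 20, base_margin = 100,
                nozzle_outer_diameter = 508, nozzle_bore = NULL,
                nozzle_height = 300, retaining_wall_height = 100,
                retaining_wall_thickness = 30, include_nozzles = FALSE),
    output = list(dir = "forge_out", decimate = 0.95, export_parts = TRUE)
  )
}

# alias table: short symbol names accepted alongside long names
config_aliases <- list(
  capillary = c(ld = "lumen_diameter", pd = "pore_diameter",
                ps = "pore_spacing", wall = "membrane_thickness")
)

merge_section <- function(defaults, user, section, problems) {
  if (is.null(user)) return(list(value = defaults, problems = problems))
  al <- config_aliases[[section]]
  if (!is.null(al)) {
    for (long in al) {
      if (!is.null(user[[long]])) {
        user[[names(al)[al == long]]] <- user[[long]]
        user[[long]] <- NULL
      }
    }
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    problems <- c(problems, paste0(section, ": unknown key(s) ",
                                   paste(unknown, collapse = ", ")))
  }
  for (nm in intersect(names(user), names(defaults))) {
    defaults[[nm]] <- user[[nm]]
  }
  list(value = defaults, problems = problems)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON config file (or takes a list), fills defaults,
#' resolves short parameter aliases (\code{ld}, \code{pd}, \code{ps},
#' \code{wall}) and validates all constraints, reporting every violation
#' at once. Re-validating a validated config is a fixed point.
#'
#' @param config file path or list.
#' @return A \code{forge_config} list with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (inherits(config, "forge_config")) config <- unclass(config)
  defs <- config_defaults()
  problems <- character(0)
  out <- list(seed = config$seed %||% defs$seed)
  top_unknown <- setdiff(names(config),
                         c("seed", "path", "capillary", "supports", "chip",
                           "output"))
  if (length(top_unknown) > 0) {
    problems <- c(problems, paste0("unknown top-level key(s): ",
                                   paste(top_unknown, collapse = ", ")))
  }
  for (sec in c("path", "capillary", "supports", "chip", "output")) {
    m <- merge_section(defs[[sec]], config[[sec]], sec, problems)
    # NULL-valued defaults are "unset"; dropping them makes a validated
    # config a serialisation fixed point
    out[[sec]] <- m$value[!vapply(m$value, is.null, logical(1))]
    problems <- m$problems
  }
  # cross-field checks
  p <- out$path
  if (!p$source %in% c("csv", "hilbert", "helix")) {
    problems <- c(problems, "path.source must be csv, hilbert or helix")
  }
  if (p$source == "csv" && (is.null(p$file) || !file.exists(p$file))) {
    problems <- c(problems, "path.file must exist for csv source")
  }
  cap <- out$capillary
  spec <- tryCatch(
    capillary_spec(cap$ld, cap$pd, cap$ps, cap$wall,
                   cap$side_pore_elongation, cap$smoothing_iterations),
    error = function(e) {
      problems <<- c(problems, conditionMessage(e))
      NULL
    })
  if (!out$supports$strategy %in% c("polygonal", "lattice", "cone",
                                    "none")) {
    problems <- c(problems,
                  "supports.strategy must be polygonal, lattice or cone")
  }
  if (!is.null(out$chip$nozzle_bore) &&
      out$chip$nozzle_bore >= out$chip$nozzle_outer_diameter) {
    problems <- c(problems, "chip.nozzle_bore must be < outer diameter")
  }
  if (out$output$decimate < 0 || out$output$decimate >= 1) {
    problems <- c(problems, "output.decimate must be in [0, 1)")
  }
  if (length(problems) > 0) {
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  }
  structure(out, class = "forge_config")
}

build_path_from_config <- function(cfg) {
  p <- cfg$path
  fillet <- p$corner_fillet_radius %||% (cfg$capillary$ld / 2)
  switch(p$source,
    csv = load_path_csv(p$file, units_scale = p$units_scale,
                        degree = p$degree,
                        corner_fillet_radius = fillet),
    hilbert = hilbert_path(p$order, dims = p$dims, step = p$step,
                           layers = p$layers, layer_gap = p$layer_gap,
                           degree = p$degree,
                           corner_fillet_radius = fillet),
    helix = helix_path(p$radius, p$pitch, p$turns, strands = p$strands,
                       degree = p$degree)[[1]])
}

#' Run the full design pipeline
#'
#' Builds the path, membrane, supports and chip described by a config,
#' exports STL files and writes a JSON manifest recording every derived
#' quantity (u, v, pore count, path length, seam positions, face counts)
#' plus file checksums. Output is deterministic under a fixed seed.
#'
#' @param config a \code{\link{validate_config}} result, config list or
#'   file path.
#' @param quiet suppress progress messages.
#' @param return_meshes attach the built meshes (\code{path},
#'   \code{membrane}, \code{supports}, \code{chip}, \code{pore_table},
#'   \code{decimated}) to the returned manifest under \code{$meshes}.
#' @return The manifest (invisibly), also written to
#'   \code{<output.dir>/manifest.json}.
#' @export
run_pipeline <- function(config, quiet = FALSE, return_meshes = FALSE) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  say <- function(...) if (!quiet) message(...)
  outdir <- cfg$output$dir
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    say("created output dir ", outdir)
  }
  cap <- cfg$capillary
  spec <- capillary_spec(cap$ld, cap$pd, cap$ps, cap$wall,
                         cap$side_pore_elongation,
                         cap$smoothing_iterations)
  path <- build_path_from_config(cfg)
  # lift the scaffold so the capillary underside clears the base plane
  zmin <- min(path$dense$xyz[, 3])
  lift <- cfg$path$z_offset %||%
    (cap$ld / 2 + cap$wall + cfg$supports$margin)
  path <- shift_path(path, c(0, 0, lift - zmin))
  grid <- subdivision_grid(path$path_length, spec)
  say("grid: u=", grid$u, " v=", grid$v, " (", grid$u * grid$v, " pores)")
  shell <- sweep_shell(path, grid, spec)
  pored <- cut_pores(shell, grid, spec)
  pored <- elongate_side_pores(pored, spec, cap$side_cone_deg)
  membrane <- thicken(pored, spec$membrane_thickness, "outward")
  pore_table <- pore_size_profile(membrane)
  if (spec$smoothing_iterations > 0) {
    membrane_sm <- smooth_mesh(membrane, spec$smoothing_iterations)
  } else {
    membrane_sm <- membrane
  }
  outer_d <- cap$ld + 2 * cap$wall
  sup <- cfg$supports
  seams <- NULL
  support_mesh <- empty_mesh()
  if (sup$strategy == "polygonal") {
    pspec <- polygonal_support_spec(sup$polygon_sides, sup$beam_diameter,
                                    sup$collar_clearance, sup$placement,
                                    sup$spacing, sup$rotational_offset)
    layout <- fov_layout(sup$fov_width, sup$overlap, sup$stitch_angle)
    if (pspec$placement == "at_fov_seams") {
      seams <- predict_fov_seams(layout, path)
    }
    pos <- support_positions(path, pspec, layout)
    support_mesh <- polygonal_supports(path, pspec, pos, outer_d)
  } else if (sup$strategy == "lattice") {
    vr <- apply(path$dense$xyz, 2, range)
    bb <- rbind(vr[1, ] - (outer_d / 2 + sup$margin),
                vr[2, ] + outer_d / 2 + sup$margin)
    bb[1, 3] <- 0  # lattice anchors on the base plane
    lspec <- lattice_spec(sup$cell_size, sup$beam_diameter, bb,
                          sup$clearance)
    edges <- lattice_edges(lspec)
    edges <- cull_struts(edges, membrane, sup$clearance,
                         radius = sup$beam_diameter / 2)
    edges <- drop_floating_struts(edges, base_z = 0)
    support_mesh <- pipe_struts(edges, sup$beam_diameter,
                                n_seg = sup$pipe_segments)
  } else if (sup$strategy == "cone") {
    anchors <- cone_anchor_positions(path, sup$cone_spacing)
    cspec <- cone_support_spec(sup$taper_angle, sup$tip_radius, anchors,
                               clearance = sup$clearance)
    support_mesh <- cone_supports(cspec, path, outer_d)
  }
  chspec <- chip_spec(cfg$chip$base_thickness, cfg$chip$base_margin,
                      cfg$chip$nozzle_outer_diameter,
                      cfg$chip$nozzle_bore %||% cap$ld,
                      cfg$chip$nozzle_height,
                      cfg$chip$retaining_wall_height,
                      cfg$chip$retaining_wall_thickness)
  scaffold <- assemble(Filter(function(m) nrow(m$faces) > 0,
                              list(membrane_sm, support_mesh)))
  base <- build_base(NULL, chspec, scaffold = scaffold)
  comps <- list(membrane_sm, support_mesh, base)
  if (isTRUE(cfg$chip$include_nozzles)) {
    ends <- path_point(path, c(0, path$path_length))
    comps <- c(comps, list(build_nozzles(ends, chspec)))
  }
  chip <- assemble(Filter(function(m) nrow(m$faces) > 0, comps))
  files <- character(0)
  if (isTRUE(cfg$output$export_parts)) {
    files["membrane"] <- file.path(outdir, "membrane.stl")
    export_stl(membrane_sm, files["membrane"])
    if (nrow(support_mesh$faces) > 0) {
      files["supports"] <- file.path(outdir, "supports.stl")
      export_stl(support_mesh, files["supports"])
    }
  }
  files["chip"] <- file.path(outdir, "chip.stl")
  export_stl(chip, files["chip"])
  decim <- NULL
  if (cfg$output$decimate > 0) {
    decimated <- decimate(chip, cfg$output$decimate)
    files["chip_decimated"] <- file.path(outdir, "chip_decimated.stl")
    export_stl(decimated, files["chip_decimated"])
    decim <- list(requested = cfg$output$decimate,
                  achieved = attr(decimated, "achieved_reduction"),
                  hausdorff_um = attr(decimated, "hausdorff_um"),
                  faces = nrow(decimated$faces))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("capforge")),
    seed = cfg$seed,
    path = list(source = cfg$path$source,
                length_um = path$path_length,
                n_points = nrow(path$points)),
    grid = list(u = grid$u, v = grid$v, s_l = grid$s_l, s_r = grid$s_r,
                pore_count = grid$u * grid$v),
    pores = list(n = nrow(pore_table),
                 mean_diameter_um = mean(pore_table$diameter_um),
                 n_elongated = sum(pore_table$elongation > 1)),
    membrane_faces = nrow(membrane_sm$faces),
    support_faces = nrow(support_mesh$faces),
    chip_faces = nrow(chip$faces),
    seams = if (!is.null(seams)) seams$s,
    decimation = decim,
    files = as.list(files),
    checksums = as.list(tools::md5sum(unname(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote ", length(files), " STL file(s) and manifest to ", outdir)
  if (return_meshes) {
    manifest$meshes <- list(
      path = path, membrane = membrane_sm, supports = support_mesh,
      chip = chip, pore_table = pore_table,
      decimated = if (cfg$output$decimate > 0) decimated)
  }
  invisible(manifest)
}

# translate a centerline path (rebuilds dense cache)
shift_path <- function(path, offset) {
  centerline_path(sweep(path$points, 2, as.double(offset), "+"),
                  degree = path$degree, closed = path$closed)
}

# anchor plan positions under the path at a given arc-length spacing
cone_anchor_positions <- function(path, spacing) {
  n <- max(2, floor(path$path_length / spacing) + 1)
  s <- seq(0, path$path_length, length.out = n)
  path_point(path, s)[, 1:2, drop = FALSE]
}
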