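default_config <- function() {
  list(
    scene = list(n_tomograms = 8, membrane_shape = "flat",
                 patch_extent = 200, extent_range = c(120, 320),
                 intermembrane_gap = 24.2,
                 n_bridges = 24, length_mean = 24.2, length_sd = 4.76,
                 length_min = 9.4, length_max = 52, tilt_scale = 16,
                 placement = "csr"),
    inputs = list(particles = NULL, er_mesh = NULL, omm_mesh = NULL,
                  pixel_size_nm = 1),
    filters = list(drop_flags = c("misaligned", "peroxisome_mcs")),
    nn = list(min_per_tomogram = 3,
              kinds = c("er_anchor", "centre", "omm_anchor")),
    tilt = list(enabled = TRUE, radius = 20),
    density = list(d_contact = 40)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full contact-site analysis pipeline
#'
#' Chains the stages simulate (or load) -> flag filtering -> dipole
#' geometry -> length classification -> nearest-neighbour analysis (ER
#' anchors, centres, OMM anchors) -> short/long contingency -> tilt
#' analysis -> contact-area and density statistics, and writes the stage
#' tables, a headline summary JSON and a reproducibility manifest to
#' \code{out_dir}.
#'
#' The configuration is a nested list (or a YAML file path) with sections
#' \code{scene} (synthetic-scene parameters, used when no input files are
#' given), \code{inputs} (paths to \code{particles} CSV and
#' \code{er_mesh}/\code{omm_mesh} OBJ files), \code{filters},
#' \code{nn}, \code{tilt} and \code{density}; omitted entries fall back to
#' documented defaults.
#'
#' @param config nested list or path to a YAML file; \code{NULL} uses the
#'   defaults (synthetic run).
#' @param seed integer seed controlling all randomness.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = tempfile()) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mcsarch",
                   version = as.character(utils::packageVersion("mcsarch")),
                   seed = as.integer(seed), config = cfg,
                   input_hashes = list(), stages = list())
  synthetic <- is.null(cfg$inputs$particles)
  meshes <- list()
  if (synthetic) {
    parts <- list()
    # per-tomogram patch extents vary over extent_range at constant bridge
    # density, so contact sites differ in area as real ones do
    set.seed(derive_seed(seed, 0L))
    extents <- stats::runif(cfg$scene$n_tomograms,
                            min(cfg$scene$extent_range),
                            max(cfg$scene$extent_range))
    dens <- cfg$scene$n_bridges / cfg$scene$patch_extent^2
    for (i in seq_len(cfg$scene$n_tomograms)) {
      sp <- do.call(scene_params, c(
        cfg$scene[setdiff(names(cfg$scene),
                          c("n_tomograms", "extent_range", "patch_extent",
                            "n_bridges"))],
        list(seed = derive_seed(seed, i),
             patch_extent = extents[i], density = dens,
             tomogram_id = sprintf("tomo-%02d", i))))
      sc <- generate_scene(sp)
      parts[[i]] <- as.data.frame(sc$particles)
      meshes[[sprintf("tomo-%02d", i)]] <- list(er = sc$er, omm = sc$omm)
    }
    t <- particle_table(do.call(rbind, parts),
                        provenance = list(list(step = "simulate",
                                               seed = seed,
                                               n_tomograms =
                                                 cfg$scene$n_tomograms)))
  } else {
    for (f in c("particles", "er_mesh", "omm_mesh")) {
      pth <- cfg$inputs[[f]]
      if (!is.null(pth)) {
        if (!file.exists(pth)) {
          stop_mcsarch(sprintf("stage inputs: file for '%s' not found: %s",
                               f, pth), "configuration_error")
        }
        manifest$input_hashes[[f]] <- unname(tools::md5sum(pth))
      }
    }
    t <- read_particle_table(cfg$inputs$particles,
                             pixel_size_nm = cfg$inputs$pixel_size_nm %||% 1)
    if (!is.null(cfg$inputs$er_mesh)) {
      meshes[["all"]] <- list(er = read_obj(cfg$inputs$er_mesh, "er"),
                              omm = read_obj(cfg$inputs$omm_mesh, "omm"))
    }
  }
  manifest$stages$input <- list(n_picked = nrow(t))

  ## filtering and geometry
  t <- filter_particles(t, cfg$filters$drop_flags)
  manifest$stages$filter <- list(
    n_after_filter = nrow(t),
    dropped = attr(t, "provenance")[[length(attr(t, "provenance"))]]$dropped_flags)
  t <- dipole_to_particle(t)
  t <- classify_by_length(t)
  cls <- attr(t, "class_summary")
  write_particle_table(t, file.path(out_dir, "particles.csv"))

  ## nearest neighbours
  nn_out <- list()
  nn_tables <- list()
  for (kind in cfg$nn$kinds) {
    rec <- nn_distances(t, kind,
                        min_per_tomogram = cfg$nn$min_per_tomogram)
    s <- nn_summary(rec)
    nn_out[[kind]] <- list(median = s$median, mad = s$mad, n = s$n,
                           n_tomograms = s$n_tomograms,
                           n_excluded_bridges =
                             attr(rec, "n_excluded_bridges"),
                           excluded_tomograms =
                             as.list(attr(rec, "excluded_tomograms")))
    nn_tables[[kind]] <- rec
  }
  utils::write.csv(do.call(rbind, nn_tables),
                   file.path(out_dir, "nn.csv"), row.names = FALSE)
  cont <- class_contingency(nn_tables[["centre"]])

  ## tilts
  tilt_out <- NULL
  if (isTRUE(cfg$tilt$enabled)) {
    if (length(meshes) == 0) {
      stop_mcsarch("stage tilt: enabled but no membrane meshes available",
                   "configuration_error")
    }
    tilts <- list()
    for (tm in names(meshes)) {
      sub <- t[if (tm == "all") TRUE else t$tomogram_id == tm, ,
               drop = FALSE]
      class(sub) <- class(t)
      if (nrow(sub) == 0) next
      tilts[[paste0(tm, "-er")]] <-
        bridge_tilts(sub, meshes[[tm]]$er, "er", radius = cfg$tilt$radius)
      tilts[[paste0(tm, "-omm")]] <-
        bridge_tilts(sub, meshes[[tm]]$omm, "omm", radius = cfg$tilt$radius)
    }
    tilts <- do.call(rbind, tilts)
    rownames(tilts) <- NULL
    utils::write.csv(tilts, file.path(out_dir, "tilts.csv"),
                     row.names = FALSE)
    tilt_out <- lapply(c(er = "er", omm = "omm"), function(m)
      tilt_summary(tilts[tilts$membrane == m, , drop = FALSE]))
  }

  ## per-MCS density (one MCS per tomogram mesh pair)
  density_out <- NULL
  if (length(meshes) > 0) {
    mcs <- do.call(rbind, lapply(names(meshes), function(tm) {
      n_b <- if (tm == "all") nrow(t) else sum(t$tomogram_id == tm)
      data.frame(mcs_id = tm, tomogram_id = tm,
                 er_contact_area = as.numeric(
                   surface_area(meshes[[tm]]$er, meshes[[tm]]$omm,
                                d_contact = cfg$density$d_contact)),
                 n_bridges = n_b)
    }))
    utils::write.csv(mcs, file.path(out_dir, "mcs.csv"), row.names = FALSE)
    apb <- area_per_bridge(mcs)
    density_out <- list(
      n_mcs = nrow(apb$mcs),
      median_area_per_bridge = apb$median,
      mad_area_per_bridge = apb$mad,
      max_density_per_1e4nm2 = apb$max_density,
      uniform_spacing_nm = uniform_spacing(apb$median))
    if (nrow(mcs) >= 3) {
      density_out$bridges_vs_area_r <- bridges_vs_area(mcs)$r
    }
  }

  summary <- list(
    counts = manifest$stages,
    classes = list(n_short = cls$short$n, n_long = cls$long$n,
                   short = cls$short, long = cls$long),
    nearest_neighbour = nn_out,
    contingency = list(table = as.list(as.data.frame(cont$table)$Freq),
                       chi_square = cont$chi_square, df = cont$df,
                       p_value = cont$p_value,
                       row_percent = as.list(as.vector(cont$row_percent))),
    tilt = tilt_out,
    density = density_out)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
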