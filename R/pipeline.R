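# End-to-end orchestration: phantom generation or stack loading ->
# isotropic resampling -> segmentation -> morphometry -> orientation
# analysis -> collagen -> group statistics, as one reproducible run.

#' Analysis parameters for one run
#'
#' Collects every tunable of the per-stack analysis with its default.
#'
#' @param bin_edges_um,mode_resolution_um diameter statistic, see
#'   [diameter_binning()].
#' @param min_component_voxels small-object filter before skeletonization.
#' @param surface_smooth_sigma_vox isosurface pre-smoothing, see
#'   [surface_density()].
#' @param block_size_um,super_block_um,gradient_sigma_um,min_signal_fraction,anisotropy_threshold
#'   orientation analysis, see [block_orientations()] / [local_disarray()].
#' @param invert_cell_channel intensity-invert the cell channel before the
#'   structure tensor (TRUE for raw membrane-stain stacks; the packaged
#'   phantom already emits the negative-style image, so FALSE by default).
#' @param collagen_method automatic threshold for the collagen channel.
#' @return named list of parameters.
#' @export
morphometry_params <- function(bin_edges_um = seq(0, 30, by = 5),
                               mode_resolution_um = 0.1,
                               min_component_voxels = 10L,
                               surface_smooth_sigma_vox = 0.7,
                               block_size_um = 60,
                               super_block_um = 120,
                               gradient_sigma_um = 2,
                               min_signal_fraction = 0.01,
                               anisotropy_threshold = 0.1,
                               invert_cell_channel = FALSE,
                               collagen_method = "isodata") {
  as.list(environment())
}

#' Full morphometric record for one stack
#'
#' Runs the whole per-stack chain and returns one record row.  Channels may
#' be NULL (the corresponding metrics come back NA).  Anisotropic grids are
#' resampled to isotropic resolution first.
#'
#' @param vessel,cell,collagen `voxel_grid`s of the three channels.
#' @param params a [morphometry_params()] list.
#' @param metadata named list merged into the record (e.g. strain,
#'   age_weeks, ventricle, region).
#' @return one-row data.frame: metadata columns plus `mean_diameter_um`,
#'   `density_um_inv`, `length_density_um_inv2`, `angular_dispersion`,
#'   `disarray_cell`, `collagen_pct`, `n_segments`.
#' @export
analyze_stack <- function(vessel, cell = NULL, collagen = NULL,
                          params = morphometry_params(),
                          metadata = list()) {
  iso <- function(g) if (!is.null(g) && !is_isotropic(g)) rescale_isotropic(g) else g
  vessel <- iso(vessel); cell <- iso(cell); collagen <- iso(collagen)

  rec <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (nrow(rec) == 0) rec <- data.frame(row.names = 1)
  rec$mean_diameter_um <- NA_real_
  rec$density_um_inv <- NA_real_
  rec$length_density_um_inv2 <- NA_real_
  rec$angular_dispersion <- NA_real_
  rec$disarray_cell <- NA_real_
  rec$collagen_pct <- NA_real_
  rec$n_segments <- NA_integer_

  if (!is.null(vessel)) {
    thr <- otsu_threshold(vessel)
    mask <- filter_small_components(binarize(vessel, thr),
                                    params$min_component_voxels)
    graph <- skeletonize(mask, min_component_voxels = 1L)
    graph <- measure_segments(graph, mask)
    rec$n_segments <- length(graph$segments)
    binning <- diameter_binning(params$bin_edges_um, params$mode_resolution_um)
    rec$mean_diameter_um <- tryCatch(mean_diameter(graph, binning),
                                     error = function(e) NA_real_)
    rec$density_um_inv <- surface_density(mask, params$surface_smooth_sigma_vox)
    rec$length_density_um_inv2 <-
      length_density(graph, prod(dim(mask$data) * mask$pitch_um))
    disp <- tryCatch({
      fld <- block_orientations(vessel, params$block_size_um,
                                params$gradient_sigma_um,
                                params$min_signal_fraction,
                                params$anisotropy_threshold)
      local_disarray(fld, params$super_block_um)$global_disarray
    }, error = function(e) NA_real_)
    rec$angular_dispersion <- disp
  }
  if (!is.null(cell)) {
    rec$disarray_cell <- tryCatch({
      fld <- block_orientations(cell, params$block_size_um,
                                params$gradient_sigma_um,
                                params$min_signal_fraction,
                                params$anisotropy_threshold,
                                invert = params$invert_cell_channel)
      local_disarray(fld, params$super_block_um)$global_disarray
    }, error = function(e) NA_real_)
  }
  if (!is.null(collagen)) {
    rec$collagen_pct <- collagen_percentage(collagen,
                                            method = params$collagen_method)
  }
  rec
}

#' Design table for a synthetic two-strain longitudinal study
#'
#' One row per stack: a hypertensive-model strain ("SHR") with
#' `density_ratio`-fold more capillaries than the control ("WKY") at every
#' age, and an orientation concentration that falls with age in the
#' hypertensive strain only (disarray and angular dispersion increase with
#' age there), constant in the control.
#'
#' @param strains,ages,regions factor levels; `regions` replicate stacks per
#'   strain x age cell.
#' @param ventricle ventricle label carried in the metadata.
#' @param n_vessels_control capillaries per control stack.
#' @param density_ratio hypertensive / control capillary count ratio.
#' @param kappa_control orientation concentration of the control strain.
#' @param kappa_by_age concentration per age for the hypertensive strain
#'   (parallel to `ages`).
#' @param seed base seed; each stack gets `seed + row index`.
#' @return data.frame usable as the `design$stacks` of [run_study()].
#' @export
phantom_study_design <- function(strains = c("WKY", "SHR"),
                                 ages = c(4, 8, 18, 24),
                                 regions = 3,
                                 ventricle = "LV",
                                 n_vessels_control = 25,
                                 density_ratio = 2,
                                 kappa_control = 30,
                                 kappa_by_age = c(30, 12, 5, 2.5),
                                 seed = 1L) {
  stopifnot(length(kappa_by_age) == length(ages))
  d <- expand.grid(region = seq_len(regions), age_weeks = ages,
                   strain = strains, stringsAsFactors = FALSE)
  d$ventricle <- ventricle
  d$n_vessels <- ifelse(d$strain == "SHR",
                        round(n_vessels_control * density_ratio),
                        n_vessels_control)
  d$kappa <- ifelse(d$strain == "SHR",
                    kappa_by_age[match(d$age_weeks, ages)],
                    kappa_control)
  d$seed <- seed + seq_len(nrow(d))
  d[, c("strain", "age_weeks", "ventricle", "region",
        "n_vessels", "kappa", "seed")]
}

#' Run a complete study
#'
#' Takes a run configuration (a list, or the path of a YAML file), analyses
#' every stack, and writes the per-stack record table, ANOVA / post hoc /
#' correlation tables, the min-max-normalized heat-map matrix, a config
#' snapshot and a parameter log into the output directory.  Reruns with the
#' same config reproduce every output byte.
#'
#' Config fields: `seed`, `out_dir`, `params` (see [morphometry_params()]),
#' and `design` - either `type: "phantom"` with a `stacks` data.frame (as
#' from [phantom_study_design()]; extra columns override [phantom_spec()]
#' fields per stack) and optional `base_spec` overrides, or `type: "files"`
#' with `stacks` rows naming `vessel`/`cell`/`collagen` TIFF paths plus
#' `pitch_z`/`pitch_xy` and metadata.
#'
#' @param config list or YAML path.
#' @return invisibly, list with `records`, `anova`, `correlations`,
#'   `out_dir`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$design))
  out_dir <- config$out_dir %||% stop("config needs an `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(morphometry_params, config$params %||% list())
  design <- config$design
  stacks <- as.data.frame(design$stacks, stringsAsFactors = FALSE)
  if (nrow(stacks) == 0) stop("design has no stacks")
  log_lines <- c("capimorph run", paste0("stacks: ", nrow(stacks)),
                 paste0("param ", names(params), " = ",
                        vapply(params, function(p) paste(format(p), collapse = ","),
                               character(1))))

  meta_cols <- intersect(c("strain", "age_weeks", "ventricle", "region"),
                         names(stacks))
  records <- vector("list", nrow(stacks))
  for (i in seq_len(nrow(stacks))) {
    row <- stacks[i, , drop = FALSE]
    meta <- as.list(row[, meta_cols, drop = FALSE])
    if (identical(design$type, "files")) {
      pz <- row$pitch_z %||% stop("files design needs pitch_z")
      pxy <- row$pitch_xy %||% stop("files design needs pitch_xy")
      pitch <- c(pz, pxy, pxy)
      get_chan <- function(name) {
        p <- row[[name]]
        if (is.null(p) || is.na(p) || !nzchar(p)) return(NULL)
        if (!file.exists(p))
          stop("stack ", i, ": missing file `", p, "`")
        load_stack(p, pitch, name)
      }
      vessel <- get_chan("vessel")
      cell <- get_chan("cell")
      collagen <- get_chan("collagen")
    } else {
      spec_args <- config$design$base_spec %||% list()
      for (f in setdiff(names(row), c(meta_cols, "seed")))
        if (f %in% names(formals(phantom_spec))) spec_args[[f]] <- row[[f]]
      spec_args$seed <- row$seed %||% ((config$seed %||% 1L) + i)
      ph <- generate_phantom(do.call(phantom_spec, spec_args))
      vessel <- ph$vessel; cell <- ph$cell; collagen <- ph$collagen
    }
    rec <- tryCatch(
      analyze_stack(vessel, cell, collagen, params, meta),
      error = function(e) stop("stage failure on stack ", i, " (",
                               paste(unlist(meta), collapse = "/"), "): ",
                               conditionMessage(e)))
    records[[i]] <- rec
    log_lines <- c(log_lines, sprintf("stack %d analysed (%s)", i,
                                      paste(unlist(meta), collapse = "/")))
  }
  records <- do.call(rbind, records)
  write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)

  ## study statistics (when the design supports them)
  metrics <- c("mean_diameter_um", "density_um_inv", "angular_dispersion",
               "disarray_cell", "collagen_pct")
  anovas <- list()
  if (all(c("strain", "age_weeks") %in% names(records)) &&
      length(unique(records$strain)) >= 2 &&
      length(unique(records$age_weeks)) >= 2) {
    for (m in metrics) {
      a <- tryCatch(two_way_anova(records, m), error = function(e) NULL)
      if (!is.null(a)) {
        anovas[[m]] <- a
        write.csv(a$table, file.path(out_dir, paste0("anova_", m, ".csv")),
                  row.names = FALSE)
      }
    }
  }
  cors <- NULL
  have <- metrics[vapply(metrics, function(m)
    m %in% names(records) && sum(!is.na(records[[m]])) >= 3 &&
      var(records[[m]], na.rm = TRUE) > 0, logical(1))]
  if (length(have) >= 2) {
    pairs <- utils::combn(have, 2)
    cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      pc <- tryCatch(pearson_cor(records[[pairs[1, j]]], records[[pairs[2, j]]]),
                     error = function(e) NULL)
      if (is.null(pc)) return(NULL)
      data.frame(metric_x = pairs[1, j], metric_y = pairs[2, j],
                 r = pc$r, n = pc$n, p_value = pc$p_value)
    }))
    if (!is.null(cors))
      write.csv(cors, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  }
  norm_ok <- have[vapply(have, function(m)
    diff(range(records[[m]], na.rm = TRUE)) > 0, logical(1))]
  if (length(norm_ok) > 0) {
    hm <- tryCatch(
      minmax_normalize(records[!is.na(records[[norm_ok[1]]]), ], norm_ok),
      error = function(e) NULL)
    if (!is.null(hm))
      write.csv(hm, file.path(out_dir, "heatmap.csv"), row.names = FALSE)
  }
  cfg <- config
  cfg$design$stacks <- NULL
  yaml::write_yaml(cfg, file.path(out_dir, "config_snapshot.yaml"))
  write.csv(stacks, file.path(out_dir, "stacks.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(records = records, anova = anovas, correlations = cors,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
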