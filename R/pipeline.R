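#' Pipeline configuration
#'
#' Loads and validates a structured (YAML) configuration holding per-stage
#' parameter blocks for an end-to-end run. Recognised blocks and defaults:
#'
#' * `stages`: subset of `segment`, `isobin`, `thickness`, `tensor`,
#'   `regions`, `project`, executed in that fixed order.
#' * `input`: paths `rgb` (colour stack), `mask` (binary volume, used when
#'   `segment`/`isobin` are not run), `labels` (anatomical regions).
#' * `segment`: `model` (colour-model YAML; package default model if null),
#'   `min_component` (artifact-cleaning size, default 1).
#' * `isobin`: `target_spacing` (mm, default 0.5).
#' * `thickness`: `cap` (default 64), `lattice_n` (default 2).
#' * `tensor`: `cap` (default 16), `lattice_n` (default 2), `output_bin`
#'   (default 2), `theta` (classification threshold, default 0).
#' * `project`: `axis` (default 2), `colormap` (default `"viridis"`).
#' * `output_dir`, `prefix` (default `"out"`), `seed` (default 1).
#'
#' The scan-range defaults (64 voxels for thickness, 16 for orientation)
#' and the 0.5 mm isometric target mirror the whole-body workflow the
#' package implements.
#'
#' @param x path to a YAML file, or a list with the same structure.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    stages = c("segment", "isobin", "thickness", "tensor", "regions", "project"),
    input = list(),
    segment = list(model = NULL, min_component = 1),
    isobin = list(target_spacing = 0.5),
    thickness = list(cap = 64, lattice_n = 2),
    tensor = list(cap = 16, lattice_n = 2, output_bin = 2, theta = 0),
    project = list(axis = 2, colormap = "viridis"),
    output_dir = ".", prefix = "out", seed = 1)
  cfg <- utils::modifyList(defaults, cfg)
  known <- c("segment", "isobin", "thickness", "tensor", "regions", "project")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0)
    stop("pipeline_config: unknown stages: ", paste(bad, collapse = ", "))
  cfg$stages <- known[known %in% cfg$stages]
  if (cfg$thickness$cap < 1 || cfg$tensor$cap < 1)
    stop("pipeline_config: scan-range caps must be >= 1")
  if (cfg$isobin$target_spacing <= 0)
    stop("pipeline_config: target_spacing must be > 0")
  if (cfg$tensor$theta < 0 || cfg$tensor$theta >= 1)
    stop("pipeline_config: theta must lie in [0, 1)")
  if (cfg$tensor$output_bin < 1)
    stop("pipeline_config: output_bin must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in the fixed order segment -> isobin ->
#' thickness -> tensor -> regions -> project, writing each stage's NIFTI /
#' CSV / PNG artefacts under `output_dir` with the configured `prefix`,
#' plus a YAML run manifest recording the parameters, the MD5 checksums of
#' the input files, and the package version. All randomness is seeded, so
#' re-running an identical configuration produces bit-identical outputs.
#'
#' Artefact names mirror the stage outputs: `<prefix>.labels.nii.gz`,
#' `<prefix>.iso.nii.gz`, `<prefix>.t.nii.gz`, `<prefix>.c<bin>.nii.gz`
#' (symmetric-matrix tensor volume) with `_e1`, `_e2`, `_westin`,
#' `_westin_rank` RGB companions, `<prefix>.regions.csv` and
#' `<prefix>.xray.png`.
#'
#' @param config a [pipeline_config()] (or path / list accepted by it).
#' @param quiet suppress progress messages.
#' @return named list of artefact paths, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  t0 <- Sys.time()
  note <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(cfg$output_dir, cfg$prefix)
  artefacts <- list()
  inputs <- unlist(cfg$input)

  mask <- NULL
  if ("segment" %in% cfg$stages) {
    if (is.null(cfg$input$rgb))
      stop("run_pipeline: stage 'segment' needs input$rgb")
    note("[segment] reading %s", cfg$input$rgb)
    rgb <- read_volume(cfg$input$rgb)
    model <- if (is.null(cfg$segment$model)) color_model()
             else read_color_model(cfg$segment$model)
    labels <- segment_collagen(rgb, model)
    labels <- clean_artifacts(labels, cfg$segment$min_component)
    artefacts$labels <- paste0(pre, ".labels.nii.gz")
    write_volume(labels, artefacts$labels)
    mask <- volume3d((labels$values > 0) * 1, spacing = labels$spacing)
    note("[segment] %d foreground voxels", sum(mask$values))
  } else if (!is.null(cfg$input$mask)) {
    v <- read_volume(cfg$input$mask)
    mask <- volume3d((v$values > 0) * 1, spacing = v$spacing)
  }

  if ("isobin" %in% cfg$stages) {
    if (is.null(mask)) stop("run_pipeline: stage 'isobin' needs a mask")
    iso_counts <- isometric_bin(mask, cfg$isobin$target_spacing)
    artefacts$iso <- paste0(pre, ".iso.nii.gz")
    write_volume(iso_counts, artefacts$iso)
    mask <- volume3d((iso_counts$values > 0) * 1, spacing = iso_counts$spacing)
    note("[isobin] %s grid at %.3g mm", paste(vol_dim(mask), collapse = "x"),
         cfg$isobin$target_spacing)
  }
  if (is.null(mask) && length(intersect(cfg$stages,
      c("thickness", "tensor", "regions", "project"))) > 0)
    stop("run_pipeline: downstream stages need input$mask or the segment/isobin stages")

  thick <- NULL
  if ("thickness" %in% cfg$stages) {
    thick <- thickness_field(mask, lattice_directions(cfg$thickness$lattice_n),
                             cap = cfg$thickness$cap)
    artefacts$thickness <- paste0(pre, ".t.nii.gz")
    write_volume(thick, artefacts$thickness)
    note("[thickness] done (cap %d)", cfg$thickness$cap)
  }

  rank <- NULL
  if ("tensor" %in% cfg$stages) {
    field <- tensor_field(mask,
                          lattice_directions(cfg$tensor$lattice_n, FALSE),
                          cap = cfg$tensor$cap,
                          output_bin = cfg$tensor$output_bin)
    cpre <- paste0(pre, ".c", cfg$tensor$output_bin)
    artefacts$tensor <- paste0(cpre, ".nii.gz")
    write_volume(field, artefacts$tensor)
    for (mode in c("e1", "e2", "westin", "rank")) {
      p <- paste0(cpre, "_", if (mode == "rank") "westin_rank" else mode, ".nii.gz")
      write_volume(encode_tensor_rgb(field, mode, threshold = cfg$tensor$theta), p)
      artefacts[[paste0("tensor_", mode)]] <- p
    }
    rank <- structure_rank(field, threshold = cfg$tensor$theta)
    note("[tensor] done (cap %d, bin %d)", cfg$tensor$cap, cfg$tensor$output_bin)
  }

  if ("regions" %in% cfg$stages) {
    if (is.null(cfg$input$labels))
      stop("run_pipeline: stage 'regions' needs input$labels")
    if (is.null(thick) || is.null(rank))
      stop("run_pipeline: stage 'regions' needs the thickness and tensor stages")
    regions <- read_volume(cfg$input$labels)
    if (!inherits(regions, "label_volume"))
      regions <- label_volume(array(as.integer(regions$values), vol_dim(regions)),
                              spacing = regions$spacing)
    tab <- compute_region_table(mask, thick, rank, regions)
    artefacts$regions <- paste0(pre, ".regions.csv")
    write_region_table(tab, artefacts$regions)
    note("[regions] %d regions", nrow(tab))
  }

  if ("project" %in% cfg$stages) {
    img <- depth_xray(mask, axis = cfg$project$axis,
                      colormap = cfg$project$colormap)
    artefacts$xray <- paste0(pre, ".xray.png")
    save_image(img, artefacts$xray)
    note("[project] wrote %s", artefacts$xray)
  }

  manifest <- list(
    package = "ctfiber",
    version = as.character(utils::packageVersion("ctfiber")),
    parameters = unclass(cfg),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs[file.exists(inputs)])) else list(),
    artefacts = lapply(artefacts, basename),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  yaml::write_yaml(manifest, paste0(pre, ".manifest.yaml"))
  artefacts$manifest <- paste0(pre, ".manifest.yaml")
  invisible(artefacts)
}
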