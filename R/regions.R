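#' Per-region connective-tissue statistics
#'
#' Aggregates the per-voxel pipeline outputs over an anatomical label map
#' into one record per region: connective-tissue volume, thickness mean and
#' standard deviation, and the structural composition (percent fibrous /
#' planar / spherical of the region's connective-tissue voxels; the
#' remainder to 100 is unclassified).
#'
#' The region label map may live on a coarser grid than the analysis volumes
#' (anatomical labelling is typically done at low resolution); it is then
#' resampled to the mask grid by nearest-neighbour lookup of voxel-centre
#' physical coordinates. Statistics use the population (not sample) standard
#' deviation. Voxels with region label 0 are excluded.
#'
#' @param mask binary [volume3d()] of connective tissue on the analysis grid.
#' @param thickness real [volume3d()] of thickness in mm, same grid.
#' @param rank [label_volume()] of structure codes (0 unclassified, 1
#'   fibrous, 2 planar, 3 spherical), e.g. from [structure_rank()];
#'   resampled to the mask grid if coarser.
#' @param regions [label_volume()] of anatomical regions; resampled to the
#'   mask grid if needed.
#' @return data.frame with columns `region`, `label`, `volume_dm3`,
#'   `thickness_mean_mm`, `thickness_sd_mm`, `pct_fibrous`, `pct_planar`,
#'   `pct_spherical`, `n_voxels`, ordered by ascending label.
#' @export
compute_region_table <- function(mask, thickness, rank, regions) {
  stopifnot(inherits(mask, "volume3d"), inherits(thickness, "volume3d"),
            inherits(rank, "label_volume"), inherits(regions, "label_volume"))
  d <- vol_dim(mask)
  if (!all(vol_dim(thickness) == d))
    stop("compute_region_table: thickness grid does not match the mask grid")
  s <- assert_isometric(mask, "compute_region_table")
  rank_v <- resample_labels_nn(rank, mask)
  reg_v <- resample_labels_nn(regions, mask)
  fg <- which(mask$values > 0 & reg_v > 0)
  lab <- reg_v[fg]
  th <- thickness$values[fg]
  rk <- rank_v[fg]
  labels <- sort(unique(lab))
  rows <- lapply(labels, function(L) {
    inL <- lab == L
    n <- sum(inL)
    data.frame(
      region = region_name(regions, L),
      label = L,
      volume_dm3 = n * s^3 / 1e6,
      thickness_mean_mm = mean(th[inL]),
      thickness_sd_mm = sqrt(mean((th[inL] - mean(th[inL]))^2)),
      pct_fibrous = 100 * sum(rk[inL] == 1L) / n,
      pct_planar = 100 * sum(rk[inL] == 2L) / n,
      pct_spherical = 100 * sum(rk[inL] == 3L) / n,
      n_voxels = n,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

region_name <- function(regions, L) {
  nm <- regions$label_names[as.character(L)]
  if (is.na(nm)) paste0("label_", L) else unname(nm)
}

# internal: nearest-neighbour resampling of a label grid onto the grid of
# `target` by physical voxel-centre coordinates (shared origin).
resample_labels_nn <- function(labels, target) {
  if (all(vol_dim(labels) == vol_dim(target)) &&
      all(abs(labels$spacing - target$spacing) < 1e-9))
    return(labels$values)
  dt <- vol_dim(target)
  ds <- vol_dim(labels)
  idx <- lapply(1:3, function(ax) {
    centers <- (seq_len(dt[ax]) - 0.5) * target$spacing[ax]
    j <- floor(centers / labels$spacing[ax]) + 1L
    pmin(pmax(j, 1L), ds[ax])
  })
  labels$values[as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))] |>
    array(dim = dt)
}

#' Write a region table as CSV
#'
#' Writes the table from [compute_region_table()] with the header
#' `region, volume_dm3, thickness_mean_mm, thickness_sd_mm, pct_fibrous,
#' pct_planar, pct_spherical, n_voxels`, regions ordered by ascending label
#' and all real values rounded to 2 decimal places.
#'
#' @param records data.frame from [compute_region_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(records, path) {
  cols <- c("region", "volume_dm3", "thickness_mean_mm", "thickness_sd_mm",
            "pct_fibrous", "pct_planar", "pct_spherical", "n_voxels")
  if (is.list(records) && !is.data.frame(records) && length(records) > 0)
    records <- do.call(rbind, records)  # list of one-row records
  if (is.null(records) || length(records) == 0 || nrow(records) == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  out <- records[order(records$label), cols, drop = FALSE]
  num <- setdiff(cols, c("region", "n_voxels"))
  out[num] <- lapply(out[num], function(x) sprintf("%.2f", x))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
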