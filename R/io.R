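#' Write an effect field (and its mask) as NIfTI volumes
#'
#' The 2D slice is stored as a rows x cols x 1 volume: float32 for the
#' per-voxel rho map (zero outside the mask) and uint8 for the mask.
#'
#' @param field An [make_effect_field()] object.
#' @param rho_path Output path for the rho volume (`.nii` / `.nii.gz`).
#' @param mask_path Optional output path for the mask volume.
#' @return Invisibly, the paths written.
#' @export
write_field_nifti <- function(field, rho_path, mask_path = NULL) {
  stopifnot(inherits(field, "effect_field"))
  g <- voxels_to_grid(field$rho, field$mask, fill = 0)
  vol <- array(g, c(dim(g), 1L))
  RNifti::writeNifti(vol, rho_path, datatype = "float")
  paths <- rho_path
  if (!is.null(mask_path)) {
    mvol <- array(as.integer(field$mask$inside), c(field$mask$shape, 1L))
    RNifti::writeNifti(mvol, mask_path, datatype = "uint8")
    paths <- c(paths, mask_path)
  }
  invisible(paths)
}

#' Read an effect-field rho volume written by [write_field_nifti()]
#'
#' Voxels with nonzero rho outside the supplied mask are rejected.
#'
#' @param rho_path Path to the rho NIfTI volume.
#' @param mask A [make_mask()] object giving the in-mask voxel ordering.
#' @return The per-voxel rho vector over `mask$idx`.
#' @export
read_field_nifti <- function(rho_path, mask) {
  stopifnot(inherits(mask, "grid_mask"))
  g <- drop_to_grid(RNifti::readNifti(rho_path))
  if (!all(dim(g) == mask$shape)) {
    stop_invalid("volume dimensions do not match the mask grid")
  }
  g[mask$idx]
}

#' Write per-voxel values as a CSV grid
#'
#' Long format with one row per in-mask voxel: `row`, `col`, `value`.
#'
#' @param values Per-voxel vector over the mask, or an `effect_field`
#'   (whose rho map is written).
#' @param mask A [make_mask()] object (ignored when `values` is an
#'   `effect_field`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_voxels_csv <- function(values, mask, path) {
  if (inherits(values, "effect_field")) {
    mask <- values$mask
    values <- values$rho
  }
  stopifnot(inherits(mask, "grid_mask"),
            length(values) == mask$n_voxels)
  df <- data.frame(
    row = ((mask$idx - 1L) %% mask$shape[1L]) + 1L,
    col = ((mask$idx - 1L) %/% mask$shape[1L]) + 1L,
    value = values
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-voxel values from a CSV grid written by [write_voxels_csv()]
#'
#' @param path CSV path with columns row, col, value.
#' @param mask A [make_mask()] object; every in-mask voxel must be
#'   present.
#' @return Per-voxel vector over `mask$idx`.
#' @export
read_voxels_csv <- function(path, mask) {
  stopifnot(inherits(mask, "grid_mask"))
  df <- utils::read.csv(path)
  lin <- (df$col - 1L) * mask$shape[1L] + df$row
  pos <- match(mask$idx, lin)
  if (anyNA(pos)) {
    stop_invalid("CSV does not cover every in-mask voxel")
  }
  df$value[pos]
}

#' Write a statistic map and its significance map as NIfTI volumes
#'
#' @param statmap A [correlate()] result.
#' @param sig Optional matching [threshold()] result.
#' @param dir Output directory; files `r_map.nii.gz`, `p_map.nii.gz`,
#'   and (when `sig` is given) `sig_map.nii.gz` are created.
#' @return Invisibly, the paths written.
#' @export
write_statmap_nifti <- function(statmap, sig = NULL, dir = ".") {
  stopifnot(inherits(statmap, "voxel_stat_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- statmap$mask
  paths <- character()
  for (nm in c("r", "p")) {
    g <- voxels_to_grid(statmap[[nm]], mk, fill = 0)
    path <- file.path(dir, sprintf("%s_map.nii.gz", nm))
    RNifti::writeNifti(array(g, c(dim(g), 1L)), path, datatype = "float")
    paths <- c(paths, path)
  }
  if (!is.null(sig)) {
    check_sig(sig)
    g <- voxels_to_grid(as.integer(sig$sig), mk, fill = 0)
    path <- file.path(dir, "sig_map.nii.gz")
    RNifti::writeNifti(array(g, c(dim(g), 1L)), path, datatype = "uint8")
    paths <- c(paths, path)
  }
  invisible(paths)
}

# Collapse a read NIfTI volume (2D slice, possibly with a singleton
# third axis) to a plain grid matrix.
drop_to_grid <- function(vol) {
  g <- array(as.numeric(vol), dim(vol))
  d <- dim(g)
  if (length(d) == 3L && d[3L] == 1L) {
    g <- g[, , 1L]
  }
  if (length(dim(g)) != 2L) {
    stop_invalid("expected a 2D slice volume")
  }
  g
}

# Long-format records CSV: scenario, n_sub, rep, metric, value.
records_to_long <- function(records) {
  metrics <- c("avg_power", "alo", "mean_sig_abs_r", "pct_sig", "dice_prev")
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(scenario = records$scenario, n_sub = records$n_sub,
               rep = records$rep, metric = m, value = records[[m]])
  }))
}

write_results_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    records = file.path(dir, "records.csv"),
    curves = file.path(dir, "curves.csv"),
    field = file.path(dir, "effect_field.nii.gz"),
    mask = file.path(dir, "truth_mask.nii.gz"),
    config = file.path(dir, "config_echo.yaml")
  )
  utils::write.csv(records_to_long(bundle$records), paths[["records"]],
                   row.names = FALSE)
  utils::write.csv(bundle$curves, paths[["curves"]], row.names = FALSE)
  write_field_nifti(bundle$field, paths[["field"]])
  g <- voxels_to_grid(as.integer(bundle$truth$true_mask),
                      bundle$field$mask, fill = 0)
  RNifti::writeNifti(array(g, c(dim(g), 1L)), paths[["mask"]],
                     datatype = "uint8")
  cfg <- bundle$config
  echo <- list(
    scenario = unclass(cfg$scenario),
    full_n = cfg$full_n, n_grid = cfg$n_grid, n_reps = cfg$n_reps,
    threshold = unclass(cfg$threshold), truth_mode = cfg$truth_mode,
    master_seed = cfg$master_seed,
    fresh_cohort_per_rep = cfg$fresh_cohort_per_rep,
    package_version = as.character(utils::packageVersion("voxelpower"))
  )
  yaml::write_yaml(echo, paths[["config"]])
  paths
}
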