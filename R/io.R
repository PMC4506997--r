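# File interchange: NIfTI volumes, TIFF sections, CSV tables, JSON records,
# YAML run configuration.

nifti_with_voxel <- function(grid, voxel_size) {
  img <- RNifti::asNifti(grid)
  nd <- length(dim(grid))
  RNifti::pixdim(img) <- rep(voxel_size, nd)
  img
}

#' Write / read a phantom as NIfTI plus JSON sidecar
#'
#' The label grid goes to `<path>.nii.gz` (voxel size in the header, recorded
#' in micrometres in the sidecar), the deposit table and metadata to
#' `<path>.json`, and the deposit-id grid to `<path>_ids.nii.gz`.
#'
#' @param phantom A `plaque_phantom`.
#' @param path Output path prefix (no extension).
#' @return `write_phantom` returns `path` invisibly; `read_phantom` the
#'   reconstructed `plaque_phantom`.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "plaque_phantom"))
  RNifti::writeNifti(nifti_with_voxel(phantom$grid, phantom$voxel_size),
                     paste0(path, ".nii.gz"))
  RNifti::writeNifti(nifti_with_voxel(phantom$deposit_id, phantom$voxel_size),
                     paste0(path, "_ids.nii.gz"))
  meta <- list(
    voxel_size_um = phantom$voxel_size,
    dimensionality = phantom$dimensionality,
    domain_size_um = phantom$domain_size,
    deposits = phantom$deposits
  )
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  jf <- paste0(path, ".json")
  if (!file.exists(jf)) abort(paste0("missing phantom sidecar: ", jf))
  meta <- tryCatch(jsonlite::read_json(jf, simplifyVector = TRUE),
                   error = function(e) {
                     abort(paste0("unreadable phantom sidecar (", jf, "): ",
                                  conditionMessage(e)))
                   })
  for (f in c("voxel_size_um", "dimensionality", "deposits")) {
    if (is.null(meta[[f]])) abort(paste0("phantom sidecar lacks field `", f, "`"))
  }
  grid <- drop_nifti(RNifti::readNifti(paste0(path, ".nii.gz")))
  ids <- drop_nifti(RNifti::readNifti(paste0(path, "_ids.nii.gz")))
  structure(
    list(grid = array(as.integer(grid), dim = dim(grid)),
         deposit_id = array(as.integer(ids), dim = dim(ids)),
         voxel_size = meta$voxel_size_um,
         deposits = as_tibble(meta$deposits),
         dimensionality = as.integer(meta$dimensionality),
         domain_size = meta$domain_size_um),
    class = "plaque_phantom"
  )
}

drop_nifti <- function(img) {
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write / read a scalar volume as NIfTI
#'
#' Works for `activity_map`, `image_volume`, or any list with `grid` and
#' `voxel_size`; reading returns grid plus voxel size.
#'
#' @param x Object with `grid` and `voxel_size`.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  RNifti::writeNifti(nifti_with_voxel(x$grid, x$voxel_size), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  list(grid = drop_nifti(img), voxel_size = vs)
}

#' Write / read a 2D image as 32-bit TIFF
#'
#' Values are divided by a power-of-two scale (so the division is exact in
#' floating point) to fit the \[0, 1\] range the TIFF writer expects; the
#' scale is recorded in a small JSON sidecar and re-applied on read.
#'
#' @param x Object with a 2D `grid` (or a plain matrix).
#' @param path Output `.tif`/`.tiff` file.
#' @export
write_section_tiff <- function(x, path) {
  g <- grid_of(x)
  if (length(dim(g)) != 2) abort("TIFF export is for 2D sections")
  lo <- min(g)
  if (lo < 0) g <- g - lo
  top <- max(g, 1e-300)
  scale <- 2^ceiling(log2(top))
  tiff::writeTIFF(g / scale, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale, offset = min(lo, 0)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_section_tiff
#' @export
read_section_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (is.list(m)) m <- m[[1]]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    m <- m * meta$scale + meta$offset
  }
  m
}

#' Write / read a time-activity curve as CSV
#'
#' Columns `time_min`, `value`, `label`.
#'
#' @param tac Data frame with `time_min` and `value` (or `bound`); `label`
#'   optional.
#' @param path CSV file.
#' @param label Label to attach when `tac` lacks one.
#' @export
write_tac <- function(tac, path, label = "tissue") {
  d <- as_tac(tac)
  d$label <- if ("label" %in% names(tac)) tac$label else label
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_min", "value") %in% names(d))) {
    abort("TAC CSV must have columns time_min, value")
  }
  d
}

#' Default end-to-end run configuration
#'
#' All tunables of [run_end_to_end()], grouped per stage. Serializes to and
#' from YAML with [write_run_config()] / [read_run_config()]; unknown keys
#' are rejected on read.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(
      domain_size = c(6000, 6000),
      voxel_size = 5,
      n_micro = 60,
      n_macro = 3,
      micro_radius_range = c(8, 20),
      macro_radius_range = c(150, 600),
      mineral_density_range = c(1, 1),
      max_attempts = 1000
    ),
    adsorption = list(
      k_on = 4.5e9,
      k_off = 0.0027,
      ligand_conc = 1e-11,
      site_density = 1e12,
      incubation_time = 60,
      penetration_depth = 20,
      sectioned_first = FALSE,
      binding = "linear"
    ),
    imaging = list(
      noise = TRUE,
      hu_bg = 0,
      hu_soft = 40,
      hu_calc = 1300
    ),
    quantification = list(
      blur_sigma = 20,
      hu_threshold = 1000
    ),
    kinetics = list(
      assoc_times = c(0, 5, 15, 30, 60),
      wash_times = c(0, 5, 10, 15, 30, 45, 60, 90, 120),
      calib_concs = 10^seq(-12, -7),
      Ki = 0.003,
      V = 0.3,
      t_start = 10
    )
  ), class = "run_config")
}

check_config_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) {
    abort(paste0("unknown configuration key(s): ",
                 paste0(path, extra, collapse = ", ")))
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(cfg[[k]])) abort(paste0("config section `", k, "` must be a mapping"))
      check_config_keys(cfg[[k]], template[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(user, template) {
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      template[[k]] <- merge_config(user[[k]], template[[k]])
    } else {
      template[[k]] <- user[[k]]
    }
  }
  template
}

#' Read / write the run configuration
#'
#' @param path YAML file.
#' @param config A `run_config` (or compatible nested list).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tpl <- default_run_config()
  check_config_keys(raw, tpl)
  structure(merge_config(raw, unclass(tpl)), class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
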