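#' @name io
#' @title File formats: NIfTI volumes, b-value tables, feature tables,
#'   run configurations
#' @description
#' DWI series are stored as a 4-D NIfTI plus an FSL-style `.bval` text
#' file; ROI masks as uint8 NIfTI; feature tables as TSV with a
#' `#`-prefixed provenance header; run configurations as YAML.
NULL

#' Write / read a DWI series as NIfTI + .bval
#'
#' @param dwi A [dwi_series()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.nii.gz` and `<prefix>.bval`.
#' @return `write_dwi` invisibly returns the two paths; `read_dwi` returns
#'   a [dwi_series()].
#' @export
write_dwi <- function(dwi, path_prefix) {
  stopifnot(inherits(dwi, "dwi_series"))
  nii <- paste0(path_prefix, ".nii.gz")
  bval <- paste0(path_prefix, ".bval")
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$voxel_size, dwi$voxel_size,
                           dwi$slice_thickness, 1)
  RNifti::writeNifti(img, nii)
  write_bvals(dwi$b_values, bval)
  invisible(c(nifti = nii, bval = bval))
}

#' @rdname write_dwi
#' @param nii_path Path to a 4-D NIfTI file.
#' @param bval_path Path to the matching b-value text file; defaults to
#'   `nii_path` with the extension replaced by `.bval`.
#' @export
read_dwi <- function(nii_path, bval_path = NULL) {
  if (!file.exists(nii_path)) stop("NIfTI file not found: ", nii_path)
  if (is.null(bval_path)) {
    bval_path <- sub("\\.nii(\\.gz)?$", ".bval", nii_path)
  }
  img <- RNifti::readNifti(nii_path)
  b <- read_bvals(bval_path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim = dim(img))
  dwi_series(arr, b, voxel_size = pd[1], slice_thickness = pd[3])
}

#' Read / write FSL-style b-value files
#'
#' A `.bval` file is a single line of whitespace-separated b-values.
#'
#' @param path File path.
#' @return `read_bvals` returns a numeric vector.
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) stop("b-value file not found: ", path)
  b <- scan(path, what = numeric(), quiet = TRUE)
  if (length(b) < 2L) stop("malformed b-value file (need >= 2 values): ", path)
  b
}

#' @rdname read_bvals
#' @param b_values Numeric vector.
#' @export
write_bvals <- function(b_values, path) {
  writeLines(paste(b_values, collapse = " "), path)
  invisible(path)
}

#' Write / read an ROI mask as uint8 NIfTI
#'
#' @param mask Logical 3-D array.
#' @param path Output path (`.nii.gz`).
#' @param voxel_size,slice_thickness Geometry to record in the header.
#' @return `read_roi_mask` returns a logical 3-D array.
#' @export
write_roi_mask <- function(mask, path, voxel_size = 1, slice_thickness = voxel_size) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- c(voxel_size, voxel_size, slice_thickness)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}

#' Write / read a feature table with a provenance header
#'
#' The table body is tab-separated; provenance (tool version, master seed,
#' protocol, design settings) is stored in leading lines prefixed with
#' `#`. Re-running the same configuration reproduces a byte-identical
#' body.
#'
#' @param table Data frame (e.g. from [run_design()]).
#' @param path Output path.
#' @param provenance Named list recorded in the header.
#' @return `read_feature_table` returns the data frame, with the parsed
#'   header in the `provenance` attribute.
#' @export
write_feature_table <- function(table, path, provenance = list()) {
  provenance <- c(list(tool = paste0("adctexture ",
                                     as.character(utils::packageVersion("adctexture")))),
                  provenance)
  hdr <- vapply(names(provenance), function(k) {
    paste0("# ", k, ": ", paste(provenance[[k]], collapse = " "))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  tab <- utils::read.table(text = lines[body], sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  prov <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    prov[[k]] <- sub("^[^:]*:\\s*", "", kv)
  }
  attr(tab, "provenance") <- prov
  tab
}

#' Run configuration
#'
#' A run configuration bundles everything needed to reproduce a full run:
#' protocol name, batch size, phantom grid, master seed, alpha, and output
#' options. Saved as YAML; `load_run_config(save_run_config(x))` is the
#' identity.
#'
#' @param protocol Protocol name (`"glioma"` or `"prostate"`).
#' @param n_rois Phantom batch size.
#' @param seed Master seed; recorded in every output header.
#' @param grid_shape Phantom grid.
#' @param include_fluid Whether phantoms carry an adjacent high-ADC slab.
#' @param s0 Signal amplitude at b = 0.
#' @param alpha Per-test significance level.
#' @return A list of class `run_config`.
#' @export
run_config <- function(protocol = "glioma", n_rois = 72L, seed = 1L,
                       grid_shape = c(48L, 48L, 3L), include_fluid = TRUE,
                       s0 = 1000, alpha = 0.01) {
  stopifnot(n_rois >= 1L)
  structure(list(protocol = protocol, n_rois = as.integer(n_rois),
                 seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 include_fluid = isTRUE(include_fluid), s0 = s0, alpha = alpha),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  run_config(protocol = x$protocol, n_rois = x$n_rois, seed = x$seed,
             grid_shape = x$grid_shape, include_fluid = x$include_fluid,
             s0 = x$s0, alpha = x$alpha)
}
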