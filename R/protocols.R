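#' Built-in diffusion-weighted imaging protocols
#'
#' Returns the acquisition settings of one of the two supported DWI
#' protocols. The `"glioma"` protocol uses six b-values (0 to
#' 1000 s/mm\eqn{^2} in steps of 200), 1.2 mm in-plane voxels and a native
#' signal noise standard deviation of 17; the `"prostate"` protocol uses two
#' b-values (0 and 800 s/mm\eqn{^2}), 1.625 mm voxels and native noise
#' standard deviation 2.5.
#'
#' @param name Protocol name, one of `"glioma"` or `"prostate"`.
#' @param n_slices Optional override of the number of slices simulated
#'   phantoms should have (defaults to the protocol's acquisition value).
#'
#' @return An object of class `protocol_spec`: a list with elements `name`,
#'   `b_values` (s/mm\eqn{^2}), `voxel_size` (in-plane, mm),
#'   `slice_thickness` (mm), `native_noise_sigma` (signal units) and
#'   `n_slices`.
#' @examples
#' make_protocol("glioma")$b_values
#' make_protocol("prostate")$native_noise_sigma
#' @export
make_protocol <- function(name, n_slices = NULL) {
  protocols <- list(
    glioma = list(
      name = "glioma",
      b_values = c(0, 200, 400, 600, 800, 1000),
      voxel_size = 1.2,
      slice_thickness = 3.0,
      native_noise_sigma = 17,
      n_slices = 19L
    ),
    prostate = list(
      name = "prostate",
      b_values = c(0, 800),
      voxel_size = 1.625,
      slice_thickness = 3.6,
      native_noise_sigma = 2.5,
      n_slices = 20L
    )
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(protocols)) {
    stop("unknown protocol '", paste(name, collapse = ","),
         "'; available protocols: ", paste(names(protocols), collapse = ", "))
  }
  p <- protocols[[name]]
  if (!is.null(n_slices)) {
    stopifnot(n_slices >= 1)
    p$n_slices <- as.integer(n_slices)
  }
  validate_protocol(p)
  structure(p, class = "protocol_spec")
}

validate_protocol <- function(p) {
  stopifnot(
    length(p$b_values) >= 2L,
    all(p$b_values >= 0),
    all(diff(p$b_values) > 0),
    p$voxel_size > 0,
    p$native_noise_sigma >= 0
  )
  invisible(p)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("DWI protocol '", x$name, "'\n", sep = "")
  cat("  b-values (s/mm^2): ", paste(x$b_values, collapse = ", "), "\n", sep = "")
  cat("  voxel size: ", x$voxel_size, " mm, slice thickness: ",
      x$slice_thickness, " mm\n", sep = "")
  cat("  native noise sigma: ", x$native_noise_sigma, "\n", sep = "")
  invisible(x)
}
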