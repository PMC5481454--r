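#' Specification of a synthetic ADC phantom
#'
#' Describes a 3-D digital phantom: an ellipsoidal region of interest (ROI)
#' carrying a spatially correlated ADC texture, optionally with an adjacent
#' fluid-like structure of high ADC (around 3000 in units of
#' 10\eqn{^{-6}} mm\eqn{^2}/s, i.e. CSF- or urine-like) bordering the ROI.
#'
#' The ADC texture is a Gaussian random field: seeded white noise smoothed
#' in-plane with a Gaussian kernel of standard deviation `corr_length`
#' voxels, then standardized and affinely mapped to mean `base_mean` and
#' standard deviation `amplitude`. Negative values are clamped to zero.
#'
#' @param grid_shape Integer vector `(rows, cols, slices)`.
#' @param roi_radii In-plane and through-plane ellipsoid radii, in voxels,
#'   length 3.
#' @param roi_center Ellipsoid center in voxel coordinates; defaults to the
#'   grid center.
#' @param base_mean Mean ADC inside the field (10\eqn{^{-6}} mm\eqn{^2}/s).
#' @param amplitude Texture standard deviation (same units). `0` gives a
#'   constant field.
#' @param corr_length Smoothing kernel standard deviation in voxels;
#'   controls the spatial correlation length of the texture.
#' @param adjacent_fluid `NULL`, or a list with elements `mean` (ADC of the
#'   fluid region, default 3000) and `width` (slab width in voxels, default
#'   4). The fluid slab is placed immediately beyond the ROI's maximum row
#'   extent, so that a one-voxel ROI dilation can capture fluid voxels.
#' @param s0 Unattenuated (b = 0) signal amplitude used when the phantom is
#'   converted to DWI signals.
#' @param seed RNG seed; identical specs with identical seeds produce
#'   bit-identical phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_adc_phantom()], [simulate_dwi()]
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 3L),
                         roi_radii = c(10, 10, 3),
                         roi_center = NULL,
                         base_mean = 1000,
                         amplitude = 300,
                         corr_length = 2,
                         adjacent_fluid = NULL,
                         s0 = 1000,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(roi_radii) == 3L, all(roi_radii > 0),
            base_mean >= 0, amplitude >= 0, corr_length > 0, s0 > 0)
  if (is.null(roi_center)) roi_center <- (grid_shape + 1) / 2
  stopifnot(length(roi_center) == 3L)
  if (!is.null(adjacent_fluid)) {
    adjacent_fluid <- utils::modifyList(list(mean = 3000, width = 4L),
                                        as.list(adjacent_fluid))
    stopifnot(adjacent_fluid$mean >= 0, adjacent_fluid$width >= 1)
  }
  structure(
    list(grid_shape = grid_shape, roi_center = roi_center,
         roi_radii = roi_radii, base_mean = base_mean,
         amplitude = amplitude, corr_length = corr_length,
         adjacent_fluid = adjacent_fluid, s0 = s0, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' ADC volume container
#'
#' @param values 3-D numeric array of apparent diffusion coefficients in
#'   units of 10\eqn{^{-6}} mm\eqn{^2}/s.
#' @param voxel_size In-plane voxel size (mm).
#' @param slice_thickness Slice thickness (mm).
#' @return An object of class `adc_volume`.
#' @export
adc_volume <- function(values, voxel_size, slice_thickness = voxel_size) {
  stopifnot(is.array(values), length(dim(values)) == 3L, voxel_size > 0)
  structure(list(values = values, voxel_size = voxel_size,
                 slice_thickness = slice_thickness),
            class = "adc_volume")
}

#' @export
print.adc_volume <- function(x, ...) {
  d <- dim(x$values)
  cat("ADC volume ", d[1], "x", d[2], "x", d[3],
      " (voxel ", x$voxel_size, " mm), range ",
      signif(min(x$values), 4), "-", signif(max(x$values), 4),
      " x1e-6 mm^2/s\n", sep = "")
  invisible(x)
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  x <- (seq_len(grid_shape[1]) - center[1]) / radii[1]
  y <- (seq_len(grid_shape[2]) - center[2]) / radii[2]
  z <- (seq_len(grid_shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D "same" convolution with edge replication
convolve_1d_same <- function(v, k) {
  r <- (length(k) - 1L) %/% 2L
  vp <- c(rep(v[1L], r), v, rep(v[length(v)], r))
  out <- stats::filter(vp, k, method = "convolution", sides = 2L)
  as.numeric(out)[(r + 1L):(r + length(v))]
}

smooth_slice_gaussian <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  m <- apply(m, 2L, convolve_1d_same, k = k)
  t(apply(t(m), 2L, convolve_1d_same, k = k))
}

#' Generate a textured ADC phantom and its ROI mask
#'
#' Realizes the Gaussian-random-field ADC texture described by a
#' [phantom_spec()], returning the ADC volume and the binary ellipsoidal
#' ROI mask on the same grid. If `spec$adjacent_fluid` is set, a slab of
#' high-ADC voxels is placed immediately beyond the ROI's maximum row
#' extent (outside the ROI), emulating tumors bordering the ventricles or
#' the bladder.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `adc` (an [adc_volume()], voxel size 1 mm
#'   placeholder until paired with a protocol), `roi` (logical 3-D array)
#'   and `spec`.
#' @examples
#' ph <- generate_adc_phantom(phantom_spec(seed = 7))
#' mean(ph$adc$values[ph$roi])
#' @export
generate_adc_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  roi <- ellipsoid_mask(g, spec$roi_center, spec$roi_radii)
  if (!any(roi)) stop("degenerate phantom geometry: ROI mask is empty")

  set.seed(spec$seed)
  field <- array(stats::rnorm(prod(g)), dim = g)
  for (z in seq_len(g[3])) {
    field[, , z] <- smooth_slice_gaussian(field[, , z], spec$corr_length)
  }
  zfield <- (field - mean(field)) / stats::sd(field)
  vals <- spec$base_mean + spec$amplitude * zfield

  if (!is.null(spec$adjacent_fluid)) {
    fl <- spec$adjacent_fluid
    # rows immediately beyond the ROI's maximum row extent, spanning the
    # ROI's column extent, all slices
    roi_rows <- which(apply(roi, 1L, any))
    roi_cols <- which(apply(roi, 2L, any))
    x0 <- max(roi_rows) + 1L
    x1 <- min(g[1], x0 + as.integer(fl$width) - 1L)
    if (x0 <= g[1]) {
      fluid <- array(FALSE, dim = g)
      fluid[x0:x1, roi_cols, ] <- TRUE
      fluid <- fluid & !roi
      vals[fluid] <- fl$mean + 0.1 * spec$amplitude * zfield[fluid]
    }
  }
  vals <- pmax(vals, 0)
  list(adc = adc_volume(vals, voxel_size = 1), roi = roi, spec = spec)
}

#' DWI series container
#'
#' @param signal 4-D numeric array `(rows, cols, slices, b)` of signal
#'   intensities, one volume per b-value.
#' @param b_values Numeric vector of b-values (s/mm\eqn{^2}), strictly
#'   increasing, one per volume.
#' @param voxel_size In-plane voxel size (mm).
#' @param slice_thickness Slice thickness (mm).
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal, b_values, voxel_size, slice_thickness = voxel_size) {
  stopifnot(is.array(signal), length(dim(signal)) == 4L,
            dim(signal)[4] == length(b_values),
            length(b_values) >= 2L, all(diff(b_values) > 0),
            voxel_size > 0)
  structure(list(signal = signal, b_values = b_values,
                 voxel_size = voxel_size, slice_thickness = slice_thickness),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI series ", d[1], "x", d[2], "x", d[3], ", b = ",
      paste(x$b_values, collapse = ", "), " s/mm^2 (voxel ",
      x$voxel_size, " mm)\n", sep = "")
  invisible(x)
}

#' Simulate a diffusion-weighted series from an ADC volume
#'
#' Applies mono-exponential signal decay
#' \eqn{S(b) = S_0 \exp(-b \cdot \mathrm{ADC} \cdot 10^{-6})} at each voxel
#' and b-value of the protocol, then adds zero-mean Gaussian noise of
#' standard deviation `noise_sigma`, independently per voxel and b-value.
#' Negative noisy signals are kept as-is; they are handled downstream by
#' [fit_adc()].
#'
#' @param adc An [adc_volume()] (units 10\eqn{^{-6}} mm\eqn{^2}/s).
#' @param s0 Unattenuated signal amplitude.
#' @param protocol A [make_protocol()] object supplying b-values, voxel
#'   size and (by default) the native noise level.
#' @param noise_sigma Noise standard deviation in signal units; defaults to
#'   the protocol's native sigma. Must be non-negative.
#' @param seed Optional RNG seed for the noise draw.
#' @return A [dwi_series()] with the protocol's b-values and voxel size.
#' @examples
#' ph <- generate_adc_phantom(phantom_spec(seed = 1))
#' dwi <- simulate_dwi(ph$adc, s0 = 1000, make_protocol("glioma"), seed = 1)
#' @export
simulate_dwi <- function(adc, s0, protocol, noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(adc, "adc_volume"), inherits(protocol, "protocol_spec"),
            s0 > 0)
  if (is.null(noise_sigma)) noise_sigma <- protocol$native_noise_sigma
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  g <- dim(adc$values)
  nb <- length(protocol$b_values)
  sig <- array(0, dim = c(g, nb))
  for (k in seq_len(nb)) {
    sig[, , , k] <- s0 * exp(-protocol$b_values[k] * adc$values * 1e-6)
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + array(stats::rnorm(length(sig), sd = noise_sigma), dim = dim(sig))
  }
  dwi_series(sig, protocol$b_values, voxel_size = protocol$voxel_size,
             slice_thickness = protocol$slice_thickness)
}

#' Generate a batch of heterogeneous DWI phantoms
#'
#' Draws per-phantom texture and geometry parameters (base ADC mean,
#' texture amplitude, correlation length, in-plane ROI radii) from fixed
#' uniform ranges so that a batch mimics an inter-patient cohort, then
#' simulates the matching noisy DWI series under the given protocol.
#' Per-phantom seeds are derived deterministically from `seed`, so
#' enlarging the batch does not perturb earlier phantoms.
#'
#' @param n Number of phantoms.
#' @param protocol A [make_protocol()] object.
#' @param seed Master seed.
#' @param grid_shape Phantom grid, default `c(48, 48, 3)`.
#' @param include_fluid If `TRUE` (default), each phantom carries an
#'   adjacent high-ADC fluid slab (mean 3000).
#' @param s0 Signal amplitude at b = 0.
#' @return A list of length `n`; each element has `dwi`, `adc`, `roi`,
#'   `spec`.
#' @export
make_phantom_batch <- function(n, protocol, seed = 1L,
                               grid_shape = c(48L, 48L, 3L),
                               include_fluid = TRUE, s0 = 1000) {
  stopifnot(n >= 1, inherits(protocol, "protocol_spec"))
  lapply(seq_len(n), function(i) {
    # per-phantom parameter draws with a derived seed, so batch size does
    # not perturb earlier phantoms
    set.seed(seed + 200000L + i)
    pars <- stats::runif(5)
    fluid <- if (include_fluid) list(mean = 3000, width = 4L) else NULL
    sp <- phantom_spec(
      grid_shape = grid_shape,
      roi_center = c(grid_shape[1] / 2 - 4, grid_shape[2] / 2, (grid_shape[3] + 1) / 2),
      roi_radii = c(8 + 4 * pars[4], 8 + 4 * pars[5], grid_shape[3]),
      base_mean = 900 + 400 * pars[1], amplitude = 200 + 200 * pars[2],
      corr_length = 1 + 2 * pars[3], adjacent_fluid = fluid,
      s0 = s0, seed = seed + i
    )
    ph <- generate_adc_phantom(sp)
    dwi <- simulate_dwi(ph$adc, s0 = s0, protocol = protocol,
                        seed = seed + 100000L + i)
    list(dwi = dwi, adc = ph$adc, roi = ph$roi, spec = sp)
  })
}
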