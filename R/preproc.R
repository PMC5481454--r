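#' @name preproc
#' @title Pre-processing chain: resolution, noise, ADC fitting
#' @description
#' The three pre-processing stages applied to a DWI series before texture
#' analysis: in-plane downsampling to a coarser resolution, injection of
#' additional Gaussian noise, and voxel-wise log-linear ADC fitting over a
#' chosen subset of b-values.
NULL

block_mean_matrix <- function(m, f) {
  nx2 <- nrow(m) %/% f
  ny2 <- ncol(m) %/% f
  m <- m[seq_len(nx2 * f), seq_len(ny2 * f), drop = FALSE]
  m1 <- rowsum(m, rep(seq_len(nx2), each = f))
  m2 <- t(rowsum(t(m1), rep(seq_len(ny2), each = f)))
  m2 / (f * f)
}

# coarse-pixel centers expressed as (fractional) fine-grid indices
coarse_centers <- function(n_old, factor) {
  n_new <- floor(n_old / factor)
  (seq_len(n_new) - 0.5) * factor + 0.5
}

bilinear_matrix <- function(m, f) {
  px <- coarse_centers(nrow(m), f)
  py <- coarse_centers(ncol(m), f)
  i0 <- pmin(pmax(floor(px), 1L), nrow(m) - 1L)
  j0 <- pmin(pmax(floor(py), 1L), ncol(m) - 1L)
  wx <- pmin(pmax(px - i0, 0), 1)
  wy <- pmin(pmax(py - j0, 0), 1)
  mr <- m[i0, , drop = FALSE] * (1 - wx) + m[i0 + 1L, , drop = FALSE] * wx
  mr[, j0, drop = FALSE] * rep(1 - wy, each = nrow(mr)) +
    mr[, j0 + 1L, drop = FALSE] * rep(wy, each = nrow(mr))
}

resample_slice <- function(m, factor) {
  if (factor == round(factor)) block_mean_matrix(m, as.integer(factor))
  else bilinear_matrix(m, factor)
}

#' Downsample a DWI series in-plane
#'
#' Increases the in-plane pixel size by `factor`, reducing the matrix size
#' accordingly (e.g. 192x192 at 1.2 mm with factor 3 becomes 64x64 at
#' 3.6 mm). Integer factors use block averaging, which emulates acquiring
#' at a coarser resolution; non-integer factors use bilinear interpolation
#' at the coarse-pixel centers. Slices and b-value volumes are resampled
#' independently.
#'
#' @param dwi A [dwi_series()].
#' @param factor Resolution factor, `>= 1` (1 returns the input unchanged).
#' @return A [dwi_series()] with voxel size multiplied by `factor`.
#' @export
resample_dwi <- function(dwi, factor) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (factor < 1) stop("resampling factor must be >= 1 (upsampling is out of design)")
  if (factor == 1) return(dwi)
  d <- dim(dwi$signal)
  nx2 <- floor(d[1] / factor)
  ny2 <- floor(d[2] / factor)
  if (nx2 < 1 || ny2 < 1) stop("resampling factor too large for grid")
  out <- array(0, dim = c(nx2, ny2, d[3], d[4]))
  for (k in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      out[, , z, k] <- resample_slice(dwi$signal[, , z, k], factor)
    }
  }
  dwi_series(out, dwi$b_values, voxel_size = dwi$voxel_size * factor,
             slice_thickness = dwi$slice_thickness)
}

#' Resample a binary ROI mask with nearest-neighbor interpolation
#'
#' Masks are never averaged or interpolated: each coarse voxel takes the
#' mask value of the nearest fine voxel, so the result stays binary.
#'
#' @param mask Logical 3-D array.
#' @param factor Resolution factor `>= 1`.
#' @return Logical 3-D array on the coarse grid.
#' @export
resample_roi <- function(mask, factor) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (factor < 1) stop("resampling factor must be >= 1")
  if (factor == 1) return(mask)
  d <- dim(mask)
  ix <- pmin(pmax(round(coarse_centers(d[1], factor)), 1L), d[1])
  iy <- pmin(pmax(round(coarse_centers(d[2], factor)), 1L), d[2])
  mask[ix, iy, , drop = FALSE]
}

#' Add Gaussian noise so that total noise scales by a factor
#'
#' Given a series whose native noise standard deviation is `native_sigma`,
#' adds independent zero-mean Gaussian noise with standard deviation
#' \eqn{\sigma\sqrt{f^2 - 1}}, so the total noise standard deviation
#' becomes \eqn{f\sigma} (variance additivity). `factor = 1` returns the
#' series unchanged and consumes no random numbers.
#'
#' @param dwi A [dwi_series()].
#' @param native_sigma Native noise standard deviation (signal units).
#' @param factor Total-noise multiplier, `>= 1`.
#' @param seed Optional RNG seed.
#' @return A [dwi_series()].
#' @export
add_noise <- function(dwi, native_sigma, factor, seed = NULL) {
  stopifnot(inherits(dwi, "dwi_series"), native_sigma >= 0)
  if (factor < 1) stop("noise factor must be >= 1")
  if (factor == 1 || native_sigma == 0) return(dwi)
  sigma_add <- native_sigma * sqrt(factor^2 - 1)
  if (!is.null(seed)) set.seed(seed)
  sig <- dwi$signal +
    array(stats::rnorm(length(dwi$signal), sd = sigma_add), dim = dim(dwi$signal))
  dwi_series(sig, dwi$b_values, dwi$voxel_size, dwi$slice_thickness)
}

#' Fit an ADC map by log-linear regression over b-values
#'
#' At every voxel, fits ordinary least squares of \eqn{\ln S} against the
#' chosen b-values; the ADC is \eqn{-\mathrm{slope} \times 10^6}, reported
#' in 10\eqn{^{-6}} mm\eqn{^2}/s. With exactly two b-values this reduces to
#' \eqn{\ln(S(b_1)/S(b_2)) / (b_2 - b_1) \times 10^6}.
#'
#' Non-positive signals (possible after noise injection) are clamped to a
#' small positive floor, \eqn{10^{-3}} of the voxel's maximum signal,
#' before taking logarithms; the number of clamped samples is recorded in
#' the `n_clamped` attribute. Voxels whose signals are all non-positive
#' cannot be fitted: their ADC is set to 0 and they are tallied in the
#' `n_failed` attribute.
#'
#' @param dwi A [dwi_series()].
#' @param b_subset b-values to use for the fit; must be a subset of
#'   `dwi$b_values` with at least two entries. Defaults to all b-values.
#' @return An [adc_volume()] with attributes `n_clamped` and `n_failed`.
#' @examples
#' ph <- generate_adc_phantom(phantom_spec(seed = 2))
#' dwi <- simulate_dwi(ph$adc, 1000, make_protocol("glioma"), noise_sigma = 0)
#' fit <- fit_adc(dwi, c(0, 1000))
#' max(abs(fit$values - ph$adc$values))  # ~0 without noise
#' @export
fit_adc <- function(dwi, b_subset = dwi$b_values) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (length(b_subset) < 2L) stop("at least two b-values are required to fit ADC")
  idx <- match(b_subset, dwi$b_values)
  if (anyNA(idx)) {
    stop("b_subset contains b-values not present in the series: ",
         paste(b_subset[is.na(idx)], collapse = ", "))
  }
  d <- dim(dwi$signal)
  nvox <- prod(d[1:3])
  nb <- length(idx)
  sig <- matrix(dwi$signal[, , , idx, drop = FALSE], nrow = nvox, ncol = nb)

  vmax <- sig[, 1L]
  for (k in seq_len(nb)[-1L]) vmax <- pmax(vmax, sig[, k])
  failed <- vmax <= 0
  floor_v <- pmax(vmax, 0) * 1e-3
  n_clamped <- 0L
  for (k in seq_len(nb)) {
    low <- sig[, k] < floor_v
    n_clamped <- n_clamped + sum(low & !failed)
    sig[low, k] <- floor_v[low]
  }
  sig[failed, ] <- 1 # placeholder; overwritten below

  b <- as.numeric(b_subset)
  bc <- b - mean(b)
  slope <- as.numeric(log(sig) %*% bc) / sum(bc^2)
  adc <- -slope * 1e6
  adc[failed] <- 0

  out <- adc_volume(array(adc, dim = d[1:3]), dwi$voxel_size, dwi$slice_thickness)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "n_failed") <- sum(failed)
  out
}
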