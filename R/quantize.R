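#' Gray-level quantization scheme
#'
#' Defines how ROI intensities are mapped to integer gray levels
#' \eqn{1..N} before GLCM construction. Three methods are supported:
#' \describe{
#'   \item{AutoROI}{limits set to the minimum and maximum ADC over the
#'     whole ROI;}
#'   \item{AutoSlice}{limits set per slice, to the minimum and maximum of
#'     that slice's ROI cross-section;}
#'   \item{Manual}{fixed user-chosen limits; out-of-range values are
#'     clipped into the boundary bins.}
#' }
#'
#' @param method One of `"AutoROI"`, `"AutoSlice"`, `"Manual"`.
#' @param n_levels Number of gray levels \eqn{N \ge 2} (typically 8-128).
#' @param manual_min,manual_max ADC limits (10\eqn{^{-6}} mm\eqn{^2}/s),
#'   required iff `method = "Manual"`; `manual_min < manual_max`.
#' @return An object of class `quantization_scheme`.
#' @export
quantization_scheme <- function(method = c("AutoROI", "AutoSlice", "Manual"),
                                n_levels = 32L,
                                manual_min = NULL, manual_max = NULL) {
  method <- match.arg(method)
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 2L)
  if (method == "Manual") {
    if (is.null(manual_min) || is.null(manual_max)) {
      stop("Manual quantization requires manual_min and manual_max")
    }
    stopifnot(manual_min < manual_max)
  }
  structure(list(method = method, n_levels = n_levels,
                 manual_min = manual_min, manual_max = manual_max),
            class = "quantization_scheme")
}

# uniform half-open bins over [lo, hi], top edge closed; optionally clip
quantize_values <- function(v, lo, hi, n_levels, clip = FALSE) {
  if (hi <= lo) {
    warning("degenerate intensity range (hi <= lo); all labels set to 1")
    return(rep(1L, length(v)))
  }
  if (clip) v <- pmin(pmax(v, lo), hi)
  lab <- 1L + floor(n_levels * (v - lo) / (hi - lo))
  lab <- pmin(pmax(lab, 1), n_levels) # v == hi maps to N; guard rounding
  as.integer(lab)
}

#' Quantize an ADC volume inside an ROI
#'
#' Maps every in-ROI voxel to a gray level in \eqn{1..N} using uniform
#' bins over limits chosen by the scheme. The bin convention is half-open
#' with closed top edge: label \eqn{= 1 + \lfloor N (v - lo)/(hi - lo)
#' \rfloor}, with \eqn{v = hi} mapping to \eqn{N}. Manual schemes clip
#' out-of-range values into bins 1 and \eqn{N}. A constant ROI (or
#' constant slice under AutoSlice) gets all labels 1 with a warning.
#'
#' @param adc An [adc_volume()].
#' @param roi Logical 3-D mask on the same grid, with at least one voxel.
#' @param scheme A [quantization_scheme()].
#' @return An object of class `quantized_roi`: list with `labels` (integer
#'   3-D array, `NA` outside the ROI), `n_levels` and `mask`.
#' @examples
#' ph <- generate_adc_phantom(phantom_spec(seed = 3))
#' q <- quantize_roi(ph$adc, ph$roi, quantization_scheme("AutoROI", 32))
#' range(q$labels, na.rm = TRUE)
#' @export
quantize_roi <- function(adc, roi, scheme) {
  stopifnot(inherits(adc, "adc_volume"), inherits(scheme, "quantization_scheme"),
            is.logical(roi), identical(dim(roi), dim(adc$values)))
  if (!any(roi)) stop("ROI mask is empty")
  N <- scheme$n_levels
  labels <- array(NA_integer_, dim = dim(roi))
  if (scheme$method == "AutoSlice") {
    for (z in seq_len(dim(roi)[3])) {
      mz <- roi[, , z]
      if (!any(mz)) next
      v <- adc$values[, , z][mz]
      lz <- labels[, , z]
      lz[mz] <- quantize_values(v, min(v), max(v), N)
      labels[, , z] <- lz
    }
  } else {
    v <- adc$values[roi]
    if (scheme$method == "AutoROI") {
      lo <- min(v); hi <- max(v); clip <- FALSE
    } else {
      lo <- scheme$manual_min; hi <- scheme$manual_max; clip <- TRUE
    }
    labels[roi] <- quantize_values(v, lo, hi, N, clip = clip)
  }
  structure(list(labels = labels, n_levels = N, mask = roi),
            class = "quantized_roi")
}

#' Choose manual quantization limits from a cohort of ROIs
#'
#' Given the per-ROI ADC value sets of a data set, returns the lower
#' quartile of the per-ROI minima and the upper quartile of the per-ROI
#' maxima — the rule used to fix manual limits for a cohort. Quartiles use
#' linear interpolation between order statistics (R's default quantile
#' type 7).
#'
#' @param roi_adc_batches A list of numeric vectors, one per ROI (the ADC
#'   values inside that ROI).
#' @return Numeric vector `c(manual_min, manual_max)`.
#' @examples
#' choose_manual_limits(list(c(0, 900), c(100, 2000), c(200, 3100), c(300, 4000)))
#' @export
choose_manual_limits <- function(roi_adc_batches) {
  if (!is.list(roi_adc_batches) || length(roi_adc_batches) == 0L) {
    stop("need at least one ROI to choose manual limits")
  }
  mins <- vapply(roi_adc_batches, min, numeric(1))
  maxs <- vapply(roi_adc_batches, max, numeric(1))
  c(manual_min = unname(stats::quantile(mins, 0.25, type = 7)),
    manual_max = unname(stats::quantile(maxs, 0.75, type = 7)))
}
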