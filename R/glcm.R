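#' @name glcm
#' @title Symmetric, directionally independent GLCMs
#' @description
#' A gray-level co-occurrence matrix (GLCM) counts, for every ordered pair
#' of adjacent voxels both inside the ROI, the combination of their gray
#' levels. Counting the closest neighbor in all eight in-plane directions
#' (left, right, up, down and the four diagonals) makes the matrix
#' symmetric and, after summing slices and normalizing, directionally
#' independent.
NULL

# ordered pairs for one offset direction; transposed sum adds the
# opposite direction
glcm_offset_pairs <- function(lab, di, dj) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr <= abs(di) || nc <= abs(dj)) return(NULL)
  ri <- seq_len(nr - abs(di)); ci <- seq_len(nc - abs(dj))
  ra <- if (di >= 0) ri else ri + abs(di)
  rb <- if (di >= 0) ri + di else ri
  ca <- if (dj >= 0) ci else ci + abs(dj)
  cb <- if (dj >= 0) ci + dj else ci
  a <- lab[ra, ca, drop = FALSE]
  b <- lab[rb, cb, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Build the symmetric GLCM of one quantized slice
#'
#' Counts every ordered pair of 8-adjacent voxels that both lie inside the
#' ROI (out-of-ROI neighbors are skipped), at distance 1 voxel. Since each
#' unordered pair is counted in both directions, the result is symmetric
#' and its total count is even. A slice without any valid neighbor pair
#' yields a zero matrix with a warning.
#'
#' @param labels_slice Integer matrix of gray levels in \eqn{1..N}, with
#'   `NA` outside the ROI.
#' @param n_levels \eqn{N}, the number of gray levels.
#' @return An `n_levels x n_levels` integer matrix of class `glcm_counts`.
#' @examples
#' glcm_slice(matrix(c(1, 1, 2, 2), nrow = 2), n_levels = 2)
#' @export
glcm_slice <- function(labels_slice, n_levels) {
  stopifnot(is.matrix(labels_slice), n_levels >= 2)
  N <- as.integer(n_levels)
  vals <- labels_slice[!is.na(labels_slice)]
  if (length(vals) && (min(vals) < 1L || max(vals) > N)) {
    stop("labels outside 1..n_levels")
  }
  counts <- matrix(0L, N, N)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    pr <- glcm_offset_pairs(labels_slice, off[1], off[2])
    if (is.null(pr) || length(pr$a) == 0L) next
    counts <- counts + matrix(tabulate((pr$a - 1L) * N + pr$b, nbins = N * N), N, N)
  }
  counts <- counts + t(counts)
  if (sum(counts) == 0L) {
    warning("slice has no valid in-ROI neighbor pairs; GLCM is all zeros")
  }
  structure(counts, class = c("glcm_counts", class(counts)), n_levels = N)
}

#' ROI-level normalized GLCM
#'
#' Sums the per-slice GLCM counts of a quantized ROI and divides by the
#' grand total, yielding the joint probability matrix \eqn{p(i,j)} with
#' \eqn{\sum_{i,j} p(i,j) = 1}. Slices with no valid pairs contribute
#' zeros and are tallied in the `n_empty_slices` attribute.
#'
#' @param q A [quantize_roi()] result, or a list of label matrices (each
#'   `NA` outside the ROI) sharing `n_levels` passed via the second
#'   argument.
#' @param n_levels Required only when `q` is a plain list of matrices.
#' @return A numeric `N x N` matrix of class `normalized_glcm` with
#'   attribute `n_levels`.
#' @examples
#' ph <- generate_adc_phantom(phantom_spec(seed = 4))
#' q <- quantize_roi(ph$adc, ph$roi, quantization_scheme("AutoROI", 32))
#' sum(glcm_roi(q))  # 1
#' @export
glcm_roi <- function(q, n_levels = NULL) {
  if (inherits(q, "quantized_roi")) {
    N <- q$n_levels
    slices <- lapply(seq_len(dim(q$labels)[3]), function(z) q$labels[, , z])
  } else {
    stopifnot(is.list(q), !is.null(n_levels))
    N <- as.integer(n_levels)
    slices <- q
  }
  total <- matrix(0, N, N)
  n_empty <- 0L
  for (s in slices) {
    if (!any(!is.na(s))) next # slice entirely outside ROI: skip silently
    cnt <- withCallingHandlers(
      glcm_slice(s, N),
      warning = function(w) {
        n_empty <<- n_empty + 1L
        invokeRestart("muffleWarning")
      }
    )
    total <- total + cnt
  }
  g <- sum(total)
  if (g == 0) stop("ROI has no texture support: all slice GLCMs are zero")
  p <- total / g
  structure(p, class = c("normalized_glcm", "matrix", "array"),
            n_levels = N, n_empty_slices = n_empty)
}
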