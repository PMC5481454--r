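#' Names of the 19 Haralick texture features
#'
#' @return Character vector of feature names in canonical order.
#' @export
haralick_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
    "correlation", "difference_entropy", "difference_variance",
    "dissimilarity", "energy", "entropy", "homogeneity", "imc1", "imc2",
    "inverse_difference", "maximum_probability", "sum_average",
    "sum_entropy", "sum_of_squares", "sum_variance")
}

shannon <- function(p) {
  p <- p[p > 0] # 0 log 0 := 0
  -sum(p * log(p))
}

#' Marginal quantities of a normalized GLCM
#'
#' Computes the row/column marginals \eqn{p_x, p_y}, the gray-level mean
#' \eqn{\mu = \sum_i i\,p_x(i)}, marginal means and standard deviations,
#' the sum and difference distributions \eqn{p_{x+y}(k)} (\eqn{k = 2..2N})
#' and \eqn{p_{x-y}(k)} (\eqn{k = 0..N-1}, over \eqn{|i-j|}), their means,
#' and the entropies \eqn{HX, HY, HXY, HXY1, HXY2} used by the information
#' measures of correlation. All entropies use the natural logarithm with
#' the convention \eqn{0 \log 0 = 0}.
#'
#' @param P Normalized GLCM (square numeric matrix summing to 1).
#' @return A list of class `glcm_marginals`.
#' @export
compute_marginals <- function(P) {
  P <- unclass(P)
  stopifnot(is.matrix(P), nrow(P) == ncol(P), all(P >= 0))
  N <- nrow(P)
  i <- seq_len(N)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(i * px)
  mu_y <- sum(i * py)
  sigma_x <- sqrt(sum((i - mu_x)^2 * px))
  sigma_y <- sqrt(sum((i - mu_y)^2 * py))

  S <- row(P) + col(P)
  p_sum <- vapply(2:(2 * N), function(k) sum(P[S == k]), numeric(1))
  D <- abs(row(P) - col(P))
  p_diff <- vapply(0:(N - 1), function(k) sum(P[D == k]), numeric(1))

  PXPY <- outer(px, py)
  pos <- P > 0
  structure(list(
    n_levels = N,
    p_x = px, p_y = py,
    mu = mu_x, mu_x = mu_x, mu_y = mu_y,
    sigma_x = sigma_x, sigma_y = sigma_y,
    p_sum = p_sum, k_sum = 2:(2 * N),
    p_diff = p_diff, k_diff = 0:(N - 1),
    mu_sum = sum((2:(2 * N)) * p_sum),
    mu_diff = sum((0:(N - 1)) * p_diff),
    HX = shannon(px), HY = shannon(py), HXY = shannon(P),
    HXY1 = -sum(P[pos] * log(PXPY[pos])),
    HXY2 = shannon(PXPY)
  ), class = "glcm_marginals")
}

#' Compute the 19 Haralick texture features from a normalized GLCM
#'
#' Evaluates, for a normalized symmetric GLCM \eqn{p(i,j)}:
#' autocorrelation \eqn{\sum ij\,p(i,j)}; cluster prominence and cluster
#' shade \eqn{\sum (i+j-2\mu)^q p(i,j)} (by default \eqn{q = 3} for
#' prominence and \eqn{q = 4} for shade; `cluster_convention =
#' "conventional"` swaps the exponents to the more widespread assignment);
#' contrast \eqn{\sum (i-j)^2 p(i,j)}; correlation
#' \eqn{(\sum ij\,p(i,j) - \mu_x\mu_y)/(\sigma_x\sigma_y)}; difference
#' entropy/variance and sum average/entropy/variance from the marginal
#' distributions; dissimilarity, energy, entropy, homogeneity, inverse
#' difference, maximum probability, sum of squares; and the two
#' information measures of correlation,
#' \eqn{\mathrm{IMC1} = (HXY - HXY1)/\max(HX, HY)} and
#' \eqn{\mathrm{IMC2} = \sqrt{1 - \exp[-2(HXY2 - HXY)]}}.
#'
#' For degenerate (zero-variance) GLCMs, correlation
#' (\eqn{\sigma_x\sigma_y = 0}) and IMC1 (\eqn{\max(HX,HY) = 0}) are
#' undefined and reported as `NA`, with the count of undefined features
#' recorded in the `n_undefined` attribute.
#'
#' @param P Normalized GLCM (square numeric matrix summing to 1).
#' @param cluster_convention `"as_printed"` (prominence: power 3, shade:
#'   power 4; the default) or `"conventional"` (prominence: power 4,
#'   shade: power 3).
#' @return Named numeric vector of length 19 (see
#'   [haralick_feature_names()]).
#' @examples
#' P <- matrix(c(1, 2, 2, 1) / 6, 2, 2)
#' compute_features(P)[c("contrast", "energy", "entropy")]
#' @export
compute_features <- function(P, cluster_convention = c("as_printed", "conventional")) {
  cluster_convention <- match.arg(cluster_convention)
  P <- unclass(P)
  stopifnot(is.matrix(P), nrow(P) == ncol(P), all(P >= 0))
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM is not normalized (entries must sum to 1)")
  m <- compute_marginals(P)
  N <- m$n_levels
  I <- row(P); J <- col(P)

  autocorrelation <- sum(I * J * P)
  csum <- I + J - 2 * m$mu
  if (cluster_convention == "as_printed") {
    cluster_prominence <- sum(csum^3 * P)
    cluster_shade <- sum(csum^4 * P)
  } else {
    cluster_prominence <- sum(csum^4 * P)
    cluster_shade <- sum(csum^3 * P)
  }
  contrast <- sum((I - J)^2 * P)
  correlation <- if (m$sigma_x * m$sigma_y == 0) NA_real_ else
    (autocorrelation - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y)
  difference_entropy <- shannon(m$p_diff)
  difference_variance <- sum((m$k_diff - m$mu_diff)^2 * m$p_diff)
  dissimilarity <- sum(abs(I - J) * P)
  energy <- sum(P^2)
  entropy <- m$HXY
  homogeneity <- sum(P / (1 + (I - J)^2))
  imc1 <- if (max(m$HX, m$HY) == 0) NA_real_ else
    (m$HXY - m$HXY1) / max(m$HX, m$HY)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (m$HXY2 - m$HXY))))
  inverse_difference <- sum(P / (1 + abs(I - J)))
  maximum_probability <- max(P)
  sum_average <- sum(m$k_sum * m$p_sum)
  sum_entropy <- shannon(m$p_sum)
  sum_of_squares <- sum((I - m$mu)^2 * P)
  sum_variance <- sum((m$k_sum - m$mu_sum)^2 * m$p_sum)

  out <- c(
    autocorrelation = autocorrelation,
    cluster_prominence = cluster_prominence,
    cluster_shade = cluster_shade,
    contrast = contrast,
    correlation = correlation,
    difference_entropy = difference_entropy,
    difference_variance = difference_variance,
    dissimilarity = dissimilarity,
    energy = energy,
    entropy = entropy,
    homogeneity = homogeneity,
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = inverse_difference,
    maximum_probability = maximum_probability,
    sum_average = sum_average,
    sum_entropy = sum_entropy,
    sum_of_squares = sum_of_squares,
    sum_variance = sum_variance
  )
  attr(out, "n_undefined") <- sum(is.na(out))
  out
}
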