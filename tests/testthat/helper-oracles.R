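# Independent reference implementations used as oracles. These are written
# directly from the defining formulas with explicit loops and stay
# independent of the package's vectorized code paths.

# every ordered pair of 8-adjacent in-ROI voxels, by brute force
naive_glcm <- function(lab, n_levels) {
  counts <- matrix(0L, n_levels, n_levels)
  nr <- nrow(lab); nc <- ncol(lab)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(lab[i, j])) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (is.na(lab[ii, jj])) next
      counts[lab[i, j], lab[ii, jj]] <- counts[lab[i, j], lab[ii, jj]] + 1L
    }
  }
  counts
}

naive_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

# all 19 features by explicit double loops over the defining sums
naive_features <- function(P) {
  N <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in seq_len(N)) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(N) - muy)^2 * py))
  psum <- numeric(2 * N - 1)  # k = 2..2N
  pdiff <- numeric(N)         # k = 0..N-1
  for (i in seq_len(N)) for (j in seq_len(N)) {
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  ks <- 2:(2 * N); kd <- 0:(N - 1)
  musum <- sum(ks * psum); mudiff <- sum(kd * pdiff)

  acor <- 0; cp <- 0; cs <- 0; con <- 0; dis <- 0; ene <- 0; ent <- 0
  hom <- 0; invd <- 0; ssq <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    p <- P[i, j]
    acor <- acor + i * j * p
    cp <- cp + (i + j - 2 * mux)^3 * p
    cs <- cs + (i + j - 2 * mux)^4 * p
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    if (p > 0) ent <- ent - p * log(p)
    hom <- hom + p / (1 + (i - j)^2)
    invd <- invd + p / (1 + abs(i - j))
    ssq <- ssq + (i - mux)^2 * p
    if (p > 0) hxy1 <- hxy1 - p * log(px[i] * py[j])
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
  }
  hx <- naive_entropy(px); hy <- naive_entropy(py)
  c(
    autocorrelation = acor,
    cluster_prominence = cp,
    cluster_shade = cs,
    contrast = con,
    correlation = if (sigx * sigy == 0) NA_real_ else (acor - mux * muy) / (sigx * sigy),
    difference_entropy = naive_entropy(pdiff),
    difference_variance = sum((kd - mudiff)^2 * pdiff),
    dissimilarity = dis,
    energy = ene,
    entropy = ent,
    homogeneity = hom,
    imc1 = if (max(hx, hy) == 0) NA_real_ else (ent - hxy1) / max(hx, hy),
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))),
    inverse_difference = invd,
    maximum_probability = max(P),
    sum_average = musum,
    sum_entropy = naive_entropy(psum),
    sum_of_squares = ssq,
    sum_variance = sum((ks - musum)^2 * psum)
  )
}

# random normalized symmetric GLCM, optionally sparse
random_glcm <- function(n_levels, sparse = FALSE) {
  M <- matrix(stats::runif(n_levels^2), n_levels, n_levels)
  if (sparse) M[M < 0.5] <- 0
  M <- M + t(M)
  if (sum(M) == 0) M[1, 1] <- 1
  M / sum(M)
}

# asymptotic two-sided two-sample KS p-value: D computed from ECDFs on the
# pooled support; p from the Kolmogorov limiting distribution, using the
# theta-function representation for small arguments
naive_ks <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(xs, function(x) mean(b <= x), numeric(1))
  D <- max(abs(Fa - Fb))
  m <- length(a); n <- length(b)
  t <- sqrt(m * n / (m + n)) * D
  if (t < 1) {
    k <- 1:50
    cdf <- sqrt(2 * pi) / t * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2)))
    p <- 1 - cdf
  } else {
    k <- 1:200
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  }
  list(D = D, p = min(1, max(0, p)))
}

# compact phantom used across tests
tiny_phantom <- function(seed = 1, fluid = FALSE, ...) {
  generate_adc_phantom(phantom_spec(
    grid_shape = c(32L, 32L, 2L), roi_radii = c(7, 7, 2),
    roi_center = c(14, 16, 1.5),
    adjacent_fluid = if (fluid) list(mean = 3000, width = 3L) else NULL,
    seed = seed, ...
  ))
}
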