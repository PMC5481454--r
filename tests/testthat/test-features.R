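test_that("marginals of the diagonal 2-level GLCM match direct summation", {
  P <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  m <- compute_marginals(P)
  expect_equal(m$p_x, c(0.5, 0.5))
  expect_equal(m$p_y, c(0.5, 0.5))
  expect_equal(m$mu_x, 1.5)
  expect_equal(m$sigma_x, 0.5)
  expect_equal(m$p_sum, c(0.5, 0, 0.5))   # k = 2, 3, 4
  expect_equal(m$p_diff, c(1, 0))         # k = 0, 1
  expect_equal(m$mu_sum, 3)
  expect_equal(m$mu_sum, m$mu_x + m$mu_y)
})

test_that("point-mass GLCM yields degenerate marginals", {
  P <- matrix(0, 3, 3); P[1, 1] <- 1
  m <- compute_marginals(P)
  expect_equal(m$mu, 1)
  expect_equal(m$sigma_x, 0)
  expect_equal(m$HX, 0)
  expect_equal(m$HXY, 0)
})

test_that("marginal distributions always normalize and symmetric GLCMs have p_x == p_y", {
  set.seed(51)
  for (N in c(2, 4, 8)) {
    P <- random_glcm(N)
    m <- compute_marginals(P)
    expect_equal(sum(m$p_x), 1, tolerance = 1e-12)
    expect_equal(sum(m$p_y), 1, tolerance = 1e-12)
    expect_equal(sum(m$p_sum), 1, tolerance = 1e-12)
    expect_equal(sum(m$p_diff), 1, tolerance = 1e-12)
    expect_equal(m$p_x, m$p_y)
    expect_equal(m$HX, m$HY)
  }
})

test_that("all 19 features match the brute-force reference on random GLCMs", {
  set.seed(53)
  for (rep in 1:100) {
    N <- sample(c(2, 4, 8, 16), 1)
    P <- random_glcm(N, sparse = rep %% 2 == 0)
    got <- compute_features(P)
    want <- naive_features(P)
    expect_equal(unclass(got)[haralick_feature_names()],
                 want[haralick_feature_names()],
                 tolerance = 1e-10, label = sprintf("rep %d N %d", rep, N),
                 ignore_attr = TRUE)
  }
})

test_that("closed forms hold for the point-mass and diagonal GLCMs", {
  P1 <- matrix(0, 4, 4); P1[1, 1] <- 1
  f1 <- compute_features(P1)
  expect_equal(unname(f1["contrast"]), 0)
  expect_equal(unname(f1["energy"]), 1)
  expect_equal(unname(f1["entropy"]), 0)
  expect_equal(unname(f1["homogeneity"]), 1)
  expect_equal(unname(f1["maximum_probability"]), 1)
  expect_equal(unname(f1["dissimilarity"]), 0)
  # zero-variance degeneracies are undefined, not numbers
  expect_true(is.na(f1["correlation"]))
  expect_true(is.na(f1["imc1"]))
  expect_equal(attr(f1, "n_undefined"), 2L)

  P2 <- diag(c(0.5, 0.5))
  f2 <- compute_features(P2)
  expect_equal(unname(f2["correlation"]), 1)
  expect_equal(unname(f2["entropy"]), log(2))
  expect_equal(unname(f2["contrast"]), 0)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["sum_average"]), 3)
})

test_that("the normalized example GLCM evaluates exactly", {
  P <- matrix(c(1, 2, 2, 1) / 6, 2, 2)
  got <- compute_features(P)
  want <- naive_features(P)
  expect_equal(unclass(got), want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(got["contrast"]), 2 / 3)
  expect_equal(unname(got["maximum_probability"]), 1 / 3)
})

test_that("feature values respect their analytic bounds", {
  set.seed(55)
  for (rep in 1:30) {
    N <- sample(c(2, 4, 8, 16), 1)
    P <- random_glcm(N, sparse = rep %% 3 == 0)
    f <- compute_features(P)
    expect_true(all(is.finite(f) | is.na(f)))
    expect_gt(f["energy"], 0); expect_lte(f["energy"], 1)
    expect_gte(f["energy"], 1 / N^2)
    expect_gte(f["entropy"], 0)
    expect_lte(f["entropy"], 2 * log(N) + 1e-12)
    expect_gte(f["contrast"], 0)
    expect_lte(f["contrast"], (N - 1)^2)
    expect_gte(f["sum_average"], 2); expect_lte(f["sum_average"], 2 * N)
    if (!is.na(f["correlation"])) {
      expect_gte(f["correlation"], -1 - 1e-12)
      expect_lte(f["correlation"], 1 + 1e-12)
    }
    expect_gte(f["imc2"], 0); expect_lt(f["imc2"], 1)
    expect_gt(f["homogeneity"], 0); expect_lte(f["homogeneity"], 1)
    expect_gt(f["inverse_difference"], 0); expect_lte(f["inverse_difference"], 1)
    # Cauchy-Schwarz on |i-j|
    expect_lte(f["dissimilarity"]^2, f["contrast"] + 1e-12)
  }
})

test_that("homogeneity and inverse difference hit 1 exactly iff the GLCM is diagonal", {
  Pd <- diag(c(0.25, 0.5, 0.25))
  fd <- compute_features(Pd)
  expect_equal(unname(fd["homogeneity"]), 1)
  expect_equal(unname(fd["inverse_difference"]), 1)
  set.seed(56)
  Po <- random_glcm(4)
  fo <- compute_features(Po)
  expect_lt(fo["homogeneity"], 1)
  expect_lt(fo["inverse_difference"], 1)
})

test_that("the cluster-feature convention flag swaps the exponents", {
  set.seed(57)
  P <- random_glcm(6)
  printed <- compute_features(P, cluster_convention = "as_printed")
  swapped <- compute_features(P, cluster_convention = "conventional")
  expect_equal(unname(printed["cluster_prominence"]),
               unname(swapped["cluster_shade"]))
  expect_equal(unname(printed["cluster_shade"]),
               unname(swapped["cluster_prominence"]))
})

test_that("coarser quantization lowers contrast and raises homogeneity", {
  ph <- tiny_phantom(seed = 14)
  f_at <- function(N) {
    q <- quantize_roi(ph$adc, ph$roi, quantization_scheme("AutoROI", N))
    compute_features(glcm_roi(q))
  }
  f8 <- f_at(8); f128 <- f_at(128)
  expect_lt(f8["contrast"], f128["contrast"])
  expect_gt(f8["homogeneity"], f128["homogeneity"])
})
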