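glioma_design <- function() experiment_design(make_protocol("glioma"))
prostate_design <- function() experiment_design(make_protocol("prostate"))

test_that("the designs enumerate the printed test counts", {
  g <- glioma_design(); p <- prostate_design()
  expect_equal(count_tests(g), 475)
  expect_equal(count_tests(p), 361)
  expect_equal(count_tests(list(g, p)), 836)
  # closed form: 19 x sum over parameters of C(s, 2)
  expect_equal(count_tests(g), 19 * sum(choose(lengths(g$varied), 2)))
})

test_that("every varied list contains the reference setting", {
  for (d in list(glioma_design(), prostate_design())) {
    for (pn in names(d$varied)) {
      labs <- vapply(d$varied[[pn]], adctexture:::setting_label, character(1),
                     parameter = pn)
      expect_true(adctexture:::setting_label(pn, d$reference[[pn]]) %in% labs,
                  label = pn)
    }
  }
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroni_threshold(0.01, 836), 0.01 / 836)
  expect_equal(bonferroni_threshold(0.01, 1), 0.01)
  expect_lt(abs(bonferroni_threshold(0.01, 836) - 1.196e-5), 1e-8)
  expect_false(0.5 < bonferroni_threshold(0.01, 836))
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0, 10), "alpha")
})

test_that("KS test handles identical, disjoint and undersized samples", {
  same <- ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  far <- ks_two_sample(c(1, 2, 3), c(11, 12, 13))
  expect_equal(far$D, 1)

  short <- ks_two_sample(c(1), c(1, 2, 3))
  expect_true(is.na(short$D) && is.na(short$p))
  with_na <- ks_two_sample(c(1, NA, 2, 3), c(4, 5, 6, NA))
  expect_false(is.na(with_na$p))
})

test_that("KS statistics and asymptotic p-values match the series oracle", {
  set.seed(61)
  for (rep in 1:100) {
    m <- sample(20:80, 1); n <- sample(20:80, 1)
    shift <- runif(1, 0, 2)
    a <- rnorm(m); b <- rnorm(n, mean = shift)
    got <- ks_two_sample(a, b)
    want <- naive_ks(a, b)
    expect_equal(got$D, want$D, tolerance = 1e-12)
    # the asymptotic series in stats::ks.test is truncated after very few
    # terms (absolute tolerance 1e-6, worst near the internal branch point
    # of the series where the dropped term reaches a few 1e-5); the oracle
    # sums the same limit distribution to machine precision
    expect_lt(abs(got$p - want$p), 5e-5)
  }
})

test_that("strongly separated distributions are detected at scale 72", {
  set.seed(63)
  hits <- vapply(1:50, function(r) {
    ks_two_sample(rnorm(72), rnorm(72, 3))$p < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("run_design executes the full setting grid per ROI", {
  prot <- make_protocol("glioma")
  batch <- make_phantom_batch(2, prot, seed = 71, grid_shape = c(32L, 32L, 2L))
  des <- experiment_design(prot)
  tab <- run_design(batch, des, seed = 71)
  expect_equal(nrow(tab), 2 * (3 + 3 + 4 + 5 + 3))
  expect_equal(attr(tab, "n_failed"), 0L)
  expect_true(all(haralick_feature_names() %in% names(tab)))

  pro <- experiment_design(make_protocol("prostate"))
  batch_p <- make_phantom_batch(1, make_protocol("prostate"), seed = 72,
                                grid_shape = c(32L, 32L, 2L))
  tab_p <- run_design(batch_p, pro, seed = 72)
  expect_equal(nrow(tab_p), 3 + 3 + 5 + 3)

  # reference setting appears once per varied parameter with identical values
  ref_rows <- tab[tab$roi == 1 &
                    tab$setting %in% c("1", "b=200,400,600,800,1000", "32", "AutoROI"), ]
  ref_rows <- ref_rows[
    (ref_rows$parameter == "resolution" & ref_rows$setting == "1") |
    (ref_rows$parameter == "b_values" & ref_rows$setting == "b=200,400,600,800,1000") |
    (ref_rows$parameter == "gray_levels" & ref_rows$setting == "32") |
    (ref_rows$parameter == "quantization" & ref_rows$setting == "AutoROI"), ]
  expect_gte(nrow(ref_rows), 4)
  for (f in haralick_feature_names()) {
    expect_equal(diff(range(ref_rows[[f]])), 0, label = f)
  }
})

test_that("the full pipeline is bit-reproducible under fixed seeds", {
  prot <- make_protocol("prostate")
  batch <- make_phantom_batch(2, prot, seed = 73, grid_shape = c(32L, 32L, 2L))
  des <- experiment_design(prot)
  t1 <- run_design(batch, des, seed = 73)
  t2 <- run_design(make_phantom_batch(2, prot, seed = 73,
                                      grid_shape = c(32L, 32L, 2L)),
                   des, seed = 73)
  expect_identical(t1, t2)
})

test_that("all_pairs_tests covers every pair and flags injected shifts", {
  des <- glioma_design()
  set.seed(75)
  # synthetic feature table: identical distributions everywhere
  fnames <- haralick_feature_names()
  mk_rows <- function(pn, labs, n = 30) {
    do.call(rbind, lapply(labs, function(s) {
      vals <- matrix(rep(seq_len(n), length(fnames)), ncol = length(fnames))
      df <- data.frame(roi = seq_len(n), parameter = pn, setting = s)
      df[fnames] <- vals
      df
    }))
  }
  tab <- do.call(rbind, lapply(names(des$varied), function(pn) {
    labs <- vapply(des$varied[[pn]], adctexture:::setting_label, character(1),
                   parameter = pn)
    mk_rows(pn, labs)
  }))
  res <- all_pairs_tests(tab, des)
  counts <- table(res$pairwise$parameter[res$pairwise$feature == "contrast"])
  expect_equal(as.vector(counts[c("resolution", "noise", "b_values",
                                  "gray_levels", "quantization")]),
               c(3L, 3L, 6L, 10L, 3L))
  expect_equal(nrow(res$pairwise), 475)
  expect_false(any(res$aggregated$significant))

  # inject a location shift into one setting of one parameter
  shifted <- tab
  sel <- shifted$parameter == "gray_levels" & shifted$setting == "128"
  shifted[sel, "contrast"] <- shifted[sel, "contrast"] + 1000
  res2 <- all_pairs_tests(shifted, des)
  agg <- res2$aggregated
  expect_true(agg$significant[agg$parameter == "gray_levels" &
                                agg$feature == "contrast"])
  expect_false(agg$significant[agg$parameter == "noise" &
                                 agg$feature == "contrast"])
})

test_that("p-values stay in [0,1] and missing features give missing p, not 1", {
  des <- prostate_design()
  fnames <- haralick_feature_names()
  labs <- unlist(lapply(names(des$varied), function(pn) {
    vapply(des$varied[[pn]], adctexture:::setting_label, character(1), pn)
  }))
  tab <- do.call(rbind, lapply(names(des$varied), function(pn) {
    do.call(rbind, lapply(des$varied[[pn]], function(s) {
      df <- data.frame(roi = 1:10, parameter = pn,
                       setting = adctexture:::setting_label(pn, s))
      df[fnames] <- rnorm(10)
      df$correlation <- NA_real_ # feature undefined everywhere
      df
    }))
  }))
  res <- all_pairs_tests(tab, des)
  p_ok <- res$pairwise$p
  expect_true(all(is.na(p_ok) | (p_ok >= 0 & p_ok <= 1)))
  cor_p <- res$pairwise$p[res$pairwise$feature == "correlation"]
  expect_true(all(is.na(cor_p)))
  cor_agg <- res$aggregated[res$aggregated$feature == "correlation", ]
  expect_true(all(is.na(cor_agg$p_min)))
  expect_false(any(cor_agg$significant))
})

test_that("in-plane dilation grows the ROI by its 8-connected border", {
  m <- array(FALSE, dim = c(7, 7, 2))
  m[4, 4, 1] <- TRUE
  d <- dilate_roi_inplane(m)
  expect_equal(sum(d[, , 1]), 9)
  expect_equal(sum(d[, , 2]), 0) # no through-plane growth
  expect_true(all(d[3:5, 3:5, 1]))
})

test_that("ROI expansion widens the AutoROI range by construction", {
  ph <- tiny_phantom(seed = 16, fluid = TRUE)
  adc <- ph$adc
  droi <- dilate_roi_inplane(ph$roi)
  expect_lte(min(adc$values[droi]), min(adc$values[ph$roi]))
  expect_gte(max(adc$values[droi]), max(adc$values[ph$roi]))
  expect_gt(max(adc$values[droi]), 2500) # dilation captures fluid voxels
})

test_that("constant fields show no feature change under dilation", {
  vals <- array(900, dim = c(16, 16, 1))
  adc <- adc_volume(vals, 1)
  roi <- array(FALSE, dim = dim(vals)); roi[6:10, 6:10, 1] <- TRUE
  rp <- suppressWarnings(roi_perturbation(adc, roi, n_levels = 8,
                                          manual_limits = c(500, 1500)))
  ok <- !is.na(rp$autoroi_pct)
  expect_true(any(ok))
  expect_true(all(abs(rp$autoroi_pct[ok]) < 1e-10))
  ok_m <- !is.na(rp$manual_pct)
  expect_true(all(abs(rp$manual_pct[ok_m]) < 1e-10))
})

test_that("Manual limits damp the ROI-expansion effect next to fluid", {
  wins <- vapply(1:5, function(s) {
    ph <- tiny_phantom(seed = 300 + s, fluid = TRUE)
    rp <- roi_perturbation(ph$adc, ph$roi, manual_limits = c(500, 1500))
    ok <- is.finite(rp$autoroi_pct) & is.finite(rp$manual_pct)
    mean(abs(rp$manual_pct[ok]) < abs(rp$autoroi_pct[ok]))
  }, numeric(1))
  expect_gt(mean(wins > 0.5), 0.5)
})

test_that("ROI touching the grid boundary is rejected for perturbation", {
  vals <- array(900, dim = c(8, 8, 1))
  roi <- array(FALSE, dim = dim(vals)); roi[1:4, 3:6, 1] <- TRUE
  expect_error(roi_perturbation(adc_volume(vals, 1), roi), "boundary")
})
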