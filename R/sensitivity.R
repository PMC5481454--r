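#' One-at-a-time experiment design
#'
#' Encodes the sensitivity-analysis design: a reference workflow
#' (resolution factor 1.0, noise factor 1.0, the protocol's reference
#' b-value subset, 32 gray levels, AutoROI quantization) and, per
#' investigated parameter, the list of settings to substitute one at a
#' time while all others stay at reference:
#' resolution \{1.0x, 1.5x, 3.0x\}; noise \{1.0x, 2.0x, 4.0x\};
#' b-value combinations (glioma protocol only) \{(0,1000), (200,1000),
#' (0..1000 step 200), (200..1000 step 200)\}; gray levels
#' \{8, 16, 32, 64, 128\}; quantization method \{AutoROI, AutoSlice,
#' Manual\}. Manual limits default to 0-3000 for the glioma protocol and
#' 0-2400 for the prostate protocol.
#'
#' @param protocol A [make_protocol()] object.
#' @param alpha Per-test significance level before correction (default
#'   0.01).
#' @param manual_limits Length-2 numeric, the Manual quantization limits;
#'   defaults depend on the protocol as above.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(protocol, alpha = 0.01, manual_limits = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"), alpha > 0, alpha < 1)
  glioma <- identical(protocol$name, "glioma")
  if (is.null(manual_limits)) {
    manual_limits <- if (glioma) c(0, 3000) else c(0, 2400)
  }
  stopifnot(length(manual_limits) == 2L, manual_limits[1] < manual_limits[2])
  ref_b <- if (glioma) seq(200, 1000, by = 200) else protocol$b_values
  varied <- list(
    resolution = list(1.0, 1.5, 3.0),
    noise = list(1.0, 2.0, 4.0),
    b_values = if (glioma) {
      list(c(0, 1000), c(200, 1000), seq(0, 1000, by = 200),
           seq(200, 1000, by = 200))
    } else NULL,
    gray_levels = list(8L, 16L, 32L, 64L, 128L),
    quantization = list("AutoROI", "AutoSlice", "Manual")
  )
  varied <- varied[!vapply(varied, is.null, logical(1))]
  structure(list(
    protocol = protocol,
    reference = list(resolution = 1.0, noise = 1.0, b_values = ref_b,
                     gray_levels = 32L, quantization = "AutoROI"),
    varied = varied,
    manual_limits = manual_limits,
    alpha = alpha
  ), class = "experiment_design")
}

setting_label <- function(parameter, value) {
  if (parameter == "b_values") paste0("b=", paste(value, collapse = ","))
  else as.character(value)
}

#' Number of pairwise KS tests implied by a design
#'
#' The design tests every unordered pair of settings of every varied
#' parameter, for each of the 19 features:
#' \eqn{19 \times \sum_p \binom{s_p}{2}}. The glioma design gives
#' \eqn{19 \times (3+3+6+10+3) = 475} tests, the prostate design
#' \eqn{19 \times (3+3+10+3) = 361}, totalling 836.
#'
#' @param design An [experiment_design()] (or a list of designs, whose
#'   counts are summed).
#' @return Integer test count.
#' @examples
#' count_tests(experiment_design(make_protocol("glioma")))
#' @export
count_tests <- function(design) {
  if (inherits(design, "experiment_design")) design <- list(design)
  stopifnot(all(vapply(design, inherits, logical(1), "experiment_design")))
  n_feat <- length(haralick_feature_names())
  sum(vapply(design, function(d) {
    n_feat * sum(choose(lengths(d$varied), 2))
  }, numeric(1)))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param n_tests Number of tests, `>= 1`.
#' @return `alpha / n_tests`; a pair is significant iff its p-value is
#'   strictly below this threshold.
#' @examples
#' bonferroni_threshold(0.01, 836)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes \eqn{D = \sup_x |F_a(x) - F_b(x)|} between the empirical
#' distribution functions of the two samples and the asymptotic two-sided
#' p-value. Missing values are dropped; if fewer than two finite values
#' remain on either side, both outputs are `NA` (never a silent 1).
#'
#' @param sample_a,sample_b Numeric vectors of feature values.
#' @return List with elements `D` and `p`.
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50, 3))
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(list(D = NA_real_, p = NA_real_))
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

derive_noise_seed <- function(master_seed, roi_index, noise_factor) {
  # depends only on (master seed, ROI, noise setting), never on which
  # design row is being executed, so the reference setting reproduces
  # identically wherever it appears
  (as.integer(master_seed) %% 100000L) * 10000L +
    (as.integer(roi_index) %% 1000L) * 10L +
    as.integer(round(noise_factor))
}

pipeline_features <- function(dwi, roi, cfg, design, noise_seed) {
  d <- resample_dwi(dwi, cfg$resolution)
  m <- resample_roi(roi, cfg$resolution)
  if (!any(m)) stop("ROI mask empty after resampling")
  d <- add_noise(d, design$protocol$native_noise_sigma, cfg$noise,
                 seed = noise_seed)
  adc <- fit_adc(d, cfg$b_values)
  scheme <- quantization_scheme(
    cfg$quantization, n_levels = cfg$gray_levels,
    manual_min = if (cfg$quantization == "Manual") design$manual_limits[1],
    manual_max = if (cfg$quantization == "Manual") design$manual_limits[2]
  )
  q <- suppressWarnings(quantize_roi(adc, m, scheme))
  P <- glcm_roi(q)
  compute_features(P)
}

#' Run the one-at-a-time design over a phantom batch
#'
#' For every ROI and every setting of every varied parameter, executes the
#' five-step chain (resample, add noise, fit ADC over the b-value subset,
#' choose GLCM size, quantize), builds the ROI-level GLCM and computes the
#' 19 features. Only the noise-injection stage is stochastic; its seed is
#' derived from `seed`, the ROI index and the noise setting alone, so the
#' reference workflow yields identical rows wherever it appears in the
#' design. Failures for a single (ROI, setting) combination produce a
#' missing row and are tallied, not fatal.
#'
#' @param phantoms A list as returned by [make_phantom_batch()]: each
#'   element has `dwi` (a [dwi_series()]) and `roi` (logical mask).
#' @param design An [experiment_design()].
#' @param seed Master seed for the noise-injection streams.
#' @return A data frame ("feature table") with columns `roi`, `parameter`,
#'   `setting` and the 19 features; attribute `n_failed` counts failed
#'   rows.
#' @export
run_design <- function(phantoms, design, seed = 1L) {
  stopifnot(length(phantoms) >= 1L, inherits(design, "experiment_design"))
  fnames <- haralick_feature_names()
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    cache <- new.env(parent = emptyenv())
    for (pn in names(design$varied)) {
      for (s in design$varied[[pn]]) {
        cfg <- design$reference
        cfg[[pn]] <- s
        key <- paste(cfg$resolution, cfg$noise,
                     paste(cfg$b_values, collapse = ","),
                     cfg$gray_levels, cfg$quantization, sep = "|")
        if (!exists(key, envir = cache, inherits = FALSE)) {
          feats <- tryCatch(
            pipeline_features(ph$dwi, ph$roi, cfg, design,
                              derive_noise_seed(seed, i, cfg$noise)),
            error = function(e) {
              n_failed <<- n_failed + 1L
              stats::setNames(rep(NA_real_, length(fnames)), fnames)
            })
          assign(key, feats, envir = cache)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          roi = i, parameter = pn, setting = setting_label(pn, s),
          as.list(get(key, envir = cache)[fnames]), check.names = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

#' All-pairs KS tests and Bonferroni significance per parameter
#'
#' For each feature and each varied parameter, runs [ks_two_sample()] on
#' every unordered pair of settings, aggregates per (parameter, feature)
#' by the minimum pairwise p-value, and flags the parameter as
#' significantly affecting the feature if any pair's p-value falls below
#' the Bonferroni-corrected threshold `alpha / n_tests`. A parameter is
#' thus deemed influential as soon as one pair of its settings shifts the
#' feature distribution.
#'
#' @param table Feature table from [run_design()].
#' @param design The [experiment_design()] that produced it.
#' @param n_tests Bonferroni denominator; defaults to
#'   `count_tests(design)`. Pass the grand total (e.g. 836) when several
#'   designs are analyzed jointly.
#' @return An object of class `sensitivity_result`: list with `pairwise`
#'   (long data frame of every test), `aggregated` (parameter x feature
#'   minimum p and significance flag), `alpha`, `n_tests`, `threshold`.
#' @export
all_pairs_tests <- function(table, design, n_tests = count_tests(design)) {
  stopifnot(inherits(design, "experiment_design"))
  thr <- bonferroni_threshold(design$alpha, n_tests)
  fnames <- haralick_feature_names()
  pw <- list()
  agg <- list()
  for (pn in names(design$varied)) {
    labs <- vapply(design$varied[[pn]], setting_label, character(1),
                   parameter = pn)
    sub <- table[table$parameter == pn, , drop = FALSE]
    pairs <- utils::combn(labs, 2L)
    for (f in fnames) {
      pvals <- numeric(0)
      for (k in seq_len(ncol(pairs))) {
        va <- sub[sub$setting == pairs[1, k], f]
        vb <- sub[sub$setting == pairs[2, k], f]
        ks <- ks_two_sample(va, vb)
        pw[[length(pw) + 1L]] <- data.frame(
          parameter = pn, feature = f,
          setting_a = pairs[1, k], setting_b = pairs[2, k],
          D = ks$D, p = ks$p
        )
        pvals <- c(pvals, ks$p)
      }
      pmin_ <- if (all(is.na(pvals))) NA_real_ else min(pvals, na.rm = TRUE)
      agg[[length(agg) + 1L]] <- data.frame(
        parameter = pn, feature = f, p_min = pmin_,
        significant = !is.na(pmin_) && pmin_ < thr
      )
    }
  }
  structure(list(
    pairwise = do.call(rbind, pw),
    aggregated = do.call(rbind, agg),
    alpha = design$alpha, n_tests = n_tests, threshold = thr
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sensitivity analysis: ", nrow(x$pairwise), " pairwise KS tests, ",
      "alpha = ", x$alpha, " Bonferroni-corrected for ", x$n_tests,
      " tests (threshold ", signif(x$threshold, 3), ")\n", sep = "")
  sig <- x$aggregated[x$aggregated$significant %in% TRUE, ]
  cat("Significant (parameter, feature) results: ", nrow(sig), " of ",
      nrow(x$aggregated), "\n", sep = "")
  invisible(x)
}

#' Dilate an ROI mask by one voxel in-plane
#'
#' Morphological dilation with a 3x3 (8-connected) structuring element,
#' applied slice by slice; no through-plane growth.
#'
#' @param mask Logical 3-D array.
#' @return Logical 3-D array.
#' @export
dilate_roi_inplane <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[3])) {
    m <- mask[, , z]
    if (!any(m)) next
    g <- m
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- matrix(FALSE, d[1], d[2])
      ri <- seq_len(d[1] - abs(di)); ci <- seq_len(d[2] - abs(dj))
      sh[if (di >= 0) ri + di else ri, if (dj >= 0) ci + dj else ci] <-
        m[if (di >= 0) ri else ri + abs(di), if (dj >= 0) ci else ci + abs(dj)]
      g <- g | sh
    }
    out[, , z] <- g
  }
  out
}

#' Feature change under one-voxel ROI expansion
#'
#' Quantifies how sensitive each feature is to the exact ROI delineation:
#' the ROI is dilated by one voxel in-plane and the 19 features are
#' recomputed under both AutoROI and Manual quantization. When the ROI
#' borders a high-ADC structure (CSF, urine), the dilation captures fluid
#' voxels and the AutoROI intensity range expands, while fixed Manual
#' limits absorb the change. Reported per feature: the percentage change
#' \eqn{100 (f_{dil} - f_{orig})/f_{orig}} under each scheme and their
#' ratio Manual/AutoROI.
#'
#' @param adc An [adc_volume()].
#' @param roi Logical 3-D mask; must not touch the in-plane grid boundary
#'   (the dilated ROI has to stay within the grid).
#' @param n_levels Gray levels for both schemes (default 32).
#' @param manual_limits Manual quantization limits, default `c(500, 1500)`
#'   — a range covering parenchyma and tumor but excluding fluid.
#' @return Data frame with columns `feature`, `autoroi_pct`, `manual_pct`,
#'   `ratio`. Features whose original value is 0 or undefined yield `NA`
#'   percentages.
#' @export
roi_perturbation <- function(adc, roi, n_levels = 32L,
                             manual_limits = c(500, 1500)) {
  stopifnot(inherits(adc, "adc_volume"), is.logical(roi),
            identical(dim(roi), dim(adc$values)))
  d <- dim(roi)
  touches <- any(roi[1, , ]) || any(roi[d[1], , ]) ||
    any(roi[, 1, ]) || any(roi[, d[2], ])
  if (touches) stop("ROI touches the in-plane grid boundary; dilation would leave the grid")
  droi <- dilate_roi_inplane(roi)

  feats_for <- function(mask, scheme) {
    q <- suppressWarnings(quantize_roi(adc, mask, scheme))
    compute_features(glcm_roi(q))
  }
  sch_auto <- quantization_scheme("AutoROI", n_levels)
  sch_man <- quantization_scheme("Manual", n_levels,
                                 manual_min = manual_limits[1],
                                 manual_max = manual_limits[2])
  pct <- function(orig, dil) {
    ifelse(is.na(orig) | is.na(dil) | orig == 0, NA_real_,
           100 * (dil - orig) / orig)
  }
  a0 <- feats_for(roi, sch_auto); a1 <- feats_for(droi, sch_auto)
  m0 <- feats_for(roi, sch_man); m1 <- feats_for(droi, sch_man)
  auto_pct <- pct(a0, a1)
  man_pct <- pct(m0, m1)
  data.frame(
    feature = haralick_feature_names(),
    autoroi_pct = unname(auto_pct),
    manual_pct = unname(man_pct),
    ratio = unname(ifelse(is.na(auto_pct) | auto_pct == 0, NA_real_,
                          man_pct / auto_pct)),
    row.names = NULL
  )
}
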