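test_that("first-order statistics match hand values and the moment oracle", {
  expect_equal(fos_features(matrix(5, 3, 3)),
               c(mean = 5, variance = 0, median = 5, skewness = 0,
                 kurtosis = 0))
  f <- fos_features(c(1, 2, 3, 4))
  expect_equal(unname(f[c("mean", "variance", "median", "skewness")]),
               c(2.5, 1.25, 2.5, 0))
  f2 <- fos_features(c(0, 0, 0, 9))
  expect_equal(unname(f2["skewness"]), 2 / sqrt(3), tolerance = 1e-12)
  for (sd_ in 1:20) {
    set.seed(sd_)
    x <- matrix(runif(49, 0, 50), 7, 7)
    expect_equal(fos_features(x), oracle_fos(x), tolerance = 1e-12)
  }
})

test_that("GLCM features match hand-derived small cases", {
  cw <- glcm_features(matrix(3, 4, 4), levels = 8)
  expect_equal(unname(cw[c("energy", "entropy", "contrast", "dissimilarity",
                           "homogeneity", "max_probability")]),
               c(1, 0, 0, 0, 1, 1))
  # 2x2 patch [[0,0],[1,1]], 2 levels, horizontal pairs only
  p <- matrix(c(0, 1, 0, 1), 2, 2)          # rows: (0,0) / (1,1)
  f <- glcm_features(p, levels = 2, angles = 0)
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["entropy"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  # 1-D checkerboard at angle 0
  cb <- matrix(rep(c(0, 1), 4), 1, 8)
  f2 <- glcm_features(rbind(cb, cb), levels = 2, angles = 0)
  expect_equal(unname(f2["contrast"]), 1)
  expect_equal(unname(f2["dissimilarity"]), 1)
  expect_equal(unname(f2["homogeneity"]), 0.5)
})

test_that("GLCM and NGTDM equal brute-force enumeration on random patches", {
  for (sd_ in 1:100) {
    set.seed(sd_)
    levels <- sample(c(4, 8), 1)
    q <- matrix(sample(seq_len(levels), 64, replace = TRUE), 8, 8)
    # GLCM: feed pre-quantized tones through an identity gray range
    x <- (q - 1) / (levels - 1)
    got <- glcm_features(x, levels = levels, gray_range = c(0, 1 + 1e-12))
    expect_equal(got, oracle_glcm(q, levels), tolerance = 1e-12)
    expect_equal(ngtdm_features(q), oracle_ngtdm(q), tolerance = 1e-12)
  }
})

test_that("NGTDM degenerate and hand cases behave as specified", {
  f <- ngtdm_features(matrix(4L, 5, 5))
  expect_equal(unname(f["coarseness"]), 1e12)
  expect_equal(unname(f[c("busyness", "ngtdm_contrast", "complexity",
                          "strength")]), c(0, 0, 0, 0))
  two_tone <- matrix(c(1L, 1L, 2L, 2L,
                       1L, 1L, 2L, 2L,
                       1L, 1L, 2L, 2L,
                       1L, 1L, 2L, 2L), 4, 4, byrow = TRUE)
  expect_equal(ngtdm_features(two_tone), oracle_ngtdm(two_tone),
               tolerance = 1e-12)
  expect_error(ngtdm_features(matrix(1, 2, 2)), "3x3")
})

test_that("NGTDM responds monotonically to quantized noise amplitude", {
  # Amadasun's contrast grows with tone spread; busyness, whose denominator
  # is the tone-weighted spread, shrinks as the same texture gets coarser
  # in amplitude.  Both move strictly monotonically.
  for (sd_ in 1:5) {
    set.seed(sd_)
    base <- matrix(8L, 9, 9)
    f <- vapply(c(1, 2, 4), function(a) {
      noisy <- base + matrix(sample(-a:a, 81, replace = TRUE), 9, 9)
      ngtdm_features(noisy)[c("ngtdm_contrast", "busyness")]
    }, c(0, 0))
    expect_gt(f["ngtdm_contrast", 3], f["ngtdm_contrast", 1])
    expect_true(all(diff(f["busyness", ]) < 0))
  }
})

test_that("differential box counting is exactly 2 on flat surfaces", {
  f <- fd_features(matrix(3, 64, 64), scales = c(2, 4, 8, 16),
                   gray_range = c(0, 10))
  expect_equal(attr(f, "fd"), 2.0, tolerance = 1e-12)
  expect_equal(as.numeric(f), log((64 / c(2, 4, 8, 16))^2), tolerance = 1e-12)
})

test_that("fractal dimension orders plane < noise and brackets the plane", {
  plane <- outer(1:64, 1:64, function(i, j) i + j)
  fp <- attr(fd_features(plane, scales = c(2, 4, 8, 16)), "fd")
  expect_gte(fp, 1.9)
  expect_lte(fp, 2.1)
  for (sd_ in 1:10) {
    set.seed(sd_)
    noise <- matrix(runif(64 * 64, 0, 128), 64, 64)
    fn <- attr(fd_features(noise, scales = c(2, 4, 8, 16)), "fd")
    expect_gt(fn, fp)
  }
})

test_that("the compiled sweep equals the single-window R functions", {
  set.seed(31)
  n_r <- 24; n_c <- 30
  img <- matrix(runif(n_r * n_c, 0, 1000), n_r, n_c)
  gr <- range(img)
  levels <- 16; wpx <- 11
  q <- quantize_gray(img, levels, gr)
  # include seam-wrapping rows and a depth-clipped column
  targets <- rbind(c(0L, 15L), c(1L, 6L), c(23L, 15L), c(12L, 28L),
                   c(11L, 5L))
  tex <- octplaq:::texture_sweep_cpp(img, q, levels, targets[, 1],
                                     targets[, 2], wpx,
                                     c(2L, 3L, 4L, 5L), gr[1], gr[2])
  for (t_ in seq_len(nrow(targets))) {
    w_raw <- extract_window(img, targets[t_, 1], targets[t_, 2], wpx)
    w_q <- extract_window(q, targets[t_, 1], targets[t_, 2], wpx)
    expect_equal(unname(tex[t_, 1:5]), unname(fos_features(w_raw)),
                 tolerance = 1e-12)
    expect_equal(unname(tex[t_, 6:12]),
                 unname(glcm_features(w_raw, levels, gr)), tolerance = 1e-12)
    expect_equal(unname(tex[t_, 13:17]), unname(ngtdm_features(w_q)),
                 tolerance = 1e-10)
    if (min(dim(w_raw)) >= 10)      # FD needs an unclipped window
      expect_equal(unname(tex[t_, 18:21]),
                   as.numeric(fd_features(w_raw, c(2, 3, 4, 5), gr)),
                   tolerance = 1e-12)
  }
})

test_that("quantization-anchored features are shift-invariant; FOS location shifts", {
  set.seed(41)
  img <- matrix(runif(400, 10, 200), 20, 20)
  w <- img[5:15, 5:15]
  off <- 37.5
  g1 <- glcm_features(w, 16, range(img))
  g2 <- glcm_features(w + off, 16, range(img) + off)
  expect_equal(g1, g2, tolerance = 1e-10)
  n1 <- ngtdm_features(quantize_gray(w, 16, range(img)))
  n2 <- ngtdm_features(quantize_gray(w + off, 16, range(img) + off))
  expect_equal(n1, n2, tolerance = 1e-10)
  f1 <- fd_features(w[1:10, 1:10], c(2, 3, 4, 5), range(img))
  f2 <- fd_features(w[1:10, 1:10] + off, c(2, 3, 4, 5), range(img) + off)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-10)
  s1 <- fos_features(w); s2 <- fos_features(w + off)
  expect_equal(unname(s2["mean"] - s1["mean"]), off, tolerance = 1e-10)
  expect_equal(unname(s2["median"] - s1["median"]), off, tolerance = 1e-10)
  expect_equal(s1[c("variance", "skewness", "kurtosis")],
               s2[c("variance", "skewness", "kurtosis")], tolerance = 1e-9)
})

test_that("the feature stack has 25 named features and boundary-anchored x", {
  sys <- system_params(n_alines = 40, axial_spacing = 0.01)
  ph <- generate_phantom(phantom_spec(seed = 17), sys = sys)
  opt <- attenuation_map(ph$image, ph$boundary, sys)
  pix <- cbind(c(0L, 5L, 10L), ph$boundary[c(1, 6, 11)])
  stack <- build_feature_stack(ph$image, opt, ph$boundary, pixels = pix)
  expect_identical(setdiff(names(stack), c("row", "col")), FEATURE_NAMES)
  expect_length(setdiff(names(stack), c("row", "col")), 25)
  expect_true(all(stack$x == 0))       # pixels on the boundary
  expect_true(all(stack$y == c(0, 5, 10)))
  expect_false(anyNA(stack))
})

test_that("GLCM contrast separates weak from strong texture sectors", {
  sys <- system_params(n_alines = 80, axial_spacing = 0.01)
  pars <- list(fibrous = tissue_optical_params(1, 20000, 4, 0.05),
               lipid = tissue_optical_params(1, 20000, 1, 0.4))
  sp <- phantom_spec(tissue_sectors = data.frame(
    start_deg = c(0, 180), end_deg = c(180, 360), label = c(1L, 3L),
    thickness_mm = 1.2), looks = Inf, seed = 19)
  ph <- generate_phantom(sp, params_by_label = pars, sys = sys)
  opt <- attenuation_map(ph$image, ph$boundary, sys)
  cand <- which(opt$roi & ph$labels$labels > 0L, arr.ind = TRUE)
  # compare within a fixed shallow depth slice so depth-driven quantization
  # variation does not swamp the texture signal
  depth <- cand[, 2] - 1L - ph$boundary[cand[, 1]]
  cand <- cand[depth >= 5 & depth <= 45, , drop = FALSE]
  set.seed(19)
  cand <- cand[sample(nrow(cand), 600), ]
  stack <- build_feature_stack(ph$image, opt, ph$boundary,
                               pixels = cbind(cand[, 1] - 1L, cand[, 2] - 1L))
  lab <- ph$labels$labels[cbind(stack$row + 1L, stack$col + 1L)]
  c1 <- stack$contrast[lab == 1L]; c3 <- stack$contrast[lab == 3L]
  pooled_sd <- sqrt((var(c1) + var(c3)) / 2)
  expect_gt(abs(mean(c3) - mean(c1)), 3 * pooled_sd)
})
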