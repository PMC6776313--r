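test_that("shape features recover analytic disk and ellipse geometry", {
  d16 <- shape_features(disk_mask(16))
  expect_equal(unname(d16["morph_area"]), pi * 256, tolerance = 0.03)
  expect_gte(unname(d16["morph_roundness"]), 0.95)
  expect_equal(unname(d16["morph_elongation"]), 1, tolerance = 0.05)
  expect_equal(unname(d16["morph_equivalent_spherical_radius"]), 16,
               tolerance = 0.03)

  sp <- render_patch(list(nucleus_spec(c(32, 32), c(20, 10))),
                     size = c(64, 64), noise_sd = 0, seed = 1)
  el <- shape_features(sp$truth_mask == 1)
  expect_equal(unname(el["morph_elongation"]), 2, tolerance = 0.05)
  expect_equal(unname(el["morph_ellipse_major_axis"]), 40, tolerance = 0.05)
  expect_equal(unname(el["morph_flatness"]), unname(el["morph_elongation"]))

  # uniform bar: major axis = length * 2/sqrt(3) from the uniform variance
  bar <- matrix(TRUE, 5, 50)
  bf <- shape_features(bar)
  expect_equal(unname(bf["morph_ellipse_major_axis"]),
               4 * sqrt((50^2 - 1) / 12), tolerance = 1e-6)
  expect_gt(unname(bf["morph_elongation"]), 5)

  expect_error(shape_features(matrix(FALSE, 4, 4)), "empty")
})

test_that("shape features are invariant to translation and 90-degree rotation", {
  sp <- render_patch(list(nucleus_spec(c(40, 40), c(18, 9),
                                       orientation = 0.6)),
                     size = c(80, 80), noise_sd = 0, seed = 2)
  mask <- sp$truth_mask == 1
  base <- shape_features(mask)
  coords <- which(mask, arr.ind = TRUE)
  shifted <- shape_features(cbind(coords[, 1] + 13, coords[, 2] + 5))
  expect_equal(base, shifted, tolerance = 1e-12)
  rotated <- shape_features(t(mask)[rev(seq_len(ncol(mask))), ])
  expect_equal(base, rotated, tolerance = 0.02)
})

test_that("doubling both semi-axes scales area x4 and perimeter x2, elongation fixed", {
  mk <- function(ab) {
    sp <- render_patch(list(nucleus_spec(c(64, 64), ab, orientation = 0.3)),
                       size = c(128, 128), noise_sd = 0, seed = 3)
    shape_features(sp$truth_mask == 1)
  }
  f1 <- mk(c(12, 8)); f2 <- mk(c(24, 16))
  expect_equal(unname(f2["morph_area"] / f1["morph_area"]), 4, tolerance = 0.05)
  expect_equal(unname(f2["morph_perimeter"] / f1["morph_perimeter"]), 2,
               tolerance = 0.05)
  expect_equal(unname(f2["morph_elongation"]), unname(f1["morph_elongation"]),
               tolerance = 0.05)
})

test_that("intensity statistics match hand-computed values and degenerate conventions", {
  plane <- matrix(0.4, 4, 4)
  v <- intensity_features(plane, matrix(TRUE, 4, 4))
  expect_equal(unname(v), c(0.4, 0.4, 0, 0, 0))

  plane2 <- matrix(c(0, 0, 1, 1), 2, 2)
  v2 <- intensity_features(plane2, matrix(TRUE, 2, 2))
  expect_equal(unname(v2["mean"]), 0.5)
  expect_equal(unname(v2["sd"]), sd(c(0, 0, 1, 1)))
  expect_equal(unname(v2["skewness"]), 0)

  sym <- matrix(rep(c(0, 1, 2), 3), 3, 3)   # symmetric about the mean
  expect_equal(unname(intensity_features(sym, matrix(TRUE, 3, 3))["skewness"]),
               0, tolerance = 1e-12)
})

test_that("GLCM features reproduce closed-form stripe and constant cases", {
  const <- glcm_features(matrix(0.7, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(unname(const["energy"]), 1)
  expect_equal(unname(const["entropy"]), 0)
  expect_equal(unname(const["inertia"]), 0)
  expect_equal(unname(const["inverse_difference_moment"]), 1)
  expect_equal(unname(const["correlation"]), 0)   # zero-variance convention

  # two-level 1-px vertical stripes; single horizontal offset, Q = 2:
  # all pairs are (1,2) or (2,1): energy 0.5, entropy ln 2, inertia 1, IDM 0.5
  stripes <- matrix(rep(c(0, 1), 4), 1, 8)
  p <- rccgrade:::glcm_matrix(stripes, matrix(TRUE, 1, 8), Q = 2)
  expect_equal(sum(p), 1)
  st <- rccgrade:::glcm_stats(p)
  expect_equal(unname(st["energy"]), 0.5)
  expect_equal(unname(st["entropy"]), log(2))
  expect_equal(unname(st["inertia"]), 1)
  expect_equal(unname(st["inverse_difference_moment"]), 0.5)

  scattered <- matrix(FALSE, 3, 3)
  scattered[c(1, 7, 3, 9)] <- TRUE          # four corners: no distance-1 pair
  expect_error(glcm_features(matrix(1, 3, 3), scattered), "pairs")
})

test_that("RLM features reproduce hand-computed run cases", {
  # constant 1x8 row, single direction: one run of length 8
  row8 <- matrix(1, 1, 8)
  v <- rlm_features(row8, matrix(TRUE, 1, 8), directions = "horizontal")
  expect_equal(unname(v["gln"]), 1)
  expect_equal(unname(v["rln"]), 1)
  expect_equal(unname(v["lrhge"]), 64)

  # alternating two-level 1x8 row: 8 runs of length 1 -> rln = 64/8 = 8
  alt <- matrix(rep(c(0, 1), 4), 1, 8)
  v2 <- rlm_features(alt, matrix(TRUE, 1, 8), Q = 2,
                     directions = "horizontal")
  expect_equal(unname(v2["rln"]), 8)

  expect_error(rlm_features(row8, matrix(FALSE, 1, 8)), "empty|runs")
})

test_that("GLCM and RLM match brute-force enumeration on random regions", {
  for (seed in 1:30) {
    rg <- random_region(seed)
    got_g <- glcm_features(rg$plane, rg$mask, Q = 8)
    exp_g <- oracle_glcm(rg$plane, rg$mask, Q = 8)
    expect_equal(got_g, exp_g, tolerance = 1e-10)
    got_r <- rlm_features(rg$plane, rg$mask, Q = 8)
    exp_r <- oracle_rlm(rg$plane, rg$mask, Q = 8)
    expect_equal(got_r, exp_r, tolerance = 1e-10)
  }
})

test_that("patch_features emits 72 named values with mean aggregation over nuclei", {
  sp <- fixture_patch(n = 3, size = c(160, 160), seed = 8)
  v <- patch_features(sp$image, sp$truth_mask)
  expect_length(v, 72)
  expect_identical(names(v), feature_names())
  expect_equal(attr(v, "n_nuclei"), 3L)
  expect_true(all(is.finite(v)))

  # one-nucleus patch: patch value equals the nucleus value
  one <- render_patch(list(nucleus_spec(c(40, 40), c(12, 9))),
                      size = c(80, 80), seed = 4)
  v1 <- patch_features(one$image, one$truth_mask)
  ch <- extract_channels(one$image)
  direct <- shape_features(one$truth_mask == 1)
  expect_equal(v1[names(direct)], direct)
  expect_equal(unname(v1["int_mean_he"]),
               mean(ch$hematoxylin[one$truth_mask == 1]))

  expect_warning(empty <- patch_features(one$image,
                                         matrix(0L, 80, 80)), "no segmented")
  expect_null(empty)
})

test_that("feature namespace identities hold", {
  fm <- feature_manifest()
  expect_equal(nrow(fm), 72)
  expect_equal(sum(fm$family == "morphology"), 9)
  expect_equal(sum(fm$family == "intensity"), 15)
  expect_equal(sum(fm$family == "texture"), 48)
  expect_equal(length(summary_feature_names()), 144)
  expect_false(any(duplicated(fm$name)))
})
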