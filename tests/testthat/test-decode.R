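test_that("top-t voxel selection is a sorted prefix with deterministic ties", {
  glm <- fake_glm(NULL, 1:9, 2, 10)
  glm$t_map <- c(5, 3, 3, 9, 1, 7, 2, 8, 4)
  glm$voxels$layer <- factor(rep(c("deeper", "middle", "superficial"), each = 3),
                             levels = c("deeper", "middle", "superficial"))
  sel <- select_voxels(glm, glm$voxels, n = 2)
  expect_equal(sel$voxel_id[sel$layer == "deeper"], c(1L, 2L))  # t 5 > 3 (tie: lower id)
  expect_equal(sel$voxel_id[sel$layer == "middle"], c(4L, 6L))  # t 9 > 7
  # identity selection at n = layer size
  sel_all <- select_voxels(glm, glm$voxels, n = 3)
  expect_setequal(sel_all$voxel_id, 1:9)
  # tie between voxels 2 and 3 (t = 3): lower id wins
  glm$t_map <- c(1, 3, 3, 2, 1, 1, 1, 1, 1)
  sel_tie <- select_voxels(glm, glm$voxels, n = 2)
  expect_equal(sel_tie$voxel_id[sel_tie$layer == "deeper"], c(2L, 3L))
  expect_error(select_voxels(glm, glm$voxels, n = 10), "fewer than")
})

test_that("a separable fixture decodes perfectly with correctly signed distances", {
  bp <- synthetic_patterns(n_runs = 4, n_vox = 30, sep = 4, noise = 0.3, seed = 1)
  dec <- crossval_decode(bp)
  expect_equal(dec$accuracy, 1)
  expect_true(all(dec$distances$distance[dec$distances$disparity == "near"] > 0))
  expect_true(all(dec$distances$distance[dec$distances$disparity == "far"] < 0))
  # one distance per test block, folds = runs
  expect_equal(nrow(dec$distances), nrow(bp$blocks))
  expect_equal(nrow(dec$folds), 4)
  # 4 runs: 60 training and 20 test patterns per fold
  expect_equal(sum(bp$blocks$run != 1), 60)
  expect_equal(sum(bp$blocks$run == 1), 20)
})

test_that("accuracy is exactly recomputable from stored distances and labels", {
  bp <- synthetic_patterns(n_runs = 3, n_vox = 20, sep = 0.8, noise = 1, seed = 2)
  dec <- crossval_decode(bp)
  d <- dec$distances
  acc_by_run <- tapply(
    (d$distance > 0 & d$disparity == "near") | (d$distance < 0 & d$disparity == "far"),
    d$run, mean)
  expect_equal(dec$accuracy, mean(acc_by_run), tolerance = 1e-12)
})

test_that("label-independent patterns decode at chance", {
  accs <- vapply(1:20, function(sd) {
    crossval_decode(synthetic_patterns(n_runs = 2, blocks_per_class_run = 10,
                                       n_vox = 25, sep = 0, seed = sd))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("decoding is invariant to orthogonal rotation of voxel space", {
  bp <- synthetic_patterns(n_runs = 3, n_vox = 20, sep = 1, seed = 3)
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
  bp_rot <- bp
  bp_rot$responses <- bp$responses %*% Q
  expect_equal(crossval_decode(bp)$accuracy, crossval_decode(bp_rot)$accuracy,
               tolerance = 1e-6)
})

test_that("test data never leak into training", {
  bp <- synthetic_patterns(n_runs = 3, n_vox = 15, sep = 0.5, seed = 4)
  dec1 <- crossval_decode(bp)
  bp2 <- bp
  touched <- which(bp$blocks$run == 1)[1]
  bp2$responses[touched, ] <- bp2$responses[touched, ] * 50
  dec2 <- crossval_decode(bp2)
  untouched <- bp$blocks$run == 1 & seq_len(nrow(bp$blocks)) != touched
  expect_equal(dec1$distances$distance[untouched],
               dec2$distances$distance[untouched], tolerance = 1e-9)
})

test_that("degenerate folds are rejected", {
  bp <- synthetic_patterns(n_runs = 2, n_vox = 10, seed = 5)
  bp$blocks$disparity[bp$blocks$run == 2] <- "near"
  expect_error(crossval_decode(bp), "missing a class")
  one_run <- synthetic_patterns(n_runs = 2, n_vox = 10, seed = 5)
  one_run$blocks$run <- 1L
  expect_error(crossval_decode(one_run), ">= 2 runs")
})

test_that("permutation null is centred on chance with the exact p formula", {
  bp <- synthetic_patterns(n_runs = 2, blocks_per_class_run = 8, n_vox = 15,
                           sep = 0, seed = 6)
  pn <- permutation_null(bp, n_perm = 200, seed = 1)
  expect_lt(abs(mean(pn$null) - 0.5), 0.03)
  # a strong signal beats every permutation: p hits its floor 1/(n_perm + 1)
  bp_sig <- synthetic_patterns(n_runs = 2, blocks_per_class_run = 8, n_vox = 15,
                               sep = 4, noise = 0.3, seed = 7)
  pn_sig <- suppressWarnings(permutation_null(bp_sig, n_perm = 99, seed = 2))
  expect_equal(pn_sig$p, 1 / 100)
  expect_warning(permutation_null(bp, n_perm = 50, seed = 3), "unstable")
})

test_that("decoding accuracy is robust to the pattern size in the saturated regime", {
  ranges <- vapply(1:3, function(sd) {
    m <- generate_cortical_patch(n_columns = 84, voxels_per_column = 9,
                                 areas = "A3A", seed = sd)
    d <- tiny_design(runs = 4, seed = sd)
    sim <- simulate_bold(m, d, tiny_spec(seed = sd))
    ds <- highpass_and_detrend(sim$datasets[["A3A"]])
    glm1 <- fit_glm(ds, d)
    la <- assign_voxels(m, build_grids(m))
    mask <- vascular_exclusion(sim$datasets[["A3A"]], glm1)
    ds_m <- match_and_zscore(ds, la, mask)
    glm2 <- fit_glm(ds_m, d)
    bp <- block_responses(ds_m, d)
    accs <- vapply(c(90, 110, 130, 150), function(n) {
      sel <- select_voxels(glm2, ds_m$voxels, n = n)
      bpn <- filter_patterns(bp, voxel_ids = sel$voxel_id[sel$layer == "superficial"],
                             block_keep = bp$blocks$stereo == "correlated")
      crossval_decode(bpn)$accuracy
    }, numeric(1))
    diff(range(accs))
  }, numeric(1))
  expect_lt(mean(ranges), 0.05)
})

test_that("mean-pattern removal kills uniform offsets but not antisymmetric patterns", {
  bp <- synthetic_patterns(n_runs = 3, n_vox = 20, sep = 0, noise = 0.5, seed = 8)
  # classes differ only by a uniform offset across voxels
  s <- ifelse(bp$blocks$disparity == "near", 1, -1)
  bp_off <- bp
  bp_off$responses <- bp$responses + outer(s, rep(2, 20))
  expect_equal(crossval_decode(bp_off)$accuracy, 1)
  bp_reg <- regress_mean_pattern(bp_off)
  expect_lt(max(abs(rowMeans(bp_reg$responses))), 1e-12)
  expect_lt(crossval_decode(bp_reg)$accuracy, 0.7)
  # a zero-mean antisymmetric pattern survives mean removal
  set.seed(8)
  pat <- rnorm(20); pat <- pat - mean(pat)
  bp_pat <- bp
  bp_pat$responses <- bp$responses + outer(s, pat)
  acc_raw <- crossval_decode(bp_pat)$accuracy
  acc_reg <- crossval_decode(regress_mean_pattern(bp_pat))$accuracy
  expect_lt(abs(acc_raw - acc_reg), 0.05)
})
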