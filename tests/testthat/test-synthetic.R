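test_that("config validation rejects bad parameters and non-monotone couplings", {
  expect_error(synthetic_config(n_cells = 0), "n_cells")
  expect_error(synthetic_config(envelope_radius = -1))
  expect_error(synthetic_config(voxel_spacing = c(1, 0, 1)))
  expect_error(coupling_affine(slope = -1))
  expect_error(coupling_function(function(p) 1 - p), "non-decreasing")
  cpl <- coupling_function(function(p) 1 + p^2)
  expect_equal(coupling_eval(cpl, c(0, 1)), c(1, 2))
  expect_equal(coupling_eval(coupling_affine(1, 1.5), 0.4), 1.6)
})

test_that("infeasible packings fail with a message naming the constraint", {
  cfg <- synthetic_config(n_cells = 64, envelope_radius = 4, seed = 1)
  expect_error(generate_embryo(cfg), "infeasible packing")
})

test_that("a single spherical cell is fully exposed", {
  emb <- generate_embryo(synthetic_config(n_cells = 1, seed = 3))
  expect_equal(emb$ground_truth$p_exposed_true, 1.0)
  rec <- quantify_embryo(emb)
  expect_equal(rec$prop_exposed, 1.0)
  expect_true(is.na(rec$aj_ratio))
})

test_that("generation is deterministic: identical config gives identical volumes", {
  cfg <- synthetic_config(n_cells = 8, seed = 7)
  e1 <- generate_embryo(cfg)
  e2 <- generate_embryo(cfg)
  expect_identical(e1$cell_labels, e2$cell_labels)
  expect_identical(e1$nucleus_labels, e2$nucleus_labels)
  expect_identical(e1$channels$yap, e2$channels$yap)
  expect_identical(e1$ground_truth, e2$ground_truth)
  e3 <- generate_embryo(synthetic_config(n_cells = 8, seed = 8))
  expect_false(identical(e1$cell_labels, e3$cell_labels))
})

test_that("labels are sane: one nucleus per cell, strictly inside it", {
  emb <- generate_embryo(synthetic_config(n_cells = 8, seed = 5))
  lab <- emb$cell_labels
  nuc <- emb$nucleus_labels
  for (i in 1:8) {
    idx <- which(nuc == i)
    expect_gt(length(idx), 0)
    expect_true(all(lab[idx] == i)) # no nucleus voxel outside its cell
    expect_lt(length(idx), sum(lab == i)) # cytoplasm non-empty
  }
  expect_setequal(sort(unique(as.vector(nuc[nuc > 0]))), 1:8)
})

test_that("cohorts carry one embryo per replicate and pooled ground truth", {
  coh <- generate_cohort(c(2, 4), 1, synthetic_config(seed = 1))
  expect_length(coh$embryos, 2)
  expect_equal(nrow(coh$ground_truth), 6)
  coh3 <- generate_cohort(8, 3, synthetic_config(seed = 1))
  expect_equal(nrow(coh3$ground_truth), 24)
  geoms <- lapply(coh3$embryos, `[[`, "cell_labels")
  expect_false(identical(geoms[[1]], geoms[[2]]))
  expect_error(generate_cohort(integer(0)), "empty")
  expect_error(generate_cohort(c(3, 8)), "stages")
})

test_that("noiseless N/C ratios recover the coupling of the oracle exposure", {
  emb <- generate_embryo(synthetic_config(n_cells = 8, seed = 7, noise_sd = 0))
  masks <- compartment_masks(emb)
  nc <- nc_ratio(emb$channels$yap, masks)
  expected <- coupling_eval(emb$config$coupling,
                            emb$ground_truth$p_exposed_true)
  expect_true(all(abs(nc$nc_ratio / expected - 1) < 0.02))
})

test_that("null coupling decorrelates exposure and realised N/C ratio", {
  # slope 0: YAP no longer tracks position; with >= 64 pooled cells the
  # sample Spearman correlation should hover near zero in nearly all runs
  n_seeds <- 20
  hits <- 0
  for (s in seq_len(n_seeds)) {
    coh <- generate_cohort(16, 6, synthetic_config(
      coupling = coupling_affine(1.5, 0), noise_sd = 0.1, seed = 1000 + s))
    nc <- unlist(lapply(coh$embryos, function(e) {
      m <- compartment_masks(e, shells = FALSE)
      nc_ratio(e$channels$yap, m)$nc_ratio
    }))
    rho <- cor(coh$ground_truth$p_exposed_true, nc, method = "spearman")
    if (abs(rho) < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("cylindrical confinement lowers the median oracle exposed proportion", {
  # the median is the robust summary here: the two end cells pressed against
  # the envelope caps keep large exposed surfaces and distort the mean
  diffs <- vapply(1:10, function(s) {
    sph <- generate_embryo(synthetic_config(n_cells = 16, seed = 500 + s))
    cyl <- generate_embryo(synthetic_config(n_cells = 16,
                                            envelope = "cylinder",
                                            seed = 500 + s))
    median(cyl$ground_truth$p_exposed_true) -
      median(sph$ground_truth$p_exposed_true)
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gte(sum(diffs < 0), 8)
})

test_that("the pERM channel is enriched on the exposed shell by 1 + polarity * k", {
  cfg <- synthetic_config(n_cells = 8, seed = 9, noise_sd = 0,
                          perm_polarity = 0.8, apical_perm_gain = 4)
  emb <- generate_embryo(cfg)
  orc <- voxel_face_domains(emb$cell_labels, emb$voxel_spacing)
  shell_val <- emb$channels$perm[orc$exposed_vox]
  expect_true(all(abs(shell_val - 100 * (1 + 0.8 * 4)) < 1e-9))
  inner <- emb$channels$perm[emb$cell_labels > 0]
  expect_setequal(round(unique(inner)), c(100, 420))
})
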