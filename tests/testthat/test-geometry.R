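test_that("mesh area of digital balls matches the analytic sphere within 5%", {
  for (R in c(16, 20)) {
    emb <- as_embryo(ball_volume(R))
    s <- extract_surfaces(emb)
    expect_lt(abs(s[[1]]$area / (4 * pi * R^2) - 1), 0.05)
  }
  # anisotropic spacing (2, 1, 1) µm, same physical ball
  emb <- as_embryo(ball_volume(20, spacing = c(2, 1, 1)), spacing = c(2, 1, 1))
  s <- extract_surfaces(emb)
  expect_lt(abs(s[[1]]$area / (4 * pi * 400) - 1), 0.05)
})

test_that("a cube split into two cells recovers the box face arithmetic", {
  L <- 40
  lab <- array(0L, c(L + 10, L + 10, L + 10))
  lab[6:(L + 5), 6:(L + 5), 6:(5 + L / 2)] <- 1L
  lab[6:(L + 5), 6:(L + 5), (6 + L / 2):(L + 5)] <- 2L
  emb <- as_embryo(lab)
  s <- extract_surfaces(emb)
  analytic <- 2 * L^2 + 4 * L * (L / 2) # 5 outer half-faces + shared face
  expect_lt(abs(s[[1]]$area / analytic - 1), 0.05)
  expect_lt(abs(s[[2]]$area / analytic - 1), 0.05)
})

test_that("tiny cells are flagged and skipped with a warning", {
  lab <- ball_volume(10)
  lab[1, 1, 1] <- 2L # 1-voxel cell
  expect_warning(s <- extract_surfaces(as_embryo(lab)), "skipped")
  expect_null(s[[2]])
  expect_identical(attr(s, "skipped"), 2L)
})

test_that("an isolated cell is fully exposed with no junctional band", {
  emb <- as_embryo(ball_volume(12))
  dm <- classify_domains(extract_surfaces(emb), emb)
  pos <- position_descriptors(dm)
  expect_equal(pos$prop_exposed, 1.0)
  expect_equal(pos$contact_area, 0)
  expect_equal(pos$junctional_area, 0)
  expect_true(is.na(pos$aj_ratio))
})

test_that("two-ball contact area matches the spherical-cap oracle within 10%", {
  R <- 20; d <- 30
  lab <- ball_chain(R, c(0, d))
  emb <- as_embryo(lab)
  s <- extract_surfaces(emb)
  cap <- 2 * pi * R * (R - d / 2)
  pos <- position_descriptors(classify_domains(s, emb))
  expect_lt(abs(pos$contact_area[1] / cap - 1), 0.10)
  expect_lt(abs(pos$contact_area[2] / cap - 1), 0.10)
  # the junctional band girdles the cap rim: every junctional face centroid
  # sits near the rim circle (x = d/2 plane, radius rho)
  dm <- classify_domains(s, emb)
  rho <- sqrt(R^2 - (d / 2)^2)
  ctr <- c(R + 5, R + 5, R + 5) # centre of ball 1 (z, y, x), µm
  for (i in 1:2) {
    jc <- dm[[i]]$centroids[dm[[i]]$tags == "junctional", , drop = FALSE]
    expect_gt(nrow(jc), 0)
    rad <- sqrt((jc[, 1] - ctr[1])^2 + (jc[, 2] - ctr[2])^2)
    expect_lt(max(abs(jc[, 3] - (ctr[3] + d / 2))), 4)
    expect_lt(max(abs(rad - rho)), 5)
  }
})

test_that("w = 0 disables the junctional band and the partition is exact", {
  lab <- ball_chain(16, c(0, 24))
  emb <- as_embryo(lab)
  s <- extract_surfaces(emb)
  pos0 <- position_descriptors(classify_domains(s, emb, domain_params(1, 0)))
  expect_equal(pos0$junctional_area, c(0, 0))
  expect_equal(pos0$prop_exposed + pos0$prop_contact, c(1, 1))
  # area conservation is exact by construction (same face partition)
  pos <- position_descriptors(classify_domains(s, emb, domain_params(1, 1)))
  for (i in 1:2) {
    expect_equal(pos$exposed_area[i] + pos$junctional_area[i] +
                   pos$contact_area[i], s[[i]]$area)
    expect_lt(abs(pos$prop_exposed[i] + pos$prop_junctional[i] +
                    pos$prop_contact[i] - 1), 1e-9)
  }
})

test_that("two identical bisector-split balls have equal contact areas", {
  lab <- two_balls_bisector(20, 30)
  emb <- as_embryo(lab)
  pos <- position_descriptors(classify_domains(extract_surfaces(emb), emb))
  expect_lt(abs(pos$contact_area[1] / pos$contact_area[2] - 1), 0.02)
})

test_that("contact grows with delta and the band with w, monotonically", {
  # two balls whose surfaces are 3 µm apart (centres 27, radii 12)
  emb <- as_embryo(ball_chain(12, c(0, 27)))
  s <- extract_surfaces(emb)
  contact <- vapply(c(0.5, 2, 3.5, 5), function(d) {
    sum(position_descriptors(
      classify_domains(s, emb, domain_params(d, 0)))$contact_area)
  }, numeric(1))
  expect_true(all(diff(contact) >= 0))
  expect_equal(contact[1], 0) # gap wider than delta: no contact
  expect_gt(contact[4], 0)
  junc <- vapply(c(0.5, 1, 2, 3), function(w) {
    sum(position_descriptors(
      classify_domains(s, emb, domain_params(5, w)))$junctional_area)
  }, numeric(1))
  expect_true(all(diff(junc) >= 0))
})

test_that("mesh domain proportions track the voxel-face oracle", {
  # chain of four balls with distinct overlap depths: exposure levels are
  # separated by construction, so both scales must agree on the ranking
  lab <- ball_chain(14, c(0, 20, 20 + 16, 20 + 16 + 22))
  emb <- as_embryo(lab)
  pos <- position_descriptors(
    classify_domains(extract_surfaces(emb), emb, domain_params(1, 0)))
  orc <- voxel_face_domains(lab, c(1, 1, 1), 1.0)$table
  po <- orc$prop_exposed[pos$cell_id]
  expect_true(all(abs(pos$prop_exposed / po - 1) < 0.15))
  pc <- (orc$contact_area / orc$total_area)[pos$cell_id]
  expect_true(all(abs(pos$prop_contact / pc - 1) < 0.15))
  expect_identical(order(pos$prop_exposed), order(po))
})

test_that("shape descriptors recover sphere and ellipsoid archetypes", {
  emb <- as_embryo(ball_volume(15))
  s <- extract_surfaces(emb)
  sh <- shape_descriptors(emb, s)
  expect_true(sh$sphericity > 0.95 && sh$sphericity < 1.05)
  expect_lt(sh$oblateness, 0.05)
  expect_lt(sh$prolateness, 0.05)
  expect_equal(sh$volume, sum(emb$cell_labels == 1))

  prol <- as_embryo(ellipsoid_volume(20, 10, 10))
  shp <- shape_descriptors(prol, extract_surfaces(prol))
  expect_lt(abs(shp$prolateness - 0.5), 0.05)
  expect_lt(abs(shp$oblateness - 0), 0.05)

  obl <- as_embryo(ellipsoid_volume(20, 20, 10))
  sho <- shape_descriptors(obl, extract_surfaces(obl))
  expect_lt(abs(sho$oblateness - 0.5), 0.05)
  expect_lt(abs(sho$prolateness - 0), 0.05)
})

test_that("rank-deficient cells are flagged degenerate", {
  lab <- array(0L, c(9, 21, 21))
  lab[5, 3:19, 3:19] <- 1L # one-voxel-thick plate
  emb <- as_embryo(lab)
  s <- suppressWarnings(extract_surfaces(emb))
  sh <- shape_descriptors(emb, s)
  expect_true(sh$degenerate)
  # the flat plate is maximally oblate; the value is still emitted
  expect_equal(sh$oblateness, 1)
})

test_that("descriptors converge with voxel resolution on a smooth cell", {
  for (sp in list(c(1, 1, 1), c(0.5, 0.5, 0.5))) {
    emb <- as_embryo(ball_volume(10, spacing = sp), spacing = sp)
    s <- extract_surfaces(emb)
    sh <- shape_descriptors(emb, s)
    assign(paste0("a", sp[1] * 10), c(sh$volume, sh$total_area,
                                      sh$sphericity))
  }
  expect_true(all(abs(a5 / a10 - 1) < 0.05))
})

test_that("a domed apical cap yields a larger A/J ratio than a flat one", {
  aj <- vapply(c(TRUE, FALSE), function(domed) {
    emb <- as_embryo(capped_cell(rho = 12, h = 4, domed = domed))
    pos <- position_descriptors(classify_domains(extract_surfaces(emb), emb))
    pos$aj_ratio[pos$cell_id == 2]
  }, numeric(1))
  expect_gt(aj[1], aj[2])
})

test_that("records drop dividing cells and join annotations", {
  emb <- generate_embryo(synthetic_config(n_cells = 8, seed = 2))
  ann <- data.frame(embryo_id = emb$embryo_id, cell_id = c(3L, 5L),
                    dividing = c(TRUE, FALSE),
                    manual_label = c("none", "TE"))
  expect_message(recs <- build_records(emb, ann), "1 dividing")
  expect_equal(nrow(recs), 7)
  expect_false(3L %in% recs$cell_id)
  expect_equal(recs$manual_label[recs$cell_id == 5], "TE")
  # no annotations: defaults
  recs0 <- build_records(emb)
  expect_equal(nrow(recs0), 8)
  expect_true(all(recs0$manual_label == "none"))
  # unknown cells rejected with offenders listed
  bad <- data.frame(embryo_id = "nope", cell_id = 1L, dividing = FALSE)
  expect_error(build_records(emb, bad), "unknown cells: nope 1")
})
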