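#' Affine exposure-to-YAP coupling
#'
#' The generator links each cell's true exposed-surface proportion `p` to its
#' expected nuclear-to-cytoplasmic YAP ratio through a non-decreasing coupling
#' function. The default is affine, `r(p) = intercept + slope * p`; with the
#' defaults a fully exposed cell expects an N/C ratio of 2.5 and a fully
#' internal cell 1.0, placing the high/low boundary of real embryos (~1.6)
#' at `p ~ 0.4`.
#'
#' @param intercept expected N/C ratio of a fully internal cell (`p = 0`).
#' @param slope increase in expected N/C ratio per unit of exposed proportion;
#'   must be `>= 0` (monotone coupling). `slope = 0` decouples YAP from
#'   position and emulates a null model.
#' @return an object of class `yap_coupling`.
#' @export
coupling_affine <- function(intercept = 1.0, slope = 1.5) {
  stopifnot(is.numeric(intercept), is.numeric(slope), slope >= 0)
  structure(list(type = "affine", intercept = intercept, slope = slope),
            class = "yap_coupling")
}

#' Arbitrary monotone coupling from an R function
#'
#' @param fun function mapping exposed proportion in \[0,1\] to an expected
#'   N/C ratio; checked for monotonicity on a grid.
#' @return an object of class `yap_coupling`.
#' @export
coupling_function <- function(fun) {
  stopifnot(is.function(fun))
  p <- seq(0, 1, by = 0.02)
  v <- vapply(p, fun, numeric(1))
  if (any(diff(v) < -1e-9)) {
    stop("coupling function must be non-decreasing on [0, 1]")
  }
  structure(list(type = "function", fun = fun), class = "yap_coupling")
}

#' Evaluate a coupling at exposed proportions
#' @param coupling a `yap_coupling`.
#' @param p numeric vector of exposed proportions.
#' @return numeric vector of expected N/C ratios.
#' @export
coupling_eval <- function(coupling, p) {
  stopifnot(inherits(coupling, "yap_coupling"))
  if (coupling$type == "affine") {
    coupling$intercept + coupling$slope * p
  } else {
    vapply(p, coupling$fun, numeric(1))
  }
}

#' Synthetic embryo configuration
#'
#' Parameters of the synthetic preimplantation-embryo generator. Cells are
#' envelope-clipped Voronoi regions of Lloyd-relaxed seed points on the voxel
#' grid; the total embryo volume is that of a sphere of radius
#' `envelope_radius` for every envelope shape, so confinement redistributes
#' rather than changes volume.
#'
#' @param n_cells number of blastomeres (1-64).
#' @param envelope embryo envelope: free spherical embryo, 25 µm microchannel
#'   (`"cylinder"`), or planar compression under a hydrogel sheet (`"slab"`).
#' @param envelope_radius equivalent-sphere embryo radius in µm; fixes total
#'   embryo volume for all envelopes. Default 20 µm (a compact idealised
#'   cleavage-stage embryo).
#' @param channel_radius cylinder envelope radius in µm; default 12.5 µm,
#'   emulating 25 µm diameter channels. The cylinder length is set by volume
#'   conservation.
#' @param slab_fraction slab thickness as a fraction of the sphere diameter
#'   (default 0.8, i.e. mild flattening); lateral extent set by volume
#'   conservation.
#' @param compaction real in \[0,1\]: 0 = loosely apposed cells separated by
#'   gaps of 15% of a cell radius, 1 = fully packed partition with no gaps.
#' @param nucleus_radius_fraction nucleus radius as a fraction of the cell's
#'   equivalent-sphere radius, in (0, 0.9).
#' @param coupling a [coupling_affine()] / [coupling_function()] object
#'   mapping true exposed proportion to expected N/C YAP ratio.
#' @param noise_sd sd of the per-voxel multiplicative log-normal intensity
#'   noise (mean-one, so compartment means are unbiased); 0 disables noise.
#' @param perm_polarity real in \[0,1\]: apical pERM enrichment; 0 emulates
#'   loss of apical pERM under ROCK inhibition.
#' @param apical_perm_gain constant `k` of the pERM intensity model: the
#'   exposed-membrane shell carries `1 + perm_polarity * k` times the
#'   baseline membrane intensity. Default 4.
#' @param voxel_spacing voxel spacing `(z, y, x)` in µm.
#' @param seed integer seed; the single source of randomness.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 8L,
                             envelope = c("sphere", "cylinder", "slab"),
                             envelope_radius = 20,
                             channel_radius = 12.5,
                             slab_fraction = 0.8,
                             compaction = 1,
                             nucleus_radius_fraction = 0.4,
                             coupling = coupling_affine(),
                             noise_sd = 0.05,
                             perm_polarity = 0.8,
                             apical_perm_gain = 4,
                             voxel_spacing = c(1, 1, 1),
                             seed = 1L) {
  envelope <- match.arg(envelope)
  n_cells <- as.integer(n_cells)
  stopifnot(length(n_cells) == 1L, n_cells >= 1L, n_cells <= 64L,
            envelope_radius > 0, channel_radius > 0,
            slab_fraction > 0, slab_fraction <= 1,
            compaction >= 0, compaction <= 1,
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 0.9,
            inherits(coupling, "yap_coupling"),
            noise_sd >= 0,
            perm_polarity >= 0, perm_polarity <= 1,
            apical_perm_gain >= 0,
            length(voxel_spacing) == 3L, all(voxel_spacing > 0),
            length(seed) == 1L, is.finite(seed))
  structure(list(n_cells = n_cells, envelope = envelope,
                 envelope_radius = envelope_radius,
                 channel_radius = channel_radius,
                 slab_fraction = slab_fraction,
                 compaction = compaction,
                 nucleus_radius_fraction = nucleus_radius_fraction,
                 coupling = coupling, noise_sd = noise_sd,
                 perm_polarity = perm_polarity,
                 apical_perm_gain = apical_perm_gain,
                 voxel_spacing = as.numeric(voxel_spacing),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Envelope half-extents (z, y, x) in µm for a config.
envelope_half_extents <- function(config) {
  R <- config$envelope_radius
  Vtot <- 4 / 3 * pi * R^3
  switch(config$envelope,
    sphere = c(R, R, R),
    cylinder = {
      rc <- config$channel_radius
      L <- Vtot / (pi * rc^2)
      c(rc, rc, L / 2)
    },
    slab = {
      h <- config$slab_fraction * 2 * R
      rl <- sqrt(Vtot / (pi * h))
      c(h / 2, rl, rl)
    })
}

# Build the envelope voxel mask and per-axis physical coordinates.
envelope_mask <- function(config) {
  sp <- config$voxel_spacing
  half <- envelope_half_extents(config)
  n <- 2L * as.integer(ceiling(half / sp)) + 5L # odd; 2-voxel background rim
  ax <- lapply(1:3, function(d) (seq_len(n[d]) - (n[d] + 1) / 2) * sp[d])
  Z <- array(ax[[1]], n)
  Y <- array(rep(ax[[2]], each = n[1]), n)
  X <- array(rep(ax[[3]], each = n[1] * n[2]), n)
  R <- config$envelope_radius
  mask <- switch(config$envelope,
    sphere = (Z^2 + Y^2 + X^2) <= R^2,
    cylinder = (Z^2 + Y^2) <= config$channel_radius^2 & abs(X) <= half[3],
    slab = abs(Z) <= half[1] & (Y^2 + X^2) <= half[2]^2)
  list(mask = mask, dims = n, coords = cbind(z = as.vector(Z)[mask],
                                             y = as.vector(Y)[mask],
                                             x = as.vector(X)[mask]))
}

# Squared distances from every envelope voxel to each seed (n_vox x n_seeds).
seed_dist2 <- function(coords, seeds) {
  n <- nrow(seeds)
  D <- matrix(0, nrow(coords), n)
  for (s in seq_len(n)) {
    D[, s] <- (coords[, 1] - seeds[s, 1])^2 +
      (coords[, 2] - seeds[s, 2])^2 +
      (coords[, 3] - seeds[s, 3])^2
  }
  D
}

#' Generate a synthetic labelled embryo
#'
#' Generates co-registered cell-label, nucleus-label and intensity volumes
#' with per-cell ground truth. Cells are the envelope-clipped Voronoi regions
#' of `n_cells` Lloyd-relaxed seed points; `compaction` opens inter-cell gaps
#' (half-width `0.15 * r_cell * (1 - compaction)`). Each cell receives a
#' spherical nucleus clipped to the cell. The YAP channel has cytoplasm level
#' 100 and nucleus level `100 * coupling(p_true)` where `p_true` is the
#' voxel-face-oracle exposed proportion; the pERM channel has membrane-shell
#' level `100 * (1 + perm_polarity * apical_perm_gain)` on the exposed shell
#' (1 µm thick) and 100 elsewhere in the cell. Multiplicative mean-one
#' log-normal noise is applied per voxel.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `labelled_embryo`: a list with `cell_labels`,
#'   `nucleus_labels`, `channels` (named list `yap`, `perm`),
#'   `voxel_spacing`, `embryo_id`, `ground_truth` (one row per cell: seed
#'   position, true exposed proportion, expected N/C and A/B ratios, stage)
#'   and the echoed `config`.
#' @export
generate_embryo <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_embryo_impl(config))
}

generate_embryo_impl <- function(config) {
  sp <- config$voxel_spacing
  env <- envelope_mask(config)
  dims <- env$dims
  coords <- env$coords
  n <- config$n_cells
  vox_vol <- prod(sp)

  if (nrow(coords) < 8 * n) {
    stop(sprintf(paste0("infeasible packing: envelope holds %d voxels but ",
                        "%d cells need at least %d (8 voxels/cell) at ",
                        "spacing (%s) um"),
                 nrow(coords), n, 8L * n, paste(sp, collapse = ",")))
  }

  env_idx <- which(env$mask)
  # Lloyd relaxation of uniformly sampled seeds
  seeds <- coords[sample.int(nrow(coords), n), , drop = FALSE]
  seeds <- matrix(seeds, ncol = 3)
  for (it in 1:10) {
    D <- seed_dist2(coords, seeds)
    assign <- max.col(-D, ties.method = "first")
    for (s in seq_len(n)) {
      sel <- assign == s
      if (!any(sel)) {
        seeds[s, ] <- coords[sample.int(nrow(coords), 1L), ]
      } else {
        seeds[s, ] <- colMeans(coords[sel, , drop = FALSE])
      }
    }
  }
  D <- seed_dist2(coords, seeds)
  assign <- max.col(-D, ties.method = "first")

  # compaction: carve gaps around Voronoi boundaries
  r_cell <- (3 * (4 / 3 * pi * config$envelope_radius^3) / n / (4 * pi))^(1 / 3)
  gap_half <- 0.15 * r_cell * (1 - config$compaction)
  if (n > 1L && gap_half > 0) {
    d1 <- sqrt(D[cbind(seq_len(nrow(D)), assign)])
    D[cbind(seq_len(nrow(D)), assign)] <- Inf
    d2 <- sqrt(do.call(pmin, as.data.frame(D)))
    keep <- (d2 - d1) >= 2 * gap_half
  } else {
    keep <- rep(TRUE, nrow(coords))
  }

  labels <- array(0L, dims)
  labels[env_idx[keep]] <- assign[keep]
  counts <- tabulate(labels, nbins = n)
  if (any(counts < 8L)) {
    stop(sprintf(paste0("infeasible packing: cell(s) %s received fewer than ",
                        "8 voxels; reduce n_cells or enlarge the envelope"),
                 paste(which(counts < 8L), collapse = ", ")))
  }

  # nuclei: sphere around the cell centroid, clipped to the cell
  nuclei <- array(0L, dims)
  for (i in seq_len(n)) {
    idx <- which(labels == i)
    pc <- voxel_coords(idx, dims, sp)
    ctr <- colMeans(pc)
    r_eq <- (3 * length(idx) * vox_vol / (4 * pi))^(1 / 3)
    rn <- config$nucleus_radius_fraction * r_eq
    d <- sqrt((pc[, 1] - ctr[1])^2 + (pc[, 2] - ctr[2])^2 +
                (pc[, 3] - ctr[3])^2)
    sel <- d <= rn
    if (!any(sel)) sel <- d == min(d)
    if (all(sel)) sel <- rank(d, ties.method = "first") <= 0.5 * length(idx)
    nuclei[idx[sel]] <- i
  }

  # ground truth from the voxel-face oracle
  oracle <- voxel_face_domains(labels, sp, delta = 1.0)
  p_true <- oracle$table$prop_exposed

  cpl <- coupling_eval(config$coupling, p_true)

  yap <- array(0, dims)
  perm <- array(0, dims)
  cell_vox <- labels > 0L
  yap[cell_vox] <- 100
  for (i in seq_len(n)) yap[nuclei == i] <- 100 * cpl[i]
  perm[cell_vox] <- 100
  if (length(oracle$exposed_vox)) {
    shell_mask <- array(FALSE, dims)
    shell_mask[oracle$exposed_vox] <- TRUE
    dsh <- edt3d(shell_mask, sp)
    perm[cell_vox & dsh <= 1.0] <-
      100 * (1 + config$perm_polarity * config$apical_perm_gain)
  }
  if (config$noise_sd > 0) {
    s <- config$noise_sd
    yap <- yap * exp(rnorm(length(yap), 0, s) - s^2 / 2)
    perm <- perm * exp(rnorm(length(perm), 0, s) - s^2 / 2)
  }

  embryo_id <- sprintf("sim-%s-n%02d-seed%d", config$envelope, n, config$seed)
  gt <- data.frame(
    embryo_id = embryo_id,
    cell_id = seq_len(n),
    seed_z = seeds[, 1], seed_y = seeds[, 2], seed_x = seeds[, 3],
    p_exposed_true = p_true,
    nc_true = cpl,
    ab_true = ifelse(oracle$table$exposed_area > 0,
                     1 + config$perm_polarity * config$apical_perm_gain, NA_real_),
    stage = n,
    stringsAsFactors = FALSE)

  structure(list(cell_labels = labels, nucleus_labels = nuclei,
                 channels = list(yap = yap, perm = perm),
                 voxel_spacing = sp, embryo_id = embryo_id,
                 ground_truth = gt, config = config),
            class = "labelled_embryo")
}

#' @export
print.labelled_embryo <- function(x, ...) {
  cat(sprintf("<labelled_embryo> %s: %d cells, %s voxels, spacing (%s) um\n",
              x$embryo_id, max(x$cell_labels),
              paste(dim(x$cell_labels), collapse = "x"),
              paste(x$voxel_spacing, collapse = ",")))
  invisible(x)
}

#' Generate a cohort of synthetic embryos across stages
#'
#' @param stages integer vector drawn from \{2, 4, 8, 16, 32, 64\}.
#' @param per_stage_n number of embryos per stage (scalar or one per stage).
#' @param config template [synthetic_config()]; `n_cells` and `seed` are
#'   overridden per embryo (seed `= config$seed + 97 * embryo_index`).
#' @return list with `embryos` (list of `labelled_embryo`) and
#'   `ground_truth` (pooled table with `embryo_id` and `stage`).
#' @export
generate_cohort <- function(stages, per_stage_n = 1L,
                            config = synthetic_config()) {
  stages <- as.integer(stages)
  if (length(stages) == 0L) stop("empty stage list")
  if (!all(stages %in% c(2L, 4L, 8L, 16L, 32L, 64L))) {
    stop("stages must be drawn from {2, 4, 8, 16, 32, 64}")
  }
  per_stage_n <- as.integer(per_stage_n)
  if (length(per_stage_n) == 1L) per_stage_n <- rep(per_stage_n, length(stages))
  stopifnot(length(per_stage_n) == length(stages), all(per_stage_n >= 1L))

  embryos <- list()
  e <- 0L
  for (si in seq_along(stages)) {
    for (rep_i in seq_len(per_stage_n[si])) {
      e <- e + 1L
      cfg <- config
      cfg$n_cells <- stages[si]
      cfg$seed <- config$seed + 97L * e
      emb <- generate_embryo(cfg)
      emb$embryo_id <- sprintf("%s-rep%d", emb$embryo_id, rep_i)
      emb$ground_truth$embryo_id <- emb$embryo_id
      embryos[[e]] <- emb
    }
  }
  gt <- do.call(rbind, lapply(embryos, function(e) e$ground_truth))
  rownames(gt) <- NULL
  list(embryos = embryos, ground_truth = gt)
}
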