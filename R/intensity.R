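#' Per-cell compartment masks
#'
#' Builds the voxel sets intensity ratios are measured over: nucleus,
#' cytoplasm (cell minus nucleus, membrane shells included), apical shell
#' (cell voxels within `shell` µm of the cell's exposed boundary) and
#' basolateral shell (within `shell` µm of its contact boundary). Boundary
#' voxels are classified exposed/contact by the same surface-proximity rule
#' as the mesh classifier: a boundary voxel is contact when the nearest
#' voxel of a different cell lies within `delta` plus one voxel step.
#'
#' @param embryo a `labelled_embryo`.
#' @param shell shell thickness t in µm (default 1, one z-step).
#' @param delta contact gap threshold in µm (default 1).
#' @param shells compute the apical/basolateral membrane shells (default
#'   TRUE); set FALSE when only nuclear/cytoplasmic ratios are needed.
#' @return object of class `compartment_masks`: list keyed by cell id with
#'   linear-index vectors `nucleus`, `cytoplasm`, `apical`, `basolateral`;
#'   attribute `shell`.
#' @export
compartment_masks <- function(embryo, shell = 1.0, delta = 1.0,
                              shells = TRUE) {
  labels <- embryo$cell_labels
  nuclei <- embryo$nucleus_labels
  sp <- embryo$voxel_spacing
  dims <- dim(labels)
  K <- max(labels)
  step <- max(sp)

  out <- vector("list", K)
  for (i in seq_len(K)) {
    cell_idx <- which(labels == i)
    if (length(cell_idx) == 0L) next
    nuc_idx <- which(nuclei == i)
    cyt_idx <- setdiff(cell_idx, nuc_idx)

    if (!shells) {
      out[[i]] <- list(cell_id = i, nucleus = nuc_idx, cytoplasm = cyt_idx,
                       apical = integer(0), basolateral = integer(0))
      next
    }

    # work on the cell bounding box plus a margin covering every distance
    # the masks compare against (contact gap + shell thickness)
    ai <- arrayInd(cell_idx, dims)
    margin <- as.integer(ceiling((delta + shell) / sp)) + 2L
    lo <- pmax(apply(ai, 2, min) - margin, 1L)
    hi <- pmin(apply(ai, 2, max) + margin, dims)
    sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sdims <- dim(sub)
    cell_mask <- sub == i
    cidx <- which(cell_mask)
    # boundary voxels: any 6-neighbour outside the cell
    boundary <- cell_mask & !(shift3(cell_mask, 1, 1, FALSE) &
                                shift3(cell_mask, -1, 1, FALSE) &
                                shift3(cell_mask, 1, 2, FALSE) &
                                shift3(cell_mask, -1, 2, FALSE) &
                                shift3(cell_mask, 1, 3, FALSE) &
                                shift3(cell_mask, -1, 3, FALSE))
    bidx <- which(boundary)
    other <- sub > 0L & sub != i
    if (any(other)) {
      D <- edt3d(other, sp)
      is_contact <- D[bidx] <= delta + step
    } else {
      is_contact <- rep(FALSE, length(bidx))
    }
    # map sub-volume linear indices back to full-volume indices
    to_full <- function(idx) {
      a <- arrayInd(idx, sdims)
      (a[, 1] + lo[1] - 1L) +
        dims[1] * ((a[, 2] + lo[2] - 2L) +
                     dims[2] * (a[, 3] + lo[3] - 2L))
    }
    apical <- integer(0)
    basolateral <- integer(0)
    if (any(!is_contact)) {
      m <- array(FALSE, sdims); m[bidx[!is_contact]] <- TRUE
      apical <- to_full(cidx[edt3d(m, sp)[cidx] <= shell])
    }
    if (any(is_contact)) {
      m <- array(FALSE, sdims); m[bidx[is_contact]] <- TRUE
      basolateral <- to_full(cidx[edt3d(m, sp)[cidx] <= shell])
    }
    out[[i]] <- list(cell_id = i, nucleus = nuc_idx, cytoplasm = cyt_idx,
                     apical = apical, basolateral = basolateral)
  }
  structure(out, class = "compartment_masks", shell = shell, delta = delta)
}

#' Nuclear-to-cytoplasmic intensity ratio per cell
#'
#' Mean intensity over nucleus voxels divided by mean intensity over
#' cytoplasm voxels. Scale-free: multiplying the channel by any positive
#' constant leaves the ratio unchanged. Cells with an empty nucleus or
#' cytoplasm get `NA` and a QC flag.
#'
#' @param channel 3D intensity array co-registered with the labels.
#' @param masks a [compartment_masks()] object.
#' @return data.frame `cell_id`, `nc_ratio`, `flag`.
#' @export
nc_ratio <- function(channel, masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  rows <- lapply(masks, function(m) {
    if (is.null(m)) return(NULL)
    if (length(m$nucleus) == 0L || length(m$cytoplasm) == 0L) {
      return(data.frame(cell_id = m$cell_id, nc_ratio = NA_real_,
                        flag = "empty_compartment"))
    }
    data.frame(cell_id = m$cell_id,
               nc_ratio = mean(channel[m$nucleus]) / mean(channel[m$cytoplasm]),
               flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apical-to-basolateral membrane intensity ratio per cell
#'
#' Mean intensity over the apical (exposed-membrane) shell divided by mean
#' intensity over the basolateral (contact-membrane) shell. Cells without an
#' exposed surface (fully internal) or without contact surface get `NA` and
#' a QC flag.
#'
#' @inheritParams nc_ratio
#' @return data.frame `cell_id`, `ab_ratio`, `flag`.
#' @export
ab_ratio <- function(channel, masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  rows <- lapply(masks, function(m) {
    if (is.null(m)) return(NULL)
    if (length(m$apical) == 0L) {
      return(data.frame(cell_id = m$cell_id, ab_ratio = NA_real_,
                        flag = "no_exposed_surface"))
    }
    if (length(m$basolateral) == 0L) {
      return(data.frame(cell_id = m$cell_id, ab_ratio = NA_real_,
                        flag = "no_contact_surface"))
    }
    data.frame(cell_id = m$cell_id,
               ab_ratio = mean(channel[m$apical]) / mean(channel[m$basolateral]),
               flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
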