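#' Voxel-face surface-domain oracle
#'
#' Brute-force 6-connectivity classification of every exposed boundary face
#' of a label volume. A boundary face of cell `i` is *contact* when marching
#' outward along its normal meets a voxel of a different cell within a
#' surface-to-surface gap of at most `delta` µm; otherwise it is *exposed*.
#' Face areas are the products of the two in-plane voxel spacings, so the
#' per-cell areas are exact voxel-face areas (which overestimate smooth
#' surfaces); this function is intended as the independent ground-truth
#' oracle for the mesh-based classifier and as the generator's source of
#' true exposed proportions.
#'
#' @param labels integer 3D array of cell labels (0 = background).
#' @param spacing voxel spacing `(z, y, x)` in µm.
#' @param delta maximum surface-to-surface gap (µm) still counted as contact.
#' @return list with `table` (per-cell `cell_id`, `exposed_area`,
#'   `contact_area`, `total_area`, `prop_exposed`), and linear voxel indices
#'   `exposed_vox` / `contact_vox` of boundary voxels owning at least one
#'   face of that class.
#' @export
voxel_face_domains <- function(labels, spacing = c(1, 1, 1), delta = 1.0) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            length(spacing) == 3L, all(spacing > 0), delta >= 0)
  K <- max(labels)
  if (K < 1L) stop("label volume is empty")
  dims <- dim(labels)
  exposed_area <- numeric(K)
  contact_area <- numeric(K)
  exposed_mask <- array(FALSE, dims)
  contact_mask <- array(FALSE, dims)

  for (axis in 1:3) {
    fa <- prod(spacing[-axis])
    tmax <- floor(delta / spacing[axis]) + 1
    for (sign in c(1L, -1L)) {
      nb1 <- shift3(labels, -sign, axis, fill = 0L)
      face <- labels > 0L & nb1 != labels
      if (!any(face)) next
      undecided <- face
      is_contact <- array(FALSE, dims)
      for (t in seq_len(tmax)) {
        if (!any(undecided)) break
        nbt <- if (t == 1L) nb1 else shift3(labels, -sign * t, axis, fill = 0L)
        hit_other <- undecided & nbt > 0L & nbt != labels
        hit_self <- undecided & nbt == labels & labels > 0L
        is_contact <- is_contact | hit_other
        undecided <- undecided & !hit_other & !hit_self
      }
      is_exposed <- face & !is_contact
      contact_area <- contact_area +
        fa * tabulate(labels[is_contact], nbins = K)
      exposed_area <- exposed_area +
        fa * tabulate(labels[is_exposed], nbins = K)
      exposed_mask <- exposed_mask | is_exposed
      contact_mask <- contact_mask | is_contact
    }
  }

  total <- exposed_area + contact_area
  tab <- data.frame(cell_id = seq_len(K),
                    exposed_area = exposed_area,
                    contact_area = contact_area,
                    total_area = total,
                    prop_exposed = ifelse(total > 0, exposed_area / total, NA_real_))
  list(table = tab,
       exposed_vox = which(exposed_mask),
       contact_vox = which(contact_mask))
}
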