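`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact anisotropic Euclidean distance transform
#'
#' Distance (in physical units) from every voxel centre to the nearest
#' `TRUE` voxel centre of `mask`. Exact separable transform; anisotropic
#' voxel spacing is honoured.
#'
#' @param mask logical 3D array.
#' @param spacing numeric length-3 voxel spacing `(z, y, x)` in µm.
#' @return numeric array of distances, same dimensions as `mask`; `Inf`
#'   when `mask` is all-`FALSE`.
#' @export
edt3d <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  storage.mode(mask) <- "logical"
  edt3d_cpp(mask, as.numeric(spacing))
}

# Trilinear interpolation of a 3D array at physical points (n x 3, dim-order
# coordinates in µm under voxel-centre convention). Points are clamped to the
# array extent.
trilinear_sample <- function(vol, pts, spacing) {
  d <- dim(vol)
  # continuous 0-based voxel coordinates
  u <- sweep(pts, 2, spacing, "/")
  out <- numeric(nrow(pts))
  u1 <- pmin(pmax(u[, 1], 0), d[1] - 1)
  u2 <- pmin(pmax(u[, 2], 0), d[2] - 1)
  u3 <- pmin(pmax(u[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(u1), d[1] - 2); i0[d[1] < 2] <- 0
  j0 <- pmin(floor(u2), d[2] - 2)
  k0 <- pmin(floor(u3), d[3] - 2)
  f1 <- u1 - i0; f2 <- u2 - j0; f3 <- u3 - k0
  at <- function(di, dj, dk) {
    vol[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  out <- at(0, 0, 0) * (1 - f1) * (1 - f2) * (1 - f3) +
    at(1, 0, 0) * f1 * (1 - f2) * (1 - f3) +
    at(0, 1, 0) * (1 - f1) * f2 * (1 - f3) +
    at(1, 1, 0) * f1 * f2 * (1 - f3) +
    at(0, 0, 1) * (1 - f1) * (1 - f2) * f3 +
    at(1, 0, 1) * f1 * (1 - f2) * f3 +
    at(0, 1, 1) * (1 - f1) * f2 * f3 +
    at(1, 1, 1) * f1 * f2 * f3
  out
}

# Shift a 3D array by s voxels along one axis, filling with `fill`.
shift3 <- function(a, s, axis, fill = 0) {
  d <- dim(a)
  if (s == 0) return(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  it <- lapply(d, seq_len)
  is <- it
  if (s > 0) {
    it[[axis]] <- (1 + s):n
    is[[axis]] <- 1:(n - s)
  } else {
    it[[axis]] <- 1:(n + s)
    is[[axis]] <- (1 - s):n
  }
  out[it[[1]], it[[2]], it[[3]]] <- a[is[[1]], is[[2]], is[[3]]]
  out
}

# Separable Gaussian blur with zero-fill boundary (background is 0 by
# convention). sigma is per-axis in voxels.
gaussian_blur3 <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(a))
    for (m in seq_along(k)) {
      acc <- acc + k[m] * shift3(a, m - 1L - r, axis)
    }
    a <- acc
  }
  a
}

# Triangle areas and centroids for an ntri x 9 triangle-soup matrix.
tri_geometry <- function(tris) {
  if (nrow(tris) == 0) {
    return(list(areas = numeric(0), centroids = matrix(0, 0, 3)))
  }
  e1 <- tris[, 4:6, drop = FALSE] - tris[, 1:3, drop = FALSE]
  e2 <- tris[, 7:9, drop = FALSE] - tris[, 1:3, drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  centroids <- (tris[, 1:3, drop = FALSE] + tris[, 4:6, drop = FALSE] +
                  tris[, 7:9, drop = FALSE]) / 3
  list(areas = areas, centroids = centroids)
}

# Physical voxel-centre coordinates (n x 3) for linear indices into a volume.
voxel_coords <- function(idx, dims, spacing) {
  aidx <- arrayInd(idx, dims)
  sweep(aidx - 1, 2, spacing, "*")
}
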