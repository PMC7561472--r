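# Digital phantoms with known analytic geometry, built in code at test time.

# Minimal embryo-like wrapper around a label volume.
as_embryo <- function(labels, spacing = c(1, 1, 1), nuclei = NULL,
                      channels = NULL, id = "phantom") {
  structure(list(cell_labels = labels,
                 nucleus_labels = nuclei %||% array(0L, dim(labels)),
                 channels = channels, voxel_spacing = spacing,
                 embryo_id = id),
            class = "labelled_embryo")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solid digital ball of radius R (µm) at given spacing, label 1.
ball_volume <- function(R, spacing = c(1, 1, 1), pad = 5) {
  n <- 2 * ceiling(R / spacing) + 2 * pad + 1
  ax <- lapply(1:3, function(d) (seq_len(n[d]) - (n[d] + 1) / 2) * spacing[d])
  Z <- array(ax[[1]], n)
  Y <- array(rep(ax[[2]], each = n[1]), n)
  X <- array(rep(ax[[3]], each = n[1] * n[2]), n)
  lab <- array(0L, n)
  lab[Z^2 + Y^2 + X^2 <= R^2] <- 1L
  lab
}

# Solid axis-aligned ellipsoid with semi-axes (a, b, c) µm along (x, y, z).
ellipsoid_volume <- function(a, b, c_, pad = 5) {
  n <- c(2 * c_ + 2 * pad + 1, 2 * b + 2 * pad + 1, 2 * a + 2 * pad + 1)
  Z <- array(seq_len(n[1]) - (n[1] + 1) / 2, n)
  Y <- array(rep(seq_len(n[2]) - (n[2] + 1) / 2, each = n[1]), n)
  X <- array(rep(seq_len(n[3]) - (n[3] + 1) / 2, each = n[1] * n[2]), n)
  lab <- array(0L, n)
  lab[(X / a)^2 + (Y / b)^2 + (Z / c_)^2 <= 1] <- 1L
  lab
}

# Chain of overlapping balls along x; later balls overwrite the lens, so each
# shared interface is the spherical cap of the later ball (area 2*pi*R*h).
ball_chain <- function(R, xcenters, pad = 5, gap_y = 0) {
  xr <- range(xcenters)
  nz <- 2 * R + 2 * pad + 1
  ny <- nz + abs(gap_y)
  nx <- diff(xr) + 2 * R + 2 * pad + 1
  lab <- array(0L, c(nz, ny, nx))
  Z <- array(seq_len(nz) - 1, dim(lab))
  Y <- array(rep(seq_len(ny) - 1, each = nz), dim(lab))
  X <- array(rep(seq_len(nx) - 1, each = nz * ny), dim(lab))
  cz <- R + pad
  cy <- R + pad
  for (i in seq_along(xcenters)) {
    cx <- xcenters[i] - xr[1] + R + pad
    lab[(Z - cz)^2 + (Y - cy)^2 + (X - cx)^2 <= R^2] <- i
  }
  lab
}

# Two identical balls labelled by the bisector plane (mirror-symmetric split
# of the overlap lens).
two_balls_bisector <- function(R, d, pad = 5) {
  nz <- 2 * R + 2 * pad + 1
  ny <- nz
  nx <- d + 2 * R + 2 * pad + 1
  lab <- array(0L, c(nz, ny, nx))
  Z <- array(seq_len(nz) - 1, dim(lab))
  Y <- array(rep(seq_len(ny) - 1, each = nz), dim(lab))
  X <- array(rep(seq_len(nx) - 1, each = nz * ny), dim(lab))
  cz <- R + pad; cy <- R + pad
  cx1 <- R + pad; cx2 <- cx1 + d
  inA <- (Z - cz)^2 + (Y - cy)^2 + (X - cx1)^2 <= R^2
  inB <- (Z - cz)^2 + (Y - cy)^2 + (X - cx2)^2 <= R^2
  mid <- (cx1 + cx2) / 2
  lab[inA & (!inB | X < mid)] <- 1L
  lab[inB & (!inA | X >= mid)] <- 2L
  lab
}

# Domed vs flat apical cap on a common basal slab (cell 1 = slab, cell 2 =
# the apical cell). `domed` gives a hemisphere of radius rho; flat gives a
# squat cylinder of the same base radius and height h.
capped_cell <- function(rho = 12, h = 4, domed = TRUE, pad = 5) {
  nz <- rho + 8 + 2 * pad
  ny <- 2 * rho + 2 * pad + 1
  nx <- ny
  lab <- array(0L, c(nz, ny, nx))
  Z <- array(seq_len(nz) - 1, dim(lab))
  Y <- array(rep(seq_len(ny) - 1, each = nz), dim(lab))
  X <- array(rep(seq_len(nx) - 1, each = nz * ny), dim(lab))
  z0 <- pad + 4 # top of the slab
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  lab[Z <= z0] <- 1L
  r2 <- (Y - cy)^2 + (X - cx)^2
  if (domed) {
    lab[Z > z0 & (Z - z0)^2 + r2 <= rho^2] <- 2L
  } else {
    lab[Z > z0 & Z <= z0 + h & r2 <= rho^2] <- 2L
  }
  lab
}
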