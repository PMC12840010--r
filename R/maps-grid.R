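# Spatial binning grid over the arena bounding box.
#
# Bins are squares of side `bin_size` tiling [-R, R] x [-R, R]; linear bin
# index is column-major in x (ix + (iy - 1) * nx). `inside` flags bins whose
# centre lies inside the octagon.
map_grid <- function(geometry, bin_size = 2) {
  r <- geometry$radius
  nx <- as.integer(ceiling(2 * r / bin_size))
  edges <- -r + (0:nx) * bin_size
  cent <- (edges[-1] + edges[-length(edges)]) / 2
  cx <- rep(cent, times = nx)
  cy <- rep(cent, each = nx)
  inside <- in_arena(cbind(cx, cy), geometry)
  list(x0 = -r, bin = bin_size, nx = nx, ny = nx, nbin = nx * nx,
       centers_x = cx, centers_y = cy, inside = inside)
}

# linear bin index of points (clamped to the grid)
grid_index <- function(x, y, g) {
  ix <- pmin(g$nx, pmax(1L, floor((x - g$x0) / g$bin) + 1L))
  iy <- pmin(g$ny, pmax(1L, floor((y - g$x0) / g$bin) + 1L))
  as.integer(ix + (iy - 1L) * g$nx)
}

# Gaussian smoothing operator restricted to a set of valid bins.
#
# Returns a dense nbin x nbin matrix K whose column j spreads the content of
# source bin j over valid bins with Gaussian weights (sd `sigma` cm), weights
# renormalized over the valid support so that column sums are 1. Applying K
# to a count vector therefore conserves total counts on the valid set.
smoothing_matrix <- function(g, sigma, valid) {
  vi <- which(valid)
  K <- matrix(0, g$nbin, g$nbin)
  if (!length(vi)) return(K)
  dx <- outer(g$centers_x[vi], g$centers_x[vi], "-")
  dy <- outer(g$centers_y[vi], g$centers_y[vi], "-")
  W <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  W <- sweep(W, 2L, colSums(W), "/")
  K[vi, vi] <- W
  K
}
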