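# Internal numerical helpers shared across modules.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Circular (wrap-around) Gaussian convolution via FFT. The kernel is normalized
# to unit sum, so the total of the field is conserved exactly. `sigma` is in
# array-index units and may be a scalar or one value per dimension.
gaussian_blur <- function(x, sigma) {
  dm <- dim(x) %||% length(x)
  nd <- length(dm)
  if (length(sigma) == 1L) sigma <- rep(sigma, nd)
  if (all(sigma <= 0)) return(x)
  kern <- 1
  for (d in seq_len(nd)) {
    n <- dm[d]
    if (sigma[d] <= 0) {
      k1 <- c(1, rep(0, n - 1L))
    } else {
      # kernel centred on index 1 with wrap-around tails
      idx <- seq_len(n) - 1L
      circ <- pmin(idx, n - idx)
      k1 <- exp(-0.5 * (circ / sigma[d])^2)
      k1 <- k1 / sum(k1)
    }
    kern <- outer(kern, k1)
  }
  kern <- array(kern, dim = dm)
  out <- Re(fft(fft(array(x, dim = dm)) * fft(kern), inverse = TRUE)) / prod(dm)
  array(out, dim = dim(x))
}

# Block-average downsampling by integer factor along every dimension,
# zero-padding up to the next multiple so totals are conserved.
block_average <- function(x, factor) {
  dm <- dim(x)
  nd <- length(dm)
  padded <- ceiling(dm / factor) * factor
  if (any(padded != dm)) {
    xp <- array(0, dim = padded)
    idx <- lapply(dm, seq_len)
    xp <- do.call(`[<-`, c(list(xp), idx, list(x)))
    x <- xp
    dm <- padded
  }
  out_dim <- dm %/% factor
  if (nd == 2L) {
    x <- array(x, dim = c(factor, out_dim[1], factor, out_dim[2]))
    out <- apply(x, c(2, 4), sum) / factor^2
  } else if (nd == 3L) {
    x <- array(x, dim = c(factor, out_dim[1], factor, out_dim[2], factor, out_dim[3]))
    out <- apply(x, c(2, 4, 6), sum) / factor^3
  } else {
    abort("block_average supports 2D and 3D arrays only")
  }
  out
}

# Bi-/tri-linear interpolation of `grid` (voxel centres at (i - 0.5) * voxel_size)
# at physical points given as a matrix with one row per point.
interp_linear <- function(grid, voxel_size, points) {
  dm <- dim(grid)
  nd <- length(dm)
  stopifnot(ncol(points) == nd)
  # continuous index coordinates (1-based voxel centres)
  ci <- points / voxel_size + 0.5
  lo <- floor(ci)
  fr <- ci - lo
  clamp <- function(v, n) pmin(pmax(v, 1L), n)
  vals <- numeric(nrow(points))
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  for (k in seq_len(nrow(corners))) {
    off <- corners[k, ]
    idx <- sapply(seq_len(nd), function(d) clamp(lo[, d] + off[d], dm[d]))
    if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
    w <- rep(1, nrow(points))
    for (d in seq_len(nd)) w <- w * ifelse(off[d] == 1, fr[, d], 1 - fr[, d])
    vals <- vals + w * grid[idx]
  }
  vals
}

# Derive a reproducible child seed from a base seed and a stage label.
child_seed <- function(seed, stage) {
  (as.integer(seed) * 1103L + sum(utf8ToInt(stage)) * 7919L) %% 2147483647L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
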