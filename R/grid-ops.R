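# Shared finite-difference and resampling primitives for the phantom,
# level-set and reconstruction code. All images are plain numeric matrices
# (rows = y, cols = x), unit pixel spacing unless stated otherwise.

# Gradient: central differences in the interior, one-sided at the boundary
# rows/columns (so a linear ramp has a constant gradient on the whole grid).
grad2d <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  stopifnot(nr >= 2, nc >= 2)
  gy <- matrix(0, nr, nc)
  gx <- matrix(0, nr, nc)
  if (nr >= 3) gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  gy[1, ] <- m[2, ] - m[1, ]
  gy[nr, ] <- m[nr, ] - m[nr - 1, ]
  if (nc >= 3) gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  gx[, 1] <- m[, 2] - m[, 1]
  gx[, nc] <- m[, nc] - m[, nc - 1]
  list(gx = gx, gy = gy)
}

div2d <- function(fx, fy) {
  grad2d(fx)$gx + grad2d(fy)$gy
}

# Shift a matrix by k rows/cols with replicate (clamped-index) padding.
shift_rows <- function(m, k) {
  idx <- pmin(pmax(seq_len(nrow(m)) + k, 1L), nrow(m))
  m[idx, , drop = FALSE]
}

shift_cols <- function(m, k) {
  idx <- pmin(pmax(seq_len(ncol(m)) + k, 1L), ncol(m))
  m[, idx, drop = FALSE]
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with replicate boundary padding.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_rows(m, i - r - 1L)
  tmp <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_cols(tmp, i - r - 1L)
  out
}

# 5-point Laplacian, replicate padding.
laplacian2d <- function(m) {
  shift_rows(m, 1L) + shift_rows(m, -1L) +
    shift_cols(m, 1L) + shift_cols(m, -1L) - 4 * m
}

# Interpolation weights for center-aligned integer upsampling of one axis.
# order 0 = nearest, 1 = linear, 3 = cubic (Catmull-Rom), indices clamped at
# the edges. Returns an (n_in * factor) x n_in weight matrix; factor 1 is the
# exact identity.
catmull_rom_weights <- function(t) {
  c(-0.5 * t^3 + t^2 - 0.5 * t,
    1.5 * t^3 - 2.5 * t^2 + 1,
    -1.5 * t^3 + 2 * t^2 + 0.5 * t,
    0.5 * t^3 - 0.5 * t^2)
}

resize_weights_1d <- function(n_in, factor, order) {
  stopifnot(factor >= 1, order %in% c(0, 1, 3))
  n_out <- n_in * factor
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    x <- (j - 0.5) / factor + 0.5
    if (order == 0) {
      W[j, min(max(round(x), 1), n_in)] <- 1
    } else if (order == 1) {
      i0 <- floor(x)
      t <- x - i0
      ia <- min(max(i0, 1), n_in)
      ib <- min(max(i0 + 1, 1), n_in)
      W[j, ia] <- W[j, ia] + (1 - t)
      W[j, ib] <- W[j, ib] + t
    } else {
      i0 <- floor(x)
      w <- catmull_rom_weights(x - i0)
      for (k in -1:2) {
        ii <- min(max(i0 + k, 1), n_in)
        W[j, ii] <- W[j, ii] + w[k + 2]
      }
    }
  }
  W
}

interp_resize <- function(m, factor, order = 3) {
  if (factor == 1 && order != 0) return(m)
  Wr <- resize_weights_1d(nrow(m), factor, order)
  Wc <- resize_weights_1d(ncol(m), factor, order)
  Wr %*% m %*% t(Wc)
}

# Block-average downsampling by an integer factor that must divide both dims.
block_mean <- function(m, factor) {
  if (factor == 1) return(m)
  if (nrow(m) %% factor != 0 || ncol(m) %% factor != 0)
    stop("downsampling factor ", factor, " does not divide the grid dimensions ",
         nrow(m), "x", ncol(m), " (no implicit cropping)")
  down_rows <- function(x, f) {
    a <- array(x, dim = c(f, nrow(x) / f, ncol(x)))
    colMeans(a)
  }
  t(down_rows(t(down_rows(m, factor)), factor))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical or 0/1 matrices of identical shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a)
  b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
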