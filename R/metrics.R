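#' SSIM parameters
#'
#' @param K1,K2 small positive stabilizing constants.
#' @param L dynamic range, `2^m - 1` for an `m`-bit image.
#' @param mode `"global"` (one statistic over the whole image, the default)
#'   or `"windowed"` (mean of the statistic over all sliding windows).
#' @param window odd window side length for windowed mode.
#' @param scale_by_L if `TRUE` (conventional), the stabilizers enter the
#'   formula as `(K1 L)^2` and `(K2 L)^2`; if `FALSE` they are used raw, for
#'   formulations that state unscaled constants.
#' @return an object of class `ssim_params`.
#' @export
ssim_params <- function(K1 = 0.01, K2 = 0.03, L = 255,
                        mode = c("global", "windowed"), window = 11L,
                        scale_by_L = TRUE) {
  mode <- match.arg(mode)
  stopifnot(K1 > 0, K2 > 0, L > 0, window >= 3, window %% 2 == 1)
  structure(list(K1 = K1, K2 = K2, L = L, mode = mode,
                 window = as.integer(window), scale_by_L = scale_by_L),
            class = "ssim_params")
}

#' Mean squared error between two images
#'
#' @param x,y numeric matrices (or vectors) of identical shape.
#' @return mean of squared pixel differences.
#' @export
img_mse <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("images must have identical shapes")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `PSNR = 10 log10((2^m - 1)^2 / MSE)` for bit depth `m`. Identical images
#' have zero MSE and are reported as `Inf` dB (a sentinel, never an error).
#'
#' @inheritParams img_mse
#' @param m bit depth (`>= 1`).
#' @return PSNR in dB; `Inf` iff the images are identical.
#' @export
psnr <- function(x, y, m = 8) {
  stopifnot(m >= 1)
  err <- img_mse(x, y)
  if (err == 0) return(Inf)
  10 * log10((2^m - 1)^2 / err)
}

# SSIM statistic from first/second moments (population convention).
ssim_stat <- function(mx, my, vx, vy, vxy, C1, C2) {
  ((2 * mx * my + C1) * (2 * vxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Sliding-window sums of a matrix via an integral image; returns the
# (nr - w + 1) x (nc - w + 1) matrix of w x w window sums.
window_sums <- function(m, w) {
  S <- apply(m, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S <- rbind(0, cbind(0, S))
  nr <- nrow(m) - w + 1
  nc <- ncol(m) - w + 1
  S[(1 + w):(nr + w), (1 + w):(nc + w)] -
    S[1:nr, (1 + w):(nc + w)] -
    S[(1 + w):(nr + w), 1:nc] +
    S[1:nr, 1:nc]
}

#' Structural similarity index
#'
#' `SSIM(x, y) = (2 mu_x mu_y + C1)(2 cov_xy + C2) /
#' ((mu_x^2 + mu_y^2 + C1)(var_x + var_y + C2))` with population (divide by
#' `n`) variances. Global mode computes one statistic from whole-image
#' moments; windowed mode averages the statistic over all sliding windows.
#' Symmetric in its two arguments and equal to 1 iff `x == y`.
#'
#' @inheritParams img_mse
#' @param params an [ssim_params()].
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("images must have identical shapes")
  stopifnot(inherits(params, "ssim_params"))
  C1 <- if (params$scale_by_L) (params$K1 * params$L)^2 else params$K1
  C2 <- if (params$scale_by_L) (params$K2 * params$L)^2 else params$K2
  if (params$mode == "global") {
    n <- length(x)
    mx <- mean(x)
    my <- mean(y)
    ssim_stat(mx, my,
              mean((x - mx)^2), mean((y - my)^2),
              sum((x - mx) * (y - my)) / n,
              C1, C2)
  } else {
    w <- params$window
    if (nrow(x) < w || ncol(x) < w)
      stop("image smaller than the SSIM window")
    n <- w * w
    sx <- window_sums(x, w) / n
    sy <- window_sums(y, w) / n
    sxx <- window_sums(x * x, w) / n - sx^2
    syy <- window_sums(y * y, w) / n - sy^2
    sxy <- window_sums(x * y, w) / n - sx * sy
    mean(ssim_stat(sx, sy, sxx, syy, sxy, C1, C2))
  }
}

#' Score an image pair with MSE, PSNR and SSIM
#'
#' @inheritParams img_mse
#' @param m bit depth for PSNR.
#' @param params SSIM parameters.
#' @param pair_id identifier recorded in the report.
#' @return one-row data frame with columns `pair_id`, `mse`, `psnr_db`,
#'   `ssim`.
#' @export
score_pair <- function(x, y, m = 8, params = ssim_params(), pair_id = "pair") {
  data.frame(pair_id = pair_id, mse = img_mse(x, y), psnr_db = psnr(x, y, m),
             ssim = ssim(x, y, params), stringsAsFactors = FALSE)
}
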