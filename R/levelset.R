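#' Parameters of the distance-regularized level-set evolution
#'
#' The contour is the zero crossing of a scalar field `phi` (negative inside
#' the object). Its evolution minimizes
#' `E(phi) = nu * R(phi) + gamma * L(phi) + mu * A(phi)`, where `R` penalizes
#' deviation of `|grad phi|` from a signed-distance profile through a
#' double-well potential, `L` is the edge-weighted contour length and `A` the
#' edge-weighted area inside the contour (the balloon term).
#'
#' @param nu distance-regularization weight (`> 0`); the explicit scheme
#'   requires `dt * nu < 1/4` at unit spacing.
#' @param gamma weighted-length weight.
#' @param mu balloon (weighted-area) weight; positive shrinks the contour,
#'   negative expands it.
#' @param sigma Gaussian scale (pixels) used by [edge_indicator()].
#' @param epsilon width of the smoothed Dirac/Heaviside pair (pixels).
#' @param dt explicit Euler time step.
#' @param c0 magnitude of the binary initialization (`phi = -c0` inside the
#'   seed region, `+c0` outside).
#' @param max_iter iteration budget (`>= 1`).
#' @param tol convergence tolerance on `max |delta phi|` per step; `Inf`
#'   stops after one iteration.
#' @return an object of class `drlse_params`.
#' @export
drlse_params <- function(nu = 0.04, gamma = 5, mu = 1.5, sigma = 1.5,
                         epsilon = 1.5, dt = 1, c0 = 2,
                         max_iter = 500L, tol = 1e-4) {
  stopifnot(nu > 0, sigma > 0, epsilon > 0, dt > 0, c0 > 0, max_iter >= 1)
  if (dt * nu >= 0.25)
    stop("explicit scheme unstable: need dt * nu < 1/4, got ", dt * nu)
  structure(list(nu = nu, gamma = gamma, mu = mu, sigma = sigma,
                 epsilon = epsilon, dt = dt, c0 = c0,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "drlse_params")
}

#' Edge indicator of an image
#'
#' `beta = 1 / (1 + |grad(G_sigma * I)|^2)`: close to 0 on strong edges of the
#' Gaussian-smoothed image, exactly 1 where the smoothed gradient vanishes.
#'
#' @param image numeric matrix (finite values).
#' @param sigma Gaussian smoothing scale in pixels (`> 0`).
#' @return matrix with values in `(0, 1]`.
#' @export
edge_indicator <- function(image, sigma = 1.5) {
  stopifnot(sigma > 0)
  if (!all(is.finite(image))) stop("image contains non-finite values")
  g <- grad2d(gaussian_blur(image, sigma))
  1 / (1 + g$gx^2 + g$gy^2)
}

#' Double-well regularization potential
#'
#' `P(a) = (1 - cos(2 pi a)) / (2 pi)^2` for `a <= 1` and `(a - 1)^2 / 2` for
#' `a >= 1`: minima at `a = 0` and `a = 1`, so the regularization energy
#' drives `|grad phi|` toward 0 far from the contour and toward 1 (a signed
#' distance profile) near it.
#'
#' @param a nonnegative scalar or array (`|grad phi|`).
#' @return potential values, same shape as `a`.
#' @export
dw_potential <- function(a) {
  if (any(a < 0)) stop("potential argument must be nonnegative")
  ifelse(a <= 1, (1 - cos(2 * pi * a)) / (2 * pi)^2, 0.5 * (a - 1)^2)
}

#' Diffusion-rate ratio `P'(a) / a` of the double-well potential
#'
#' The regularization flow is `div(d(|grad phi|) grad phi)` with
#' `d(a) = P'(a) / a`; the removable singularity at `a = 0` is filled with its
#' limit 1.
#'
#' @param a nonnegative scalar or array.
#' @return `d(a)`, same shape as `a`.
#' @export
dw_potential_ratio <- function(a) {
  if (any(a < 0)) stop("potential argument must be nonnegative")
  out <- ifelse(a <= 1,
                sin(2 * pi * a) / (2 * pi * pmax(a, .Machine$double.xmin)),
                (a - 1) / pmax(a, .Machine$double.xmin))
  out[a < 1e-8] <- 1
  out
}

#' Smoothed Dirac delta with compact support
#'
#' `delta_eps(s) = (1 + cos(pi s / eps)) / (2 eps)` for `|s| <= eps`, 0
#' outside; integrates to 1 and is the derivative of [heaviside_smooth()].
#'
#' @param s scalar or array.
#' @param eps support half-width (`> 0`).
#' @return values, same shape as `s`.
#' @export
dirac_smooth <- function(s, eps) {
  if (eps <= 0) stop("eps must be positive")
  ifelse(abs(s) <= eps, (1 + cos(pi * s / eps)) / (2 * eps), 0)
}

#' Smoothed Heaviside step
#'
#' `H_eps(s) = (1 + s/eps + sin(pi s / eps) / pi) / 2` for `|s| <= eps`, 0
#' below, 1 above.
#'
#' @inheritParams dirac_smooth
#' @export
heaviside_smooth <- function(s, eps) {
  if (eps <= 0) stop("eps must be positive")
  ifelse(s < -eps, 0,
         ifelse(s > eps, 1,
                0.5 * (1 + s / eps + sin(pi * s / eps) / pi)))
}

#' Distance-regularization energy
#'
#' Grid sum of the double-well potential of `|grad phi|`; zero iff the
#' gradient magnitude sits in a well (0 or 1) everywhere.
#'
#' @param phi level-set field (numeric matrix).
#' @param spacing pixel spacing (isotropic).
#' @return nonnegative scalar.
#' @export
regularization_energy <- function(phi, spacing = 1) {
  g <- grad2d(phi)
  sum(dw_potential(sqrt((g$gx / spacing)^2 + (g$gy / spacing)^2))) * spacing^2
}

#' Edge-weighted contour length energy
#'
#' Grid sum of `beta * delta_eps(phi) * |grad phi|`; by the co-area formula
#' this approximates the `beta`-weighted length of the zero level set.
#'
#' @param phi level-set field.
#' @param beta edge indicator matrix (same shape).
#' @param eps Dirac smoothing width.
#' @param spacing pixel spacing.
#' @return nonnegative scalar.
#' @export
weighted_length <- function(phi, beta, eps = 1.5, spacing = 1) {
  g <- grad2d(phi)
  sum(beta * dirac_smooth(phi, eps) *
        sqrt((g$gx / spacing)^2 + (g$gy / spacing)^2)) * spacing^2
}

#' Edge-weighted interior area energy
#'
#' Grid sum of `beta * H_eps(-phi)`: the `beta`-weighted area of the region
#' inside the contour (`phi < 0`).
#'
#' @inheritParams weighted_length
#' @return scalar between 0 and `sum(beta) * spacing^2`.
#' @export
weighted_area <- function(phi, beta, eps = 1.5, spacing = 1) {
  sum(beta * heaviside_smooth(-phi, eps)) * spacing^2
}

#' Total level-set energy
#'
#' `nu * R(phi) + gamma * L(phi) + mu * A(phi)` with the three terms computed
#' by [regularization_energy()], [weighted_length()] and [weighted_area()].
#'
#' @param phi level-set field.
#' @param beta edge indicator.
#' @param params a [drlse_params()].
#' @return finite scalar.
#' @export
total_energy <- function(phi, beta, params) {
  params$nu * regularization_energy(phi) +
    params$gamma * weighted_length(phi, beta, params$epsilon) +
    params$mu * weighted_area(phi, beta, params$epsilon)
}

#' One explicit Euler step of the DRLSE gradient flow
#'
#' Updates `phi` by
#' `dt * (nu * div(d(|grad phi|) grad phi)
#'        + gamma * delta_eps(phi) * div(beta grad phi / |grad phi|)
#'        + mu * beta * delta_eps(phi))`,
#' with `|grad phi|` floored at `1e-10` before normalization and one-sided
#' differences at the grid boundary.
#'
#' @inheritParams total_energy
#' @return the updated level-set field.
#' @export
evolve_step <- function(phi, beta, params) {
  stopifnot(identical(dim(phi), dim(beta)))
  g <- grad2d(phi)
  mag <- sqrt(g$gx^2 + g$gy^2)
  d <- dw_potential_ratio(mag)
  reg <- div2d(d * g$gx, d * g$gy)
  magr <- mag + 1e-10
  curv <- div2d(beta * g$gx / magr, beta * g$gy / magr)
  del <- dirac_smooth(phi, params$epsilon)
  out <- phi + params$dt *
    (params$nu * reg + params$gamma * del * curv + params$mu * beta * del)
  if (!all(is.finite(out)))
    stop("level-set update diverged; the explicit scheme requires ",
         "dt * nu < 1/4 (CFL bound) and a moderate dt * gamma")
  out
}

#' Binary step initialization of the level-set field
#'
#' @param dims `c(rows, cols)` of the grid.
#' @param seed_mask logical/0-1 matrix marking the seed region (inside).
#' @param c0 step magnitude (`> 0`).
#' @return matrix equal to `-c0` inside the seed region and `+c0` outside.
#' @export
initialize_binary <- function(dims, seed_mask, c0 = 2) {
  stopifnot(c0 > 0, identical(as.integer(dims), as.integer(dim(seed_mask))))
  matrix(ifelse(as.logical(seed_mask), -c0, c0), dims[1], dims[2])
}

#' Axis-aligned rectangular seed mask
#'
#' @param dims `c(rows, cols)`.
#' @param r0,c0,r1,c1 inclusive 0-based corner coordinates.
#' @return logical matrix, `TRUE` inside the box.
#' @export
box_mask <- function(dims, r0, c0, r1, c1) {
  Y <- matrix(0:(dims[1] - 1), dims[1], dims[2])
  X <- matrix(rep(0:(dims[2] - 1), each = dims[1]), dims[1], dims[2])
  Y >= r0 & Y <= r1 & X >= c0 & X <= c1
}

#' Segment an image by distance-regularized level-set evolution
#'
#' Computes the edge indicator at the params' `sigma`, initializes `phi` as a
#' binary step on the seed region, and iterates [evolve_step()] until
#' `max |delta phi| < tol` or the iteration budget is exhausted (in which case
#' the result is returned with `converged = FALSE`, not an error). The total
#' energy is recorded at every iteration.
#'
#' @param image numeric matrix.
#' @param params a [drlse_params()].
#' @param seed_mask logical/0-1 matrix marking the initial interior.
#' @return list with `phi`, `mask` (`phi < 0`, 0/1), `energy` (per-iteration
#'   trace), `iterations`, `converged`, and `beta` (the edge indicator used).
#' @export
segment <- function(image, params, seed_mask) {
  stopifnot(inherits(params, "drlse_params"),
            identical(dim(image), dim(seed_mask)))
  beta <- edge_indicator(image, params$sigma)
  phi <- initialize_binary(dim(image), seed_mask, params$c0)
  energy <- numeric(params$max_iter)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(params$max_iter)) {
    phi_new <- evolve_step(phi, beta, params)
    delta <- max(abs(phi_new - phi))
    phi <- phi_new
    energy[it] <- total_energy(phi, beta, params)
    iterations <- it
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  list(phi = phi, mask = (phi < 0) + 0, energy = energy[seq_len(iterations)],
       iterations = iterations, converged = converged, beta = beta)
}
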