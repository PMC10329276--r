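#' Specification of a synthetic knee-bone phantom
#'
#' Describes a 2D MRI-like phantom of the proximal tibia: a bright bone on a
#' darker soft-tissue background, built from a capsule-shaped shaft, elliptical
#' condyles and an optional darker fracture line, together with the degradation
#' applied to emulate a low-quality acquisition (Gaussian blur, integer
#' downsampling, additive noise).
#'
#' Pixel coordinates are 0-based `(row, col)`; intensities live in
#' `[0, 2^bit_depth - 1]`.
#'
#' @param height,width grid size in pixels (at least 3).
#' @param background background (soft tissue) intensity.
#' @param bone_intensity intensity of the bone interior.
#' @param shaft `NULL` or a list with `center = c(row, col)`, `length`,
#'   `width`, and `angle_deg` (capsule axis, degrees from the row axis).
#' @param condyles list of ellipses, each a list with `center = c(row, col)`
#'   and `radii = c(row_radius, col_radius)`.
#' @param fracture `NULL` or a list with `from`, `to` (segment endpoints,
#'   `c(row, col)`), `gap` (full width, pixels) and `drop` (intensity drop
#'   inside the fracture line).
#' @param blur_sigma Gaussian blur scale of the degradation, pixels (`>= 0`).
#' @param factor integer downsampling factor (`>= 1`, must divide both grid
#'   dimensions when used).
#' @param noise_sd noise scale of the degradation (`>= 0`).
#' @param noise_model `"gaussian"` (additive) or `"rician"`.
#' @param bit_depth `m`, so intensities are clamped to `[0, 2^m - 1]`.
#' @param seed integer seed driving the degradation noise.
#' @return an object of class `phantom_spec`.
#' @seealso [make_phantom()], [degrade()]
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         background = 50, bone_intensity = 200,
                         shaft = NULL,
                         condyles = list(),
                         fracture = NULL,
                         blur_sigma = 1, factor = 2L, noise_sd = 5,
                         noise_model = c("gaussian", "rician"),
                         bit_depth = 8L, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(height >= 3, width >= 3, blur_sigma >= 0, noise_sd >= 0,
            factor >= 1, factor == as.integer(factor), bit_depth >= 1)
  peak <- 2^bit_depth - 1
  if (background < 0 || background > peak || bone_intensity < 0 ||
      bone_intensity > peak)
    stop("intensities must lie in [0, ", peak, "]")
  inside <- function(p) all(p >= 0) && p[1] <= height - 1 && p[2] <= width - 1
  if (!is.null(shaft)) {
    a <- shaft$angle_deg * pi / 180
    d <- c(cos(a), sin(a)) * shaft$length / 2
    for (p in list(shaft$center + d, shaft$center - d))
      if (!inside(p + shaft$width / 2) || !inside(p - shaft$width / 2))
        stop("shaft capsule extends outside the grid")
  }
  for (e in condyles) {
    if (!inside(e$center + e$radii) || !inside(e$center - e$radii))
      stop("condyle ellipse extends outside the grid")
    stopifnot(all(e$radii > 0))
  }
  if (!is.null(fracture)) {
    if (!inside(fracture$from) || !inside(fracture$to))
      stop("fracture segment extends outside the grid")
    stopifnot(fracture$gap > 0, fracture$drop >= 0)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 background = background, bone_intensity = bone_intensity,
                 shaft = shaft, condyles = condyles, fracture = fracture,
                 blur_sigma = blur_sigma, factor = as.integer(factor),
                 noise_sd = noise_sd, noise_model = noise_model,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Distance from every pixel center to a segment p--q (0-based coords).
segment_distance <- function(height, width, p, q) {
  Y <- matrix(0:(height - 1), height, width)
  X <- matrix(rep(0:(width - 1), each = height), height, width)
  v <- q - p
  len2 <- sum(v^2)
  if (len2 == 0) {
    sqrt((Y - p[1])^2 + (X - p[2])^2)
  } else {
    t <- clamp(((Y - p[1]) * v[1] + (X - p[2]) * v[2]) / len2, 0, 1)
    sqrt((Y - (p[1] + t * v[1]))^2 + (X - (p[2] + t * v[2]))^2)
  }
}

#' Render a phantom reference image and its ground-truth bone mask
#'
#' Renders the noise-free, full-resolution reference image described by a
#' [phantom_spec()]: bone (shaft capsule plus condyle ellipses) at
#' `bone_intensity` on the background, with the fracture line darkened by
#' `drop` where it crosses bone. Rendering uses no random numbers, so the
#' output is identical on every call with the same spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (numeric matrix) and `mask` (0/1 matrix, 1 =
#'   bone).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height
  w <- spec$width
  mask <- matrix(FALSE, h, w)
  if (!is.null(spec$shaft)) {
    a <- spec$shaft$angle_deg * pi / 180
    d <- c(cos(a), sin(a)) * spec$shaft$length / 2
    dist <- segment_distance(h, w, spec$shaft$center - d, spec$shaft$center + d)
    mask <- mask | (dist <= spec$shaft$width / 2)
  }
  Y <- matrix(0:(h - 1), h, w)
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  for (e in spec$condyles) {
    mask <- mask |
      (((Y - e$center[1]) / e$radii[1])^2 +
         ((X - e$center[2]) / e$radii[2])^2 <= 1)
  }
  img <- spec$background + (spec$bone_intensity - spec$background) * mask
  if (!is.null(spec$fracture)) {
    line <- segment_distance(h, w, spec$fracture$from, spec$fracture$to) <=
      spec$fracture$gap / 2
    img[line & mask] <- pmax(img[line & mask] - spec$fracture$drop, 0)
  }
  list(image = img, mask = mask + 0)
}

#' Degrade a reference image into a low-quality acquisition
#'
#' Applies, in order: Gaussian blur at `blur_sigma`, block-average
#' downsampling by `factor` (which must divide both grid dimensions), and
#' seeded additive Gaussian (or Rician) noise at scale `noise_sd`. The result
#' is clamped to the declared intensity range. With `blur_sigma = 0`,
#' `factor = 1` and `noise_sd = 0` the output equals the input exactly.
#'
#' @param reference numeric matrix matching the spec's grid.
#' @param spec a [phantom_spec()]; its `seed` drives the noise draw.
#' @return degraded image matrix of size `dim(reference) / factor`.
#' @export
degrade <- function(reference, spec) {
  stopifnot(inherits(spec, "phantom_spec"),
            nrow(reference) == spec$height, ncol(reference) == spec$width)
  out <- gaussian_blur(reference, spec$blur_sigma)
  out <- block_mean(out, spec$factor)
  if (spec$noise_sd > 0) {
    out <- with_seed(spec$seed, {
      n <- length(out)
      if (spec$noise_model == "gaussian") {
        out + matrix(stats::rnorm(n, sd = spec$noise_sd), nrow(out))
      } else {
        sqrt((out + matrix(stats::rnorm(n, sd = spec$noise_sd), nrow(out)))^2 +
               matrix(stats::rnorm(n, sd = spec$noise_sd), nrow(out))^2)
      }
    })
    out <- clamp(out, 0, 2^spec$bit_depth - 1)
  }
  out
}

#' A seeded suite of varied phantoms
#'
#' Generates `n` phantom specs with randomized geometry (condyle radii and
#' centers, shaft width, fracture position) around a tibia-like template,
#' sharing the degradation settings. Per-phantom noise seeds are derived from
#' `seed`, so the suite is fully reproducible.
#'
#' @param n number of phantoms.
#' @param seed integer master seed.
#' @param height,width,blur_sigma,factor,noise_sd,bit_depth passed to
#'   [phantom_spec()].
#' @return list of `phantom_spec` objects.
#' @export
phantom_suite <- function(n = 20, seed = 100L, height = 128L, width = 128L,
                          blur_sigma = 1, factor = 2L, noise_sd = 5,
                          bit_depth = 8L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ry <- stats::runif(1, 14, 20)
      rx <- stats::runif(1, 16, 24)
      cy <- height * 0.32 + stats::runif(1, -5, 5)
      cx <- width * 0.5 + stats::runif(1, -8, 8)
      sw <- stats::runif(1, 14, 20)
      phantom_spec(
        height = height, width = width,
        shaft = list(center = c(height * 0.62, width * 0.5),
                     length = height * 0.5, width = sw, angle_deg = 0),
        condyles = list(
          list(center = c(cy, cx - rx * 0.9), radii = c(ry, rx)),
          list(center = c(cy, cx + rx * 0.9), radii = c(ry, rx))),
        fracture = list(from = c(cy + ry + 2, width * 0.30),
                        to = c(cy + ry + 8 + stats::runif(1, 0, 6), width * 0.70),
                        gap = stats::runif(1, 2, 4), drop = 120),
        blur_sigma = blur_sigma, factor = factor, noise_sd = noise_sd,
        bit_depth = bit_depth,
        seed = seed + i)
    })
  })
}

#' Write a phantom image to PNG (8-bit) or NIfTI (float)
#'
#' @param image numeric matrix.
#' @param path output path; format chosen by extension (`.png` or `.nii`/
#'   `.nii.gz`).
#' @param bit_depth used to scale PNG output to `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 8L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(clamp(image / (2^bit_depth - 1), 0, 1), target = path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(image), file = path)
  }
  invisible(path)
}
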