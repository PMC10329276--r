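# Shared fixtures and independent oracles used across the suite.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Noise-free disk phantom (one circular condyle) at full resolution.
disk_spec <- function(r = 20, h = 128L, seed = 1L, blur = 0, factor = 1L,
                      noise = 0) {
  c0 <- (h - 1) / 2
  phantom_spec(height = h, width = h,
               condyles = list(list(center = c(c0, c0), radii = c(r, r))),
               blur_sigma = blur, factor = factor, noise_sd = noise,
               seed = seed)
}

# Signed distance to a centered circle, negative inside.
circle_sdf <- function(h, r) {
  c0 <- (h - 1) / 2
  Y <- matrix(0:(h - 1), h, h)
  X <- t(Y)
  sqrt((Y - c0)^2 + (X - c0)^2) - r
}

# Independent SSIM oracle: direct transcription of the similarity formula
# using stats moments (population convention via the (n-1)/n correction).
ssim_oracle <- function(x, y, C1, C2) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  f <- (n - 1) / n
  vx <- stats::var(x) * f
  vy <- stats::var(y) * f
  vxy <- stats::cov(x, y) * f
  mx <- mean(x)
  my <- mean(y)
  (2 * mx * my + C1) * (2 * vxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Independent PSNR oracle via log identities.
psnr_oracle <- function(x, y, m) {
  20 * log10(2^m - 1) - 10 * log10(mean((as.numeric(x) - as.numeric(y))^2))
}

# Two-sided p from the t statistic by direct quadrature of the t density.
t_p_oracle <- function(t, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t), Inf,
                       rel.tol = 1e-12)$value
}

# Pearson chi-square statistic from a brute-force expected-count matrix.
chisq_oracle <- function(tab) {
  E <- matrix(0, nrow(tab), ncol(tab))
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab)))
      E[i, j] <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
  sum((tab - E)^2 / E)
}

# Mean absolute deviation of |grad phi| from 1 over {|phi| <= halfwidth}.
band_gradient_deviation <- function(phi, halfwidth) {
  g <- kneemri:::grad2d(phi)
  mag <- sqrt(g$gx^2 + g$gy^2)
  band <- abs(phi) <= halfwidth
  mean(abs(mag[band] - 1))
}

# A cohort whose rom/pain columns encode exactly the given per-arm grade
# counts (excellent, good, intermediate, poor) at each timepoint.
cohort_from_counts <- function(small_6m, common_6m,
                               small_12m = small_6m, common_12m = common_6m) {
  enc <- function(c6, c12, prefix, group) {
    g6 <- rep(1:4, c6)
    g12 <- rep(1:4, c12)
    stopifnot(length(g6) == length(g12))
    rom <- c(130, 100, 80, 40)
    n <- length(g6)
    data.frame(patient_id = sprintf("%s%03d", prefix, seq_len(n)),
               group = group, age_years = 30, sex = "male", bmi = 22,
               op_time_min = 100, blood_loss_ml = 200, full_load_weeks = 15,
               healing_weeks = 18,
               rom_6m_deg = rom[g6], pain_6m = pain_levels()[g6],
               rom_12m_deg = rom[g12], pain_12m = pain_levels()[g12],
               stringsAsFactors = FALSE)
  }
  rbind(enc(small_6m, small_12m, "S", "small_incision"),
        enc(common_6m, common_12m, "C", "common"))
}
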