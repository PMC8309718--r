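#' Contrast-stretch the tumor gray levels to 0..255
#'
#' Affinely maps the in-mask attenuation range onto the full 8-bit span:
#' `g' = floor(255 * (g - gmin) / (gmax - gmin))`, with the maximum mapping to
#' exactly 255. A constant-valued tumor maps to all zeros. Stretching is
#' monotone, so voxel rank order is preserved.
#'
#' @param volume A `rccad_volume`.
#' @param mask An aligned `rccad_mask`.
#' @return An object of class `rccad_stretched`: `grid` (integer array, values
#'   0..255 inside the mask, -1 outside), `mask`, `spacing`.
#' @export
contrast_stretch <- function(volume, mask) {
  stopifnot(inherits(volume, "rccad_volume"), inherits(mask, "rccad_mask"))
  check_aligned(volume, mask)
  g <- volume$grid[mask$grid]
  rng <- range(g)
  stretched <- if (rng[2] > rng[1]) {
    pmin(255L, as.integer(floor(255 * (g - rng[1]) / (rng[2] - rng[1]))))
  } else {
    rep.int(0L, length(g))
  }
  out <- array(-1L, dim(mask$grid))
  out[mask$grid] <- stretched
  structure(list(grid = out, mask = mask, spacing = mask$spacing),
            class = "rccad_stretched")
}

stretched_values <- function(st) st$grid[st$mask$grid]

#' First-order (histogram) texture features
#'
#' Moments, entropy, percentiles and the cumulative distribution of the
#' contrast-stretched gray levels over the tumor voxels. Moments use population
#' denominators; kurtosis is non-excess (a normal distribution scores 3);
#' entropy is Shannon entropy in bits over the 256-level histogram; percentiles
#' (10th..100th in 10-point steps) use linear interpolation between order
#' statistics.
#'
#' @param st A `rccad_stretched` tumor.
#' @return A list of class `rccad_first_order`: `mean`, `variance`,
#'   `standard_deviation`, `skewness`, `kurtosis`, `entropy`, `percentiles`
#'   (length 10), `cdf` (length 256, ending at 1).
#' @export
first_order_features <- function(st) {
  stopifnot(inherits(st, "rccad_stretched"))
  x <- as.numeric(stretched_values(st))
  n <- length(x)
  if (n < 2) abort("first-order moments need at least 2 tumor voxels")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean((x - mu)^3) / s^3
    kurt <- mean((x - mu)^4) / v^2
  } else {
    skew <- 0
    kurt <- 3
  }
  counts <- tabulate(as.integer(x) + 1L, nbins = 256L)
  p <- counts / n
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  pct <- quantile(x, probs = seq(0.1, 1, by = 0.1), type = 7, names = FALSE)
  structure(list(mean = mu, variance = v, standard_deviation = s,
                 skewness = skew, kurtosis = kurt, entropy = entropy,
                 percentiles = setNames(pct, sprintf("p%d", seq(10, 100, 10))),
                 cdf = cumsum(p)),
            class = "rccad_first_order")
}

#' 26-neighborhood offsets for the rotation-invariant GLCM
#'
#' The half-set of the 26-connected voxel neighborhood (13 direction offsets);
#' symmetric accumulation covers the other half. With `max_mm` set, offsets
#' whose physical length exceeds that distance are dropped (the published
#' <= 2 mm criterion, meaningful for near-isotropic voxels).
#'
#' @param spacing Voxel spacing in mm.
#' @param max_mm Optional physical distance cutoff in mm.
#' @return Integer matrix (K x 3) of voxel offsets.
#' @export
glcm_offsets <- function(spacing = c(1, 1, 1), max_mm = NULL) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  half <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
                (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
  if (!is.null(max_mm)) {
    d <- sqrt(colSums((t(half) * spacing)^2))
    half <- half[d <= max_mm + 1e-9, , drop = FALSE]
    if (!nrow(half)) abort("max_mm excludes every neighborhood offset")
  }
  storage.mode(half) <- "integer"
  half
}

#' Gray-level co-occurrence matrix over the 3D tumor
#'
#' Counts co-occurrences of stretched gray-level pairs over all neighbor
#' directions of the 26-connected voxel neighborhood at once (in-plane and
#' across adjacent planes), which makes the derived features rotation
#' invariant. Each unordered voxel pair contributes to both (i, j) and (j, i),
#' so the matrix is symmetric; `normalized` sums to 1.
#'
#' @param st A `rccad_stretched` tumor.
#' @param max_mm Optional physical distance cutoff passed to [glcm_offsets()].
#' @return An object of class `rccad_glcm` with `counts` and `normalized`
#'   256 x 256 matrices.
#' @export
build_glcm <- function(st, max_mm = NULL) {
  stopifnot(inherits(st, "rccad_stretched"))
  off <- glcm_offsets(st$spacing, max_mm)
  counts <- cpp_glcm(as.integer(st$grid), dim(st$grid), off)
  tot <- sum(counts)
  if (tot == 0) abort("no in-neighborhood voxel pairs; tumor too small for GLCM")
  structure(list(counts = counts, normalized = counts / tot), class = "rccad_glcm")
}

#' @export
print.rccad_glcm <- function(x, ...) {
  cat(sprintf("<GLCM> 256 x 256, %g paired counts\n", sum(x$counts)))
  invisible(x)
}

#' Second-order (Haralick) texture features of a GLCM
#'
#' Standard Haralick statistics of the normalized co-occurrence matrix P(i,j):
#' contrast `sum P (i-j)^2`, dissimilarity `sum P |i-j|`, homogeneity (inverse
#' difference moment) `sum P / (1 + (i-j)^2)`, angular second moment
#' `sum P^2`, energy `sqrt(ASM)`, and correlation
#' `sum (i - mu_i)(j - mu_j) P / (sigma_i sigma_j)`. A zero-variance
#' (single-gray-level) tumor is reported as perfectly correlated (1).
#'
#' @param glcm A `rccad_glcm`.
#' @return A named list of class `rccad_second_order` with the six features.
#' @export
second_order_features <- function(glcm) {
  stopifnot(inherits(glcm, "rccad_glcm"))
  P <- glcm$normalized
  lev <- 0:255
  D <- outer(lev, lev, "-")
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mu_i <- sum(lev * pi_)
  mu_j <- sum(lev * pj_)
  s_i <- sqrt(sum((lev - mu_i)^2 * pi_))
  s_j <- sqrt(sum((lev - mu_j)^2 * pj_))
  asm <- sum(P^2)
  corr <- if (s_i > 0 && s_j > 0) {
    sum(outer(lev - mu_i, lev - mu_j) * P) / (s_i * s_j)
  } else 1
  structure(list(contrast = sum(P * D^2),
                 dissimilarity = sum(P * abs(D)),
                 homogeneity = sum(P / (1 + D^2)),
                 asm = asm,
                 energy = sqrt(asm),
                 correlation = corr),
            class = "rccad_second_order")
}

#' All texture features of one phase as a tidy row
#'
#' Convenience wrapper chaining [contrast_stretch()],
#' [first_order_features()], [build_glcm()] and [second_order_features()].
#'
#' @inheritParams contrast_stretch
#' @inheritParams build_glcm
#' @return A one-row tibble with the 6 histogram, 10 percentile and 6 GLCM
#'   features using the canonical feature names.
#' @export
texture_features <- function(volume, mask, max_mm = NULL) {
  st <- contrast_stretch(volume, mask)
  fo <- first_order_features(st)
  so <- second_order_features(build_glcm(st, max_mm = max_mm))
  tibble::as_tibble(c(
    list(hist_mean = fo$mean, hist_variance = fo$variance,
         hist_sd = fo$standard_deviation, hist_skewness = fo$skewness,
         hist_kurtosis = fo$kurtosis, hist_entropy = fo$entropy),
    as.list(fo$percentiles),
    list(glcm_contrast = so$contrast, glcm_dissimilarity = so$dissimilarity,
         glcm_homogeneity = so$homogeneity, glcm_asm = so$asm,
         glcm_energy = so$energy, glcm_correlation = so$correlation)
  ))
}
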