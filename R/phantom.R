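#' Class presets for the phantom generator
#'
#' Reads the versioned preset file shipped with the package
#' (`extdata/class_presets.json`). Presets encode the qualitative contrasts
#' the classifier exploits: benign AML phantoms are smooth, texturally
#' homogeneous and enhance weakly; ccRCC phantoms have the most complex
#' surfaces, the strongest heterogeneity and the steepest wash-in/wash-out;
#' nccRCC sits in between.
#'
#' @return Named list of per-class parameter lists.
#' @export
phantom_presets <- function() {
  path <- system.file("extdata", "class_presets.json", package = "rccad")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Specification of one synthetic tumor phantom
#'
#' @param class_label `"AML"`, `"ccRCC"` or `"nccRCC"`.
#' @param base_radius Mean tumor radius in mm.
#' @param shape_bump_amplitude Relative amplitude of the random
#'   spherical-harmonic surface perturbation (fraction of radius).
#' @param shape_bump_max_degree Highest SH degree carrying surface bumps.
#' @param texture_sd Standard deviation (HU) of the correlated intensity
#'   texture inside the tumor.
#' @param texture_correlation_length Correlation length (mm) of that texture.
#' @param enhancement Mean tumor HU at the precontrast / portal-venous /
#'   delayed phases.
#' @param grid_shape,spacing Voxel lattice (default 96^3 at 1 mm isotropic;
#'   pass e.g. `spacing = c(1, 1, 2.5)` to exercise anisotropic handling).
#' @param seed Seed for all random draws of this phantom.
#' @return A list of class `rccad_phantom_spec`. Unspecified parameters are
#'   taken from the class preset.
#' @export
phantom_spec <- function(class_label = c("AML", "ccRCC", "nccRCC"),
                         base_radius = 12,
                         shape_bump_amplitude = NULL,
                         shape_bump_max_degree = NULL,
                         texture_sd = NULL,
                         texture_correlation_length = NULL,
                         enhancement = NULL,
                         grid_shape = c(96, 96, 96),
                         spacing = c(1, 1, 1),
                         seed = 17) {
  class_label <- match.arg(class_label)
  preset <- phantom_presets()[[class_label]]
  spec <- list(
    class_label = class_label,
    base_radius = base_radius,
    shape_bump_amplitude = shape_bump_amplitude %||% preset$shape_bump_amplitude,
    shape_bump_max_degree = shape_bump_max_degree %||% preset$shape_bump_max_degree,
    texture_sd = texture_sd %||% preset$texture_sd,
    texture_correlation_length = texture_correlation_length %||% preset$texture_correlation_length,
    enhancement = enhancement %||% as.numeric(preset$enhancement),
    grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing),
    seed = as.integer(seed)
  )
  if (spec$shape_bump_amplitude < 0 || spec$texture_sd < 0) {
    abort("amplitudes must be >= 0")
  }
  if (length(spec$enhancement) != 3) abort("enhancement must give 3 phase means")
  check_spacing(spec$spacing)
  structure(spec, class = "rccad_phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a star-shaped phantom tumor mask
#'
#' Voxelizes the region `rho <= R * (1 + a * p(theta, phi))` where `p` is a
#' random SH perturbation with
#' degrees 2..`shape_bump_max_degree`, normalized to unit angular standard
#' deviation. Smooth presets (low amplitude/degree) emulate benign AML
#' surfaces; rough presets emulate malignant complexity. Deterministic per
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A `rccad_mask` centered in the grid.
#' @export
generate_shape <- function(spec) {
  stopifnot(inherits(spec, "rccad_phantom_spec"))
  R <- spec$base_radius
  D <- max(2L, as.integer(spec$shape_bump_max_degree))
  coef <- numeric((D + 1)^2)
  coef[1] <- R * sqrt(4 * pi) # constant term: radius R
  if (spec$shape_bump_amplitude > 0 && spec$shape_bump_max_degree >= 2) {
    set.seed(spec$seed)
    for (tau in 2:spec$shape_bump_max_degree) {
      cols <- tau^2 + seq_len(2 * tau + 1)
      coef[cols] <- rnorm(2 * tau + 1)
    }
    pert <- coef[-1]
    scale_ <- spec$shape_bump_amplitude * R / sqrt(sum(pert^2) / (4 * pi))
    coef[-1] <- pert * scale_
  }
  dims <- spec$grid_shape
  center <- (dims - 1) / 2 * spec$spacing
  rmax <- R * (1 + 6 * spec$shape_bump_amplitude) + 2
  grid <- cpp_radial_mask(dims, spec$spacing, center, coef,
                          D, rmax, 0.25 * R)
  g <- array(as.logical(grid), dims)
  if (any(g[1, , ]) || any(g[dims[1], , ]) || any(g[, 1, ]) || any(g[, dims[2], ]) ||
      any(g[, , 1]) || any(g[, , dims[3]])) {
    abort("tumor region touches the grid boundary; enlarge grid_shape or shrink base_radius")
  }
  tumor_mask(g, spec$spacing)
}

#' Generate a complete three-phase phantom subject
#'
#' Fills the phantom mask, per phase, with the preset mean enhancement plus a
#' correlated Gaussian random field (white noise smoothed with a Gaussian
#' kernel of width `texture_correlation_length`, standardized inside the mask
#' and scaled to `texture_sd`), on a mildly noisy ~0 HU background. The same
#' structural field underlies all three phases — lesion architecture does not
#' change between acquisitions — with a small independent per-phase
#' fluctuation (10% of `texture_sd`). Values are rounded to integer HU.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `rccad_phantom_subject`: `volumes` (list of three
#'   `rccad_volume`s), `mask`, `truth` (the spec).
#' @export
generate_subject <- function(spec) {
  mask <- generate_shape(spec)
  dims <- spec$grid_shape
  set.seed(spec$seed + 1L)
  field <- if (spec$texture_sd > 0) {
    f <- gaussian_random_field(dims, spec$texture_correlation_length / spec$spacing)
    inm <- f[mask$grid]
    (f - mean(inm)) / max(sd(inm), 1e-12)
  } else {
    array(0, dims)
  }
  phases <- c("precontrast", "portal_venous", "delayed")
  times <- c(0, 80, 300)
  volumes <- vector("list", 3)
  for (k in 1:3) {
    bg <- array(rnorm(prod(dims), 0, 5), dims)
    g <- bg
    nvox <- sum(mask$grid)
    phase_noise <- if (spec$texture_sd > 0) rnorm(nvox, 0, 0.1 * spec$texture_sd) else 0
    g[mask$grid] <- spec$enhancement[k] + spec$texture_sd * field[mask$grid] + phase_noise
    volumes[[k]] <- ct_volume(round(g), spec$spacing, phase = phases[k],
                              acquisition_time = times[k])
  }
  structure(list(volumes = setNames(volumes, phases), mask = mask, truth = spec),
            class = "rccad_phantom_subject")
}

# periodic Gaussian smoothing of white noise via FFT; sigma in voxels per axis
gaussian_random_field <- function(dims, sigma_vox) {
  noise <- array(rnorm(prod(dims)), dims)
  axis_kernel <- function(n, s) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-0.5 * (d / max(s, 1e-6))^2)
    k / sum(k)
  }
  k1 <- axis_kernel(dims[1], sigma_vox[1])
  k2 <- axis_kernel(dims[2], sigma_vox[2])
  k3 <- axis_kernel(dims[3], sigma_vox[3])
  kern <- outer(outer(k1, k2), k3)
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / prod(dims)
  sm
}

#' @export
print.rccad_phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom subject> %s, radius %g mm, grid %s\n",
              x$truth$class_label, x$truth$base_radius,
              paste(x$truth$grid_shape, collapse = "x")))
  invisible(x)
}

#' Generate a seeded phantom cohort
#'
#' Draws per-subject phantom specs around the class presets (mild seeded
#' jitter of radius, amplitude, texture and enhancement so subjects are not
#' clones) and generates all subjects. Default sizes mirror a 140-subject
#' study: 70 benign AML, 40 ccRCC, 30 nccRCC.
#'
#' @param n_aml,n_ccrcc,n_nccrcc Class sizes.
#' @param seed Cohort seed; per-subject seeds are derived from it.
#' @param grid_shape,spacing,base_radius Shared geometry of all phantoms.
#' @return A list of class `rccad_cohort`: `subjects` (list of
#'   `rccad_phantom_subject`) and `truth` (tibble of all generated
#'   parameters).
#' @export
generate_cohort <- function(n_aml = 70, n_ccrcc = 40, n_nccrcc = 30, seed = 17,
                            grid_shape = c(96, 96, 96), spacing = c(1, 1, 1),
                            base_radius = 12) {
  n <- n_aml + n_ccrcc + n_nccrcc
  if (n < 1) abort("cohort must contain at least one subject")
  labels <- rep(c("AML", "ccRCC", "nccRCC"), times = c(n_aml, n_ccrcc, n_nccrcc))
  set.seed(seed)
  jit <- tibble(
    radius_f = runif(n, 0.85, 1.15),
    amp_f = runif(n, 0.8, 1.2),
    tex_f = runif(n, 0.85, 1.15),
    e1 = rnorm(n, 0, 3), e2 = rnorm(n, 0, 8), e3 = rnorm(n, 0, 6)
  )
  presets <- phantom_presets()
  subjects <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    p <- presets[[labels[i]]]
    sseed <- as.integer((seed + 104729 * i) %% 2147483647)
    spec <- phantom_spec(
      labels[i],
      base_radius = base_radius * jit$radius_f[i],
      shape_bump_amplitude = p$shape_bump_amplitude * jit$amp_f[i],
      shape_bump_max_degree = p$shape_bump_max_degree,
      texture_sd = p$texture_sd * jit$tex_f[i],
      texture_correlation_length = p$texture_correlation_length,
      enhancement = as.numeric(p$enhancement) + c(jit$e1[i], jit$e2[i], jit$e3[i]),
      grid_shape = grid_shape, spacing = spacing, seed = sseed
    )
    subjects[[i]] <- generate_subject(spec)
    truth[[i]] <- tibble(subject_id = sprintf("S%03d", i), label = labels[i],
                         base_radius = spec$base_radius,
                         shape_bump_amplitude = spec$shape_bump_amplitude,
                         shape_bump_max_degree = spec$shape_bump_max_degree,
                         texture_sd = spec$texture_sd,
                         texture_correlation_length = spec$texture_correlation_length,
                         hu_pre = spec$enhancement[1], hu_pv = spec$enhancement[2],
                         hu_del = spec$enhancement[3], seed = spec$seed)
  }
  structure(list(subjects = setNames(subjects, sprintf("S%03d", seq_len(n))),
                 truth = dplyr::bind_rows(truth)),
            class = "rccad_cohort")
}

#' @export
print.rccad_cohort <- function(x, ...) {
  cat(sprintf("<phantom cohort> %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%s: %d", names(table(x$truth$label)),
                            table(x$truth$label)), collapse = ", ")))
  invisible(x)
}
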