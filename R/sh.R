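#' Real spherical-harmonic basis
#'
#' Evaluates the orthonormal real spherical harmonic of degree `tau` and order
#' `beta` at the given angles: negative orders use the sine branch, zero the
#' constant branch, positive the cosine branch, with normalization
#' `sqrt((2*tau+1)/(4*pi) * (tau-|beta|)!/(tau+|beta|)!)` (times `sqrt(2)` for
#' `beta != 0`) so that the basis integrates to the identity over the sphere.
#'
#' @param theta Polar angle(s) in `[0, pi]`.
#' @param phi Azimuthal angle(s) in `[0, 2*pi)`.
#' @param tau Degree (>= 0).
#' @param beta Order, `|beta| <= tau`.
#' @return Numeric vector of basis values.
#' @examples
#' sh_basis(1.2, 0.3, 0, 0) # 1/sqrt(4*pi)
#' @export
sh_basis <- function(theta, phi, tau, beta) {
  if (abs(beta) > tau) abort("|beta| must not exceed tau")
  if (any(theta < -1e-12 | theta > pi + 1e-12)) abort("theta must lie in [0, pi]")
  B <- cpp_sh_basis(as.numeric(theta), as.numeric(phi), as.integer(tau))
  B[, tau^2 + beta + tau + 1]
}

sh_basis_matrix <- function(theta, phi, max_degree) {
  cpp_sh_basis(as.numeric(theta), as.numeric(phi), as.integer(max_degree))
}

#' Fit a spherical-harmonic model of the tumor radius function
#'
#' Least-squares fit of the per-vertex radii r_i (distance from the interior
#' origin, mm) against the real SH basis evaluated at the spherical-map angles,
#' solved by ridge-stabilized normal equations. With basis columns ordered by
#' ascending degree, a single Cholesky factorization yields the residual sum of
#' squares of every nested lower-order model, which is what the
#' reconstruction-error spectrum consumes.
#'
#' @param mesh A `rccad_mesh`.
#' @param map The matching `rccad_spherical_map` from [attraction_repulsion()].
#' @param max_degree Highest SH degree N of the model.
#' @param ridge Ridge added to the normal-equation diagonal for conditioning.
#' @param precision `"double"` (default) or `"single"`; single precision halves
#'   the time of large-degree fits at the cost of ~1e-3 absolute accuracy in
#'   the error spectrum, which is immaterial for feature extraction.
#' @param fit_max_vertices Cap on the number of surface samples entering the
#'   fit; when the mesh has more vertices, a seeded uniform subsample is used.
#' @param subsample_seed Seed for that subsample.
#' @return An object of class `rccad_sh_model`: `max_degree`, `coefficients`
#'   (length `(N+1)^2`, degree-ascending), `rss` (residual sum of squares of
#'   the nested models for degrees `0..N`), `n_fit`, `mean_radius`.
#' @export
fit_sh <- function(mesh, map, max_degree, ridge = 1e-10,
                   precision = c("double", "single"),
                   fit_max_vertices = Inf, subsample_seed = 17) {
  stopifnot(inherits(map, "rccad_spherical_map"))
  precision <- match.arg(precision)
  n <- (max_degree + 1L)^2
  idx <- seq_along(map$theta)
  if (is.finite(fit_max_vertices) && length(idx) > fit_max_vertices) {
    idx <- with_seed(subsample_seed, sort(sample.int(length(idx), fit_max_vertices)))
  }
  if (length(idx) < n) {
    abort(sprintf(
      "underdetermined SH fit: %d surface samples for %d coefficients; lower max_degree (<= %d) or subdivide the mesh",
      length(idx), n, floor(sqrt(length(idx))) - 1))
  }
  r <- map$radii[idx]
  if (any(r <= 0)) abort("all vertex radii must be positive")
  fit <- cpp_sh_nested_fit(map$theta[idx], map$phi[idx], r, as.integer(max_degree),
                           ridge, identical(precision, "single"))
  structure(list(max_degree = as.integer(max_degree),
                 coefficients = fit$coefficients,
                 rss = as.numeric(fit$rss),
                 n_fit = length(idx),
                 mean_radius = mean(r)),
            class = "rccad_sh_model")
}

#' @export
print.rccad_sh_model <- function(x, ...) {
  cat(sprintf("<SH model> degree %d (%d coefficients), fit on %d samples, RMS residual %.4g mm\n",
              x$max_degree, length(x$coefficients), x$n_fit,
              sqrt(x$rss[length(x$rss)] / x$n_fit)))
  invisible(x)
}

#' Evaluate a fitted SH radius model
#'
#' @param object A `rccad_sh_model`.
#' @param theta,phi Angles at which to evaluate the modeled radius (mm).
#' @param ... Unused.
#' @export
predict.rccad_sh_model <- function(object, theta, phi, ...) {
  cpp_sh_eval(as.numeric(theta), as.numeric(phi), object$coefficients, object$max_degree)
}

#' Spherical-harmonic reconstruction-error (SHRE) morphology features
#'
#' For model orders k = 1..`n_orders`, the reconstruction error e(k) is the
#' root-mean-square radial residual of the order-k SH model, normalized by the
#' mean vertex radius so tumors of different sizes are comparable. Smooth,
#' near-spherical (benign-like) surfaces are captured by low orders and decay
#' fast; complex (malignant-like) surfaces keep appreciable error up to high
#' orders. The spectrum is non-increasing in k because the models are nested.
#'
#' @inheritParams fit_sh
#' @param n_orders Number of error entries (default 70, the feature-set size).
#' @param min_vertex_factor The fit requires at least
#'   `ceiling(min_vertex_factor * (n_orders+1)^2)` vertices; fewer is an error
#'   instructing to subdivide before mapping (see [ensure_vertex_count()]).
#' @return Numeric vector of class `rccad_shre`, length `n_orders`, with
#'   attributes `mean_radius` and `n_vertices`.
#' @export
shre_features <- function(mesh, map, n_orders = 70, ridge = 1e-10,
                          precision = c("double", "single"),
                          fit_max_vertices = Inf, subsample_seed = 17,
                          min_vertex_factor = 1.05) {
  need <- ceiling(min_vertex_factor * (n_orders + 1)^2)
  if (length(map$theta) < need) {
    abort(sprintf(
      "SHRE at %d orders needs >= %d surface samples (have %d); Loop-subdivide the mesh before mapping (ensure_vertex_count)",
      n_orders, need, length(map$theta)))
  }
  fit <- fit_sh(mesh, map, max_degree = n_orders, ridge = ridge,
                precision = match.arg(precision),
                fit_max_vertices = fit_max_vertices, subsample_seed = subsample_seed)
  e <- sqrt(fit$rss[-1] / fit$n_fit) / fit$mean_radius # orders 1..n_orders
  structure(setNames(e, sprintf("shre_%02d", seq_len(n_orders))),
            mean_radius = fit$mean_radius, n_vertices = fit$n_fit,
            class = "rccad_shre")
}

#' @export
print.rccad_shre <- function(x, ...) {
  cat(sprintf("<SHRE spectrum> %d orders, e(1) = %.4g, e(%d) = %.4g (relative RMS)\n",
              length(x), x[[1]], length(x), x[[length(x)]]))
  invisible(x)
}

#' Guarantee enough vertices for a high-order SH fit
#'
#' Loop-subdivides the mesh until it has at least
#' `ceiling(factor * (n_orders + 1)^2)` vertices. Apply before
#' [attraction_repulsion()] when targeting high SH orders on coarse meshes.
#'
#' @param mesh A `rccad_mesh`.
#' @param n_orders Target SHRE order count.
#' @param factor Safety factor on the minimum sample count.
#' @return The (possibly subdivided) mesh.
#' @export
ensure_vertex_count <- function(mesh, n_orders = 70, factor = 1.05) {
  need <- ceiling(factor * (n_orders + 1)^2)
  while (nrow(mesh$vertices) < need) mesh <- subdivide_mesh(mesh)
  mesh
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
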