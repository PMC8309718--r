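#' Attraction-repulsion parameters
#'
#' Weights and stopping rule for the attraction-repulsion spherical
#' parameterization. The attraction weights `ca1`, `ca2` pull every node
#' toward its mesh neighbors; the repulsion weight `cr` inflates the spherical
#' mesh with an all-pairs inverse-square push so nodes cannot collapse onto
#' each other. Iteration stops once the maximum per-vertex displacement (after
#' reprojection onto the sphere) drops to `threshold`, or at `max_iterations`.
#'
#' The attraction force per neighbor is
#' `ca1 * (d * ||d||^2 + ca2 * d / ||d||)` for `attraction_form = "product"`
#' (default) or `ca1 * (d / ||d||^2 + ca2 * d / ||d||)` for `"quotient"`;
#' both readings are exposed because the published update rule is
#' typographically ambiguous between them.
#'
#' @param ca1,ca2 Attraction weights (> 0 and >= 0).
#' @param cr Repulsion weight (> 0).
#' @param threshold Convergence threshold on max vertex displacement
#'   (unit-sphere coordinates).
#' @param max_iterations Iteration cap; hitting it is recorded as
#'   non-convergence, not an error.
#' @param attraction_form `"product"` or `"quotient"`.
#' @return A list of class `rccad_ar_params`.
#' @export
ar_params <- function(ca1 = 0.1, ca2 = 0.05, cr = 0.2, threshold = 1e-4,
                      max_iterations = 10000, attraction_form = c("product", "quotient")) {
  if (ca1 < 0 || ca2 < 0 || cr < 0) abort("attraction/repulsion weights must be non-negative")
  if (threshold <= 0) abort("threshold must be > 0")
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  structure(list(ca1 = ca1, ca2 = ca2, cr = cr, threshold = threshold,
                 max_iterations = as.integer(max_iterations),
                 attraction_form = match.arg(attraction_form)),
            class = "rccad_ar_params")
}

neighbors_csr <- function(neighbors) {
  deg <- lengths(neighbors)
  list(ptr = c(0L, cumsum(deg)),
       idx = as.integer(unlist(neighbors, use.names = FALSE)) - 1L)
}

#' Initial spherical parameterization
#'
#' Projects every mesh vertex radially from an interior origin onto the unit
#' sphere — a topology-preserving initial map for star-shaped surfaces. The
#' origin defaults to the foreground centroid of `mask` (or, lacking a mask,
#' the vertex centroid); if the centroid falls outside the tumor, the interior
#' voxel farthest from the background is used instead.
#'
#' @param mesh A genus-0 `rccad_mesh`.
#' @param mask Optional `rccad_mask` the mesh was extracted from; used to pick
#'   and validate the origin.
#' @param origin Optional explicit origin (mm).
#' @return An object of class `rccad_spherical_map` with elements
#'   `unit_coords` (I x 3), `theta`, `phi`, `radii` (mm, distance of each mesh
#'   vertex to the origin), `origin`, `iterations_run`, `converged`.
#' @export
initial_spherical_map <- function(mesh, mask = NULL, origin = NULL) {
  stopifnot(inherits(mesh, "rccad_mesh"))
  if (is.null(origin)) origin <- choose_origin(mesh, mask)
  rel <- sweep(mesh$vertices, 2, origin)
  r <- sqrt(rowSums(rel^2))
  if (any(r < 1e-9)) abort("origin coincides with a mesh vertex")
  u <- rel / r
  dup <- duplicated(round(u, 12))
  if (any(dup)) abort("radial projection maps two vertices to the same point; surface is not star-shaped from this origin")
  spherical_map(u, mesh, origin = origin, radii = r,
                iterations_run = 0L, converged = NA)
}

choose_origin <- function(mesh, mask) {
  if (is.null(mask)) return(colMeans(mesh$vertices))
  idx <- which(mask$grid, arr.ind = TRUE)
  origin <- (colMeans(idx) - 1) * mask$spacing
  vox <- round(origin / mask$spacing) + 1
  inside <- all(vox >= 1) && all(vox <= dim(mask$grid)) &&
    mask$grid[vox[1], vox[2], vox[3]]
  if (!inside) {
    # centroid fell outside a non-star-shaped tumor: fall back to the interior
    # point with maximal distance to the background
    vox <- cpp_interior_point(mask$grid, dim(mask$grid))
    origin <- (vox - 1) * mask$spacing
  }
  origin
}

spherical_map <- function(u, mesh, origin, radii, iterations_run, converged) {
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  structure(list(unit_coords = u, theta = theta, phi = phi,
                 radii = radii, origin = origin,
                 iterations_run = iterations_run, converged = converged),
            class = "rccad_spherical_map")
}

#' @export
print.rccad_spherical_map <- function(x, ...) {
  cat(sprintf("<spherical map> %d vertices, %d iterations, converged: %s\n",
              nrow(x$unit_coords), x$iterations_run, x$converged))
  invisible(x)
}

#' Single attraction / repulsion updates
#'
#' Exposed mainly for inspection and testing; [attraction_repulsion()] drives
#' them to convergence. `attraction_step()` moves each node toward its mesh
#' neighbors; `repulsion_step()` applies the all-pairs inverse-square push
#' `C''_i = C'_i + cr/(2I) * sum_j (C'_i - C'_j)/||C'_i - C'_j||^2`. Neither
#' renormalizes; coincident pairs are skipped (reported via attribute
#' `skipped`).
#'
#' @param coords Numeric matrix (I x 3) of current node positions.
#' @param mesh The source `rccad_mesh` (for the neighbor sets).
#' @param params A `rccad_ar_params`.
#' @return Updated coordinate matrix with attribute `skipped`.
#' @export
attraction_step <- function(coords, mesh, params = ar_params()) {
  if (nrow(coords) != length(mesh$neighbors)) {
    abort("coords must have one row per mesh vertex")
  }
  csr <- neighbors_csr(mesh$neighbors)
  res <- cpp_attraction(as.matrix(coords), csr$ptr, csr$idx, params$ca1, params$ca2,
                        identical(params$attraction_form, "product"))
  structure(res$coords, skipped = res$skipped)
}

#' @rdname attraction_step
#' @export
repulsion_step <- function(coords, params = ar_params()) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) abort("repulsion needs at least two nodes")
  res <- cpp_repulsion(coords, params$cr)
  structure(res$coords, skipped = res$skipped)
}

#' Attraction-repulsion spherical parameterization
#'
#' Iteratively maps a genus-0 tumor mesh onto the unit sphere: each iteration
#' applies the attraction step, the repulsion step, and reprojection to unit
#' norm, until the maximum per-vertex displacement falls to
#' `params$threshold` or `params$max_iterations` is reached. The final map is
#' a one-to-one correspondence between mesh vertices and unit-sphere points
#' with the mesh topology preserved.
#'
#' @inheritParams initial_spherical_map
#' @param params A [ar_params()] object.
#' @param seed Seed for the (rare) tie-breaking jitter applied when the
#'   initial projection maps two vertices onto the same point. Default 17.
#' @return A `rccad_spherical_map`; `iterations_run` holds the terminal
#'   iteration count and `converged` whether the displacement threshold was
#'   met before the iteration cap.
#' @export
attraction_repulsion <- function(mesh, params = ar_params(), mask = NULL,
                                 origin = NULL, seed = 17) {
  map0 <- tryCatch(
    initial_spherical_map(mesh, mask = mask, origin = origin),
    error = function(e) {
      if (!grepl("same point", conditionMessage(e))) stop(e)
      # duplicate images: seeded jitter then reproject
      set.seed(seed)
      o <- if (is.null(origin)) choose_origin(mesh, mask) else origin
      rel <- sweep(mesh$vertices, 2, o)
      r <- sqrt(rowSums(rel^2))
      u <- rel / r + matrix(rnorm(length(rel), sd = 1e-8), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      spherical_map(u, mesh, origin = o, radii = r, iterations_run = 0L, converged = NA)
    })
  csr <- neighbors_csr(mesh$neighbors)
  u <- map0$unit_coords
  product <- identical(params$attraction_form, "product")
  converged <- FALSE
  iters <- 0L
  for (alpha in seq_len(params$max_iterations)) {
    att <- cpp_attraction(u, csr$ptr, csr$idx, params$ca1, params$ca2, product)
    rep_ <- cpp_repulsion(att$coords, params$cr)
    if (rep_$skipped > 0) {
      abort(sprintf("degenerate collapse: %d coincident vertex pairs during repulsion", rep_$skipped))
    }
    unew <- rep_$coords / sqrt(rowSums(rep_$coords^2))
    disp <- max(sqrt(rowSums((unew - u)^2)))
    u <- unew
    iters <- alpha
    if (disp <= params$threshold) { converged <- TRUE; break }
  }
  if (!converged) {
    message(sprintf("attraction-repulsion stopped at the %d-iteration cap (max displacement still > %g)",
                    iters, params$threshold))
  }
  spherical_map(u, mesh, origin = map0$origin, radii = map0$radii,
                iterations_run = iters, converged = converged)
}
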