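# Fixtures built in code: digitized balls, icospheres, small phantoms, and a
# memoized full-resolution phantom extraction shared by the acceptance tests.

ball_mask <- function(radius = 10, dims = rep(2 * radius + 9, 3), spacing = c(1, 1, 1)) {
  ctr <- (dims - 1) / 2
  idx <- expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1,
                     z = seq_len(dims[3]) - 1)
  d2 <- ((idx$x - ctr[1]) * spacing[1])^2 + ((idx$y - ctr[2]) * spacing[2])^2 +
    ((idx$z - ctr[3]) * spacing[3])^2
  tumor_mask(array(d2 <= radius^2, dims), spacing)
}

# geodesic sphere with exact radius: subdivided icosahedron, vertices projected
icosphere <- function(subdivisions = 3, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v / sqrt(rowSums(v^2)), f)
  for (s in seq_len(subdivisions)) {
    mesh <- subdivide_mesh(mesh)
    mesh$vertices <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  }
  mesh$vertices <- mesh$vertices * radius
  mesh
}

# small, fast phantom for component tests (low SH order budget)
small_spec <- function(class_label = "ccRCC", seed = 4, amplitude = NULL,
                       max_degree = NULL) {
  phantom_spec(class_label, base_radius = 6, grid_shape = c(32, 32, 32),
               shape_bump_amplitude = amplitude, shape_bump_max_degree = max_degree,
               seed = seed)
}

fast_ar <- function(max_iterations = 10) ar_params(max_iterations = max_iterations)

# configuration used for full-resolution acceptance runs: published protocol
# values plus the package's budgeted compute settings (capped
# attraction-repulsion iterations, capped single-precision SH fit)
acceptance_config <- function(seed = 17, repeats = 1) {
  rccad_config(ar = ar_params(max_iterations = 10),
               sh_precision = "single", sh_fit_max_vertices = 5045,
               repeats = repeats, seed = seed)
}

# one full-resolution malignant phantom with its mesh, map and features,
# computed once per test run and shared
acceptance_subject_cache <- new.env(parent = emptyenv())
full_phantom_fixture <- function() {
  if (is.null(acceptance_subject_cache$fx)) {
    cfg <- acceptance_config(seed = 23)
    subj <- generate_subject(phantom_spec("ccRCC", seed = 23))
    mesh <- extract_mesh(subj$mask)
    mesh <- laplacian_smooth(mesh, cfg$smooth_iterations, cfg$smooth_step)
    mesh <- ensure_vertex_count(mesh, cfg$sh_orders)
    map <- suppressMessages(attraction_repulsion(mesh, cfg$ar, mask = subj$mask))
    shre <- shre_features(mesh, map, n_orders = cfg$sh_orders,
                          precision = cfg$sh_precision,
                          fit_max_vertices = cfg$sh_fit_max_vertices)
    feats <- suppressMessages(extract_subject_features(subj, cfg, subject_id = "FX1"))
    acceptance_subject_cache$fx <- list(cfg = cfg, subj = subj, mesh = mesh,
                                        map = map, shre = shre, feats = feats)
  }
  acceptance_subject_cache$fx
}

# toy 94-feature cohort with class-dependent shifts, for classifier plumbing
toy_feature_cohort <- function(n_aml = 12, n_cc = 8, n_ncc = 8, seed = 99,
                               shift = 3) {
  set.seed(seed)
  n <- n_aml + n_cc + n_ncc
  labels <- rep(c("AML", "ccRCC", "nccRCC"), c(n_aml, n_cc, n_ncc))
  mu <- c(AML = 0, ccRCC = shift, nccRCC = shift / 2)
  X <- matrix(rnorm(n * 94), n, 94) + mu[labels]
  colnames(X) <- feature_columns()
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("T%02d", seq_len(n)),
                                  label = labels),
                   tibble::as_tibble(X))
}
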