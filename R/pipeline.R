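#' Pipeline run configuration
#'
#' Collects every tunable of the feature-extraction and evaluation pipeline in
#' one serializable object. Defaults follow the published protocol where one
#' is stated (phase times 0/80/300 s, SHRE order 70, 26-voxel neighborhood,
#' MLP 50+25 with the trainlm stopping criteria) and the package's documented
#' choices elsewhere.
#'
#' @param smooth_iterations,smooth_step Laplacian smoothing of the extracted
#'   mesh.
#' @param ar [ar_params()] for the spherical parameterization.
#' @param sh_orders SHRE order count (feature-set size).
#' @param sh_ridge Ridge for the SH normal equations.
#' @param sh_precision `"double"` or `"single"` (see [fit_sh()]).
#' @param sh_fit_max_vertices Cap on surface samples entering the SH fit.
#' @param texture_phase Phase feeding texture extraction.
#' @param glcm_max_mm Optional physical distance cutoff for the co-occurrence
#'   neighborhood (`NULL` = plain 26-neighborhood).
#' @param phase_times Acquisition times (s) of the three phases.
#' @param mlp A [mlp_spec()].
#' @param scheme,repeats Evaluation scheme and repeat count.
#' @param seed Base seed of the run.
#' @return A list of class `rccad_config`.
#' @export
rccad_config <- function(smooth_iterations = 10, smooth_step = 0.5,
                         ar = ar_params(),
                         sh_orders = 70, sh_ridge = 1e-10,
                         sh_precision = "double",
                         sh_fit_max_vertices = Inf,
                         texture_phase = "portal_venous",
                         glcm_max_mm = NULL,
                         phase_times = c(0, 80, 300),
                         mlp = mlp_spec(),
                         scheme = "loso", repeats = 10, seed = 17) {
  cfg <- list(smooth_iterations = smooth_iterations, smooth_step = smooth_step,
              ar = ar, sh_orders = as.integer(sh_orders), sh_ridge = sh_ridge,
              sh_precision = match.arg(sh_precision, c("double", "single")),
              sh_fit_max_vertices = sh_fit_max_vertices,
              texture_phase = match.arg(texture_phase,
                                        c("portal_venous", "precontrast", "delayed")),
              glcm_max_mm = glcm_max_mm,
              phase_times = as.numeric(phase_times),
              mlp = mlp,
              scheme = match.arg(scheme, c("loso", "stratified_10fold")),
              repeats = as.integer(repeats), seed = as.integer(seed))
  problems <- character(0)
  if (cfg$smooth_iterations < 0) problems <- c(problems, "smooth_iterations must be >= 0")
  if (cfg$sh_orders < 1) problems <- c(problems, "sh_orders must be >= 1")
  if (length(cfg$phase_times) != 3 || any(diff(cfg$phase_times) <= 0)) {
    problems <- c(problems, "phase_times must be 3 strictly increasing times")
  }
  if (cfg$repeats < 1) problems <- c(problems, "repeats must be >= 1")
  if (length(problems)) abort(paste(c("invalid configuration:", problems), collapse = "\n- "))
  structure(cfg, class = "rccad_config")
}

#' Serialize / restore a run configuration
#'
#' JSON round-trips are stable, which is what makes manifest-driven reruns
#' reproducible.
#'
#' @param config A `rccad_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$ar <- do.call(ar_params, raw$ar)
  raw$mlp <- do.call(mlp_spec, raw$mlp[setdiff(names(raw$mlp), NULL)])
  if (is.null(raw$sh_fit_max_vertices) || !is.finite(raw$sh_fit_max_vertices)) {
    raw$sh_fit_max_vertices <- Inf
  }
  do.call(rccad_config, raw)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Extract the combined 94-feature record of one subject
#'
#' Runs the full feature chain on three aligned phase volumes and a mask:
#' mesh extraction, Laplacian smoothing and (if needed) Loop subdivision;
#' attraction-repulsion spherical mapping and the 70 SHRE morphology
#' features; contrast stretching, first-order histogram/percentile and
#' GLCM texture features of the configured phase; and the wash-in/wash-out
#' kinetic slopes. Deterministic for a given configuration.
#'
#' @param subject A `rccad_phantom_subject`, or a list with elements
#'   `volumes` (list of three `rccad_volume`s) and `mask`.
#' @param config A [rccad_config()].
#' @param subject_id Identifier stored in the output row.
#' @return A one-row tibble: `subject_id`, optional `label`, and the 94
#'   canonical feature columns.
#' @export
extract_subject_features <- function(subject, config = rccad_config(),
                                     subject_id = "subject") {
  vols <- subject$volumes
  if (length(vols) != 3) {
    abort("functional_features: need precontrast, portal_venous and delayed volumes")
  }
  phases <- vapply(vols, function(v) v$phase, character(1))
  need <- c("precontrast", "portal_venous", "delayed")
  if (!setequal(phases, need)) {
    abort(sprintf("functional_features: missing phase(s) %s",
                  paste(setdiff(need, phases), collapse = ", ")))
  }
  vols <- vols[match(need, phases)]
  for (k in 1:3) vols[[k]]$acquisition_time <- config$phase_times[k]
  mask <- subject$mask
  for (v in vols) check_aligned(v, mask)

  # morphology
  mesh <- extract_mesh(mask)
  mesh <- laplacian_smooth(mesh, config$smooth_iterations, config$smooth_step)
  mesh <- ensure_vertex_count(mesh, config$sh_orders)
  map <- attraction_repulsion(mesh, config$ar, mask = mask, seed = config$seed)
  shre <- shre_features(mesh, map, n_orders = config$sh_orders,
                        ridge = config$sh_ridge, precision = config$sh_precision,
                        fit_max_vertices = config$sh_fit_max_vertices,
                        subsample_seed = config$seed)

  # texture
  tex <- texture_features(vols[[match(config$texture_phase, need)]], mask,
                          max_mm = config$glcm_max_mm)

  # kinetics
  kin <- kinetic_features(enhancement_curve(vols, mask))

  vec <- assemble_features(
    histogram = unlist(tex[1, 1:6]),
    percentiles = unlist(tex[1, 7:16]),
    glcm = unlist(tex[1, 17:22]),
    shre = as.numeric(shre),
    kinetics = c(kin$wash_in, kin$wash_out)
  )
  out <- tibble::as_tibble(as.list(vec))
  out <- dplyr::mutate(out, subject_id = subject_id, .before = 1)
  if (!is.null(subject$truth$class_label)) {
    out <- dplyr::mutate(out, label = subject$truth$class_label, .after = 1)
  }
  out
}

#' Extract features for a whole cohort
#'
#' @param cohort A `rccad_cohort` (or list of subjects).
#' @param config A [rccad_config()].
#' @param progress Emit a message every 20 subjects.
#' @return Tibble with one row per subject.
#' @export
extract_cohort_features <- function(cohort, config = rccad_config(), progress = FALSE) {
  subjects <- if (inherits(cohort, "rccad_cohort")) cohort$subjects else cohort
  ids <- names(subjects) %||% sprintf("S%03d", seq_along(subjects))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    rows[[i]] <- extract_subject_features(subjects[[i]], config, subject_id = ids[i])
    if (progress && i %% 20 == 0) message(sprintf("extracted %d/%d subjects", i, length(subjects)))
  }
  dplyr::bind_rows(rows)
}

#' End-to-end phantom experiment
#'
#' Simulates a cohort (or accepts a precomputed feature table), extracts the
#' 94 combined features and evaluates the two-stage classifier, returning the
#' evaluation report plus a manifest (configuration, seeds, package version,
#' cohort truth) sufficient to reproduce the run.
#'
#' @param config A [rccad_config()].
#' @param n_aml,n_ccrcc,n_nccrcc Cohort composition (defaults mirror the
#'   140-subject study: 70/40/30).
#' @param features Optional precomputed feature tibble; skips simulation.
#' @param progress Passed to [extract_cohort_features()].
#' @return A list of class `rccad_experiment`: `report` (a `rccad_eval`),
#'   `features`, `manifest`.
#' @export
run_experiment <- function(config = rccad_config(), n_aml = 70, n_ccrcc = 40,
                           n_nccrcc = 30, features = NULL, progress = FALSE) {
  truth <- NULL
  if (is.null(features)) {
    cohort <- generate_cohort(n_aml, n_ccrcc, n_nccrcc, seed = config$seed)
    features <- extract_cohort_features(cohort, config, progress = progress)
    truth <- cohort$truth
  }
  report <- evaluate_cohort(features, spec = config$mlp, scheme = config$scheme,
                            repeats = config$repeats, seed = config$seed)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rccad")),
    config = unclass_deep(config),
    cohort = if (!is.null(truth)) list(n = nrow(truth), truth = truth) else NULL,
    seed = config$seed
  )
  structure(list(report = report, features = features, manifest = manifest),
            class = "rccad_experiment")
}

#' @export
print.rccad_experiment <- function(x, ...) {
  cat("<rccad experiment>\n")
  print(glance(x$report))
  invisible(x)
}
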