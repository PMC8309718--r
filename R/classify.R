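#' Canonical feature layout
#'
#' The 94 combined features, in fixed order: 6 first-order histogram features,
#' 10 gray-level percentiles, 6 GLCM features, 70 SH reconstruction errors and
#' 2 enhancement-kinetic slopes.
#'
#' @return Character vector of the 94 feature column names.
#' @export
feature_columns <- function() {
  c(paste0("hist_", c("mean", "variance", "sd", "skewness", "kurtosis", "entropy")),
    sprintf("p%d", seq(10, 100, 10)),
    paste0("glcm_", c("contrast", "dissimilarity", "homogeneity", "asm", "energy", "correlation")),
    sprintf("shre_%02d", 1:70),
    c("wash_in", "wash_out"))
}

block_sizes <- c(histogram = 6L, percentiles = 10L, glcm = 6L, shre = 70L, kinetics = 2L)

#' Assemble the combined 94-feature vector
#'
#' Concatenates the five feature blocks in the canonical order (histogram,
#' percentiles, GLCM, SHRE, kinetics) after checking their lengths
#' (6/10/6/70/2).
#'
#' @param histogram,percentiles,glcm,shre,kinetics Numeric blocks.
#' @return Named numeric vector of length 94 (names from
#'   [feature_columns()]).
#' @export
assemble_features <- function(histogram, percentiles, glcm, shre, kinetics) {
  blocks <- list(histogram = as.numeric(histogram), percentiles = as.numeric(percentiles),
                 glcm = as.numeric(glcm), shre = as.numeric(shre),
                 kinetics = as.numeric(kinetics))
  for (nm in names(block_sizes)) {
    if (length(blocks[[nm]]) != block_sizes[[nm]]) {
      abort(sprintf("%s expected %d features, got %d", nm, block_sizes[[nm]], length(blocks[[nm]])))
    }
    if (anyNA(blocks[[nm]]) || any(!is.finite(blocks[[nm]]))) {
      abort(sprintf("%s block contains missing or non-finite values", nm))
    }
  }
  setNames(unlist(blocks, use.names = FALSE), feature_columns())
}

#' Two-stage diagnosis of one feature record
#'
#' Stage 1 decides malignant (RCC) vs. benign (AML); only if malignant does
#' stage 2 refine the call to ccRCC vs. nccRCC.
#'
#' @param features Named numeric vector (or one-row data frame) with the 94
#'   canonical features.
#' @param stage1 Trained `rccad_mlp` for RCC-vs-AML (positive = malignant).
#' @param stage2 Trained `rccad_mlp` for ccRCC-vs-nccRCC (positive = ccRCC).
#' @return `"AML"`, `"ccRCC"` or `"nccRCC"`.
#' @export
two_stage_predict <- function(features, stage1, stage2) {
  x <- features_matrix(features)
  malignant <- predict(stage1, x, type = "prob") > 0.5
  out <- rep("AML", nrow(x))
  if (any(malignant)) {
    cc <- predict(stage2, x[malignant, , drop = FALSE], type = "prob") > 0.5
    out[malignant] <- ifelse(cc, "ccRCC", "nccRCC")
  }
  out
}

features_matrix <- function(features) {
  cols <- feature_columns()
  if (is.data.frame(features)) {
    missing_cols <- setdiff(cols, names(features))
    if (length(missing_cols)) {
      abort(sprintf("missing feature columns: %s", paste(head(missing_cols, 5), collapse = ", ")))
    }
    as.matrix(features[, cols])
  } else {
    m <- matrix(as.numeric(features), nrow = 1)
    if (ncol(m) != length(cols)) abort(sprintf("expected %d features, got %d", length(cols), ncol(m)))
    colnames(m) <- cols
    m
  }
}

#' Confusion-matrix classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), Dice similarity
#' coefficient 2TP/(2TP+FP+FN) and accuracy (TP+TN)/total.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return A one-row tibble with the four metrics and the counts.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  tibble(sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         dsc = 2 * tp / (2 * tp + fp + fn),
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Cross-validated two-stage evaluation of a feature cohort
#'
#' Runs the complete diagnostic evaluation on a per-subject feature table:
#' stage 1 (malignant vs. benign, malignant positive) on all subjects and
#' stage 2 (ccRCC vs. nccRCC, ccRCC positive) on the ground-truth malignant
#' subjects, under leave-one-subject-out or randomly stratified 10-fold
#' cross-validation, repeated `repeats` times with seeds
#' `seed, seed + 1, ...`. Metrics are reported per repeat; [glance()] gives
#' the mean and standard deviation across repeats.
#'
#' Features are z-scored inside [mlp_train()] with training-fold statistics
#' only, so no test information leaks into the fit.
#'
#' @param features Tibble with `subject_id`, `label`
#'   (`AML`/`ccRCC`/`nccRCC`) and the 94 canonical feature columns.
#' @param spec A [mlp_spec()].
#' @param scheme `"loso"` or `"stratified_10fold"`.
#' @param repeats Number of evaluation repeats (paper protocol: 10).
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @return An object of class `rccad_eval` with elements `metrics` (per
#'   repeat and stage), `predictions`, `confusion` (aggregate counts),
#'   `scheme`, `repeats`, `seed`.
#' @export
evaluate_cohort <- function(features, spec = mlp_spec(),
                            scheme = c("loso", "stratified_10fold"),
                            repeats = 10, seed = 17) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(features), repeats >= 1)
  labs <- as.character(features$label)
  if (!all(labs %in% c("AML", "ccRCC", "nccRCC"))) {
    abort("labels must be AML, ccRCC or nccRCC")
  }
  X <- features_matrix(features)
  n <- nrow(X)
  y1 <- factor(ifelse(labs == "AML", "benign", "malignant"),
               levels = c("benign", "malignant"))
  rcc <- which(labs != "AML")
  y2 <- factor(ifelse(labs[rcc] == "nccRCC", "nccRCC", "ccRCC"),
               levels = c("nccRCC", "ccRCC"))
  metrics <- list()
  preds <- list()
  for (r in seq_len(repeats)) {
    rs <- seed + r - 1L
    p1 <- cv_binary(X, y1, spec, scheme, rs)
    p2 <- cv_binary(X[rcc, , drop = FALSE], y2, spec, scheme, rs)
    m1 <- classification_metrics(
      tp = sum(p1 == "malignant" & y1 == "malignant"),
      fn = sum(p1 == "benign" & y1 == "malignant"),
      tn = sum(p1 == "benign" & y1 == "benign"),
      fp = sum(p1 == "malignant" & y1 == "benign"))
    m2 <- classification_metrics(
      tp = sum(p2 == "ccRCC" & y2 == "ccRCC"),
      fn = sum(p2 == "nccRCC" & y2 == "ccRCC"),
      tn = sum(p2 == "nccRCC" & y2 == "nccRCC"),
      fp = sum(p2 == "ccRCC" & y2 == "nccRCC"))
    metrics[[r]] <- dplyr::bind_rows(
      dplyr::mutate(m1, stage = "stage1_rcc_vs_aml", .before = 1),
      dplyr::mutate(m2, stage = "stage2_ccrcc_vs_nccrcc", .before = 1))
    metrics[[r]]$repeat_id <- r
    stage2_pred <- rep(NA_character_, n)
    stage2_pred[rcc] <- as.character(p2)
    preds[[r]] <- tibble(subject_id = features$subject_id, repeat_id = r,
                         label = labs, stage1 = as.character(p1),
                         stage2 = stage2_pred)
  }
  metrics <- dplyr::bind_rows(metrics)
  confusion <- metrics |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(dplyr::across(c("tp", "fn", "tn", "fp"), sum), .groups = "drop")
  structure(list(metrics = metrics, predictions = dplyr::bind_rows(preds),
                 confusion = confusion, scheme = scheme,
                 repeats = repeats, seed = seed),
            class = "rccad_eval")
}

# cross-validated out-of-fold class predictions for one binary problem
cv_binary <- function(X, y, spec, scheme, seed) {
  n <- nrow(X)
  folds <- if (scheme == "loso") {
    as.list(seq_len(n))
  } else {
    stratified_folds(y, k = 10, seed = seed)
  }
  pred <- factor(rep(levels(y)[1], n), levels = levels(y))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    model <- mlp_train(X[train, , drop = FALSE], y[train], spec,
                       seed = seed + 1000L * f)
    pred[test] <- predict(model, X[test, , drop = FALSE], type = "class")
  }
  pred
}

# stratified k-fold assignment; re-draws with the next seed if a fold would
# lose a class entirely from its training complement
stratified_folds <- function(y, k = 10, seed = 17) {
  for (attempt in 0:20) {
    set.seed(seed + attempt)
    fold_of <- integer(length(y))
    for (cl in levels(y)) {
      ic <- sample(which(y == cl))
      fold_of[ic] <- rep_len(seq_len(k), length(ic))
    }
    folds <- split(seq_along(y), fold_of)
    ok <- all(vapply(folds, function(te) {
      length(unique(y[-te])) == nlevels(y) && min(table(y[-te])) >= 2
    }, logical(1)))
    if (ok) {
      if (attempt > 0) message(sprintf("re-stratified folds with seed offset %d", attempt))
      return(folds)
    }
  }
  abort("could not stratify folds with both classes in every training split")
}
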