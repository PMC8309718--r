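# minimal MLP-compatible stub that always outputs `prob`
constant_mlp <- function(prob, p = 94, levels = c("a", "b")) {
  bias <- -log(1 / prob - 1)
  structure(list(
    weights = list(W = list(matrix(0, p, 2), matrix(0, 2, 1)),
                   b = list(c(0, 0), bias)),
    sizes = c(p, 2, 1), center = rep(0, p), scale = rep(1, p),
    levels = levels, optimizer = "stub",
    history = tibble::tibble(), stopped_by = "stub", seed = 0
  ), class = "rccad_mlp")
}

test_that("feature assembly enforces the 6/10/6/70/2 block layout", {
  vec <- assemble_features(histogram = 1:6, percentiles = 1:10, glcm = 1:6,
                           shre = rep(0.5, 70), kinetics = c(1, 0.1))
  expect_length(vec, 94)
  expect_identical(names(vec), feature_columns())
  # kinetics occupy the final two positions
  expect_equal(unname(vec[93:94]), c(1, 0.1))
  expect_equal(names(vec)[93:94], c("wash_in", "wash_out"))

  expect_error(assemble_features(1:6, 1:10, 1:6, rep(0, 69), c(1, 2)),
               "shre expected 70")
  expect_error(assemble_features(1:5, 1:10, 1:6, rep(0, 70), c(1, 2)),
               "histogram expected 6")
  expect_error(assemble_features(1:6, 1:10, 1:6, c(NA, rep(0, 69)), c(1, 2)),
               "missing")
})

test_that("the two-stage cascade stops at a benign stage-1 call", {
  rec <- setNames(rnorm(94), feature_columns())
  benign <- constant_mlp(0.1)
  malignant <- constant_mlp(0.9)
  cc <- constant_mlp(0.9)
  ncc <- constant_mlp(0.1)
  expect_equal(two_stage_predict(rec, benign, cc), "AML")
  expect_equal(two_stage_predict(rec, benign, ncc), "AML") # stage 2 irrelevant
  expect_equal(two_stage_predict(rec, malignant, cc), "ccRCC")
  expect_equal(two_stage_predict(rec, malignant, ncc), "nccRCC")
})

test_that("classification metrics match hand-computed confusion matrices", {
  perfect <- classification_metrics(tp = 10, fn = 0, tn = 12, fp = 0)
  expect_equal(unlist(perfect[, c("sensitivity", "specificity", "dsc", "accuracy")]),
               c(sensitivity = 1, specificity = 1, dsc = 1, accuracy = 1))

  m <- classification_metrics(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$dsc, 18 / 21)
  expect_equal(m$accuracy, 17 / 20)

  # DSC equals the precision/sensitivity harmonic mean on random confusions
  set.seed(14)
  for (i in 1:20) {
    cm <- as.list(sample(1:30, 4))
    names(cm) <- c("tp", "fn", "tn", "fp")
    mm <- do.call(classification_metrics, cm)
    prec <- cm$tp / (cm$tp + cm$fp)
    expect_equal(mm$dsc, 2 * prec * mm$sensitivity / (prec + mm$sensitivity))
  }
})

test_that("stratified folds preserve class proportions within one subject", {
  y <- factor(rep(c("a", "b"), c(70, 70)))
  folds <- rccad:::stratified_folds(y, k = 10, seed = 5)
  expect_length(folds, 10)
  expect_equal(sort(unname(unlist(folds))), 1:140)
  for (f in folds) {
    tab <- table(y[f])
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
})

test_that("cohort evaluation reports both stages with the right bookkeeping", {
  feats <- toy_feature_cohort()
  spec <- mlp_spec(hidden = c(5), max_epochs = 60, val_fraction = 0)
  ev <- evaluate_cohort(feats, spec, scheme = "stratified_10fold",
                        repeats = 2, seed = 5)
  td <- tidy(ev)
  expect_equal(nrow(td), 4) # 2 stages x 2 repeats
  expect_true(all(td$sensitivity >= 0 & td$sensitivity <= 1))
  g <- glance(ev)
  expect_equal(nrow(g), 8)
  expect_true(all(g$sd >= 0))
  # confusion counts sum to the evaluated subjects
  conf <- ev$confusion
  n_all <- sum(conf[conf$stage == "stage1_rcc_vs_aml", c("tp", "fn", "tn", "fp")])
  expect_equal(n_all, nrow(feats) * 2)
  n_rcc <- sum(conf[conf$stage == "stage2_ccrcc_vs_nccrcc", c("tp", "fn", "tn", "fp")])
  expect_equal(n_rcc, sum(feats$label != "AML") * 2)
  # per-repeat predictions cover every subject in every repeat
  expect_equal(nrow(ev$predictions), 2 * nrow(feats))

  # strongly separated toy classes should be learned nearly perfectly
  expect_gt(mean(td$accuracy[td$stage == "stage1_rcc_vs_aml"]), 0.85)

  ev1 <- evaluate_cohort(feats, spec, scheme = "loso", repeats = 1, seed = 5)
  expect_equal(glance(ev1)$sd, rep(0, 8)) # single repeat: zero SD
  expect_error(evaluate_cohort(dplyr::mutate(feats, label = "kidney"), spec),
               "labels")
})
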