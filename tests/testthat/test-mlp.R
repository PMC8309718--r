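sep_toy <- function(n = 10, gap = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n), n, 2), matrix(rnorm(2 * n, gap), n, 2))
  list(x = x, y = rep(c(0, 1), each = n))
}

test_that("both optimizers drive a separable toy problem to perfect accuracy", {
  toy <- sep_toy()
  for (opt in c("lm", "rprop")) {
    m <- mlp_train(toy$x, toy$y, mlp_spec(hidden = 5, val_fraction = 0,
                                          optimizer = opt), seed = 3)
    expect_equal(mean((predict(m, toy$x, "prob") > 0.5) == toy$y), 1,
                 info = opt)
  }
})

test_that("training is deterministic given a seed", {
  toy <- sep_toy()
  sp <- mlp_spec(hidden = c(6, 3), val_fraction = 0, optimizer = "rprop",
                 max_epochs = 100)
  m1 <- mlp_train(toy$x, toy$y, sp, seed = 11)
  m2 <- mlp_train(toy$x, toy$y, sp, seed = 11)
  expect_identical(predict(m1, toy$x, "prob"), predict(m2, toy$x, "prob"))
  m3 <- mlp_train(toy$x, toy$y, sp, seed = 12)
  expect_false(identical(predict(m1, toy$x, "prob"), predict(m3, toy$x, "prob")))
})

test_that("label-permuted data yields chance-level LOSO accuracy", {
  set.seed(21)
  n <- 24
  x <- matrix(rnorm(2 * n), n, 2)
  y <- sample(rep(c(0, 1), each = n / 2)) # labels carry no signal
  sp <- mlp_spec(hidden = 4, val_fraction = 0, optimizer = "lm", max_epochs = 60)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- mlp_train(x[-i, ], y[-i], sp, seed = 100 + i)
    pred[i] <- predict(m, x[i, , drop = FALSE], "prob") > 0.5
  }
  acc <- mean(pred == y)
  # within binomial noise of 0.5 (3 sigma ~ 0.31)
  expect_gt(acc, 0.18)
  expect_lt(acc, 0.82)
})

test_that("degenerate training sets and inputs are rejected or guarded", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(mlp_train(x, rep(1, 10)), "single class")
  expect_error(mlp_train(x, c(1, rep(0, 9))), "at least 2")
  # constant feature columns must not poison standardization
  x2 <- cbind(x, 7)
  toy <- mlp_train(x2, rep(c(0, 1), 5), mlp_spec(hidden = 3, val_fraction = 0,
                                                 max_epochs = 20), seed = 2)
  expect_true(all(is.finite(predict(toy, x2, "prob"))))
})

test_that("stopping criteria are honored and reported", {
  toy <- sep_toy()
  m <- mlp_train(toy$x, toy$y, mlp_spec(hidden = 5, val_fraction = 0,
                                        optimizer = "lm"), seed = 3)
  expect_true(m$stopped_by %in% c("min_gradient", "goal", "max_epochs", "mu_max"))
  expect_lte(nrow(m$history), 500)
  m2 <- mlp_train(toy$x, toy$y, mlp_spec(hidden = 5, val_fraction = 0,
                                         optimizer = "rprop", max_epochs = 7),
                  seed = 3)
  expect_equal(nrow(m2$history), 7)
  g <- glance(m2)
  expect_equal(g$epochs, 7)
  expect_equal(g$optimizer, "rprop")
})

test_that("auto optimizer selection follows the parameter-count cutoff", {
  toy <- sep_toy()
  small <- mlp_train(toy$x, toy$y, mlp_spec(hidden = 3, val_fraction = 0,
                                            max_epochs = 10), seed = 1)
  expect_equal(small$optimizer, "lm")
  big <- mlp_train(matrix(rnorm(40 * 94), 40, 94), rep(c(0, 1), 20),
                   mlp_spec(max_epochs = 5, val_fraction = 0), seed = 1)
  expect_equal(big$optimizer, "rprop") # 50x25 net exceeds the LM cutoff
})
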