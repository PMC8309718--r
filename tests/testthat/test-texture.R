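stretch_fixture <- function(values, dims = NULL, spacing = c(1, 1, 1)) {
  n <- length(values)
  if (is.null(dims)) dims <- c(n, 1, 1)
  vol <- ct_volume(array(values, dims), spacing)
  mask <- tumor_mask(array(TRUE, dims), spacing)
  contrast_stretch(vol, mask)
}

test_that("contrast stretching maps the tumor range onto 0..255", {
  st <- stretch_fixture(c(10, 20, 30))
  expect_equal(sort(rccad:::stretched_values(st)), c(0, 127, 255))
  expect_true(all(st$grid[!st$mask$grid] == -1L | all(st$mask$grid)))

  expect_equal(unique(rccad:::stretched_values(stretch_fixture(rep(50, 8), c(2, 2, 2)))), 0L)

  st3 <- stretch_fixture(c(0, 100, 255))
  v <- rccad:::stretched_values(st3)
  expect_equal(v[c(1, 3)], c(0L, 255L))

  # monotone: quantization never inverts the rank order of voxel values
  set.seed(2)
  x <- sample(-500:1500, 200)
  stm <- stretch_fixture(x, c(200, 1, 1))
  expect_true(all(diff(rccad:::stretched_values(stm)[order(x)]) >= 0))
})

test_that("first-order features match closed forms and conventions", {
  two <- first_order_features(stretch_fixture(c(0, 255), c(2, 1, 1)))
  expect_equal(two$mean, 127.5)
  expect_equal(two$variance, 16256.25)
  expect_equal(two$skewness, 0)
  expect_equal(two$standard_deviation, sqrt(two$variance))
  expect_equal(unname(two$percentiles[10]), 255) # p100 = max
  expect_equal(two$cdf[256], 1)

  # uniform histogram over all 256 levels: entropy exactly 8 bits
  uni <- first_order_features(stretch_fixture(rep(0:255, 4), c(1024, 1, 1)))
  expect_equal(uni$entropy, 8)
  expect_false(is.unsorted(uni$percentiles))

  # large quantized normal sample: non-excess kurtosis ~ 3
  set.seed(41)
  x <- rnorm(2e5)
  norm_fo <- first_order_features(stretch_fixture(x, c(length(x), 1, 1)))
  expect_equal(norm_fo$kurtosis, 3, tolerance = 0.05)
  expect_equal(norm_fo$skewness, 0, tolerance = 0.05)

  expect_error(first_order_features(stretch_fixture(5, c(1, 1, 1))), "at least 2")
})

test_that("GLCM accumulation matches hand counts and stays 256 x 256", {
  # 2-voxel tumor (0, 255): one symmetric pair
  g <- build_glcm(stretch_fixture(c(0, 255), c(2, 1, 1)))
  expect_equal(dim(g$counts), c(256L, 256L))
  expect_equal(g$counts[1, 256], 1)
  expect_equal(g$counts[256, 1], 1)
  expect_equal(sum(g$counts), 2)
  expect_equal(sum(g$normalized), 1)

  # constant tumor: all mass at (0, 0)
  gc <- build_glcm(stretch_fixture(rep(7, 27), c(3, 3, 3)))
  expect_equal(gc$normalized[1, 1], 1)
  expect_equal(sum(gc$normalized), 1)
})

test_that("GLCM equals an exhaustive ordered-pair enumeration oracle", {
  set.seed(12)
  dims <- c(4, 4, 2)
  vals <- array(sample(0:255, prod(dims), replace = TRUE), dims)
  st <- stretch_fixture(vals, dims)
  got <- build_glcm(st)$counts

  oracle <- matrix(0, 256, 256)
  idx <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1:2))
  sv <- st$grid
  for (i in seq_len(nrow(idx))) for (j in seq_len(nrow(idx))) {
    if (i == j) next
    d <- abs(idx[i, ] - idx[j, ])
    if (max(d) <= 1) {
      a <- sv[idx[i, 1], idx[i, 2], idx[i, 3]]
      b <- sv[idx[j, 1], idx[j, 2], idx[j, 3]]
      oracle[a + 1, b + 1] <- oracle[a + 1, b + 1] + 1
    }
  }
  expect_equal(got, oracle, ignore_attr = TRUE)
  expect_equal(got, t(got)) # symmetric by construction
})

test_that("the physical distance filter respects anisotropic spacing", {
  # with 2.5 mm slices a 2 mm cutoff keeps only in-plane offsets
  off <- glcm_offsets(spacing = c(1, 1, 2.5), max_mm = 2)
  expect_true(all(off[, 3] == 0))
  expect_equal(nrow(glcm_offsets()), 13) # half of the 26-neighborhood
  expect_error(glcm_offsets(spacing = c(5, 5, 5), max_mm = 2), "excludes")
})

test_that("Haralick features match hand evaluations and identities", {
  delta <- build_glcm(stretch_fixture(rep(3, 8), c(2, 2, 2)))
  so <- second_order_features(delta)
  expect_equal(so$contrast, 0)
  expect_equal(so$dissimilarity, 0)
  expect_equal(so$homogeneity, 1)
  expect_equal(so$asm, 1)
  expect_equal(so$energy, 1)
  expect_equal(so$correlation, 1) # degenerate zero-variance convention

  # two-cell checkerboard: contrast 255^2, dissimilarity 255, ASM 0.5
  g2 <- build_glcm(stretch_fixture(c(0, 255), c(2, 1, 1)))
  so2 <- second_order_features(g2)
  expect_equal(so2$contrast, 65025)
  expect_equal(so2$dissimilarity, 255)
  expect_equal(so2$asm, 0.5)
  expect_equal(so2$energy, sqrt(0.5))
  expect_equal(so2$correlation, -1, tolerance = 1e-12)

  # energy^2 = ASM on random co-occurrence structures
  set.seed(9)
  for (rep in 1:5) {
    dims <- c(5, 4, 3)
    st <- stretch_fixture(sample(0:400, prod(dims), replace = TRUE), dims)
    so_r <- second_order_features(build_glcm(st))
    expect_equal(so_r$energy^2, so_r$asm, tolerance = 1e-12)
    expect_gte(so_r$correlation, -1)
    expect_lte(so_r$correlation, 1)
    expect_gt(so_r$homogeneity, 0)
  }
})

test_that("second-order features are invariant under 90-degree rotations", {
  set.seed(33)
  dims <- c(8, 8, 8)
  vals <- array(sample(0:255, prod(dims), replace = TRUE), dims)
  base <- unlist(second_order_features(build_glcm(stretch_fixture(vals, dims))))
  rots <- list(
    function(a) aperm(a, c(2, 1, 3))[dims[2]:1, , , drop = FALSE], # z-axis 90
    function(a) aperm(a, c(1, 3, 2))[, dims[3]:1, , drop = FALSE], # x-axis 90
    function(a) aperm(a, c(3, 2, 1))[, , dims[1]:1, drop = FALSE]  # y-axis 90
  )
  for (rot in rots) {
    r <- unlist(second_order_features(build_glcm(stretch_fixture(rot(vals), dim(rot(vals))))))
    expect_equal(r, base, tolerance = 1e-9)
  }
})
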