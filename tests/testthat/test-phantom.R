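test_that("phantom shapes are deterministic, centered and genus 0", {
  spec <- small_spec("ccRCC", seed = 31)
  m1 <- generate_shape(spec)
  m2 <- generate_shape(spec)
  expect_identical(m1$grid, m2$grid)

  for (s in c(1, 2, 3)) {
    for (cl in c("AML", "ccRCC", "nccRCC")) {
      msk <- generate_shape(small_spec(cl, seed = s))
      mesh <- extract_mesh(msk)
      expect_equal(euler_characteristic(mesh), 2)
    }
  }

  # a phantom too large for its grid is refused
  expect_error(generate_shape(phantom_spec("AML", base_radius = 14,
                                           grid_shape = c(24, 24, 24))),
               "boundary")
})

test_that("zero-amplitude phantoms digitize a ball", {
  spec <- small_spec("AML", amplitude = 0)
  mask <- generate_shape(spec)
  # compare against the analytic ball with the same center and radius
  dims <- spec$grid_shape
  ctr <- (dims - 1) / 2
  idx <- which(array(TRUE, dims), arr.ind = TRUE) - 1
  inside <- sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= spec$base_radius
  expect_identical(as.vector(mask$grid), as.vector(inside))
})

test_that("surface complexity presets control the SHRE magnitude", {
  shre_mean <- function(amp, deg, seed = 6) {
    msk <- generate_shape(small_spec("ccRCC", amplitude = amp, max_degree = deg,
                                     seed = seed))
    mesh <- ensure_vertex_count(laplacian_smooth(extract_mesh(msk)), 12)
    map <- suppressMessages(attraction_repulsion(mesh, fast_ar(8), mask = msk))
    mean(shre_features(mesh, map, n_orders = 12))
  }
  expect_gt(shre_mean(0.15, 12), shre_mean(0.02, 3))
})

test_that("phantom subjects realize the requested texture and enhancement", {
  # noiseless texture: constant intensity inside the mask in every phase
  spec <- phantom_spec("ccRCC", base_radius = 5, grid_shape = c(24, 24, 24),
                       texture_sd = 0, enhancement = c(30, 110, 88), seed = 2)
  subj <- generate_subject(spec)
  for (v in subj$volumes) {
    expect_equal(stats::var(v$grid[subj$mask$grid]), 0)
  }
  st <- contrast_stretch(subj$volumes$portal_venous, subj$mask)
  expect_equal(second_order_features(build_glcm(st))$homogeneity, 1)
  k <- kinetic_features(enhancement_curve(subj$volumes, subj$mask))
  expect_equal(k$wash_in, 1.0)
  expect_equal(k$wash_out, 0.1)

  # nonzero texture raises in-mask variance roughly to spec
  spec2 <- phantom_spec("ccRCC", base_radius = 6, grid_shape = c(32, 32, 32),
                        texture_sd = 25, seed = 3)
  subj2 <- generate_subject(spec2)
  sd_in <- sd(subj2$volumes$portal_venous$grid[subj2$mask$grid])
  expect_gt(sd_in, 15)
  bg_sd <- sd(subj2$volumes$portal_venous$grid[!subj2$mask$grid])
  expect_lt(bg_sd, 8) # background stays mildly noisy around 0 HU
})

test_that("cohort generation is seeded, labeled and proportioned", {
  co <- generate_cohort(3, 2, 1, seed = 5, grid_shape = c(32, 32, 32),
                        base_radius = 6)
  expect_length(co$subjects, 6)
  expect_equal(table(co$truth$label),
               table(factor(rep(c("AML", "ccRCC", "nccRCC"), c(3, 2, 1)))))
  co2 <- generate_cohort(3, 2, 1, seed = 5, grid_shape = c(32, 32, 32),
                         base_radius = 6)
  expect_identical(co$truth, co2$truth)
  expect_identical(co$subjects$S001$volumes$delayed$grid,
                   co2$subjects$S001$volumes$delayed$grid)

  one <- generate_cohort(1, 0, 0, seed = 1, grid_shape = c(32, 32, 32),
                         base_radius = 6)
  expect_length(one$subjects, 1)
  expect_equal(one$truth$label, "AML")
  expect_error(generate_cohort(0, 0, 0), "at least one")
})
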