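test_that("initial spherical map projects onto the unit sphere bijectively", {
  # mesh already on the unit sphere maps to itself
  ico <- icosphere(2)
  map <- initial_spherical_map(ico)
  expect_equal(map$unit_coords, ico$vertices, tolerance = 1e-9, ignore_attr = TRUE)

  # ellipsoid (20, 15, 10) mm: all norms exactly 1
  ell <- ico
  ell$vertices <- sweep(ico$vertices, 2, c(20, 15, 10), "*")
  m2 <- initial_spherical_map(ell)
  expect_lt(max(abs(sqrt(rowSums(m2$unit_coords^2)) - 1)), 1e-9)
  expect_equal(nrow(m2$unit_coords), nrow(ell$vertices))
  expect_false(any(duplicated(round(m2$unit_coords, 10))))

  # star-shaped bumpy phantom: bijection preserved
  spec <- small_spec("ccRCC")
  mask <- generate_shape(spec)
  mesh <- laplacian_smooth(extract_mesh(mask))
  m3 <- initial_spherical_map(mesh, mask = mask)
  expect_equal(nrow(m3$unit_coords), nrow(mesh$vertices))
  expect_false(any(duplicated(round(m3$unit_coords, 10))))
  # angle/coordinate consistency
  rebuilt <- cbind(sin(m3$theta) * cos(m3$phi), sin(m3$theta) * sin(m3$phi),
                   cos(m3$theta))
  expect_equal(rebuilt, m3$unit_coords, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("attraction step matches the hand-evaluated update rule", {
  # vertex at (1,0,0), one neighbor at (0,1,0), ca1 = 0.1, ca2 = 0:
  # d = (-1,1,0), ||d||^2 = 2, C' = C + 0.1 * d * 2 = (0.8, 0.2, 0)
  coords <- rbind(c(1, 0, 0), c(0, 1, 0))
  res <- rccad:::cpp_attraction(coords, c(0L, 1L, 2L), c(1L, 0L),
                                0.1, 0, TRUE)
  expect_equal(res$coords[1, ], c(0.8, 0.2, 0), tolerance = 1e-12)
  expect_equal(res$coords[2, ], c(0.2, 0.8, 0), tolerance = 1e-12)

  # quotient reading divides by ||d||^2 instead
  resq <- rccad:::cpp_attraction(coords, c(0L, 1L, 2L), c(1L, 0L),
                                 0.1, 0, FALSE)
  expect_equal(resq$coords[1, ], c(1, 0, 0) + 0.1 * c(-1, 1, 0) / 2,
               tolerance = 1e-12)

  # ca1 = 0 leaves coordinates unchanged
  res0 <- rccad:::cpp_attraction(coords, c(0L, 1L, 2L), c(1L, 0L), 0, 0.5, TRUE)
  expect_equal(res0$coords, coords, ignore_attr = TRUE)

  # coincident neighbors exert zero force and are counted as skipped
  same <- rbind(c(1, 0, 0), c(1, 0, 0))
  ressame <- rccad:::cpp_attraction(same, c(0L, 1L, 2L), c(1L, 0L), 0.1, 0.05, TRUE)
  expect_equal(ressame$coords, same, ignore_attr = TRUE)
  expect_equal(ressame$skipped, 2L)
})

test_that("repulsion pushes nodes apart with the inverse-square rule", {
  # antipodal pair, cr = 0.4, I = 2: displacement 0.05 outward per node
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0))
  res <- repulsion_step(pts, ar_params(cr = 0.4))
  expect_equal(res[1, ], c(1.05, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res[2, ], c(-1.05, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)

  # cr = 0 is the identity
  expect_equal(repulsion_step(pts, ar_params(cr = 0)), pts,
               tolerance = 1e-15, ignore_attr = TRUE)

  # regular tetrahedron: net displacement is purely radial by symmetry
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  out <- repulsion_step(tet, ar_params(cr = 0.3))
  disp <- out - tet
  radial <- rowSums(disp * tet)
  tangential <- disp - radial * tet
  expect_lt(max(abs(tangential)), 1e-12)
  expect_true(all(radial > 0)) # inflation

  expect_error(repulsion_step(tet[1, , drop = FALSE]), "at least two")
})

test_that("attraction-repulsion converges on a near-uniform sphere and is deterministic", {
  ico <- icosphere(3)
  p <- ar_params(threshold = 1e-3)
  map <- attraction_repulsion(ico, p)
  expect_true(map$converged)
  expect_lte(map$iterations_run, 5)

  # an enormous threshold stops after exactly one iteration
  p1 <- ar_params(threshold = 10)
  expect_equal(attraction_repulsion(ico, p1)$iterations_run, 1L)

  # bumpy phantom, fixed seed: identical maps across runs
  spec <- small_spec("ccRCC")
  mask <- generate_shape(spec)
  mesh <- laplacian_smooth(extract_mesh(mask))
  pa <- fast_ar(5)
  m1 <- suppressMessages(attraction_repulsion(mesh, pa, mask = mask, seed = 3))
  m2 <- suppressMessages(attraction_repulsion(mesh, pa, mask = mask, seed = 3))
  expect_identical(m1$unit_coords, m2$unit_coords)
})

test_that("every iteration ends exactly on the unit sphere", {
  spec <- small_spec("nccRCC")
  mask <- generate_shape(spec)
  mesh <- laplacian_smooth(extract_mesh(mask))
  u <- initial_spherical_map(mesh, mask = mask)$unit_coords
  p <- ar_params()
  for (it in 1:5) {
    u <- attraction_step(u, mesh, p)
    u <- repulsion_step(u, p)
    u <- u / sqrt(rowSums(u^2))
    expect_lt(max(abs(sqrt(rowSums(u^2)) - 1)), 1e-9)
  }
})
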