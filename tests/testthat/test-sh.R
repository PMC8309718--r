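test_that("real SH basis is orthonormal and matches closed forms", {
  expect_equal(sh_basis(c(0.3, 1.2, 2.9), c(0, 2, 5), 0, 0),
               rep(1 / sqrt(4 * pi), 3), tolerance = 1e-12)
  # Y10 has a node at the equator
  expect_equal(sh_basis(pi / 2, 0.7, 1, 0), 0, tolerance = 1e-12)
  # Y10 = sqrt(3/(4 pi)) cos(theta)
  expect_equal(sh_basis(0.4, 1, 1, 0), sqrt(3 / (4 * pi)) * cos(0.4),
               tolerance = 1e-12)
  expect_error(sh_basis(1, 1, 2, 3), "beta")

  # Gram matrix over Gauss-Legendre x uniform-phi quadrature is the identity
  gl <- pracma::gaussLegendre(40, -1, 1)
  phis <- seq(0, 2 * pi, length.out = 81)[-1]
  grid <- expand.grid(th = acos(gl$x), ph = phis)
  B <- rccad:::sh_basis_matrix(grid$th, grid$ph, 4)
  W <- rep(gl$w, times = length(phis)) * (2 * pi / length(phis))
  G <- t(B * W) %*% B
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-6)
})

test_that("SH fitting recovers constant and planted spectra", {
  ico <- icosphere(3, radius = 9)
  map <- initial_spherical_map(ico)
  fit <- fit_sh(ico, map, max_degree = 4)
  expect_length(fit$coefficients, 25)
  expect_equal(fit$coefficients[1], 9 * sqrt(4 * pi), tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-8)

  # planted coefficient at (2, 0): r = 10 + 0.5 * Y20
  ico1 <- icosphere(3)
  map1 <- initial_spherical_map(ico1)
  r <- 10 + 0.5 * sh_basis(map1$theta, map1$phi, 2, 0)
  mesh1 <- ico1
  mesh1$vertices <- ico1$vertices * r
  map_planted <- initial_spherical_map(mesh1)
  fitp <- fit_sh(mesh1, map_planted, max_degree = 4)
  a20 <- fitp$coefficients[2^2 + 0 + 2 + 1]
  expect_equal(a20, 0.5, tolerance = 1e-6)
  expect_equal(fitp$coefficients[1], 10 * sqrt(4 * pi), tolerance = 1e-6)

  # evaluating the fitted model reproduces the planted radius function
  th <- c(0.4, 1.1, 2.2)
  ph <- c(0.2, 3.0, 5.5)
  expect_equal(predict(fitp, th, ph), 10 + 0.5 * sh_basis(th, ph, 2, 0),
               tolerance = 1e-6)

  # nested models: residual norm non-increasing with degree
  expect_true(all(diff(fitp$rss) <= 1e-9))
  fit8 <- fit_sh(mesh1, map_planted, max_degree = 8)
  expect_lte(fit8$rss[9], fitp$rss[5] + 1e-9)

  # underdetermined systems are refused with advice
  tiny <- icosphere(0)
  expect_error(fit_sh(tiny, initial_spherical_map(tiny), max_degree = 10),
               "underdetermined")
})

test_that("nested residuals equal independent per-order refits", {
  # oracle: explicit QR least squares at each truncation order
  set.seed(8)
  ico <- icosphere(2)
  map0 <- initial_spherical_map(ico)
  r <- 8 + 0.3 * sh_basis(map0$theta, map0$phi, 3, 1) +
    0.1 * sh_basis(map0$theta, map0$phi, 5, -2) + rnorm(length(map0$theta), 0, 0.02)
  mesh <- ico
  mesh$vertices <- ico$vertices * r
  map <- initial_spherical_map(mesh)
  fit <- fit_sh(mesh, map, max_degree = 6, ridge = 0)
  B <- rccad:::sh_basis_matrix(map$theta, map$phi, 6)
  for (k in c(1, 3, 5, 6)) {
    cols <- seq_len((k + 1)^2)
    rss_oracle <- sum(qr.resid(qr(B[, cols]), map$radii)^2)
    expect_equal(fit$rss[k + 1], rss_oracle, tolerance = 1e-8)
  }
})

test_that("SHRE spectrum separates planted frequency content", {
  # exact sphere: all reconstruction errors are numerically zero
  ico <- icosphere(5, radius = 9) # 10242 vertices
  maps <- initial_spherical_map(ico)
  es <- shre_features(ico, maps, n_orders = 70)
  expect_length(es, 70)
  expect_true(all(es >= 0))
  expect_lt(max(es), 1e-6)

  # energy planted only at degree 5: error collapses at order 5 (down to the
  # normal-equation noise floor)
  ico3 <- icosphere(3)
  m0 <- initial_spherical_map(ico3, origin = c(0, 0, 0))
  r <- 10 + 0.4 * sh_basis(m0$theta, m0$phi, 5, 2)
  mesh5 <- ico3
  mesh5$vertices <- ico3$vertices * r
  map5 <- initial_spherical_map(mesh5, origin = c(0, 0, 0))
  e <- shre_features(mesh5, map5, n_orders = 8)
  expect_gt(e[4], 100 * e[5])
  expect_lt(max(e[5:8]), 1e-4)

  # too few vertices for the requested order: actionable error
  expect_error(shre_features(ico3, m0, n_orders = 30), "subdivide")
})

test_that("SHRE contrasts bumpy and smooth phantoms and is rotation invariant", {
  smooth_spec <- small_spec("AML", amplitude = 0.02, max_degree = 3)
  bumpy_spec <- small_spec("ccRCC", amplitude = 0.15, max_degree = 8)
  shre_of <- function(spec, rotate = NULL) {
    mask <- generate_shape(spec)
    mesh <- ensure_vertex_count(laplacian_smooth(extract_mesh(mask)), 10)
    if (!is.null(rotate)) {
      ctr <- colMeans(mesh$vertices)
      mesh$vertices <- sweep(sweep(mesh$vertices, 2, ctr) %*% t(rotate), 2, ctr, "+")
    }
    map <- suppressMessages(attraction_repulsion(mesh, fast_ar(8),
                                                 origin = colMeans(mesh$vertices)))
    shre_features(mesh, map, n_orders = 10)
  }
  e_smooth <- shre_of(smooth_spec)
  e_bumpy <- shre_of(bumpy_spec)
  expect_gt(mean(e_bumpy), 3 * mean(e_smooth))

  # rigid rotation of the mesh leaves the spectrum unchanged (1e-3 relative)
  th <- 0.83
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e_rot <- shre_of(bumpy_spec, rotate = Rz)
  expect_lt(max(abs(e_rot - e_bumpy) / max(e_bumpy)), 1e-3)
})
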