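test_that("moment tensor matches hand computations and the naive oracle", {
  # two voxels 1 um apart along x: variance of {-0.5, +0.5}
  g <- make_grid(rbind(c(1, 1, 1), c(1, 1, 2)), dim = c(3, 3, 3))
  mt <- moment_tensor(g)
  expect_equal(mt$M["x", "x"], 0.25)
  expect_equal(mt$M[cbind(c("y", "z"), c("y", "z"))], c(0, 0))
  expect_equal(sum(abs(mt$M)) - 0.25, 0)

  # naive double-loop oracle on random small masks, anisotropic spacing
  set.seed(42)
  for (i in 1:5) {
    idx <- unique(cbind(sample(1:15, 60, TRUE), sample(1:15, 60, TRUE),
                        sample(1:15, 60, TRUE)))
    g <- make_grid(idx, dim = c(15, 15, 15), spacing = c(0.516, 0.516, 0.775))
    expect_equal(unname(moment_tensor(g)$M), naive_moment(g),
                 tolerance = 1e-12)
  }

  expect_error(moment_tensor(make_grid(rbind(c(2, 2, 2)), dim = c(3, 3, 3))),
               "single-voxel")
  expect_error(moment_tensor(voxel_grid(array(FALSE, dim = c(3, 3, 3)),
                                        c(1, 1, 1))), "empty")
})

test_that("moment tensor is translation invariant", {
  set.seed(7)
  idx <- unique(cbind(sample(1:8, 40, TRUE), sample(1:8, 40, TRUE),
                      sample(1:8, 40, TRUE)))
  g1 <- make_grid(idx, dim = c(20, 20, 20), spacing = c(0.516, 0.516, 0.775))
  g2 <- make_grid(idx + rep(c(3, 5, 7), each = nrow(idx)),
                  dim = c(20, 20, 20), spacing = c(0.516, 0.516, 0.775))
  expect_equal(moment_tensor(g1)$M, moment_tensor(g2)$M, tolerance = 1e-12)
})

test_that("solid sphere tensor approaches (r^2/5) * identity", {
  g <- render_phantom(phantom_spec(5, 5, 5, grid_shape = c(44, 44, 44),
                                   spacing = c(0.25, 0.25, 0.25)))
  M <- moment_tensor(g)$M
  expect_equal(unname(diag(M)), rep(25 / 5, 3), tolerance = 0.02)
  expect_lt(max(abs(M[upper.tri(M)])), 0.01)
})

test_that("eigen features are sorted, normalized and similarity invariant", {
  for (k in c(0.1, 1, 17)) {
    expect_equal(unname(eigen_features(diag(c(4, 1, 1)) * k)),
                 c(4 / 6, 1 / 6, 1 / 6))
  }
  expect_equal(unname(eigen_features(diag(3))), rep(1 / 3, 3))
  # rotation of the tensor leaves the triple unchanged
  set.seed(3)
  M <- diag(c(5, 2, 1))
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(eigen_features(Q %*% M %*% t(Q)), eigen_features(M),
               tolerance = 1e-12)
  expect_equal(sum(eigen_features(Q %*% M %*% t(Q))), 1, tolerance = 1e-12)
  expect_error(eigen_features(matrix(0, 3, 3)), "degenerate")
})

test_that("skewness is zero for symmetric solids and positive for teardrops", {
  ell <- render_phantom(phantom_spec(8, 5, 4, grid_shape = c(40, 40, 40),
                                     spacing = c(0.5, 0.5, 0.5)))
  expect_lt(skewness(ell)$A, 0.01)
  td <- render_phantom(phantom_spec(8, 5, 4, skew = 0.6,
                                    grid_shape = c(40, 40, 40),
                                    spacing = c(0.5, 0.5, 0.5)))
  sk <- skewness(td)
  expect_gt(sk$A, 0.02)
  # d agrees with a brute-force centroid vs principal-box-centre computation
  xyz <- voxel_coordinates(td)
  E <- eigen(naive_moment(td), symmetric = TRUE)$vectors
  q <- xyz %*% E
  geom <- E %*% ((apply(q, 2, min) + apply(q, 2, max)) / 2)
  expect_equal(sk$d, sqrt(sum((geom - colMeans(xyz))^2)), tolerance = 1e-9)
  # volume = count * voxel volume
  expect_equal(sk$v, sum(td$mask) * 0.125)
})

test_that("skewness is scale invariant (x2 size, half voxel pitch)", {
  a <- render_phantom(phantom_spec(6, 4, 3, skew = 0.5,
                                   grid_shape = c(40, 40, 40),
                                   spacing = c(0.5, 0.5, 0.5)))
  b <- render_phantom(phantom_spec(12, 8, 6, skew = 0.5,
                                   grid_shape = c(40, 40, 40),
                                   spacing = c(1, 1, 1)))
  expect_lt(abs(skewness(a)$A - skewness(b)$A), 0.01)
})

test_that("feature vector of canonical phantoms matches continuum values", {
  sph <- render_phantom(phantom_spec(5, 5, 5, grid_shape = c(32, 32, 32),
                                     spacing = c(0.5, 0.5, 0.5)))
  f <- feature_vector(sph)
  expect_lt(abs(f$lambda1_norm - 1 / 3), 0.01)
  expect_lt(abs(f$lambda2_norm - 1 / 3), 0.01)
  expect_lt(f$skewness, 0.01)
  expect_equal(f$lambda1_norm + f$lambda2_norm + f$lambda3_norm, 1,
               tolerance = 1e-9)

  # continuum moments of an ellipsoid are a^2/5 etc: normalized 100/118, 9/118
  ell <- render_phantom(phantom_spec(10, 3, 3, grid_shape = c(48, 48, 48),
                                     spacing = c(0.5, 0.5, 0.5)))
  fe <- feature_vector(ell)
  expect_lt(abs(fe$lambda1_norm - 100 / 118), 0.01)
  expect_lt(abs(fe$lambda2_norm - 9 / 118), 0.01)
})

test_that("features are invariant under arbitrary rotations of phantoms", {
  base <- phantom_spec(10, 3, 3, grid_shape = c(48, 48, 48),
                       spacing = c(0.5, 0.5, 0.5))
  f0 <- feature_vector(render_phantom(base))
  rot <- phantom_spec(10, 3, 3, angles = c(30, 40, 50) * pi / 180,
                      grid_shape = c(48, 48, 48), spacing = c(0.5, 0.5, 0.5))
  f1 <- feature_vector(render_phantom(rot))
  expect_lt(abs(f1$lambda1_norm - f0$lambda1_norm), 0.02)
  expect_lt(abs(f1$lambda2_norm - f0$lambda2_norm), 0.02)
  expect_lt(abs(f1$skewness - f0$skewness), 0.02)
})

test_that("features are exactly invariant under the 24 cubic rotations", {
  set.seed(9)
  mask <- array(FALSE, dim = c(15, 15, 15))
  mask[4:12, 5:10, 6:9] <- TRUE
  mask[sample(which(!mask), 40)] <- TRUE
  mask <- keep_largest_component(voxel_grid(mask, c(1, 1, 1)))$mask
  f0 <- feature_vector(voxel_grid(mask, c(1, 1, 1)))
  for (R in cubic_rotations()) {
    fr <- feature_vector(voxel_grid(rotate_mask(mask, R), c(1, 1, 1)))
    expect_equal(fr$lambda1_norm, f0$lambda1_norm, tolerance = 1e-9)
    expect_equal(fr$lambda2_norm, f0$lambda2_norm, tolerance = 1e-9)
    expect_equal(fr$skewness, f0$skewness, tolerance = 1e-9)
  }
})

test_that("features are exactly invariant under uniform spacing scaling", {
  set.seed(13)
  idx <- unique(cbind(sample(1:10, 80, TRUE), sample(1:10, 80, TRUE),
                      sample(1:10, 80, TRUE)))
  f1 <- feature_vector(make_grid(idx, dim = c(12, 12, 12),
                                 spacing = c(0.5, 0.5, 0.8)))
  f2 <- feature_vector(make_grid(idx, dim = c(12, 12, 12),
                                 spacing = 3 * c(0.5, 0.5, 0.8)))
  expect_equal(f2$lambda1_norm, f1$lambda1_norm, tolerance = 1e-12)
  expect_equal(f2$lambda2_norm, f1$lambda2_norm, tolerance = 1e-12)
  expect_equal(f2$skewness, f1$skewness, tolerance = 1e-12)
})

test_that("feature distance is a metric on the eigenvalue simplex", {
  expect_equal(feature_distance(c(0.5, 0.3), c(0.5, 0.3)), 0)
  expect_equal(feature_distance(c(1, 0, 0), c(0, 1, 0)), sqrt(2))
  set.seed(21)
  for (i in 1:20) {
    tri <- lapply(1:3, function(j) {
      x <- sort(stats::runif(3), decreasing = TRUE); x / sum(x)
    })
    dab <- feature_distance(tri[[1]], tri[[2]])
    dbc <- feature_distance(tri[[2]], tri[[3]])
    dac <- feature_distance(tri[[1]], tri[[3]])
    expect_lte(dac, dab + dbc + 1e-12)
    expect_equal(dab, feature_distance(tri[[2]], tri[[1]]))
    expect_gte(dab, 0)
  }
})
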