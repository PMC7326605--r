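test_that("quality metrics score the regular tet 1 at any scale and degenerate tets 0", {
  for (s in c(1, 1e-3, 1e4)) {
    p <- regular_tet_points(s)
    expect_equal(volume_edge_ratio(p[1, ], p[2, ], p[3, ], p[4, ]), 1,
                 tolerance = 1e-12)
    expect_equal(min_dihedral_sine(p[1, ], p[2, ], p[3, ], p[4, ]), 1,
                 tolerance = 1e-12)
  }
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(volume_edge_ratio(flat[1, ], flat[2, ], flat[3, ], flat[4, ]), 0)
  expect_equal(min_dihedral_sine(flat[1, ], flat[2, ], flat[3, ], flat[4, ]), 0)
})

test_that("volume-edge ratio matches an independent arithmetic oracle", {
  # right-corner unit tet: V = 1/6, edges 1,1,1,sqrt(2),sqrt(2),sqrt(2)
  l_rms <- sqrt((3 * 1 + 3 * 2) / 6)
  oracle <- 6 * sqrt(2) * (1 / 6) / l_rms^3
  expect_equal(volume_edge_ratio(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               oracle, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    v <- abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])) / 6)
    l2 <- c(sum((p[1, ] - p[2, ])^2), sum((p[1, ] - p[3, ])^2),
            sum((p[1, ] - p[4, ])^2), sum((p[2, ] - p[3, ])^2),
            sum((p[2, ] - p[4, ])^2), sum((p[3, ] - p[4, ])^2))
    oracle <- min(1, 6 * sqrt(2) * v / mean(l2)^1.5)
    expect_equal(volume_edge_ratio(p[1, ], p[2, ], p[3, ], p[4, ]), oracle,
                 tolerance = 1e-12)
  }
})

test_that("minimal dihedral sine agrees with brute-force angles via face normals", {
  dihedral_oracle <- function(p) {
    faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
    nrm <- lapply(faces, function(f) {
      n <- pracma::cross(p[f[2], ] - p[f[1], ], p[f[3], ] - p[f[1], ])
      n / sqrt(sum(n^2))
    })
    pairs <- list(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(3, 4))
    s <- vapply(pairs, function(fp) {
      cosang <- sum(nrm[[fp[1]]] * nrm[[fp[2]]])
      sin(acos(max(-1, min(1, cosang))))
    }, numeric(1))
    min(s) / (2 * sqrt(2) / 3)
  }
  set.seed(17)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(min_dihedral_sine(p[1, ], p[2, ], p[3, ], p[4, ]),
                 min(1, dihedral_oracle(p)), tolerance = 1e-9)
  }
  # sliver flattened to 1e-6 thickness scores ~0
  sl <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1e-6))
  expect_lt(min_dihedral_sine(sl[1, ], sl[2, ], sl[3, ], sl[4, ]), 1e-3)
})

test_that("quality reports are element-wise and the histogram sums to the tet count", {
  p <- regular_tet_points()
  m1 <- mesh(p, rbind(1:4))
  r1 <- quality_report(m1)
  expect_equal(r1$min, 1, tolerance = 1e-12)
  expect_equal(r1$mean, 1, tolerance = 1e-12)
  m <- jitter_mesh(box_tet_mesh(4, 4, 4), sigma = 0.1, seed = 2)
  r <- quality_report(m, bins = 17)
  expect_identical(sum(r$histogram), sum(m$etype == 4L))
  tv <- meshops:::volume_edge_ratios(m$points, m$conn)
  expect_equal(r$per_elem, tv)
  expect_error(quality_report(icosphere(1)), class = "mt_geometry_error")
})

test_that("zero iterations of smoothing is the identity", {
  m <- jitter_mesh(box_tet_mesh(3, 3, 3), sigma = 0.05, seed = 4)
  out <- taubin_smooth(m, params = smoothing_params(iterations = 0))
  expect_identical(out$points, m$points)
})

test_that("Taubin smoothing preserves enclosed volume where Laplacian shrinks it", {
  set.seed(31)
  ico <- icosphere(3, 1)
  s <- surface(ico$conn[, 1:3], n_points(ico))
  v_clean <- enclosed_volume(s, ico$points)
  noisy <- ico
  noisy$points <- ico$points + matrix(rnorm(3 * n_points(ico), sd = 0.02),
                                      ncol = 3)
  lab <- decompose_manifolds(noisy, feature_angle_deg = 180)
  for (iters in c(10, 50, 200)) {
    taubin <- taubin_smooth(noisy, lab, smoothing_params(iterations = iters))
    laplace <- taubin_smooth(noisy, lab,
                             smoothing_params(mu = 0, iterations = iters))
    dv_t <- abs(enclosed_volume(s, taubin$points) - v_clean) / v_clean
    dv_l <- abs(enclosed_volume(s, laplace$points) - v_clean) / v_clean
    expect_lt(dv_t, dv_l)
  }
})

test_that("the quality threshold is never crossed downwards during smoothing", {
  m <- box_tet_mesh(6, 6, 6, label_planes = list(axis = "z", at = 3))
  lab <- decompose_manifolds(m)
  mj <- jitter_mesh(m, sigma = 0.3, seed = 8, labeling = lab)
  q0 <- quality_report(mj)$min
  sm <- taubin_smooth(mj, lab,
                      smoothing_params(iterations = 20, quality_threshold = 0.1))
  expect_gte(quality_report(sm)$min, min(0.1, q0))
  # interface vertices stay on their (smoothed) interface patch: their
  # neighbour averages only involve interface vertices, so the surviving
  # spread shrinks
  iv <- which(lab$patch_id == "1|2" & lab$vertex_class == "SURFACE")
  expect_lt(diff(range(sm$points[iv, 3])), diff(range(mj$points[iv, 3])))
  expect_error(
    taubin_smooth(icosphere(1), params = smoothing_params(quality_threshold = 0.1)),
    class = "mt_geometry_error")
})

test_that("flat patches and corner points are fixed points of mesh smoothing", {
  m <- box_tet_mesh(3, 3, 3)
  lab <- decompose_manifolds(m)
  sm <- taubin_smooth(m, lab, smoothing_params(iterations = 30))
  # boundary vertices of the already-flat box never leave their planes
  for (ax in 1:3) {
    on0 <- m$points[, ax] == 0
    expect_lt(max(abs(sm$points[on0, ax])), 1e-9)
  }
  corners <- which(lab$vertex_class == "POINT")
  expect_identical(sm$points[corners, ], m$points[corners, ])
})

test_that("data smoothing damps noise and leaves constants untouched", {
  m <- box_tet_mesh(5, 5, 5)
  g <- mesh_graph(m)
  const <- data_field(rep(3.5, n_points(m)), "node")
  out <- smooth_data(const, g, smoothing_params(iterations = 15))
  expect_equal(out$values, const$values, tolerance = 1e-12)

  set.seed(6)
  noise <- data_field(rnorm(n_points(m)), "node")
  sm <- smooth_data(noise, g, smoothing_params(iterations = 10))
  expect_lt(stats::var(sm$values[, 1]), stats::var(noise$values[, 1]))

  spike <- data_field(rep(0, n_points(m)), "node")
  centre <- which.min(rowSums((m$points - 2.5)^2))
  spike$values[centre, 1] <- 1
  prev <- 1
  f <- spike
  for (i in 1:5) {
    f <- smooth_data(f, g, smoothing_params(iterations = 1))
    expect_lt(f$values[centre, 1], prev)
    prev <- f$values[centre, 1]
  }
  expect_error(smooth_data(data_field(1:10, "element"), g),
               class = "mt_usage_error")
})
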