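test_that("resample specs validate their parameters", {
  expect_error(resample_spec(), class = "mt_usage_error")
  expect_error(resample_spec(max_edge = -1), class = "mt_usage_error")
  expect_error(resample_spec(min_edge = 0), class = "mt_usage_error")
  expect_error(resample_spec(min_edge = 2, max_edge = 1), class = "mt_usage_error")
  expect_error(resample_spec(min_edge = 1, normal_change_max_deg = 200),
               class = "mt_usage_error")
  sp <- resample_spec(avg_edge = 2)
  expect_equal(sp$min_edge, 1.4)
  expect_equal(sp$max_edge, 2.8)
})

test_that("splitting leaves a mesh with no over-long edges untouched", {
  m <- box_tet_mesh(2, 2, 2)
  out <- split_long_edges(m, resample_spec(max_edge = 2))
  expect_identical(out$conn, m$conn)
  expect_identical(out$points, m$points)
})

test_that("edge bisection enforces the cap, conserves volume and keeps orientation", {
  m <- unit_tet()
  L <- max(all_edge_lengths(m))
  v0 <- sum(meshops:::tet_volumes(m$points, m$conn))
  out <- split_long_edges(m, resample_spec(max_edge = 0.6 * L))
  expect_lte(max(all_edge_lengths(out)), 0.6 * L)
  vols <- meshops:::tet_volumes(out$points, out$conn)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), v0, tolerance = 1e-9)
  expect_true(all(out$tags == 1L))
})

test_that("splitting interpolates node fields at edge midpoints", {
  m <- unit_tet()
  # a linear function is reproduced exactly by midpoint interpolation
  f <- data_field(m$points[, 1] + 2 * m$points[, 2] - m$points[, 3], "node")
  out <- split_long_edges(m, resample_spec(max_edge = 0.9), fields = list(f))
  expect_equal(out$fields[[1]]$values[, 1],
               out$mesh$points[, 1] + 2 * out$mesh$points[, 2] -
                 out$mesh$points[, 3],
               tolerance = 1e-12)
})

test_that("tag-restricted splitting leaves the far region untouched", {
  m <- box_tet_mesh(2, 2, 4, label_planes = list(axis = "z", at = 2))
  out <- split_long_edges(m, resample_spec(max_edge = 1.2,
                                           tag_restriction = 1L))
  # region-2 elements away from the interface must be bit-identical:
  # identify them by centroids beyond one layer from the interface plane
  elem_coord_keys <- function(mm, ids) {
    sort(vapply(ids, function(i) {
      cc <- mm$points[mm$conn[i, 1:4], , drop = FALSE]
      paste(sort(apply(cc, 1, paste, collapse = ",")), collapse = ";")
    }, character(1)))
  }
  cen_in <- meshops:::elem_centroids(m)
  far_in <- which(m$tags == 2L & cen_in[, 3] > 3)
  cen_out <- meshops:::elem_centroids(out)
  far_out <- which(out$tags == 2L & cen_out[, 3] > 3)
  expect_identical(elem_coord_keys(out, far_out), elem_coord_keys(m, far_in))
  # the restricted region got refined
  expect_gt(sum(out$tags == 1L), sum(m$tags == 1L))
})

test_that("collapsing leaves a mesh with no short edges untouched", {
  m <- box_tet_mesh(2, 2, 2)
  res <- collapse_short_edges(m, resample_spec(min_edge = 0.5))
  expect_identical(res$mesh$conn, m$conn)
  expect_identical(res$n_collapsed, 0L)
})

test_that("collapsing an over-refined box keeps orientation and its outer shape", {
  m <- box_tet_mesh(5, 5, 5)
  res <- collapse_short_edges(m, resample_spec(min_edge = 2))
  out <- res$mesh
  expect_lt(n_elems(out), n_elems(m))
  expect_true(all(meshops:::tet_volumes(out$points, out$conn) > 0))
  # boundary vertices remain exactly on the box surface: collapses move
  # lower manifold classes into higher ones, never the other way
  s <- extract_boundary_surface(out, 1)
  p <- out$points[s$vertex_set, , drop = FALSE]
  on_box <- apply(p, 1, function(q) any(abs(q) < 1e-9 | abs(q - 5) < 1e-9))
  expect_true(all(on_box))
  # the 8 corners are immovable
  corners <- as.matrix(expand.grid(c(0, 5), c(0, 5), c(0, 5)))
  for (i in seq_len(8)) {
    expect_true(any(rowSums(abs(sweep(out$points, 2, corners[i, ]))) < 1e-12))
  }
})

test_that("a collapse that would invert a tet is dismissed and reported", {
  # triangular bipyramid around base ABC: interior vertex E sits just above
  # the base, apex D just below it.  The only short edge is E-D; merging E
  # into D would flip the surviving tet (A,B,C,E->D), so the attempt must be
  # dismissed and the edge reported as uncollapsible.
  A <- c(0, 0, 0); B <- c(1, 0, 0); C <- c(0.3, 1, 0)
  E <- c(0.3, 0.3, 0.05); D <- c(0.3, 0.3, -0.1)
  m <- mesh(rbind(A, B, C, E, D),
            rbind(c(1, 2, 3, 4), c(1, 2, 4, 5), c(2, 3, 4, 5), c(3, 1, 4, 5)))
  lab <- decompose_manifolds(m)
  expect_identical(lab$vertex_class[4], "VOLUME")
  res <- collapse_short_edges(m, resample_spec(min_edge = 0.2,
                                               quality_floor = 0))
  expect_identical(res$n_collapsed, 0L)
  expect_identical(res$uncollapsible, 1L)
  expect_identical(res$mesh$conn, m$conn)
  expect_true(all(meshops:::tet_volumes(res$mesh$points, res$mesh$conn) > 0))
})

test_that("two-phase resampling hits per-region targets on a three-region box", {
  m <- box_tet_mesh(8, 8, 9, h = 1, label_planes = list(axis = "z", at = c(3, 6)))
  targets <- c(`1` = 2.0, `2` = 1.6, `3` = 1.3)
  out <- m
  reports <- list()
  for (r in c(1, 2)) {
    res <- resample_mesh(out, resample_spec(avg_edge = targets[[as.character(r)]],
                                            tag_restriction = r))
    out <- res$mesh
    reports[[as.character(r)]] <- res$report
  }
  for (r in 1:3) {
    len <- region_edge_lengths(out, r)
    tgt <- targets[[as.character(r)]]
    expect_lt(abs(mean(len) - tgt) / tgt, 0.2)
    expect_lte(max(len), 1.4 * tgt + 1e-9)
  }
  expect_true(all(meshops:::tet_volumes(out$points, out$conn) > 0))
  # conformity: interior faces shared by exactly 2 tets
  ft <- meshops:::tet_face_table(out$conn, seq_len(n_elems(out)))
  expect_true(all(table(meshops:::face_keys(ft$faces, n_points(out))) <= 2))
  # untouched region is element-wise identical to the input
  key3 <- function(mm) {
    el <- which(mm$tags == 3L)
    sort(vapply(el, function(i) {
      cc <- mm$points[mm$conn[i, 1:4], , drop = FALSE]
      paste(sort(apply(cc, 1, paste, collapse = ",")), collapse = ";")
    }, character(1)))
  }
  expect_identical(key3(out), key3(m))
  # uncollapsible edges are a report, never an error
  expect_gte(reports[["1"]]$uncollapsible, 0L)
  # quality is only slightly degraded
  expect_lt(reports[["1"]]$quality_before$mean -
              reports[["2"]]$quality_after$mean, 0.15)
})

test_that("resampling a coarse mesh with only a max edge is the identity plus report", {
  m <- box_tet_mesh(3, 3, 3)
  res <- resample_mesh(m, resample_spec(max_edge = 5))
  expect_identical(res$mesh$conn, m$conn)
  expect_identical(res$report$n_splits, 0L)
  expect_identical(res$report$n_elems_before, res$report$n_elems_after)
})
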