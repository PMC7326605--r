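test_that("extracting all tags reproduces the mesh with identity mappings", {
  m <- two_label_box(3)
  res <- extract_submesh(m, c(1, 2))
  expect_identical(res$mesh$conn, m$conn)
  expect_equal(res$mesh$points, m$points)
  expect_identical(res$mapping$node_map, seq_len(n_points(m)))
  expect_identical(res$mapping$elem_map, seq_len(n_elems(m)))
  expect_error(extract_submesh(m, 42), class = "mt_empty_selection_error")
})

test_that("single-label extraction maps coordinates and tags faithfully", {
  m <- two_label_box(3)
  res <- extract_submesh(m, 1)
  expect_identical(n_elems(res$mesh), sum(m$tags == 1L))
  expect_equal(res$mesh$points, m$points[res$mapping$node_map, , drop = FALSE])
  expect_true(all(res$mesh$tags == 1L))
})

test_that("extraction of a random tag partition reinserts to the original exactly", {
  m <- box_tet_mesh(3, 3, 3)
  set.seed(19)
  m$tags <- sample(1:4, n_elems(m), replace = TRUE)
  m$fibers <- matrix(stats::rnorm(3 * n_elems(m)), ncol = 3)
  rebuilt <- m
  rebuilt$points[] <- 0
  rebuilt$tags[] <- 0L
  rebuilt$fibers[] <- 0
  for (tg in 1:4) {
    part <- extract_submesh(m, tg)
    rebuilt <- insert_submesh(rebuilt, part$mesh, part$mapping)
  }
  expect_equal(rebuilt$points, m$points)
  expect_identical(rebuilt$tags, m$tags)
  expect_equal(rebuilt$fibers, m$fibers)
})

test_that("insertion detects stale mappings after topology changes", {
  m <- box_tet_mesh(3, 3, 3, label_planes = list(axis = "x", at = 1))
  part <- extract_submesh(m, 1)
  shrunk <- collapse_short_edges(part$mesh, resample_spec(min_edge = 1.2))$mesh
  expect_lt(n_elems(shrunk), n_elems(part$mesh))
  expect_error(insert_submesh(m, shrunk, part$mapping),
               class = "mt_mapping_stale_error")
  # smoothed (topology-preserving) submesh inserts cleanly and only mapped
  # nodes change
  sm <- part$mesh
  sm$points <- sm$points * 0.99
  out <- insert_submesh(m, sm, part$mapping)
  unmapped <- setdiff(seq_len(n_points(m)), part$mapping$node_map)
  expect_equal(out$points[unmapped, ], m$points[unmapped, ])
  expect_equal(out$points[part$mapping$node_map, ], sm$points)
})

test_that("data gather/scatter through mappings matches an index-loop oracle", {
  m <- two_label_box(3)
  part <- extract_submesh(m, 2)
  set.seed(23)
  nodal <- data_field(matrix(stats::rnorm(3 * n_points(m)), ncol = 3), "node")
  elem <- data_field(stats::rnorm(n_elems(m)), "element")
  gn <- extract_data(nodal, part$mapping)
  ge <- extract_data(elem, part$mapping)
  for (i in seq_along(part$mapping$node_map)) {
    expect_identical(gn$values[i, ], nodal$values[part$mapping$node_map[i], ])
  }
  for (j in seq_along(part$mapping$elem_map)) {
    expect_identical(ge$values[j, ], elem$values[part$mapping$elem_map[j], ])
  }
  # scatter back: gather-then-scatter is the identity on mapped entries,
  # untouched elsewhere
  gn$values <- gn$values + 1
  back <- insert_data(nodal, gn, part$mapping)
  expect_equal(back$values[part$mapping$node_map, ], gn$values)
  unmapped <- setdiff(seq_len(n_points(m)), part$mapping$node_map)
  expect_identical(back$values[unmapped, ], nodal$values[unmapped, ])
})

test_that("overlap extraction partitions the mesh and matches the all-pairs oracle", {
  m <- box_tet_mesh(4, 4, 3)
  rod <- rod_surface(2, 0.4, 12)
  probe <- mesh(rod$points + rep(c(2, 2, 0.5), each = nrow(rod$points)),
                rod$surface$faces)
  res <- extract_overlap(m, probe, size = 0.6)
  n_ov <- length(res$overlap$mapping$elem_map)
  n_co <- length(res$complement$mapping$elem_map)
  expect_identical(n_ov + n_co, n_elems(m))
  expect_identical(length(intersect(res$overlap$mapping$elem_map,
                                    res$complement$mapping$elem_map)), 0L)
  cen <- meshops:::elem_centroids(m)
  d <- apply(cen, 1, function(q)
    min(sqrt(colSums((t(probe$points) - q)^2))))
  expect_identical(sort(res$overlap$mapping$elem_map), which(d <= 0.6))

  # distant probe: empty overlap, complement is the whole mesh
  far <- probe
  far$points <- far$points + 1000
  res2 <- extract_overlap(m, far, size = 0.6)
  expect_null(res2$overlap$mesh)
  expect_identical(length(res2$complement$mapping$elem_map), n_elems(m))

  # size 0 captures only exact centroid/vertex coincidences (none here)
  res3 <- extract_overlap(m, probe, size = 0)
  expect_null(res3$overlap$mesh)
})

test_that("merging distant meshes concatenates, nearby vertices unify", {
  m <- box_tet_mesh(2, 2, 2)
  far <- m
  far$points <- far$points + 100
  mm <- merge_meshes(m, far)
  expect_identical(n_points(mm), 2L * n_points(m))
  expect_identical(n_elems(mm), 2L * n_elems(m))

  # split a box into its two tag halves and re-merge across the interface
  box <- box_tet_mesh(3, 3, 4, label_planes = list(axis = "z", at = 2))
  a <- extract_submesh(box, 1)$mesh
  b <- extract_submesh(box, 2)$mesh
  joined <- merge_meshes(a, b, tolerance = 1e-6 * 5)
  expect_identical(n_points(joined), n_points(box))
  expect_identical(n_elems(joined), n_elems(box))
  expect_identical(sort(unique(joined$tags)), c(1L, 2L))
  # the joined mesh is conforming again
  ft <- meshops:::tet_face_table(joined$conn, seq_len(n_elems(joined)))
  expect_true(all(table(meshops:::face_keys(ft$faces, n_points(joined))) <= 2))

  # tolerance 0 only unifies bit-identical coordinates
  joined0 <- merge_meshes(a, b, tolerance = 0)
  expect_identical(n_points(joined0), n_points(box))
})

test_that("unification that would degenerate an element is an error", {
  tri1 <- mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  # second triangle has two vertices within tolerance of the SAME msh1 vertex
  tri2 <- mesh(rbind(c(0, 0, 1e-9), c(1e-9, 0, 0), c(5, 5, 5)), rbind(1:3))
  expect_error(merge_meshes(tri1, tri2, tolerance = 1e-3),
               class = "mt_geometry_error")
})
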