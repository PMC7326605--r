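test_that("a single tet's boundary is its four outward faces", {
  m <- unit_tet()
  s <- extract_boundary_surface(m, 1)
  expect_identical(nrow(s$faces), 4L)
  # outward: each face normal points away from the opposite vertex, so the
  # enclosed volume equals the tet volume with positive sign
  expect_equal(enclosed_volume(s, m$points), 1 / 6)
  expect_error(extract_boundary_surface(m, 99),
               class = "mt_empty_selection_error")
})

test_that("boundary extraction matches the face-multiplicity oracle", {
  m <- two_label_box(3)
  for (tags in list(1, 2, c(1, 2))) {
    s <- extract_boundary_surface(m, tags)
    expect_identical(surface_face_keys(s), oracle_boundary_face_keys(m, tags))
  }
  # whole-box boundary contains no interface faces
  s_all <- extract_boundary_surface(m, c(1, 2))
  s1 <- extract_boundary_surface(m, 1)
  s2 <- extract_boundary_surface(m, 2)
  iface <- surface_intersection(s1, s2)
  expect_gt(nrow(iface$faces), 0L)
  expect_identical(nrow(surface_intersection(s_all, iface)$faces), 0L)
})

test_that("boundary surfaces of ball-like tag regions are closed with Euler characteristic 2", {
  m <- two_label_box(3)
  for (tags in list(1, 2, c(1, 2))) {
    s <- extract_boundary_surface(m, tags)
    expect_identical(euler_characteristic(s), 2L)
    expect_gt(enclosed_volume(s, m$points), 0)
  }
  sh <- shell_with_cavity(1, 0.55, 8)
  expect_identical(euler_characteristic(extract_boundary_surface(sh, 1)), 2L)
})

test_that("surface set algebra satisfies the set identities", {
  m <- two_label_box(3)
  a <- extract_boundary_surface(m, 1)
  empty <- surface(matrix(integer(0), 0, 3), a$parent_point_count)
  expect_identical(surface_face_keys(surface_intersection(a, a)),
                   surface_face_keys(a))
  expect_identical(nrow(surface_difference(a, a)$faces), 0L)
  expect_identical(surface_face_keys(surface_union(a, empty)),
                   surface_face_keys(a))
  b <- extract_boundary_surface(m, 2)
  expect_error(surface_union(a, surface(rbind(c(1, 2, 3)), 3)),
               class = "mt_usage_error")
  # random face subsets against a brute-force key-set oracle
  set.seed(21)
  for (i in 1:5) {
    fa <- a$faces[sample(nrow(a$faces), 20), ]
    fb <- b$faces[sample(nrow(b$faces), 20), ]
    sa <- surface(fa, a$parent_point_count)
    sb <- surface(fb, a$parent_point_count)
    ka <- surface_face_keys(sa); kb <- surface_face_keys(sb)
    expect_identical(surface_face_keys(surface_union(sa, sb)),
                     sort(union(ka, kb)))
    expect_identical(surface_face_keys(surface_intersection(sa, sb)),
                     sort(intersect(ka, kb)))
    expect_identical(surface_face_keys(surface_difference(sa, sb)),
                     sort(setdiff(ka, kb)))
  }
})

test_that("the interface of tissue and cavity equals their boundary intersection", {
  sh <- shell_with_cavity(1, 0.55, 10)
  tissue <- extract_boundary_surface(sh, 2)
  pool <- extract_boundary_surface(sh, 1)
  endo <- surface_intersection(tissue, pool)
  # oracle: faces shared between a tissue tet and a cavity tet
  ft <- meshops:::tet_face_table(sh$conn, seq_len(n_elems(sh)))
  fk <- meshops:::face_keys(ft$faces, n_points(sh))
  tags_by_face <- split(sh$tags[ft$elem], fk)
  iface_keys <- names(tags_by_face)[vapply(tags_by_face, function(x)
    length(x) == 2 && length(unique(x)) == 2, logical(1))]
  expect_identical(nrow(endo$faces), length(iface_keys))
  expect_setequal(as.character(meshops:::face_keys(endo$faces, n_points(sh))),
                  iface_keys)
  expect_identical(euler_characteristic(endo), 2L)
})

test_that("seeded traversal with edge blocking isolates flat patches exactly", {
  m <- box_tet_mesh(3, 3, 3)
  s <- extract_boundary_surface(m, 1)
  r <- restrict_by_traversal(s, m$points, seeds = c(1.5, 1.5, 0),
                             block_angle_deg = 45, snap_radius = Inf)
  # exactly the bottom patch: 18 faces, all at z = 0
  expect_identical(nrow(r$faces), 18L)
  expect_true(all(m$points[unique(as.vector(r$faces)), 3] == 0))
  # no blocking, unlimited distance: the full component
  r_all <- restrict_by_traversal(s, m$points, seeds = c(1.5, 1.5, 0),
                                 snap_radius = Inf)
  expect_identical(surface_face_keys(r_all), surface_face_keys(s))
  # distance 0 keeps no face ("seed vertex only" semantics)
  r0 <- restrict_by_traversal(s, m$points, seeds = c(1, 1, 0),
                              max_edge_distance = 0, snap_radius = Inf)
  expect_identical(nrow(r0$faces), 0L)
  # off-surface seeds are snapped with a warning, never silently
  expect_warning(
    restrict_by_traversal(s, m$points, seeds = c(1.5, 1.5, -2),
                          snap_radius = 0.5),
    "snapped")
})

test_that("traversal output is monotone in distance and block angle", {
  m <- box_tet_mesh(3, 3, 3)
  s <- extract_boundary_surface(m, 1)
  seed <- c(0, 0, 0)
  prev <- character(0)
  for (d in c(1, 2.5, 5, Inf)) {
    r <- restrict_by_traversal(s, m$points, seed, max_edge_distance = d,
                               snap_radius = Inf)
    keys <- surface_face_keys(r)
    expect_true(all(prev %in% keys))
    expect_true(all(keys %in% surface_face_keys(s)))
    prev <- keys
  }
  prev <- character(0)
  for (ang in c(30, 60, 95)) {
    r <- restrict_by_traversal(s, m$points, seed, block_angle_deg = ang,
                               snap_radius = Inf)
    keys <- surface_face_keys(r)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})
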