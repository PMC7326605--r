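# Shared in-code fixtures for the test suite.

unit_tet <- function() {
  mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), rbind(1:4))
}

two_tets <- function() {
  # two tets sharing face (2,3,4)
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  mesh(pts, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
}

two_label_box <- function(n = 3) {
  box_tet_mesh(n, n, n, label_planes = list(axis = "z", at = floor(n / 2) + 1))
}

# positions of a regular tetrahedron with unit edge
regular_tet_points <- function(scale = 1) {
  scale * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
}

# independent brute-force: count faces occurring once among tets of a tag set
oracle_boundary_face_keys <- function(m, tag_set) {
  tets <- which(m$tags %in% tag_set & m$etype == 4L)
  cc <- m$conn[tets, , drop = FALSE]
  keys <- character(0)
  for (i in seq_len(nrow(cc))) {
    for (f in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
      keys <- c(keys, paste(sort(cc[i, f]), collapse = "-"))
    }
  }
  tb <- table(keys)
  sort(names(tb)[tb == 1])
}

surface_face_keys <- function(s) {
  sort(apply(s$faces, 1, function(f) paste(sort(f), collapse = "-")))
}

# edges of the elements carrying a tag, with lengths
region_edge_lengths <- function(m, tag) {
  el <- which(m$tags == tag)
  ei <- meshops:::elem_edge_instances(m$conn[el, , drop = FALSE], m$etype[el])
  k <- unique(meshops:::edge_keys(ei$edges, nrow(m$points)))
  lo <- k %/% (nrow(m$points) + 1)
  hi <- k %% (nrow(m$points) + 1)
  meshops:::edge_lengths(m$points, cbind(lo, hi))
}

all_edge_lengths <- function(m) {
  meshops:::edge_lengths(m$points, mesh_graph(m)$unique_edges)
}
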