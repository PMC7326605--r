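# Surface definition files: basename.surf (face list) + basename.vtx
# (vertex list).
#
#   .surf  line 1 = face count, then "Tr v0 v1 v2" per face (0-based)
#   .vtx   line 1 = vertex count, line 2 = "intra" (compatibility token,
#          written always, ignored on read), then one 0-based index per line

#' Read a surface definition (.surf + .vtx pair)
#'
#' The vertex set is rebuilt from the faces; `.vtx` entries absent from all
#' faces are retained with a warning.
#'
#' @param path_surf path to the `.surf` file.
#' @param path_vtx path to the `.vtx` file; defaults to `path_surf` with the
#'   extension swapped.  May be missing.
#' @param parent_point_count parent indexing size; defaults to the largest
#'   referenced index.
#' @return A [surface()].
#' @export
read_surface <- function(path_surf, path_vtx = NULL,
                         parent_point_count = NULL) {
  if (!file.exists(path_surf)) mt_format_error("missing file: %s", path_surf)
  path_vtx <- path_vtx %||% sub("\\.surf$", ".vtx", path_surf)
  lines <- readLines(path_surf)
  nf <- parse_count_header(lines[1], path_surf)
  if (length(lines) < nf + 1)
    mt_parse_error("%s: declared %d faces but file ends at line %d",
                   basename(path_surf), nf, length(lines))
  fl <- split_fields(lines[1 + seq_len(nf)])
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    f <- fl[[i]]
    if (length(f) != 4 || f[1] != "Tr")
      mt_parse_error("%s: line %d: expected 'Tr v0 v1 v2'",
                     basename(path_surf), i + 1L)
    faces[i, ] <- as.integer(f[2:4]) + 1L
  }
  vtx <- integer(0)
  if (file.exists(path_vtx)) {
    vl <- readLines(path_vtx)
    nv <- parse_count_header(vl[1], path_vtx)
    if (length(vl) < nv + 2)
      mt_parse_error("%s: declared %d vertices but file ends at line %d",
                     basename(path_vtx), nv, length(vl))
    vtx <- as.integer(vl[2 + seq_len(nv)]) + 1L
  }
  parent_point_count <- parent_point_count %||%
    max(c(faces, vtx, 0L))
  s <- surface(faces, parent_point_count)
  orphan <- setdiff(vtx, s$vertex_set)
  if (length(orphan))
    warning(sprintf("%d .vtx vertices are absent from all faces; retained in file only",
                    length(orphan)))
  s
}

#' Write a surface definition (.surf + .vtx pair)
#'
#' The vertex file is recomputed from the faces and carries the `intra`
#' domain keyword on line 2.
#'
#' @param surf a [surface()].
#' @param basename output path without extension.
#' @return `basename`, invisibly.
#' @export
write_surface <- function(surf, basename) {
  f <- surf$faces
  writeLines(c(as.character(nrow(f)),
               if (nrow(f)) paste("Tr", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             paste0(basename, ".surf"))
  vs <- surf$vertex_set
  writeLines(c(as.character(length(vs)), "intra", as.character(vs - 1L)),
             paste0(basename, ".vtx"))
  invisible(basename)
}
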