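# CARP plain-text multi-file mesh dialect: basename.pts / .elem / .lon.
#
#   .pts   line 1 = point count, then "x y z" per line
#   .elem  line 1 = element count, then "Tt v0 v1 v2 v3 tag" per tet and
#          "Tr v0 v1 v2 tag" per triangle; 0-based indices
#   .lon   line 1 = number of fiber directions per element (must be 1),
#          then one unit triple per element
#
# Indices are converted to this package's 1-based convention on read and
# back on write.

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

parse_count_header <- function(line, path) {
  n <- suppressWarnings(as.integer(line))
  if (is.na(n) || n < 0)
    mt_parse_error("%s: line 1: expected a non-negative count, got '%s'",
                   basename(path), line)
  n
}

#' Read a CARP-format mesh
#'
#' @param basename path without extension; `basename.pts` and
#'   `basename.elem` must exist, `basename.lon` (fibers) is optional.
#' @return A [mesh].
#' @export
read_carp_mesh <- function(basename) {
  pts_path <- paste0(basename, ".pts")
  elem_path <- paste0(basename, ".elem")
  if (!file.exists(pts_path)) mt_format_error("missing file: %s", pts_path)
  if (!file.exists(elem_path)) mt_format_error("missing file: %s", elem_path)

  plines <- readLines(pts_path)
  np <- parse_count_header(plines[1], pts_path)
  if (length(plines) < np + 1)
    mt_parse_error("%s: expected %d point lines, file ends at line %d",
                   basename(pts_path), np, length(plines))
  pts <- matrix(scan(text = plines[1 + seq_len(np)], what = double(),
                     quiet = TRUE), ncol = 3, byrow = TRUE)

  elines <- readLines(elem_path)
  ne <- parse_count_header(elines[1], elem_path)
  if (length(elines) < ne + 1)
    mt_parse_error("%s: declared %d elements but file ends at line %d",
                   basename(elem_path), ne, length(elines))
  fl <- split_fields(elines[1 + seq_len(ne)])
  conn <- matrix(NA_integer_, ne, 4)
  tags <- integer(ne)
  etok <- vapply(fl, `[`, character(1), 1L)
  bad <- which(!etok %in% c("Tt", "Tr"))
  if (length(bad))
    mt_format_error("%s: line %d: unsupported element token '%s' (only Tt/Tr)",
                    basename(elem_path), bad[1] + 1L, etok[bad[1]])
  for (i in seq_len(ne)) {
    f <- fl[[i]]
    need <- if (f[1] == "Tt") 6L else 5L
    if (length(f) != need)
      mt_parse_error("%s: line %d: expected %d fields, got %d",
                     basename(elem_path), i + 1L, need, length(f))
    v <- as.integer(f[-1])
    conn[i, seq_len(need - 2L)] <- v[seq_len(need - 2L)] + 1L
    tags[i] <- v[need - 1L]
  }

  fibers <- NULL
  lon_path <- paste0(basename, ".lon")
  if (file.exists(lon_path)) {
    llines <- readLines(lon_path)
    ndir <- parse_count_header(llines[1], lon_path)
    if (ndir != 1L)
      mt_format_error("%s: %d fiber directions per element unsupported (only 1)",
                      basename(lon_path), ndir)
    if (length(llines) < ne + 1)
      mt_parse_error("%s: expected %d fiber lines, file ends at line %d",
                     basename(lon_path), ne, length(llines))
    fibers <- matrix(scan(text = llines[1 + seq_len(ne)], what = double(),
                          quiet = TRUE), ncol = 3, byrow = TRUE)
  }
  mesh(pts, conn, tags = tags, fibers = fibers, reorient = FALSE)
}

fmt_num <- function(x, digits) {
  formatC(x, digits = digits, format = "g")
}

#' Write a CARP-format mesh
#'
#' Emits `basename.pts`, `basename.elem` and, when fibers are present,
#' `basename.lon`.
#'
#' @param m a [mesh].
#' @param basename output path without extension.
#' @param digits significant digits for coordinates (default 6; increase for
#'   bit-stable round-trips of non-representable values).
#' @return `basename`, invisibly.
#' @export
write_carp_mesh <- function(m, basename, digits = 6) {
  pts <- m$points
  writeLines(c(as.character(nrow(pts)),
               paste(fmt_num(pts[, 1], digits), fmt_num(pts[, 2], digits),
                     fmt_num(pts[, 3], digits))),
             paste0(basename, ".pts"))
  tet <- m$etype == 4L
  lines <- character(n_elems(m))
  if (any(tet))
    lines[tet] <- paste("Tt", m$conn[tet, 1] - 1L, m$conn[tet, 2] - 1L,
                        m$conn[tet, 3] - 1L, m$conn[tet, 4] - 1L, m$tags[tet])
  if (any(!tet))
    lines[!tet] <- paste("Tr", m$conn[!tet, 1] - 1L, m$conn[!tet, 2] - 1L,
                         m$conn[!tet, 3] - 1L, m$tags[!tet])
  writeLines(c(as.character(n_elems(m)), lines), paste0(basename, ".elem"))
  if (!is.null(m$fibers))
    writeLines(c("1",
                 paste(fmt_num(m$fibers[, 1], digits),
                       fmt_num(m$fibers[, 2], digits),
                       fmt_num(m$fibers[, 3], digits))),
               paste0(basename, ".lon"))
  invisible(basename)
}
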