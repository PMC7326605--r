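# VTK legacy ASCII unstructured grids (DATASET UNSTRUCTURED_GRID, cell
# types 10 = tetra and 5 = triangle, optional integer CELL_DATA SCALARS
# named "tags").

#' Read a VTK legacy ASCII unstructured grid
#'
#' Supports cell types 10 (tetrahedron) and 5 (triangle); an integer
#' `CELL_DATA` scalar array named `tags` becomes the mesh's region tags
#' (default 0 otherwise, matching the format's convention).  Binary files
#' are rejected with advice to convert.
#'
#' @param path file path.
#' @return A [mesh].
#' @export
read_vtk_mesh <- function(path) {
  if (!file.exists(path)) mt_format_error("missing file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) mt_parse_error("%s: truncated VTK file", basename(path))
  enc <- toupper(trimws(lines[3]))
  if (enc == "BINARY")
    mt_format_error("%s: BINARY VTK is unsupported; convert to ASCII first",
                    basename(path))
  if (enc != "ASCII")
    mt_parse_error("%s: line 3: expected ASCII or BINARY, got '%s'",
                   basename(path), lines[3])
  dataset <- toupper(trimws(lines[4]))
  if (!grepl("^DATASET\\s+UNSTRUCTURED_GRID$", dataset))
    mt_format_error("%s: only DATASET UNSTRUCTURED_GRID is supported (got '%s')",
                    basename(path), lines[4])
  toks <- scan(text = lines[-(1:4)], what = character(), quiet = TRUE)
  p <- 1L
  peek <- function() if (p <= length(toks)) toks[p] else NA_character_
  take <- function(k = 1L) {
    if (p + k - 1L > length(toks))
      mt_parse_error("%s: unexpected end of file", basename(path))
    out <- toks[p:(p + k - 1L)]; p <<- p + k; out
  }
  pts <- NULL; cells <- NULL; ctypes <- NULL; tags <- NULL
  while (!is.na(peek())) {
    kw <- toupper(peek())
    if (kw == "POINTS") {
      take()
      np <- as.integer(take())
      take()  # dtype
      pts <- matrix(as.numeric(take(3L * np)), ncol = 3, byrow = TRUE)
    } else if (kw == "CELLS") {
      take()
      nc <- as.integer(take())
      total <- as.integer(take())
      raw <- as.integer(take(total))
      cells <- vector("list", nc)
      q <- 1L
      for (i in seq_len(nc)) {
        k <- raw[q]
        cells[[i]] <- raw[(q + 1L):(q + k)]
        q <- q + k + 1L
      }
    } else if (kw == "CELL_TYPES") {
      take()
      nc <- as.integer(take())
      ctypes <- as.integer(take(nc))
    } else if (kw == "CELL_DATA") {
      take(); take()  # count
    } else if (kw == "POINT_DATA") {
      take(); take()
    } else if (kw == "SCALARS") {
      take()
      name <- take(); take()  # dtype
      ncomp <- 1L
      if (!is.na(peek()) && !is.na(suppressWarnings(as.integer(peek()))))
        ncomp <- as.integer(take())
      if (toupper(peek()) == "LOOKUP_TABLE") { take(); take() }
      nvals <- length(ctypes) * ncomp
      vals <- as.numeric(take(nvals))
      if (name == "tags") tags <- as.integer(vals)
    } else if (kw == "LOOKUP_TABLE") {
      take(); take()
    } else {
      mt_parse_error("%s: unsupported VTK section '%s'", basename(path), peek())
    }
  }
  if (is.null(pts) || is.null(cells) || is.null(ctypes))
    mt_parse_error("%s: missing POINTS/CELLS/CELL_TYPES section", basename(path))
  bad <- which(!ctypes %in% c(10L, 5L))
  if (length(bad))
    mt_format_error("%s: unsupported cell type %d (only 10 = tetra, 5 = triangle)",
                    basename(path), ctypes[bad[1]])
  conn <- matrix(NA_integer_, length(cells), 4)
  for (i in seq_along(cells)) {
    v <- cells[[i]] + 1L
    if (length(v) != ifelse(ctypes[i] == 10L, 4L, 3L))
      mt_parse_error("%s: cell %d has %d vertices, inconsistent with its type",
                     basename(path), i, length(v))
    conn[i, seq_along(v)] <- v
  }
  mesh(pts, conn, tags = tags %||% rep(0L, length(cells)), reorient = FALSE)
}

#' Write a VTK legacy ASCII unstructured grid
#'
#' Emits POINTS (float), CELLS, CELL_TYPES and the region tags as an integer
#' CELL_DATA scalar named `tags`.
#'
#' @param m a [mesh].
#' @param path output path.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(m, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "meshops unstructured grid",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n_points(m))), con)
  writeLines(paste(fmt_num(m$points[, 1], digits), fmt_num(m$points[, 2], digits),
                   fmt_num(m$points[, 3], digits)), con)
  tet <- m$etype == 4L
  nrows <- n_elems(m)
  total <- sum(m$etype + 1L)
  writeLines(sprintf("CELLS %d %d", nrows, total), con)
  lines <- character(nrows)
  if (any(tet))
    lines[tet] <- paste(4L, m$conn[tet, 1] - 1L, m$conn[tet, 2] - 1L,
                        m$conn[tet, 3] - 1L, m$conn[tet, 4] - 1L)
  if (any(!tet))
    lines[!tet] <- paste(3L, m$conn[!tet, 1] - 1L, m$conn[!tet, 2] - 1L,
                         m$conn[!tet, 3] - 1L)
  writeLines(lines, con)
  writeLines(sprintf("CELL_TYPES %d", nrows), con)
  writeLines(as.character(ifelse(tet, 10L, 5L)), con)
  writeLines(c(sprintf("CELL_DATA %d", nrows),
               "SCALARS tags int 1",
               "LOOKUP_TABLE default",
               as.character(m$tags)), con)
  invisible(path)
}
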