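# Data field files: .dat (one scalar per line), .vec (three numbers per
# line); no headers.  Length is validated against a mesh at attach time
# ([validate_field()]), not at read time.

#' Read a scalar (.dat) or vector (.vec) data field
#'
#' @param path file path; width is inferred from the extension (`.vec` = 3,
#'   anything else = 1) unless given.
#' @param attachment `"node"` or `"element"`.
#' @param width 1 or 3; overrides the extension.
#' @return A [data_field()].
#' @export
read_data <- function(path, attachment = c("node", "element"), width = NULL) {
  attachment <- match.arg(attachment)
  if (!file.exists(path)) mt_format_error("missing file: %s", path)
  width <- width %||% if (grepl("\\.vec$", path)) 3L else 1L
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data_field(matrix(numeric(0), 0, width), attachment))
  fl <- split_fields(lines)
  bad <- which(lengths(fl) != width)
  if (length(bad))
    mt_parse_error("%s: line %d has %d values, expected %d",
                   basename(path), bad[1], lengths(fl)[bad[1]], width)
  vals <- matrix(as.numeric(unlist(fl)), ncol = width, byrow = TRUE)
  data_field(vals, attachment)
}

#' Write a data field to a .dat/.vec file
#'
#' @param field a [data_field()].
#' @param path output path.
#' @param digits significant digits.
#' @return `path`, invisibly.
#' @export
write_data <- function(field, path, digits = 6) {
  v <- field$values
  lines <- if (field$width == 1L) fmt_num(v[, 1], digits) else
    paste(fmt_num(v[, 1], digits), fmt_num(v[, 2], digits),
          fmt_num(v[, 3], digits))
  writeLines(lines, path)
  invisible(path)
}
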