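# Internal helpers: error conditions, small vector algebra, spatial hashing.

mt_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mt_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

mt_usage_error    <- function(msg, ...) mt_error("mt_usage_error", msg, ...)
mt_parse_error    <- function(msg, ...) mt_error("mt_parse_error", msg, ...)
mt_format_error   <- function(msg, ...) mt_error("mt_format_error", msg, ...)
mt_geometry_error <- function(msg, ...) mt_error("mt_geometry_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1], deparse.level = 0)
}

row_norms <- function(m) sqrt(rowSums(m * m))

# Normalise rows; zero rows stay zero.
normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

as_point_matrix <- function(x, what = "points") {
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3)
    mt_usage_error("%s must be an n x 3 numeric matrix", what)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

bbox_diagonal <- function(points) {
  if (nrow(points) == 0) return(0)
  rng <- apply(points, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

# Encode small integer tuples (columns of m, each value in [1, base-1]) as
# one double key. Caller must ensure base^ncol stays below 2^53.
tuple_key <- function(m, base) {
  k <- as.numeric(m[, 1])
  for (j in seq_len(ncol(m))[-1]) k <- k * base + m[, j]
  k
}

edge_keys <- function(edges, n_points) {
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  tuple_key(cbind(lo, hi), n_points + 1)
}

# Sort each row ascending (for canonical face identity). m: n x 3 integer.
sort_rows3 <- function(m) {
  lo <- pmin(m[, 1], m[, 2], m[, 3])
  hi <- pmax(m[, 1], m[, 2], m[, 3])
  mid <- m[, 1] + m[, 2] + m[, 3] - lo - hi
  cbind(lo, mid, hi, deparse.level = 0)
}

face_keys <- function(faces, n_points) {
  if (n_points > 200000L)
    mt_usage_error("meshes beyond 200k points are not supported")
  tuple_key(sort_rows3(faces), n_points + 1)
}

# --- uniform-grid spatial hash -------------------------------------------
# Nearest / within-radius queries without an external kd-tree dependency.

grid_index <- function(points, cell) {
  stopifnot(cell > 0)
  origin <- apply(points, 2, min)
  ijk <- floor(sweep(points, 2, origin) / cell)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  list(points = points, cell = cell, origin = origin,
       buckets = split(seq_len(nrow(points)), key))
}

grid_candidates <- function(gi, q) {
  ijk <- floor((q - gi$origin) / gi$cell)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keys <- paste(ijk[1] + off[, 1], ijk[2] + off[, 2], ijk[3] + off[, 3])
  unlist(gi$buckets[keys], use.names = FALSE)
}

# Indices of `queries` rows having at least one `points` row within `radius`.
within_radius_any <- function(queries, points, radius) {
  if (nrow(points) == 0 || nrow(queries) == 0) return(integer(0))
  if (radius <= 0) {
    key_p <- paste(points[, 1], points[, 2], points[, 3])
    key_q <- paste(queries[, 1], queries[, 2], queries[, 3])
    return(which(key_q %in% key_p))
  }
  gi <- grid_index(points, radius)
  r2 <- radius^2
  hits <- vapply(seq_len(nrow(queries)), function(i) {
    cand <- grid_candidates(gi, queries[i, ])
    if (length(cand) == 0) return(FALSE)
    d2 <- (points[cand, 1] - queries[i, 1])^2 +
          (points[cand, 2] - queries[i, 2])^2 +
          (points[cand, 3] - queries[i, 3])^2
    any(d2 <= r2)
  }, logical(1))
  which(hits)
}

# Nearest row of `points` for one query coordinate; ties -> lowest index.
nearest_point <- function(points, q) {
  d2 <- (points[, 1] - q[1])^2 + (points[, 2] - q[2])^2 + (points[, 3] - q[3])^2
  i <- which.min(d2)
  list(index = i, dist = sqrt(d2[i]))
}
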