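#' Minimum-image displacement in a rectangular periodic box
#'
#' Applies the minimum-image convention componentwise: each displacement is
#' shifted by integer multiples of the box edge so that it lies in
#' `[-L/2, L/2)`.
#'
#' @param d numeric matrix (n x k) or vector of raw displacements.
#' @param box numeric vector of box edge lengths, one per column of `d`.
#' @return object of the same shape as `d`, wrapped to the minimum image.
#' @export
min_image <- function(d, box) {
  d <- as.matrix(d)
  if (length(box) != ncol(d)) {
    stop("`box` must supply one edge length per coordinate column")
  }
  for (k in seq_along(box)) {
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}

#' Minimum-image Euclidean distances between one point and a set
#'
#' @param p numeric vector, a single point.
#' @param pts matrix of points (rows), same dimension as `p`.
#' @param box box edge lengths.
#' @return numeric vector of distances.
#' @export
min_image_dist <- function(p, pts, box) {
  d <- min_image(sweep(as.matrix(pts), 2, p), box)
  sqrt(rowSums(d^2))
}

# Wrap coordinates into [0, L)
wrap_coords <- function(x, box) {
  x <- as.matrix(x)
  for (k in seq_along(box)) x[, k] <- x[, k] %% box[k]
  x
}

# Cell-list construction for fixed-radius neighbour queries under PBC.
# Cell widths are >= `cutoff`, so all neighbours of a point lie in the
# 3^k block of cells around it.
make_cell_list <- function(pts, box, cutoff) {
  pts <- as.matrix(pts)
  k <- ncol(pts)
  m <- pmax(1L, as.integer(floor(box / cutoff)))
  w <- box / m
  idx <- matrix(0L, nrow(pts), k)
  for (j in seq_len(k)) {
    idx[, j] <- pmin(as.integer(floor((pts[, j] %% box[j]) / w[j])), m[j] - 1L)
  }
  key <- idx[, 1]
  mult <- 1L
  for (j in seq_len(k)[-1]) {
    mult <- mult * m[j - 1]
    key <- key + idx[, j] * mult
  }
  members <- split(seq_len(nrow(pts)), key)
  list(pts = pts, box = box, m = m, members = members, key = key)
}

# Indices of points within `cutoff` (<=) of point p, minimum image.
cell_query <- function(cl, p, cutoff) {
  k <- length(p)
  m <- cl$m
  w <- cl$box / m
  base <- pmin(as.integer(floor((p %% cl$box) / w)), m - 1L)
  offs <- lapply(seq_len(k), function(j) {
    if (m[j] >= 3L) -1L:1L else seq_len(m[j]) - 1L - base[j]
  })
  grid <- as.matrix(expand.grid(offs))
  keys <- integer(nrow(grid))
  mult <- 1L
  for (j in seq_len(k)) {
    cj <- (base[j] + grid[, j]) %% m[j]
    keys <- keys + cj * mult
    mult <- mult * m[j]
  }
  cand <- unlist(cl$members[as.character(unique(keys))], use.names = FALSE)
  if (is.null(cand) || length(cand) == 0L) return(integer(0))
  d <- min_image(sweep(cl$pts[cand, , drop = FALSE], 2, p), cl$box)
  cand[rowSums(d^2) <= cutoff^2]
}
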