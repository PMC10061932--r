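#' DBSCAN clustering with periodic-boundary distances
#'
#' Standard DBSCAN (core / border / noise) on 2D points with minimum-image
#' Euclidean distances in a rectangular periodic box. Neighbourhoods are
#' found with a cell list (cells at least `eps` wide), so only the 3x3
#' block of cells around a point is searched. `min_pts` counts the query
#' point itself, i.e. a core point has at least `min_pts - 1` other points
#' within `eps` (inclusive).
#'
#' Clusters are grown from core points in ascending point-index order, so a
#' border point reachable from several clusters is assigned to the
#' lowest-numbered (first-reaching) cluster; the labelling is therefore
#' deterministic, and stable under point reordering up to relabelling of
#' the non-boundary structure.
#'
#' @param points_xy n x 2 matrix of positions (nm) inside the box.
#' @param box_xy box edges `(Lx, Ly)` (nm).
#' @param eps neighbourhood radius (nm); must be below `min(box_xy) / 2`
#'   or periodic images become ambiguous.
#' @param min_pts minimum neighbourhood size (including the point itself)
#'   for a core point.
#' @return integer vector of cluster labels, `1..k`; `-1` marks noise.
#' @export
dbscan_pbc <- function(points_xy, box_xy, eps, min_pts) {
  pts <- as.matrix(points_xy)
  stopifnot(ncol(pts) == 2L, eps > 0, min_pts >= 1)
  if (eps >= min(box_xy) / 2) {
    stop("eps >= min(box)/2: periodic images ambiguous")
  }
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  cl <- make_cell_list(pts, box_xy, eps)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) nbrs[[i]] <- cell_query(cl, pts[i, ], eps)
  is_core <- lengths(nbrs) >= min_pts
  labels <- rep.int(-1L, n)
  visited <- rep.int(FALSE, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !is_core[i]) next
    cid <- cid + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cid
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (labels[q] == -1L) labels[q] <- cid
        if (!visited[q] && is_core[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}
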