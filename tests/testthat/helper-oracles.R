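# Independent reference implementations used as oracles. These are written
# against the textbook definitions (full O(n^2) distance matrices, direct
# search over rigid motions) and stay independent of the package's
# neighbour-search code paths.

# Textbook DBSCAN on a full periodic distance matrix. min_pts counts the
# point itself; clusters grow from core points in index order, so border
# points go to the first (lowest-id) cluster that reaches them — the same
# deterministic tie rule the package documents.
ref_dbscan <- function(pts, box, eps, min_pts) {
  n <- nrow(pts)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) D[i, ] <- min_image_dist(pts[i, ], pts, box)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  lab <- rep(-1L, n)
  vis <- rep(FALSE, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (vis[i] || !core[i]) next
    cid <- cid + 1L
    queue <- i
    vis[i] <- TRUE
    lab[i] <- cid
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (j in nb[[p]]) {
        if (lab[j] == -1L) lab[j] <- cid
        if (!vis[j] && core[j]) {
          vis[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# TRUE when two labelings define the same partition (including the noise
# set) up to renaming of cluster ids: both are relabelled canonically by
# first occurrence and compared exactly.
same_partition <- function(a, b) {
  canon <- function(l) {
    u <- unique(l[l != -1L])
    m <- match(l, u)
    m[l == -1L] <- -1L
    m
  }
  length(a) == length(b) && identical(canon(a), canon(b))
}

# Brute-force RMSD under optimal superposition: coarse search over Euler
# angles refined with optim, centroids aligned by construction.
ref_rmsd_superposed <- function(x, y, n_grid = 10) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  rot <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    Rz1 <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
    Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
    Rz2 <- rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((xc %*% rot(ang) - yc)^2)))
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  best <- c(0, 0, 0)
  best_v <- obj(best)
  for (a in grid) for (b in seq(0, pi, length.out = n_grid)) for (g in grid) {
    v <- obj(c(a, b, g))
    if (v < best_v) { best_v <- v; best <- c(a, b, g) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Minimal role/leaflet-complete topology of n single-atom molecules, for
# tests that need a topology without the full generator.
point_topology <- function(n, resname = "DPPC", atom_name = "P",
                           lipid_type = "DPPC", leaflet = "upper") {
  tp <- as_topology(data.frame(
    atom_id = seq_len(n), mol_id = seq_len(n), resid = seq_len(n),
    resname = resname, atom_name = atom_name, stringsAsFactors = FALSE))
  tp$role_phosphorus <- atom_name == "P"
  tp$role_chain_marker <- FALSE
  tp$role_chol_marker <- FALSE
  tp$role_protein <- FALSE
  tp$lipid_type <- lipid_type
  tp$leaflet <- leaflet
  tp
}

make_frame <- function(xyz, box, time = 0) {
  structure(list(time = time, box = box, xyz = as.matrix(xyz)),
            class = "md_frame")
}
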