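#' Specification for a synthetic monolayer configuration
#'
#' Describes a two-leaflet monolayer of DPPC/POPC/POPG/CHOL (default molar
#' ratios 60/20/10/10) with a planted fraction `f_lc` of chain markers on
#' hexagonally packed condensed (Lc) patches, the remainder placed as a
#' disordered (Le) background with a guaranteed minimum separation
#' (strictly above the DBSCAN radius, so the background never clusters),
#' and an optional pseudo-protein disc with a condensed-phase depletion
#' halo.
#'
#' The defaults define the study conditions for all planted-truth tests:
#' 400 lipids per leaflet at 90 Angstrom^2 per lipid (the expanded starting
#' state of a compression run), 0.48 nm condensed lattice spacing (so
#' condensed patches are resolvable at the default DBSCAN radius of
#' 0.55 nm), and a 0.56 nm minimum separation for disordered markers (just
#' above the DBSCAN radius, so the background never clusters).
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param composition named molar fractions over DPPC/POPC/POPG/CHOL;
#'   must sum to 1.
#' @param apl area per lipid (Angstrom^2).
#' @param f_lc planted condensed marker fraction in [0, 1].
#' @param lattice_spacing hexagonal marker spacing in condensed patches (nm).
#' @param patch_count number of condensed patches per leaflet; reduced
#'   automatically when the plant is too small to give every patch at
#'   least 12 markers (smaller islands would not count as condensed).
#' @param le_min_dist minimum separation of disordered markers (nm).
#' @param protein `NULL` or a list with `radius` (disc radius, nm),
#'   `n_beads`, `halo_width` (nm), `halo_lc_suppression` in [0, 1], and
#'   optionally `residues` (recycled residue names for the beads).
#' @param z_model list: `box_z` (nm), `leaflet_sep` (phosphorus
#'   plane-to-plane distance, nm), `p_sigma` (phosphorus z spread, nm),
#'   `marker_offset` (marker depth from the phosphorus plane toward the
#'   chain side, nm), `marker_sigma`; partial lists merge with the
#'   defaults.
#' @param seed integer RNG seed.
#' @return list of class `monolayer_spec`.
#' @export
monolayer_spec <- function(n_lipids_per_leaflet = 400,
                           composition = c(DPPC = 0.6, POPC = 0.2,
                                           POPG = 0.1, CHOL = 0.1),
                           apl = 90, f_lc = 0.3,
                           lattice_spacing = 0.48,
                           patch_count = 3,
                           le_min_dist = 0.55,
                           protein = NULL,
                           z_model = list(),
                           seed = 1L) {
  z_model <- utils::modifyList(
    list(box_z = 12, leaflet_sep = 5, p_sigma = 0.15,
         marker_offset = 1.0, marker_sigma = 0.05),
    z_model)
  stopifnot(abs(sum(composition) - 1) < 1e-9, apl > 0,
            f_lc >= 0, f_lc <= 1, lattice_spacing > 0,
            patch_count >= 1, le_min_dist > 0,
            n_lipids_per_leaflet >= 4)
  if (!is.null(protein)) {
    protein <- utils::modifyList(
      list(radius = 1.5, n_beads = 100, halo_width = 1.5,
           halo_lc_suppression = 1,
           residues = c("LEU", "VAL", "LYS", "ARG", "PHE",
                        "SER", "GLY", "ILE", "THR", "ALA")),
      protein)
    stopifnot(protein$radius > 0, protein$n_beads >= 3,
              protein$halo_width >= 0,
              protein$halo_lc_suppression >= 0,
              protein$halo_lc_suppression <= 1)
  }
  structure(list(n_lipids_per_leaflet = n_lipids_per_leaflet,
                 composition = composition, apl = apl, f_lc = f_lc,
                 lattice_spacing = lattice_spacing,
                 patch_count = patch_count, le_min_dist = le_min_dist,
                 protein = protein, z_model = z_model, seed = as.integer(seed)),
            class = "monolayer_spec")
}

# Largest-remainder apportionment of n molecules to fractions.
apportion <- function(fracs, n) {
  tgt <- fracs * n
  base <- floor(tgt)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(tgt - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

# Poisson-disc sampler in a periodic rectangle: n points, all strictly
# beyond min_dist from each other and from `existing`. Rejection uses an
# occupancy grid with cells >= min_dist wide, so each proposal is screened
# against at most the 3x3 block of neighbouring cells; batches of
# proposals are screened with vectorized gather operations.
#
# Plain dart throwing (random sequential adsorption) jams near
# 0.547 * 4 / (pi * min_dist^2) points per unit area -- about
# 2.3 /nm^2 at 0.55 nm -- which is below the chain density of compressed
# monolayers. Above 80% of that jamming density the whole background is
# therefore proposed from a randomly oriented, jittered hexagonal
# candidate grid at 1.05 * min_dist instead (capacity ~3.5 /nm^2 at
# 0.55 nm). Every candidate passes the same strict distance check, so
# the separation guarantee -- the property the planted phases rely on --
# is identical in both regimes. Packings that stay incomplete even on
# the grid raise a geometry error.
poisson_disc_points <- function(n, box_xy, min_dist, existing = NULL,
                                max_attempts = NULL) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (is.null(max_attempts)) max_attempts <- max(5e5, 2000 * n)
  ex <- if (is.null(existing) || !nrow(existing)) matrix(numeric(0), 0, 2)
        else wrap_coords(as.matrix(existing), box_xy)
  md2 <- min_dist^2
  mg <- pmax(3L, as.integer(floor(box_xy / min_dist)))
  w <- box_xy / mg
  ncell <- mg[1] * mg[2]
  K <- 10L                       # max points a cell can hold
  cellpts <- matrix(NA_integer_, ncell, K)
  counts <- integer(ncell)
  all_pts <- matrix(NA_real_, nrow(ex) + n, 2)
  n_all <- 0L
  insert <- function(p) {
    n_all <<- n_all + 1L
    all_pts[n_all, ] <<- p
    ck <- cell_of(p)
    cn <- counts[ck] + 1L
    if (cn > K) stop("poisson-disc cell overflow (min_dist too small?)")
    cellpts[ck, cn] <<- n_all
    counts[ck] <<- cn
  }
  cell_of <- function(p) {
    cx <- pmin(as.integer(floor(p[1] / w[1])), mg[1] - 1L)
    cy <- pmin(as.integer(floor(p[2] / w[2])), mg[2] - 1L)
    cx + mg[1] * cy + 1L
  }
  for (i in seq_len(nrow(ex))) insert(ex[i, ])
  # 3x3 neighbour-cell keys for a vector of cell coords
  nb_keys <- function(cx, cy) {
    out <- matrix(0L, length(cx), 9L)
    k <- 0L
    for (dx in -1:1) for (dy in -1:1) {
      k <- k + 1L
      out[, k] <- ((cx + dx) %% mg[1]) + mg[1] * ((cy + dy) %% mg[2]) + 1L
    }
    out
  }
  check_and_insert <- function(p) {
    ck <- cell_of(p)
    cx <- (ck - 1L) %% mg[1]
    cy <- (ck - 1L) %/% mg[1]
    nbr <- cellpts[nb_keys(cx, cy), ]
    nbr <- nbr[!is.na(nbr)]
    if (length(nbr)) {
      d <- min_image(all_pts[nbr, , drop = FALSE] -
                       matrix(p, length(nbr), 2, byrow = TRUE), box_xy)
      if (any(rowSums(d^2) <= md2)) return(FALSE)
    }
    insert(p)
    TRUE
  }
  hex_fill <- function(n_acc) {
    a <- 1.05 * min_dist
      m_ext <- ceiling(sum(box_xy) / a)
      ij <- expand.grid(i = -m_ext:m_ext, j = -m_ext:m_ext)
      ang <- stats::runif(1, 0, pi / 3)
      rot <- cbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
      cand <- cbind(a * (ij$i + ij$j / 2), a * ij$j * sqrt(3) / 2) %*% rot
      cand <- cand + matrix(stats::rnorm(2 * nrow(cand), 0, 0.004),
                            ncol = 2)
      cand <- sweep(cand, 2, stats::runif(2) * box_xy, "+")
    keep <- cand[, 1] >= 0 & cand[, 1] < box_xy[1] &
      cand[, 2] >= 0 & cand[, 2] < box_xy[2]
    cand <- cand[keep, , drop = FALSE]
    for (ci in sample(nrow(cand))) {
      if (n_acc >= n) break
      if (check_and_insert(cand[ci, ])) n_acc <- n_acc + 1L
    }
    if (n_acc < n) {
      stop("requested packing infeasible: placed ", n_acc, " of ", n,
           " markers at minimum distance ", min_dist,
           " nm (increase apl?)")
    }
    n_acc
  }
  rho_jam <- 0.547 * 4 / (pi * min_dist^2)
  # area effectively unavailable around pre-placed points (their packing
  # cell plus part of the exclusion rim), used only to pick the regime
  free_a <- max(0.4 * prod(box_xy),
                prod(box_xy) - nrow(ex) * 0.25 * (min_dist / 0.55)^2)
  if (n / free_a > 0.8 * rho_jam) {
    hex_fill(0L)
    return(all_pts[nrow(ex) + seq_len(n), , drop = FALSE])
  }
  n_acc <- 0L
  attempts <- 0
  while (n_acc < n) {
    if (attempts >= max_attempts) {
      # dart throwing jammed unexpectedly; complete from the grid
      hex_fill(n_acc)
      break
    }
    m <- min(max(512L, 8L * (n - n_acc)), 8192L,
             as.integer(max_attempts - attempts) + 1L)
    px <- stats::runif(m) * box_xy[1]
    py <- stats::runif(m) * box_xy[2]
    attempts <- attempts + m
    cx <- pmin(as.integer(floor(px / w[1])), mg[1] - 1L)
    cy <- pmin(as.integer(floor(py / w[2])), mg[2] - 1L)
    keys <- nb_keys(cx, cy)
    # gather candidate point indices: m x 9K matrix, NA where empty
    cand <- matrix(cellpts[as.vector(keys), ], nrow = m)
    qx <- matrix(all_pts[cand, 1], nrow = m)
    dxv <- abs(qx - px)
    dxv <- pmin(dxv, box_xy[1] - dxv)
    qy <- matrix(all_pts[cand, 2], nrow = m)
    dyv <- abs(qy - py)
    dyv <- pmin(dyv, box_xy[2] - dyv)
    conflict <- rowSums(dxv * dxv + dyv * dyv <= md2, na.rm = TRUE) > 0
    for (s in which(!conflict)) {
      if (n_acc >= n) break
      p <- c(px[s], py[s])
      # re-check against points accepted earlier in this batch
      nbr <- cellpts[keys[s, ], ]
      nbr <- nbr[!is.na(nbr)]
      okay <- TRUE
      if (length(nbr)) {
        d <- min_image(all_pts[nbr, , drop = FALSE] -
                         matrix(p, length(nbr), 2, byrow = TRUE), box_xy)
        okay <- all(rowSums(d^2) > md2)
      }
      if (!okay) next
      insert(p)
      n_acc <- n_acc + 1L
    }
  }
  all_pts[nrow(ex) + seq_len(n), , drop = FALSE]
}

# n points of a triangular lattice with spacing a, spiralling out from
# `center`, randomly rotated; coordinates are unwrapped.
hex_patch_points <- function(n, center, a, angle = stats::runif(1, 0, pi / 3)) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  k <- 0L
  while (1 + 3 * k * (k + 1) < n) k <- k + 1L
  k <- k + 1L
  ij <- expand.grid(i = -k:k, j = -k:k)
  x <- a * (ij$i + ij$j / 2)
  y <- a * ij$j * sqrt(3) / 2
  keep <- order(x^2 + y^2)[seq_len(n)]
  rot <- cbind(c(cos(angle), sin(angle)), c(-sin(angle), cos(angle)))
  pts <- cbind(x[keep], y[keep]) %*% rot
  sweep(pts, 2, center, "+")
}

#' Generate a synthetic two-leaflet monolayer with planted phase labels
#'
#' Builds a full atomistic-style configuration (CHARMM36 atom names) from a
#' [monolayer_spec()]: per leaflet, `round(f_lc * n_markers)` chain markers
#' sit on hexagonal condensed patches and the rest form a disordered
#' background with guaranteed minimum separation; whole lipids (phosphorus,
#' glycerol filler, two chains with their 10th-carbon markers) are then
#' assembled around the markers, mirrored in z across the water slab.
#' An optional pseudo-protein disc suppresses condensed packing within its
#' halo. Ground-truth phase labels are returned for every marker.
#'
#' All randomness comes from `spec$seed`; the same spec always yields the
#' same configuration.
#'
#' @param spec a [monolayer_spec()].
#' @return list of class `monolayer`: `topology` (roles and leaflets
#'   assigned), `frame`, `truth` (data.frame: `leaflet`, `atom_id`,
#'   `mol_id`, `lipid_type`, `x`, `y`, `phase`, `in_halo`), `spec`.
#' @export
generate_monolayer <- function(spec) {
  stopifnot(inherits(spec, "monolayer_spec"))
  set.seed(spec$seed)
  n <- spec$n_lipids_per_leaflet
  L <- sqrt(n * spec$apl / 100)
  zm <- spec$z_model
  box <- c(L, L, zm$box_z)
  counts <- apportion(spec$composition, n)
  n_pl <- sum(counts[c("DPPC", "POPC", "POPG")])
  n_chol <- counts[["CHOL"]]
  n_markers <- 2L * n_pl + n_chol
  z_p <- c(lower = zm$box_z / 2 - zm$leaflet_sep / 2,
           upper = zm$box_z / 2 + zm$leaflet_sep / 2)
  pr <- spec$protein
  bead_xy <- NULL
  if (!is.null(pr)) {
    i <- seq_len(pr$n_beads)
    r <- pr$radius * sqrt(i / pr$n_beads)
    th <- i * pi * (3 - sqrt(5))
    bead_xy <- cbind(L / 2 + r * cos(th), L / 2 + r * sin(th))
  }
  leaf_data <- list()
  atoms <- list()
  truth <- list()
  mol_counter <- 0L
  atom_counter <- 0L
  for (lf in c("lower", "upper")) {
    out <- outward_sign(lf)
    mk <- place_markers(spec, box, bead_xy)
    asm <- assemble_leaflet(mk, counts, z_p[[lf]], out, zm, spec, bead_xy,
                            mol_offset = mol_counter,
                            atom_offset = atom_counter)
    mol_counter <- asm$mol_counter
    atom_counter <- asm$atom_counter
    asm$truth$leaflet <- lf
    atoms[[lf]] <- asm$atoms
    truth[[lf]] <- asm$truth
  }
  at <- do.call(rbind, atoms)
  xyz <- cbind(wrap_coords(at[, c("x", "y")], box[1:2]), at$z)
  colnames(xyz) <- NULL
  topo <- as_topology(data.frame(atom_id = seq_len(nrow(at)),
                                 mol_id = at$mol_id, resid = at$resid,
                                 resname = at$resname,
                                 atom_name = at$atom_name,
                                 stringsAsFactors = FALSE))
  frame <- structure(list(time = 0, box = box, xyz = xyz), class = "md_frame")
  topo <- assign_roles(topo)
  topo <- assign_leaflets(frame, topo)
  tr <- do.call(rbind, truth)
  rownames(tr) <- NULL
  structure(list(topology = topo, frame = frame, truth = tr, spec = spec),
            class = "monolayer")
}

# Plant condensed-lattice and disordered marker positions for one leaflet.
place_markers <- function(spec, box, bead_xy) {
  n <- spec$n_lipids_per_leaflet
  counts <- apportion(spec$composition, n)
  n_markers <- 2L * sum(counts[c("DPPC", "POPC", "POPG")]) + counts[["CHOL"]]
  n_lc_target <- round(spec$f_lc * n_markers)
  a <- spec$lattice_spacing
  pr <- spec$protein
  lc_pts <- matrix(numeric(0), 0, 2)
  if (n_lc_target > 0) {
    # never split the plant into patches too small to count as condensed
    n_patches <- max(1L, min(spec$patch_count, n_lc_target %/% 12L))
    sizes <- diff(round(seq(0, n_lc_target, length.out = n_patches + 1)))
    sizes <- sizes[sizes > 0]
    radii <- a * sqrt(sizes * sqrt(3) / 2 / pi) + a
    centers <- matrix(NA_real_, length(sizes), 2)
    for (p in seq_along(sizes)) {
      placed <- FALSE
      for (try in 1:2000) {
        cand <- stats::runif(2) * box[1:2]
        ok <- TRUE
        if (p > 1) {
          d <- min_image_dist(cand, centers[seq_len(p - 1), , drop = FALSE], box[1:2])
          ok <- all(d > radii[p] + radii[seq_len(p - 1)] + 0.6)
        }
        if (ok && !is.null(bead_xy)) {
          # keep the patch centre out of the halo; edge points that still
          # fall inside it are handled by the suppression demotion below
          db <- min_image_dist(cand, bead_xy, box[1:2])
          ok <- all(db > pr$halo_width + 0.6)
        }
        if (ok) { centers[p, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) centers[p, ] <- stats::runif(2) * box[1:2]
    }
    lc_pts <- do.call(rbind, lapply(seq_along(sizes), function(p) {
      hex_patch_points(sizes[p], centers[p, ], a)
    }))
    lc_pts <- wrap_coords(lc_pts, box[1:2])
  }
  in_halo_lc <- rep(FALSE, nrow(lc_pts))
  if (!is.null(bead_xy) && nrow(lc_pts)) {
    db <- vapply(seq_len(nrow(lc_pts)), function(i) {
      min(min_image_dist(lc_pts[i, ], bead_xy, box[1:2]))
    }, numeric(1))
    in_halo_lc <- db <= pr$halo_width
    demote <- (in_halo_lc & stats::runif(nrow(lc_pts)) < pr$halo_lc_suppression) |
      db <= spec$le_min_dist
    lc_pts <- lc_pts[!demote, , drop = FALSE]
    in_halo_lc <- in_halo_lc[!demote]
  }
  n_le <- n_markers - nrow(lc_pts)
  le_pts <- poisson_disc_points(n_le, box[1:2], spec$le_min_dist,
                                existing = rbind(lc_pts, bead_xy))
  pts <- rbind(lc_pts, le_pts)
  list(pts = pts,
       phase = c(rep("Lc", nrow(lc_pts)), rep("Le", n_le)),
       n_markers = n_markers)
}

# Assemble whole molecules around planted marker positions for one leaflet.
assemble_leaflet <- function(mk, counts, z_plane, out, zm, spec, bead_xy,
                             mol_offset, atom_offset) {
  pts <- mk$pts
  phase <- mk$phase
  box_xy <- c(sqrt(spec$n_lipids_per_leaflet * spec$apl / 100),
              sqrt(spec$n_lipids_per_leaflet * spec$apl / 100))
  n_markers <- nrow(pts)
  n_chol <- counts[["CHOL"]]
  chol_idx <- if (n_chol > 0) sample(n_markers, n_chol) else integer(0)
  pair_pool <- setdiff(seq_len(n_markers), chol_idx)
  pairs <- greedy_pair(pts[pair_pool, , drop = FALSE], box_xy)
  pairs <- matrix(pair_pool[pairs], ncol = 2)
  pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
  types <- rep(c("DPPC", "POPC", "POPG"),
               counts[c("DPPC", "POPC", "POPG")])
  n_pl <- nrow(pairs)
  stopifnot(length(types) == n_pl)
  q1 <- pts[pairs[, 1], , drop = FALSE]
  q2 <- pts[pairs[, 2], , drop = FALSE]
  mid <- q1 + 0.5 * min_image(q2 - q1, box_xy)
  p_z <- z_plane + stats::rnorm(n_pl, 0, zm$p_sigma)
  jit <- function(m, s = 0.05) m + matrix(stats::rnorm(2 * nrow(m), 0, s), ncol = 2)
  mz1 <- p_z + out * (zm$marker_offset + stats::rnorm(n_pl, 0, zm$marker_sigma))
  mz2 <- p_z + out * (zm$marker_offset + stats::rnorm(n_pl, 0, zm$marker_sigma))
  slots <- list(
    list(name = "P",    xy = jit(mid),                                    z = p_z),
    list(name = "C2",   xy = jit(mid),                                    z = p_z + out * 0.15),
    list(name = "C22",  xy = mid + 0.25 * min_image(q1 - mid, box_xy),    z = p_z + out * 0.35),
    list(name = "C210", xy = q1,                                          z = mz1),
    list(name = "C216", xy = jit(q1),                                     z = p_z + out * (zm$marker_offset + 0.55)),
    list(name = "C32",  xy = mid + 0.25 * min_image(q2 - mid, box_xy),    z = p_z + out * 0.35),
    list(name = "C310", xy = q2,                                          z = mz2),
    list(name = "C316", xy = jit(q2),                                     z = p_z + out * (zm$marker_offset + 0.55))
  )
  ns <- length(slots)
  arr <- array(NA_real_, c(ns, n_pl, 3))
  for (s in seq_len(ns)) {
    arr[s, , 1] <- slots[[s]]$xy[, 1]
    arr[s, , 2] <- slots[[s]]$xy[, 2]
    arr[s, , 3] <- slots[[s]]$z
  }
  pl_xyz <- matrix(as.vector(arr), ncol = 3)
  pl <- data.frame(
    mol_id = mol_offset + rep(seq_len(n_pl), each = ns),
    resid = mol_offset + rep(seq_len(n_pl), each = ns),
    resname = rep(types, each = ns),
    atom_name = rep(vapply(slots, `[[`, character(1), "name"), n_pl),
    x = pl_xyz[, 1], y = pl_xyz[, 2], z = pl_xyz[, 3],
    stringsAsFactors = FALSE
  )
  mol_counter <- mol_offset + n_pl
  # cholesterol: hydroxyl oxygen, one ring filler, C14 marker at chain depth
  chol <- NULL
  if (n_chol > 0) {
    qc <- pts[chol_idx, , drop = FALSE]
    cz <- z_plane + stats::rnorm(n_chol, 0, zm$p_sigma)
    cs <- list(
      list(name = "O3",  xy = jit(qc), z = cz + out * 0.10),
      list(name = "C3",  xy = jit(qc), z = cz + out * 0.55),
      list(name = "C14", xy = qc,      z = cz + out * zm$marker_offset)
    )
    arrc <- array(NA_real_, c(3, n_chol, 3))
    for (s in 1:3) {
      arrc[s, , 1] <- cs[[s]]$xy[, 1]
      arrc[s, , 2] <- cs[[s]]$xy[, 2]
      arrc[s, , 3] <- cs[[s]]$z
    }
    cxyz <- matrix(as.vector(arrc), ncol = 3)
    chol <- data.frame(
      mol_id = mol_counter + rep(seq_len(n_chol), each = 3),
      resid = mol_counter + rep(seq_len(n_chol), each = 3),
      resname = "CHL1",
      atom_name = rep(c("O3", "C3", "C14"), n_chol),
      x = cxyz[, 1], y = cxyz[, 2], z = cxyz[, 3],
      stringsAsFactors = FALSE
    )
    mol_counter <- mol_counter + n_chol
  }
  prot <- NULL
  pr <- spec$protein
  if (!is.null(pr)) {
    nb <- pr$n_beads
    layer <- rep(c(0.25, 0.85), length.out = nb)
    prot <- data.frame(
      mol_id = mol_counter + 1L,
      resid = mol_counter + seq_len(nb),
      resname = rep(pr$residues, length.out = nb),
      atom_name = "CA",
      x = bead_xy[, 1], y = bead_xy[, 2],
      z = z_plane + out * layer + stats::rnorm(nb, 0, 0.05),
      stringsAsFactors = FALSE
    )
    mol_counter <- mol_counter + 1L
  }
  at <- rbind(pl, chol, prot)
  # ground truth rows for every marker, with final atom ids
  marker_atom <- function(slot, molrow) atom_offset + (molrow - 1L) * ns + slot
  tr_pl <- data.frame(
    atom_id = c(marker_atom(4L, seq_len(n_pl)), marker_atom(7L, seq_len(n_pl))),
    mol_id = rep(mol_offset + seq_len(n_pl), 2),
    lipid_type = rep(types, 2),
    x = c(q1[, 1], q2[, 1]) %% box_xy[1],
    y = c(q1[, 2], q2[, 2]) %% box_xy[2],
    phase = c(phase[pairs[, 1]], phase[pairs[, 2]]),
    stringsAsFactors = FALSE
  )
  tr <- tr_pl
  if (n_chol > 0) {
    chol_marker_atom <- atom_offset + ns * n_pl + (seq_len(n_chol) - 1L) * 3L + 3L
    tr <- rbind(tr, data.frame(
      atom_id = chol_marker_atom,
      mol_id = mol_offset + n_pl + seq_len(n_chol),
      lipid_type = "CHOL",
      x = pts[chol_idx, 1] %% box_xy[1],
      y = pts[chol_idx, 2] %% box_xy[2],
      phase = phase[chol_idx],
      stringsAsFactors = FALSE
    ))
  }
  tr$in_halo <- FALSE
  if (!is.null(bead_xy)) {
    db <- vapply(seq_len(nrow(tr)), function(i) {
      min(min_image_dist(c(tr$x[i], tr$y[i]), bead_xy, box_xy))
    }, numeric(1))
    tr$in_halo <- db <= pr$halo_width
  }
  list(atoms = at, truth = tr,
       mol_counter = mol_counter,
       atom_counter = atom_offset + nrow(at))
}

# Greedy nearest-neighbour pairing of 2D points (minimum image); returns a
# two-column matrix of row indices.
greedy_pair <- function(pts, box_xy) {
  m <- nrow(pts)
  stopifnot(m %% 2 == 0)
  dx <- abs(outer(pts[, 1], pts[, 1], "-"))
  dx <- pmin(dx, box_xy[1] - dx)
  dy <- abs(outer(pts[, 2], pts[, 2], "-"))
  dy <- pmin(dy, box_xy[2] - dy)
  d2 <- dx * dx + dy * dy
  diag(d2) <- Inf
  unpaired <- rep(TRUE, m)
  pairs <- matrix(0L, m / 2, 2)
  k <- 0L
  for (i in seq_len(m)) {
    if (!unpaired[i]) next
    unpaired[i] <- FALSE
    row <- d2[i, ]
    row[!unpaired] <- Inf
    j <- which.min(row)
    unpaired[j] <- FALSE
    k <- k + 1L
    pairs[k, ] <- c(i, j)
  }
  pairs
}

#' Specification for a planted 2D Brownian trajectory
#'
#' @param D_true lateral diffusion coefficient (nm^2/ns).
#' @param n_particles independent particles (tracked as one-atom lipids).
#' @param dt frame spacing (ns).
#' @param n_steps number of steps (frames = `n_steps + 1`).
#' @param box_xy lateral box edge (nm, square).
#' @param seed RNG seed.
#' @return list of class `brownian_spec`.
#' @export
brownian_spec <- function(D_true = 0.05, n_particles = 100, dt = 0.5,
                          n_steps = 200, box_xy = 30, seed = 1L) {
  stopifnot(D_true >= 0, dt > 0, n_particles >= 1, n_steps >= 1, box_xy > 0)
  structure(list(D_true = D_true, n_particles = n_particles, dt = dt,
                 n_steps = n_steps, box_xy = box_xy, seed = as.integer(seed)),
            class = "brownian_spec")
}

#' Generate a 2D Brownian trajectory with known diffusion coefficient
#'
#' Each particle performs independent Gaussian steps of per-axis variance
#' `2 * D_true * dt`, wrapped into the periodic box; the unwrapped tracks
#' are kept as ground truth. Particles are exposed as single-phosphorus
#' DPPC-type molecules in one leaflet so the trajectory feeds directly
#' into [lateral_displacements()].
#'
#' @param spec a [brownian_spec()].
#' @return list of class `brownian`: `topology`, `trajectory`
#'   (`md_trajectory`), `unwrapped` (frames x particles x 2 array), `spec`.
#' @export
generate_brownian <- function(spec) {
  stopifnot(inherits(spec, "brownian_spec"))
  set.seed(spec$seed)
  np <- spec$n_particles
  nf <- spec$n_steps + 1L
  sd_step <- sqrt(2 * spec$D_true * spec$dt)
  start <- matrix(stats::runif(2 * np, 0, spec$box_xy), ncol = 2)
  steps <- array(stats::rnorm(spec$n_steps * np * 2, 0, sd_step),
                 dim = c(spec$n_steps, np, 2))
  unwrapped <- array(0, dim = c(nf, np, 2))
  unwrapped[1, , ] <- start
  for (f in 2:nf) unwrapped[f, , ] <- unwrapped[f - 1, , ] + steps[f - 1, , ]
  box <- c(spec$box_xy, spec$box_xy, 10)
  frames <- lapply(seq_len(nf), function(f) {
    xy <- wrap_coords(matrix(unwrapped[f, , ], ncol = 2), box[1:2])
    structure(list(time = (f - 1) * spec$dt, box = box,
                   xyz = cbind(xy, 5)), class = "md_frame")
  })
  topo <- as_topology(data.frame(
    atom_id = seq_len(np), mol_id = seq_len(np), resid = seq_len(np),
    resname = "DPPC", atom_name = "P", stringsAsFactors = FALSE))
  topo$role_phosphorus <- TRUE
  topo$role_chain_marker <- FALSE
  topo$role_chol_marker <- FALSE
  topo$role_protein <- FALSE
  topo$lipid_type <- "DPPC"
  topo$leaflet <- "upper"
  structure(list(topology = topo,
                 trajectory = structure(list(times = (seq_len(nf) - 1) * spec$dt,
                                             frames = frames),
                                        class = "md_trajectory"),
                 unwrapped = unwrapped, spec = spec),
            class = "brownian")
}

#' Generate a pressure-tensor series with a planted surface-tension schedule
#'
#' The pressure anisotropy is set so that the two-interface tension formula
#' (see [surface_tension()]) returns the scheduled tension exactly before
#' additive Gaussian noise on each component; the APL column follows a
#' compression ramp whose box edge changes linearly in time (area, and
#' hence APL, quadratic in time).
#'
#' @param gamma_schedule function of time (ns) returning the target surface
#'   tension (mN/m), or a single constant.
#' @param gamma0 clean-interface tension (mN/m), stored for downstream
#'   surface-pressure conversion.
#' @param Lz box height (nm).
#' @param noise_sd per-component Gaussian noise (bar).
#' @param t_end,dt time span and spacing (ns).
#' @param apl_ramp APL at the start and end of the ramp (Angstrom^2).
#' @param seed RNG seed.
#' @return data.frame of class `pressure_series`: `time`, `Pxx`, `Pyy`,
#'   `Pzz`, `Lz`, `apl`; attributes `gamma_true`, `gamma0`.
#' @export
generate_pressure_series <- function(gamma_schedule, gamma0 = 69.4, Lz = 12,
                                     noise_sd = 0, t_end = 1000, dt = 1,
                                     apl_ramp = c(90, 45), seed = 1L) {
  set.seed(as.integer(seed))
  if (is.numeric(gamma_schedule)) {
    g0 <- gamma_schedule
    gamma_schedule <- function(t) rep(g0, length(t))
  }
  times <- seq(0, t_end, by = dt)
  gam <- gamma_schedule(times)
  stopifnot(length(gam) == length(times))
  aniso <- gam / (0.1 * Lz / 2)
  nt <- length(times)
  out <- data.frame(
    time = times,
    Pxx = 1 - aniso + stats::rnorm(nt, 0, noise_sd),
    Pyy = 1 - aniso + stats::rnorm(nt, 0, noise_sd),
    Pzz = 1 + stats::rnorm(nt, 0, noise_sd),
    Lz = Lz,
    apl = (sqrt(apl_ramp[1]) + (sqrt(apl_ramp[2]) - sqrt(apl_ramp[1])) *
             times / t_end)^2
  )
  attr(out, "gamma_true") <- gam
  attr(out, "gamma0") <- gamma0
  class(out) <- c("pressure_series", "data.frame")
  out
}

#' Generate a compression stack of configurations with planted truth
#'
#' One configuration per APL grid point, with the planted condensed
#' fraction given by `f_lc_of_apl` (which must be nonincreasing in APL:
#' compression orders the chains). All configurations share identical
#' molecule counts and ordering, so the stack behaves as a multi-frame
#' trajectory with a single topology.
#'
#' @param spec base [monolayer_spec()]; `apl`, `f_lc` and `seed` are
#'   overridden per grid point.
#' @param apl_grid APL values (Angstrom^2).
#' @param f_lc_of_apl function of APL or vector parallel to `apl_grid`.
#' @param times optional frame times (ns); defaults to grid index - 1.
#' @return list of class `compression_stack`: `topology`, `frames`,
#'   `truths`, `apl_grid`, `f_lc`.
#' @export
generate_compression_stack <- function(spec, apl_grid, f_lc_of_apl,
                                       times = NULL) {
  f_lc <- if (is.function(f_lc_of_apl)) f_lc_of_apl(apl_grid)
          else rep_len(f_lc_of_apl, length(apl_grid))
  o <- order(apl_grid)
  if (any(diff(f_lc[o]) > 1e-9)) {
    stop("f_lc_of_apl must be nonincreasing in APL")
  }
  if (is.null(times)) times <- seq_along(apl_grid) - 1
  frames <- vector("list", length(apl_grid))
  truths <- vector("list", length(apl_grid))
  topo <- NULL
  for (i in seq_along(apl_grid)) {
    sp <- spec
    sp$apl <- apl_grid[i]
    sp$f_lc <- f_lc[i]
    sp$seed <- spec$seed + i - 1L
    ml <- generate_monolayer(sp)
    ml$frame$time <- times[i]
    frames[[i]] <- ml$frame
    truths[[i]] <- ml$truth
    if (is.null(topo)) topo <- ml$topology
  }
  structure(list(topology = topo, frames = frames, truths = truths,
                 apl_grid = apl_grid, f_lc = f_lc,
                 trajectory = structure(list(times = times, frames = frames),
                                        class = "md_trajectory")),
            class = "compression_stack")
}
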