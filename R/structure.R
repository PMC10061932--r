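#' Liquid-condensed / liquid-expanded phase labels for one leaflet
#'
#' Projects the chain-marker atoms (10th acyl-chain carbons plus the
#' cholesterol marker) of one leaflet to the xy plane and clusters them
#' with [dbscan_pbc()]. Markers in clusters of at least `min_cluster_size`
#' points are labelled `Lc` (liquid-condensed, tightly packed); everything
#' else, including DBSCAN noise, is `Le` (liquid-expanded).
#'
#' @param frame frame providing coordinates.
#' @param topology role- and leaflet-assigned `topology`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param eps,min_pts DBSCAN parameters (nm / count), see [dbscan_pbc()].
#' @param min_cluster_size minimum cluster size called condensed.
#' @return data.frame of class `phase_labeling` with one row per marker:
#'   `mol_id`, `atom_id`, `lipid_type`, `x`, `y`, `cluster`, `phase`;
#'   attributes `params` and `box_xy`.
#' @export
phase_labels <- function(frame, topology, leaflet = "upper",
                         eps = 0.55, min_pts = 4, min_cluster_size = 10) {
  sel <- (topology$role_chain_marker | topology$role_chol_marker) &
    topology$leaflet == leaflet
  if (sum(sel) < min_pts) stop("leaflet '", leaflet, "' has fewer markers than min_pts")
  xy <- wrap_coords(frame$xyz[sel, 1:2, drop = FALSE], frame$box[1:2])
  labels <- dbscan_pbc(xy, frame$box[1:2], eps, min_pts)
  size <- table(labels[labels > 0])
  big <- as.integer(names(size)[size >= min_cluster_size])
  out <- data.frame(
    mol_id = topology$mol_id[sel],
    atom_id = topology$atom_id[sel],
    lipid_type = topology$lipid_type[sel],
    x = xy[, 1], y = xy[, 2],
    cluster = labels,
    phase = ifelse(labels %in% big, "Lc", "Le"),
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- list(eps = eps, min_pts = min_pts,
                              min_cluster_size = min_cluster_size)
  attr(out, "box_xy") <- frame$box[1:2]
  class(out) <- c("phase_labeling", "data.frame")
  out
}

#' Condensed fraction versus distance from the protein
#'
#' For each marker, the shortest 2D minimum-image distance to any protein
#' heavy atom is computed; markers are then binned by that distance and the
#' fraction labelled `Lc` is reported per bin. Distances are in-plane
#' because the phases are defined in the monolayer plane; empty bins are
#' reported as `NA`, not 0.
#'
#' @param labeling a `phase_labeling` (see [phase_labels()]).
#' @param protein_heavy_xy m x 2 matrix of protein heavy-atom xy (nm).
#' @param box_xy box edges (nm); defaults to the labeling's box.
#' @param bin_edges increasing distance bin edges (nm).
#' @return data.frame with `bin_low`, `bin_high`, `n`, `n_lc`,
#'   `lc_fraction` (NA where `n == 0`).
#' @export
lc_fraction_vs_distance <- function(labeling, protein_heavy_xy,
                                    box_xy = attr(labeling, "box_xy"),
                                    bin_edges = seq(0, 8, by = 0.5)) {
  protein_heavy_xy <- as.matrix(protein_heavy_xy)
  if (!nrow(protein_heavy_xy)) {
    stop("no protein atoms supplied; use phase_labels() alone for protein-free systems")
  }
  stopifnot(all(diff(bin_edges) > 0))
  xy <- cbind(labeling$x, labeling$y)
  d <- vapply(seq_len(nrow(xy)), function(i) {
    min(min_image_dist(xy[i, ], protein_heavy_xy, box_xy))
  }, numeric(1))
  bin <- cut(d, bin_edges, right = FALSE)
  n <- as.integer(table(bin))
  n_lc <- as.integer(table(bin[labeling$phase == "Lc"]))
  data.frame(bin_low = bin_edges[-length(bin_edges)],
             bin_high = bin_edges[-1],
             n = n, n_lc = n_lc,
             lc_fraction = ifelse(n > 0, n_lc / n, NA_real_))
}

#' Species selectors for density profiles
#'
#' Built-in selectors map a topology to logical atom masks: all
#' phospholipid atoms, cholesterol, protein, or individual lipid types.
#'
#' @param which character vector of selector names.
#' @return named list of functions `topology -> logical`.
#' @export
species_selectors <- function(which = c("phospholipid", "CHOL", "protein")) {
  all_sel <- list(
    phospholipid = function(tp) tp$lipid_type %in% c("DPPC", "POPC", "POPG") & tp$is_heavy,
    CHOL = function(tp) tp$lipid_type %in% "CHOL" & tp$is_heavy,
    protein = function(tp) tp$lipid_type %in% "PROTEIN" & tp$is_heavy,
    DPPC = function(tp) tp$lipid_type %in% "DPPC" & tp$is_heavy,
    POPC = function(tp) tp$lipid_type %in% "POPC" & tp$is_heavy,
    POPG = function(tp) tp$lipid_type %in% "POPG" & tp$is_heavy
  )
  all_sel[which]
}

#' Phosphorus-aligned transverse density map
#'
#' Per frame and per leaflet, atom z coordinates are re-expressed as
#' `z' = -s * (z - <z_P>)` where `<z_P>` is that leaflet's mean phosphorus
#' z and `s` its outward normal sign, so the phosphorus plane sits at
#' `z' = 0` for every frame and the acyl-chain (air) side is negative for
#' both leaflets. Mass-weighted histograms are accumulated per species,
#' averaged over the two leaflets and over the frames of each
#' surface-pressure regime, and the extent curve records the outermost
#' positions where each species' density crosses 5% of its maximum
#' (linearly interpolated between bin centres).
#'
#' @param frames list of frames (or a single frame).
#' @param topology role- and leaflet-assigned topology.
#' @param species named list of selector functions, see
#'   [species_selectors()].
#' @param z_bins histogram bin edges for z' (nm).
#' @param pressure_per_frame surface pressure of each frame (mN/m); NULL
#'   pools everything into one `"all"` regime.
#' @param regimes regime table, see [pressure_regimes()].
#' @param extent_level threshold as a fraction of the species maximum.
#' @return list of class `density_map`: `z_mid`, `density` (array species x
#'   z-bin x regime, kg/m^3), `extents` (data.frame `species`, `regime`,
#'   `z_low`, `z_high`), `regimes`.
#' @export
density_profile <- function(frames, topology,
                            species = species_selectors(),
                            z_bins = seq(-4, 3, by = 0.1),
                            pressure_per_frame = NULL,
                            regimes = pressure_regimes(),
                            extent_level = 0.05) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  nf <- length(frames)
  if (is.null(pressure_per_frame)) {
    regime_of <- rep("all", nf)
    regime_labels <- "all"
  } else {
    stopifnot(length(pressure_per_frame) == nf)
    regime_of <- assign_regime(pressure_per_frame, regimes)
    regime_labels <- regimes$label[regimes$label %in% regime_of]
  }
  masses <- atom_masses(topology$atom_name)
  nb <- length(z_bins) - 1L
  z_mid <- (z_bins[-1] + z_bins[-length(z_bins)]) / 2
  dz <- diff(z_bins)
  leaflets <- unique(topology$leaflet)
  dens <- array(0, dim = c(length(species), nb, length(regime_labels)),
                dimnames = list(names(species), NULL, regime_labels))
  nframes_reg <- stats::setNames(rep(0L, length(regime_labels)), regime_labels)
  present <- vapply(species, function(f) any(f(topology)), logical(1))
  if (any(!present)) {
    warning("species with no atoms skipped: ",
            paste(names(species)[!present], collapse = ", "))
    species <- species[present]
    dens <- dens[present, , , drop = FALSE]
  }
  amu_nm3_to_kg_m3 <- 1.66053907
  for (fi in seq_len(nf)) {
    reg <- regime_of[fi]
    if (is.na(reg)) next
    fr <- frames[[fi]]
    area <- fr$box[1] * fr$box[2]
    acc <- matrix(0, length(species), nb)
    for (lf in leaflets) {
      in_leaf <- topology$leaflet == lf
      pz <- mean(fr$xyz[in_leaf & topology$role_phosphorus, 3])
      zp <- -outward_sign(lf) * (fr$xyz[, 3] - pz)
      for (si in seq_along(species)) {
        sel <- species[[si]](topology) & in_leaf
        if (!any(sel)) next
        b <- findInterval(zp[sel], z_bins, rightmost.closed = TRUE)
        ok <- b >= 1L & b <= nb
        h <- vapply(seq_len(nb), function(k) sum(masses[sel][ok][b[ok] == k]),
                    numeric(1))
        acc[si, ] <- acc[si, ] + h / (area * dz) * amu_nm3_to_kg_m3
      }
    }
    dens[, , reg] <- dens[, , reg] + acc / length(leaflets)
    nframes_reg[reg] <- nframes_reg[reg] + 1L
  }
  for (r in regime_labels) {
    if (nframes_reg[r] > 0) dens[, , r] <- dens[, , r] / nframes_reg[r]
  }
  ext <- expand.grid(species = names(species), regime = regime_labels,
                     stringsAsFactors = FALSE)
  ext$z_low <- NA_real_
  ext$z_high <- NA_real_
  for (i in seq_len(nrow(ext))) {
    d <- dens[ext$species[i], , ext$regime[i]]
    if (all(d <= 0)) next
    cr <- extent_crossings(z_mid, d, extent_level * max(d))
    ext$z_low[i] <- cr[1]
    ext$z_high[i] <- cr[2]
  }
  structure(list(z_mid = z_mid, density = dens, extents = ext,
                 regimes = regime_labels, n_frames = nframes_reg),
            class = "density_map")
}

# Outermost threshold crossings of a binned profile, interpolated linearly
# between bin centres; falls back to the outermost bin centre at the edges.
extent_crossings <- function(z, d, thr) {
  above <- which(d >= thr)
  i1 <- above[1]
  i2 <- above[length(above)]
  z_low <- if (i1 > 1) {
    z[i1 - 1] + (thr - d[i1 - 1]) / (d[i1] - d[i1 - 1]) * (z[i1] - z[i1 - 1])
  } else z[i1]
  z_high <- if (i2 < length(z)) {
    z[i2] + (d[i2] - thr) / (d[i2] - d[i2 + 1]) * (z[i2 + 1] - z[i2])
  } else z[i2]
  c(z_low, z_high)
}

#' Monolayer thickness from a density map
#'
#' Thickness is the width `z_high - z_low` of the 5%-of-maximum extent of
#' the chosen species (phospholipid by default), per pressure regime.
#'
#' @param density_map a `density_map`.
#' @param species species name present in the map.
#' @return named numeric vector, one thickness (nm) per regime.
#' @export
monolayer_thickness <- function(density_map, species = "phospholipid") {
  ext <- density_map$extents
  sel <- ext$species == species
  if (!any(sel) || all(is.na(ext$z_low[sel]))) {
    stop("no density extent for species '", species, "'")
  }
  stats::setNames(ext$z_high[sel] - ext$z_low[sel], ext$regime[sel])
}

#' Acyl-chain tilt angles
#'
#' The tilt of a chain is the angle between the vector from its first
#' defined carbon to its last (by default the second carbon to the
#' 10th-carbon marker of each chain) and the outward leaflet normal
#' (+z upper leaflet, -z lower). Chains with missing end atoms are skipped
#' with a count recorded in the `n_skipped` attribute.
#'
#' @param frame frame providing coordinates.
#' @param topology role- and leaflet-assigned topology.
#' @param chain_atoms list of character pairs `c(first, last)` atom names
#'   defining each chain.
#' @return data.frame with `mol_id`, `lipid_type`, `leaflet`, `chain`,
#'   `tilt_deg` in [0, 180].
#' @export
chain_tilt <- function(frame, topology,
                       chain_atoms = list(sn1 = c("C32", "C310"),
                                          sn2 = c("C22", "C210"))) {
  out <- list()
  n_skipped <- 0L
  is_pl <- topology$lipid_type %in% c("DPPC", "POPC", "POPG")
  mols <- unique(topology$mol_id[is_pl])
  for (ch in names(chain_atoms)) {
    a1 <- chain_atoms[[ch]][1]
    a2 <- chain_atoms[[ch]][2]
    i1 <- match(paste(mols, a1), paste(topology$mol_id, topology$atom_name))
    i2 <- match(paste(mols, a2), paste(topology$mol_id, topology$atom_name))
    ok <- !is.na(i1) & !is.na(i2)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    v <- min_image(frame$xyz[i2[ok], , drop = FALSE] -
                     frame$xyz[i1[ok], , drop = FALSE], frame$box)
    lf <- topology$leaflet[i1[ok]]
    cosang <- outward_sign(lf) * v[, 3] / sqrt(rowSums(v^2))
    out[[ch]] <- data.frame(
      mol_id = topology$mol_id[i1[ok]],
      lipid_type = topology$lipid_type[i1[ok]],
      leaflet = lf, chain = ch,
      tilt_deg = acos(pmin(1, pmax(-1, cosang))) * 180 / pi,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Tilt of a protein's principal axis
#'
#' The protein axis is the largest-variance principal direction of the
#' (centred) backbone coordinates, with its sign fixed to point from the
#' first to the last residue (N to C terminus); with exactly two points the
#' direct vector is used. The returned angle is measured against the
#' outward monolayer normal and lies in [0, 180] degrees, so a value near
#' 90 means the helix lies in the monolayer plane.
#'
#' @param backbone_xyz m x 3 matrix of backbone coordinates in residue
#'   order (nm); must not straddle a periodic boundary.
#' @param outward outward normal sign of the protein's leaflet (+1 or -1).
#' @return angle in degrees.
#' @export
protein_axis_tilt <- function(backbone_xyz, outward = 1) {
  x <- as.matrix(backbone_xyz)
  if (nrow(x) < 2L) stop("need at least 2 backbone points")
  if (nrow(x) == 2L) {
    axis <- x[2, ] - x[1, ]
  } else {
    xc <- scale(x, scale = FALSE)
    axis <- svd(xc)$v[, 1]
    ends <- x[nrow(x), ] - x[1, ]
    if (sum(axis * ends) < 0) axis <- -axis
  }
  axis <- axis / sqrt(sum(axis^2))
  acos(pmin(1, pmax(-1, outward * axis[3]))) * 180 / pi
}
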