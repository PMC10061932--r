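test_that("periodic DBSCAN handles the degenerate extremes", {
  # well-separated points are all noise
  set.seed(1)
  pts <- cbind(seq(0.5, 9.5, by = 1), seq(0.5, 9.5, by = 1))
  expect_true(all(dbscan_pbc(pts, c(12, 12), eps = 0.55, min_pts = 4) == -1L))
  # a hexagonal lattice at eps = 1.2 * spacing is one cluster
  hex <- psurftools:::hex_patch_points(40, c(6, 6), a = 0.48, angle = 0)
  hex <- psurftools:::wrap_coords(hex, c(12, 12))
  lab <- dbscan_pbc(hex, c(12, 12), eps = 1.2 * 0.48, min_pts = 4)
  expect_equal(unique(lab), 1L)
  expect_error(dbscan_pbc(pts, c(1, 12), eps = 0.55, min_pts = 4),
               "ambiguous")
})

test_that("cell-list DBSCAN equals the brute-force reference on random data", {
  for (s in 1:15) {
    set.seed(s)
    n <- 200
    box <- c(8, 8)
    pts <- cbind(runif(n) * box[1], runif(n) * box[2])
    fast <- dbscan_pbc(pts, box, eps = 0.55, min_pts = 4)
    slow <- ref_dbscan(pts, box, eps = 0.55, min_pts = 4)
    expect_true(same_partition(fast, slow))
  }
  # clustering straddling the periodic boundary
  set.seed(99)
  edge <- cbind(c(7.9, 0.05, 7.8, 0.15, 7.95), c(4, 4, 4.1, 4.1, 3.9))
  lab <- dbscan_pbc(edge, c(8, 8), eps = 0.3, min_pts = 3)
  expect_equal(length(unique(lab[lab > 0])), 1L)
  expect_true(all(lab > 0))
})

test_that("phase labels recover planted condensed fractions", {
  ml <- generate_monolayer(monolayer_spec(f_lc = 0.4, seed = 7))
  for (lf in c("upper", "lower")) {
    lab <- phase_labels(ml$frame, ml$topology, lf)
    tr <- ml$truth[ml$truth$leaflet == lf, ]
    m <- merge(as.data.frame(lab)[, c("atom_id", "phase")],
               tr[, c("atom_id", "phase")], by = "atom_id")
    expect_equal(nrow(m), nrow(tr))
    expect_lt(abs(mean(m$phase.x == "Lc") - mean(m$phase.y == "Lc")), 0.03)
  }
  # no plant, no condensed phase
  ml0 <- generate_monolayer(monolayer_spec(n_lipids_per_leaflet = 100,
                                           f_lc = 0, seed = 5))
  expect_equal(mean(phase_labels(ml0$frame, ml0$topology)$phase == "Lc"), 0)
  # an unreachable cluster-size threshold suppresses everything
  lab_big <- phase_labels(ml$frame, ml$topology, "upper",
                          min_cluster_size = 10000)
  expect_equal(mean(lab_big$phase == "Lc"), 0)
})

test_that("condensed fraction responds monotonically to its two thresholds", {
  ml <- generate_monolayer(monolayer_spec(n_lipids_per_leaflet = 150,
                                          f_lc = 0.35, seed = 13))
  frac <- function(eps, mcs) {
    mean(phase_labels(ml$frame, ml$topology, "upper", eps = eps,
                      min_cluster_size = mcs)$phase == "Lc")
  }
  # nonincreasing in min_cluster_size
  f_mcs <- vapply(c(5, 10, 25, 60), function(m) frac(0.55, m), numeric(1))
  expect_true(all(diff(f_mcs) <= 1e-12))
  # nondecreasing in eps
  f_eps <- vapply(c(0.4, 0.55, 0.7), function(e) frac(e, 10), numeric(1))
  expect_true(all(diff(f_eps) >= -1e-12))
  expect_true(all(c(f_mcs, f_eps) >= 0 & c(f_mcs, f_eps) <= 1))
})

test_that("condensed fraction versus protein distance tracks the planted halo", {
  ml <- generate_monolayer(monolayer_spec(
    f_lc = 0.4, seed = 11,
    protein = list(radius = 1.5, halo_width = 1.5, halo_lc_suppression = 1)))
  lab <- phase_labels(ml$frame, ml$topology, "upper")
  psel <- ml$topology$role_protein & ml$topology$leaflet == "upper"
  pxy <- ml$frame$xyz[psel, 1:2, drop = FALSE]
  prof <- lc_fraction_vs_distance(lab, pxy, ml$frame$box[1:2],
                                  bin_edges = seq(0, 6, by = 0.5))
  near <- prof$lc_fraction[prof$bin_high <= 1.5 & !is.na(prof$lc_fraction)]
  expect_true(all(near < 0.05))
  # beyond the halo the profile matches the generator's bookkeeping
  tr <- ml$truth[ml$truth$leaflet == "upper", ]
  d_tr <- vapply(seq_len(nrow(tr)), function(i) {
    min(min_image_dist(c(tr$x[i], tr$y[i]), pxy, ml$frame$box[1:2]))
  }, numeric(1))
  tr_prof <- tapply(tr$phase == "Lc",
                    cut(d_tr, seq(0, 6, 0.5), right = FALSE), mean)
  far <- prof$bin_low >= 2.5
  expect_true(all(abs(prof$lc_fraction[far] - as.numeric(tr_prof)[far]) < 0.05,
                  na.rm = TRUE))
  # a single condensed marker lands its bin at fraction 1
  one <- data.frame(mol_id = 1, atom_id = 1, lipid_type = "DPPC",
                    x = 2.3, y = 0, cluster = 1, phase = "Lc")
  attr(one, "box_xy") <- c(10, 10)
  class(one) <- c("phase_labeling", "data.frame")
  p1 <- lc_fraction_vs_distance(one, matrix(c(0, 0), 1),
                                bin_edges = seq(0, 5, 0.5))
  expect_equal(p1$lc_fraction[p1$bin_low == 2], 1)
  expect_true(is.na(p1$lc_fraction[p1$bin_low == 4]))
  expect_error(lc_fraction_vs_distance(one, matrix(numeric(0), 0, 2)),
               "protein")
})

test_that("labels with no spatial structure yield a flat distance profile", {
  set.seed(21)
  n <- 4000
  lab <- data.frame(mol_id = seq_len(n), atom_id = seq_len(n),
                    lipid_type = "DPPC",
                    x = runif(n) * 20, y = runif(n) * 20,
                    cluster = -1L,
                    phase = sample(c("Lc", "Le"), n, TRUE, prob = c(0.3, 0.7)))
  attr(lab, "box_xy") <- c(20, 20)
  class(lab) <- c("phase_labeling", "data.frame")
  prof <- lc_fraction_vs_distance(lab, matrix(c(10, 10), 1),
                                  bin_edges = seq(0, 8, 1))
  ok <- !is.na(prof$lc_fraction) & prof$n >= 30
  ci <- 3 * sqrt(0.3 * 0.7 / prof$n[ok])
  expect_true(all(abs(prof$lc_fraction[ok] - 0.3) < pmax(ci, 0.08)))
})

test_that("density maps align on phosphorus and cross 5% where a Gaussian should", {
  set.seed(3)
  n <- 20000
  tp <- point_topology(n)
  fr <- make_frame(cbind(runif(n) * 10, runif(n) * 10, rnorm(n, 5, 0.5)),
                   c(10, 10, 10))
  dm <- density_profile(fr, tp, species = species_selectors("phospholipid"),
                        z_bins = seq(-3, 3, by = 0.1))
  ext <- dm$extents
  expected <- 0.5 * sqrt(2 * log(20))
  expect_lt(abs(ext$z_low + expected), 0.1)
  expect_lt(abs(ext$z_high - expected), 0.1)
  # histogram mass equals total species mass
  tot <- sum(dm$density) * 0.1 * 100 / 1.66053907
  expect_equal(tot, sum(psurftools:::atom_masses(tp$atom_name)),
               tolerance = 1e-6)
  # scaling masses scales density but not the extent
  tp2 <- tp
  tp2$atom_name <- "S1"  # sulfur: heavier atoms, same positions
  dm2 <- density_profile(fr, tp2, species = list(
    phospholipid = function(t) rep(TRUE, nrow(t))), z_bins = seq(-3, 3, 0.1))
  pos <- dm$density[1, , 1] > 0
  expect_equal(dm2$density[1, pos, 1] / dm$density[1, pos, 1],
               rep(32.06 / 30.974, sum(pos)), tolerance = 1e-9)
  expect_equal(dm2$extents$z_low, dm$extents$z_low, tolerance = 1e-9)
})

test_that("point masses at the phosphorus plane collapse the extent to one bin", {
  n <- 500
  tp <- point_topology(n)
  fr <- make_frame(cbind(runif(n) * 8, runif(n) * 8, rep(4, n)), c(8, 8, 10))
  dm <- density_profile(fr, tp, species = species_selectors("phospholipid"),
                        z_bins = seq(-2, 2, by = 0.1))
  # the 5% crossings interpolate into the adjacent (empty) bins, so the
  # extent stays within one bin width of the plane on either side
  expect_lt(dm$extents$z_high - dm$extents$z_low, 0.2 + 1e-9)
  expect_lt(abs(dm$extents$z_low), 0.15 + 1e-9)
  expect_lt(abs(dm$extents$z_high), 0.15 + 1e-9)
})

test_that("monolayer thickness is the extent width and narrows on expansion", {
  ml_c <- generate_monolayer(monolayer_spec(n_lipids_per_leaflet = 150,
                                            apl = 60, f_lc = 0.6, seed = 2))
  ml_e <- generate_monolayer(monolayer_spec(n_lipids_per_leaflet = 150,
                                            apl = 90, f_lc = 0, seed = 2))
  th <- function(ml) {
    dm <- density_profile(ml$frame, ml$topology,
                          species = species_selectors("phospholipid"),
                          z_bins = seq(-4, 3, 0.1))
    unname(monolayer_thickness(dm))
  }
  # same z model, so same thickness: arithmetic is extent width
  dm <- density_profile(ml_c$frame, ml_c$topology,
                        species = species_selectors("phospholipid"),
                        z_bins = seq(-4, 3, 0.1))
  expect_equal(unname(monolayer_thickness(dm)),
               dm$extents$z_high - dm$extents$z_low)
  expect_error(monolayer_thickness(dm, species = "nope"), "extent")
  expect_gt(th(ml_c), 0.5)
  expect_gt(th(ml_e), 0.5)
  # planted chain lengthening (deeper markers at lower APL) gives monotone
  # nonincreasing thickness versus APL
  offs <- c(1.5, 1.15, 0.8)   # marker depth as compression orders chains
  apls <- c(60, 75, 90)
  ths <- vapply(seq_along(apls), function(i) {
    ml <- generate_monolayer(monolayer_spec(
      n_lipids_per_leaflet = 120, apl = apls[i], f_lc = 0, seed = 3,
      z_model = list(marker_offset = offs[i])))
    th(ml)
  }, numeric(1))
  expect_true(all(diff(ths) <= 0))
})

test_that("chain tilt measures the angle to the outward leaflet normal", {
  # two hand-built lipids: one chain straight out, one lying in-plane
  tp <- as_topology(data.frame(
    atom_id = 1:16, mol_id = rep(1:2, each = 8), resid = rep(1:2, each = 8),
    resname = "DPPC",
    atom_name = rep(c("P", "C2", "C22", "C210", "C216", "C32", "C310",
                      "C316"), 2), stringsAsFactors = FALSE))
  tp <- assign_roles(tp)
  tp$leaflet <- "upper"
  xyz <- matrix(0, 16, 3)
  xyz[, 1] <- rep(c(2, 6), each = 8)
  xyz[, 3] <- 5
  xyz[4, 3] <- 6    # mol 1 sn2: C22 at z=5, C210 at z=6 -> along +z
  xyz[7, 3] <- 6    # mol 1 sn1 likewise
  xyz[12, 1] <- 7   # mol 2 sn2: C210 displaced in x -> in-plane
  xyz[15, 1] <- 7
  fr <- make_frame(xyz, c(10, 10, 10))
  ct <- chain_tilt(fr, tp)
  expect_equal(sort(unique(round(ct$tilt_deg[ct$mol_id == 1]))), 0)
  expect_equal(sort(unique(round(ct$tilt_deg[ct$mol_id == 2]))), 90)
  # a lower-leaflet chain pointing down is also 0 degrees from outward
  tp$leaflet <- "lower"
  xyz2 <- xyz
  xyz2[c(4, 7, 12, 15), ] <- xyz[c(4, 7, 12, 15), ]
  xyz2[4, 3] <- 4
  xyz2[7, 3] <- 4
  ct2 <- chain_tilt(make_frame(xyz2, c(10, 10, 10)), tp)
  expect_equal(unique(round(ct2$tilt_deg[ct2$mol_id == 1])), 0)
})

test_that("a planted 30-degree tilt cone is recovered within a degree", {
  set.seed(17)
  n <- 500
  phi <- runif(n, 0, 2 * pi)
  theta <- 30 * pi / 180
  len <- 1.2
  v <- cbind(len * sin(theta) * cos(phi), len * sin(theta) * sin(phi),
             len * cos(theta))
  base <- cbind(runif(n) * 30, runif(n) * 30, 5)
  tp <- as_topology(data.frame(
    atom_id = seq_len(2 * n), mol_id = rep(seq_len(n), each = 2),
    resid = rep(seq_len(n), each = 2), resname = "DPPC",
    atom_name = rep(c("C22", "C210"), n), stringsAsFactors = FALSE))
  tp$lipid_type <- "DPPC"
  tp$leaflet <- "upper"
  tp$role_phosphorus <- FALSE
  tp$role_chain_marker <- tp$atom_name == "C210"
  tp$role_chol_marker <- FALSE
  tp$role_protein <- FALSE
  xyz <- matrix(0, 2 * n, 3)
  xyz[seq(1, 2 * n, 2), ] <- base
  xyz[seq(2, 2 * n, 2), ] <- base + v
  ct <- chain_tilt(make_frame(xyz, c(30, 30, 12)), tp,
                   chain_atoms = list(sn2 = c("C22", "C210")))
  expect_equal(nrow(ct), n)
  expect_lt(abs(mean(ct$tilt_deg) - 30), 1)
})

test_that("protein axis tilt recovers planted rotations to half a degree", {
  # straight backbone decorated with mirrored perpendicular offsets: the
  # offsets cancel exactly in the covariance, so the principal axis is
  # the z axis by construction
  set.seed(30)
  nseg <- 25
  zline <- seq(0, 3, length.out = nseg)
  off <- cbind(rnorm(nseg, 0, 0.2), rnorm(nseg, 0, 0.2), 0)
  helix <- rbind(cbind(0, 0, zline) + off, cbind(0, 0, zline) - off)
  helix <- helix[order(rep(zline, 2)), ]
  expect_lt(abs(protein_axis_tilt(helix, outward = 1) - 0), 0.5)
  # rotate the helix axis to a planted angle of 95.3 degrees
  ang <- 95.3 * pi / 180
  R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
  expect_lt(abs(protein_axis_tilt(helix %*% t(R)) - 95.3), 0.5)
  # in-plane two-point fallback
  expect_equal(protein_axis_tilt(rbind(c(0, 0, 0), c(1, 1, 0))), 90)
  # invariance under rotation about z and translation
  th <- 0.8
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(protein_axis_tilt(helix %*% t(R) %*% t(Rz) + 5),
               protein_axis_tilt(helix %*% t(R)), tolerance = 1e-6)
  expect_error(protein_axis_tilt(matrix(1, 1, 3)), "2 backbone")
})
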