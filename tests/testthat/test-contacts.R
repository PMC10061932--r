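# Minimal protein + lipid system builder: protein CA beads plus single-atom
# lipid molecules at given positions.
contact_system <- function(bead_xyz, lipid_xyz, lipid_types, box,
                           bead_res = NULL) {
  nb <- nrow(bead_xyz)
  nl <- nrow(lipid_xyz)
  if (is.null(bead_res)) bead_res <- rep("LEU", nb)
  tp <- as_topology(data.frame(
    atom_id = seq_len(nb + nl),
    mol_id = c(rep(1L, nb), 1L + seq_len(nl)),
    resid = c(seq_len(nb), nb + seq_len(nl)),
    resname = c(bead_res, lipid_types),
    atom_name = c(rep("CA", nb), rep("C1", nl)),
    stringsAsFactors = FALSE))
  tp$role_phosphorus <- FALSE
  tp$role_chain_marker <- FALSE
  tp$role_chol_marker <- FALSE
  tp$role_protein <- c(rep(TRUE, nb), rep(FALSE, nl))
  tp$lipid_type <- c(rep("PROTEIN", nb), lipid_types)
  tp$leaflet <- "upper"
  list(topology = tp,
       frame = make_frame(rbind(bead_xyz, lipid_xyz), box))
}

test_that("contacts respect the cutoff boundary and periodic images", {
  box <- c(6, 6, 6)
  sys <- contact_system(matrix(c(0.15, 1, 1), 1),
                        rbind(c(0.44, 1, 1), c(0.46, 1, 1), c(5.90, 1, 1)),
                        c("DPPC", "DPPC", "POPG"), box)
  cc <- count_contacts(sys$frame, sys$topology, cutoff = 0.3)
  # 0.29 nm in; 0.31 nm out; 0.25 nm across the periodic image in
  expect_equal(cc$count[cc$lipid_type == "DPPC"], 1L)
  expect_equal(cc$count[cc$lipid_type == "POPG"], 1L)
  expect_error(count_contacts(sys$frame, sys$topology, cutoff = 3.1),
               "ambiguous")
})

test_that("neighbour-search contacts equal the all-pairs reference", {
  for (s in 1:5) {
    set.seed(s)
    box <- c(7, 7, 7)
    nb <- 60
    nl <- 440
    bead <- cbind(runif(nb) * 7, runif(nb) * 7, runif(nb) * 7)
    lip <- cbind(runif(nl) * 7, runif(nl) * 7, runif(nl) * 7)
    types <- sample(c("DPPC", "POPC", "POPG", "CHL1"), nl, TRUE)
    sys <- contact_system(bead, lip, types, box)
    cc <- count_contacts(sys$frame, sys$topology, cutoff = 0.5)
    # brute force over all pairs
    ref <- 0L
    per_res <- integer(nb)
    for (i in seq_len(nb)) {
      d <- min_image_dist(bead[i, ], lip, box)
      per_res[i] <- sum(d <= 0.5)
      ref <- ref + per_res[i]
    }
    expect_equal(sum(cc$count), ref)
    by_res <- tapply(cc$count, cc$residue_index, sum)
    expect_equal(unname(as.integer(by_res[order(as.integer(names(by_res)))])),
                 per_res)
  }
})

test_that("contacts are invariant under rigid translation with wrapping", {
  set.seed(8)
  box <- c(6, 6, 6)
  bead <- cbind(runif(10) * 6, runif(10) * 6, runif(10) * 6)
  lip <- cbind(runif(200) * 6, runif(200) * 6, runif(200) * 6)
  types <- sample(c("DPPC", "POPG"), 200, TRUE)
  sys <- contact_system(bead, lip, types, box)
  cc1 <- count_contacts(sys$frame, sys$topology, cutoff = 0.45)
  shift <- c(2.3, -1.1, 4.4)
  xyz2 <- sweep(sys$frame$xyz, 2, shift, "+") %% rep(box, each = nrow(sys$frame$xyz))
  cc2 <- count_contacts(make_frame(xyz2, box), sys$topology, cutoff = 0.45)
  expect_equal(cc1$count, cc2$count)
})

test_that("normalization divides by available partners and mole fraction", {
  # equal raw counts, type B twice as abundant -> normalized A = 2 x B
  box <- c(8, 8, 8)
  lipA <- cbind(runif(50) * 8, runif(50) * 8, runif(50) * 8)
  lipB <- cbind(runif(100) * 8, runif(100) * 8, runif(100) * 8)
  sys <- contact_system(matrix(c(4, 4, 4), 1), rbind(lipA, lipB),
                        c(rep("POPC", 50), rep("POPG", 100)), box)
  raw <- data.frame(residue_index = 1L, residue_name = "LEU",
                    lipid_type = c("POPC", "POPG"), count = c(12L, 12L))
  attr(raw, "cutoff") <- 0.3
  ct <- normalize_contacts(raw, sys$topology, leaflet = "upper")
  nt <- ct$by_type
  expect_equal(nt$normalized[nt$lipid_type == "POPC"],
               2 * nt$normalized[nt$lipid_type == "POPG"])
  # single lipid, single contact
  sys1 <- contact_system(matrix(c(4, 4, 4), 1), matrix(c(4.2, 4, 4), 1),
                         "DPPC", box)
  raw1 <- count_contacts(sys1$frame, sys1$topology, cutoff = 0.3)
  ct1 <- normalize_contacts(raw1, sys1$topology)
  expect_equal(ct1$by_type$normalized, 1 / 1)
  # duplicating every lipid of a type and its contacts leaves the
  # normalized value unchanged (scale equivariance)
  raw2 <- raw
  raw2$count <- c(12L, 24L)
  sysD <- contact_system(matrix(c(4, 4, 4), 1),
                         rbind(lipA, lipB, lipB),
                         c(rep("POPC", 50), rep("POPG", 200)), box)
  ctD <- normalize_contacts(raw2, sysD$topology)
  expect_equal(ctD$by_type$normalized[ctD$by_type$lipid_type == "POPG"],
               nt$normalized[nt$lipid_type == "POPG"])
})

test_that("a planted 4:1 POPG:POPC contact preference is recovered", {
  # equal abundance of POPC and POPG; lipids placed in the contact shell
  # with 4:1 odds for POPG over POPC, mirroring a strong PG preference
  set.seed(12)
  box <- c(10, 10, 10)
  nb <- 20
  th <- seq(0, 2 * pi, length.out = nb + 1)[-1]
  bead <- cbind(5 + 0.8 * cos(th), 5 + 0.8 * sin(th), 5)
  n_each <- 150
  far <- function(n) cbind(runif(n) * 10, runif(n) * 10,
                           sample(c(1.5, 8.5), n, TRUE))
  lip <- rbind(far(n_each), far(n_each))
  types <- c(rep("POPC", n_each), rep("POPG", n_each))
  n_contact <- 100
  pick_pg <- runif(n_contact) < 0.8          # 4:1 odds
  slots <- integer(n_contact)
  slots[pick_pg] <- n_each + sample(n_each, sum(pick_pg))
  slots[!pick_pg] <- sample(n_each, sum(!pick_pg))
  for (k in seq_len(n_contact)) {
    b <- sample(nb, 1)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    lip[slots[k], ] <- bead[b, ] + dir * runif(1, 0.1, 0.28)
  }
  sys <- contact_system(bead, lip, types, box)
  cc <- count_contacts(sys$frame, sys$topology, cutoff = 0.3)
  ct <- normalize_contacts(cc, sys$topology)
  nt <- ct$by_type
  ratio <- nt$normalized[nt$lipid_type == "POPG"] /
    nt$normalized[nt$lipid_type == "POPC"]
  p_hat <- mean(pick_pg)
  expect_gt(ratio, 2.3)
  expect_lt(abs(ratio - p_hat / (1 - p_hat)), 1.6)
})

test_that("regime stratification averages frames and reports replica spread", {
  tabs <- list(
    data.frame(lipid_type = c("POPC", "POPG"), count = c(2, 8)),
    data.frame(lipid_type = c("POPC", "POPG"), count = c(4, 10)),
    data.frame(lipid_type = c("POPC", "POPG"), count = c(6, 2)),
    data.frame(lipid_type = c("POPC", "POPG"), count = c(8, 4)))
  # one regime covering everything equals the plain mean
  one <- data.frame(label = "all", lower = -Inf, upper = Inf)
  st <- stratify_by_regime(tabs, c(5, 10, 35, 40), regimes = one)
  expect_equal(st$mean[st$lipid_type == "POPC"], mean(c(2, 4, 6, 8)))
  # distinct planted preferences per regime are recovered per regime
  expect_warning(st2 <- stratify_by_regime(tabs, c(5, 10, 35, 40)),
                 "omitted")
  expect_equal(st2$mean[st2$regime == "0-15" & st2$lipid_type == "POPG"], 9)
  expect_equal(st2$mean[st2$regime == "30-45" & st2$lipid_type == "POPG"], 3)
  # identical replicas have zero standard error
  st3 <- suppressWarnings(
    stratify_by_regime(tabs[c(1, 1, 1, 1)], rep(5, 4),
                       replica = c("a", "b", "c", "d")))
  expect_equal(st3$se, rep(0, nrow(st3)))
  # frames outside all regimes are dropped with a message
  expect_message(suppressWarnings(stratify_by_regime(tabs, c(5, 10, 35, -2))),
                 "dropped")
})
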