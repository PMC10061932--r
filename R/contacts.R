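#' Count heavy-atom lipid-protein contacts in one frame
#'
#' A contact is a (protein heavy atom, lipid heavy atom) pair whose 3D
#' minimum-image distance is at most `cutoff`. Counts are accumulated per
#' protein residue and lipid type. Neighbour candidates come from a cell
#' list, which is exactly equivalent to the all-pairs search.
#'
#' @param frame frame providing coordinates.
#' @param topology role-assigned topology (leaflets optional).
#' @param cutoff contact distance (nm); 0.3 nm is the heavy-atom
#'   convention.
#' @param include_atoms optional logical mask further restricting the
#'   protein atoms considered (e.g. to exclude covalently attached
#'   palmitoyl chains); default uses all protein heavy atoms.
#' @return data.frame with `residue_index`, `residue_name`, `lipid_type`,
#'   `count`; attribute `cutoff`.
#' @export
count_contacts <- function(frame, topology, cutoff = 0.3,
                           include_atoms = NULL) {
  if (cutoff >= min(frame$box) / 2) {
    stop("cutoff >= half the smallest box edge: periodic images ambiguous")
  }
  stopifnot(cutoff > 0)
  prot <- topology$role_protein
  if (!is.null(include_atoms)) prot <- prot & include_atoms
  lip <- !topology$lipid_type %in% "PROTEIN" & topology$is_heavy &
    !is.na(topology$lipid_type)
  if (!any(prot)) stop("no protein heavy atoms in topology")
  lip_idx <- which(lip)
  cl <- make_cell_list(frame$xyz[lip_idx, , drop = FALSE], frame$box,
                       max(cutoff, 0.8))
  p_idx <- which(prot)
  rows <- vector("list", length(p_idx))
  for (k in seq_along(p_idx)) {
    i <- p_idx[k]
    hits <- cell_query(cl, frame$xyz[i, ], cutoff)
    if (!length(hits)) next
    rows[[k]] <- data.frame(residue_index = topology$resid[i],
                            residue_name = topology$resname[i],
                            lipid_type = topology$lipid_type[lip_idx][hits],
                            stringsAsFactors = FALSE)
  }
  hits_df <- do.call(rbind, rows)
  prot_res <- unique(data.frame(residue_index = topology$resid[p_idx],
                                residue_name = topology$resname[p_idx],
                                stringsAsFactors = FALSE))
  types <- sort(unique(topology$lipid_type[lip_idx]))
  out <- merge(prot_res, data.frame(lipid_type = types), by = NULL)
  key <- paste(out$residue_index, out$lipid_type)
  cnt <- if (is.null(hits_df)) integer(0) else
    table(paste(hits_df$residue_index, hits_df$lipid_type))
  out$count <- as.integer(cnt[key])
  out$count[is.na(out$count)] <- 0L
  out <- out[order(out$residue_index, out$lipid_type), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Normalize contact counts by available contact partners
#'
#' Per lipid type, the aggregate preference is the raw contact count
#' divided by the number of heavy atoms of that type in the protein's
#' leaflet (correcting for both copy number and molecular size); with
#' `per = "molecule"` the divisor is the molecule count instead.
#' Per-residue values are additionally divided by the lipid-type mole
#' fraction so residue maps are comparable across compositions. Types with
#' zero abundance are reported as `NA`.
#'
#' @param raw contact table from [count_contacts()] (or a frame-averaged
#'   table with the same columns).
#' @param topology role- and leaflet-assigned topology.
#' @param leaflet leaflet whose lipid abundances to use.
#' @param per `"heavy_atom"` (default) or `"molecule"`.
#' @return list of class `contact_table` with `by_type` (lipid_type, raw,
#'   normalized), `by_residue` (residue-resolved, mole-fraction scaled)
#'   and the normalization metadata.
#' @export
normalize_contacts <- function(raw, topology, leaflet = "upper",
                               per = c("heavy_atom", "molecule")) {
  per <- match.arg(per)
  in_leaf <- topology$leaflet == leaflet & !topology$lipid_type %in% "PROTEIN" &
    !is.na(topology$lipid_type)
  types <- sort(unique(raw$lipid_type))
  abund <- vapply(types, function(ty) {
    sel <- in_leaf & topology$lipid_type == ty
    if (per == "heavy_atom") sum(sel & topology$is_heavy)
    else length(unique(topology$mol_id[sel]))
  }, numeric(1))
  n_mol <- vapply(types, function(ty) {
    length(unique(topology$mol_id[in_leaf & topology$lipid_type == ty]))
  }, numeric(1))
  mole_frac <- n_mol / sum(n_mol)
  by_type <- stats::aggregate(count ~ lipid_type, data = raw, FUN = sum)
  by_type$normalized <- ifelse(abund[by_type$lipid_type] > 0,
                               by_type$count / abund[by_type$lipid_type],
                               NA_real_)
  by_res <- raw
  by_res$normalized <- ifelse(
    abund[by_res$lipid_type] > 0 & mole_frac[by_res$lipid_type] > 0,
    by_res$count / abund[by_res$lipid_type] / mole_frac[by_res$lipid_type],
    NA_real_)
  structure(list(by_type = by_type, by_residue = by_res,
                 per = per, leaflet = leaflet,
                 abundance = abund, mole_fraction = mole_frac,
                 cutoff = attr(raw, "cutoff")),
            class = "contact_table")
}

#' Stratify per-frame tables by surface-pressure regime
#'
#' Assigns each frame to the regime containing its surface pressure
#' (frames outside every regime are dropped with a message), then averages
#' the value column over the frames of each regime for every key
#' combination. When replica labels are given, the regime mean is the mean
#' of per-replica means and a standard error across replicas is attached
#' (the monolayers of independent simulations are the independent samples).
#'
#' @param per_frame list of per-frame data.frames sharing key columns and
#'   one value column.
#' @param pressure_per_frame surface pressure of each frame (mN/m).
#' @param regimes regime table, see [pressure_regimes()].
#' @param value name of the value column.
#' @param replica optional replica label per frame.
#' @return data.frame: key columns, `regime`, `mean`, `se` (NA without
#'   replicas), `n_frames`.
#' @export
stratify_by_regime <- function(per_frame, pressure_per_frame,
                               regimes = pressure_regimes(),
                               value = "count", replica = NULL) {
  stopifnot(length(per_frame) == length(pressure_per_frame))
  reg <- assign_regime(pressure_per_frame, regimes)
  if (anyNA(reg)) {
    message(sum(is.na(reg)), " frame(s) outside all pressure regimes dropped")
  }
  if (is.null(replica)) replica <- rep("r1", length(per_frame))
  keep <- which(!is.na(reg))
  if (!length(keep)) stop("no frames fall inside any regime")
  keys <- setdiff(names(per_frame[[1]]), value)
  big <- do.call(rbind, lapply(keep, function(i) {
    df <- per_frame[[i]]
    df$.regime <- reg[i]
    df$.replica <- replica[i]
    df$.frame <- i
    df
  }))
  fml <- stats::as.formula(paste(value, "~", paste(c(keys, ".regime", ".replica"), collapse = "+")))
  per_rep <- stats::aggregate(fml, data = big, FUN = mean)
  fml2 <- stats::as.formula(paste(value, "~", paste(c(keys, ".regime"), collapse = "+")))
  out <- stats::aggregate(fml2, data = per_rep, FUN = mean)
  names(out)[names(out) == value] <- "mean"
  se <- stats::aggregate(fml2, data = per_rep,
                         FUN = function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
  out$se <- se[[value]]
  nfr <- stats::aggregate(stats::as.formula(paste(".frame ~", paste(c(keys, ".regime"), collapse = "+"))),
                          data = big, FUN = function(x) length(unique(x)))
  out$n_frames <- nfr$.frame
  names(out)[names(out) == ".regime"] <- "regime"
  empty <- setdiff(regimes$label, out$regime)
  if (length(empty)) {
    warning("empty pressure regime(s) omitted: ", paste(empty, collapse = ", "))
  }
  out
}
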