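#' Construct a topology table
#'
#' A topology is a data.frame with one row per atom and columns `atom_id`,
#' `mol_id`, `resid`, `resname`, `atom_name`, plus `is_heavy` (derived from
#' the atom name unless supplied). Role columns (`role_phosphorus`,
#' `role_chain_marker`, `role_chol_marker`, `role_protein`), `lipid_type`
#' and `leaflet` are added by [assign_roles()] and [assign_leaflets()].
#'
#' @param df data.frame with at least the five core columns.
#' @param heavy_rule function mapping atom names to a logical heavy-atom
#'   flag; the default treats every atom whose name does not start with `H`
#'   (after stripping leading digits) as heavy.
#' @return the data.frame with class `topology` prepended.
#' @export
as_topology <- function(df, heavy_rule = default_heavy_rule) {
  need <- c("atom_id", "mol_id", "resid", "resname", "atom_name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("topology lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$is_heavy)) df$is_heavy <- heavy_rule(df$atom_name)
  class(df) <- c("topology", "data.frame")
  df
}

#' @rdname as_topology
#' @param atom_name character vector of atom names.
#' @export
default_heavy_rule <- function(atom_name) {
  !grepl("^[0-9]*H", atom_name)
}

#' Default residue-to-role map (CHARMM36 atom names)
#'
#' Maps residue names to the analysis roles: the head-group phosphorus, the
#' two 10th acyl-chain carbons used as chain markers (`C210` sn-2, `C310`
#' sn-1), the cholesterol `C14` marker on `CHL1`, and the set of amino-acid
#' residue names treated as protein. The chemistry (10th chain carbons,
#' cholesterol C14) is fixed by the analysis; the atom labels are
#' force-field conventions and fully overridable, e.g. via
#' [read_role_map()].
#'
#' @return nested list keyed by residue name; entry `PROTEIN` holds the
#'   amino-acid residue names.
#' @export
default_role_map <- function() {
  pl <- function(type) list(type = type, phosphorus = "P",
                            chain_markers = c("C210", "C310"))
  list(
    DPPC = pl("DPPC"),
    POPC = pl("POPC"),
    POPG = pl("POPG"),
    CHL1 = list(type = "CHOL", chol_marker = "C14"),
    PROTEIN = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE",
                "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  )
}

#' Read a role map from a YAML config file
#'
#' The file mirrors the structure of [default_role_map()]: one entry per
#' residue name with `type`, `phosphorus`, `chain_markers` / `chol_marker`
#' fields, plus an optional `PROTEIN` list of residue names. Entries merge
#' over (and override) the defaults.
#'
#' @param path YAML file path.
#' @param base role map to merge into.
#' @return role map list.
#' @export
read_role_map <- function(path, base = default_role_map()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' Assign analysis roles to topology atoms
#'
#' Tags each heavy atom with its analysis roles and each molecule with its
#' lipid type. Every phospholipid must end up with exactly one phosphorus
#' and exactly two chain markers, and every cholesterol with exactly one
#' marker; violations and unknown residue names are errors.
#'
#' @param topology a `topology`.
#' @param role_map see [default_role_map()].
#' @return the topology with role columns and `lipid_type` filled in.
#' @export
assign_roles <- function(topology, role_map = default_role_map()) {
  tp <- topology
  protein_res <- role_map$PROTEIN
  known <- setdiff(names(role_map), "PROTEIN")
  unknown <- setdiff(unique(tp$resname), c(known, protein_res))
  if (length(unknown)) {
    stop("residue name(s) not in role map and not protein: ",
         paste(unknown, collapse = ", "))
  }
  tp$role_phosphorus <- FALSE
  tp$role_chain_marker <- FALSE
  tp$role_chol_marker <- FALSE
  tp$role_protein <- tp$resname %in% protein_res & tp$is_heavy
  tp$lipid_type <- ifelse(tp$resname %in% protein_res, "PROTEIN", NA_character_)
  for (nm in known) {
    ent <- role_map[[nm]]
    sel <- tp$resname == nm
    if (!any(sel)) next
    tp$lipid_type[sel] <- ent$type
    if (!is.null(ent$phosphorus)) {
      tp$role_phosphorus[sel & tp$atom_name %in% ent$phosphorus & tp$is_heavy] <- TRUE
    }
    if (!is.null(ent$chain_markers)) {
      tp$role_chain_marker[sel & tp$atom_name %in% ent$chain_markers & tp$is_heavy] <- TRUE
    }
    if (!is.null(ent$chol_marker)) {
      tp$role_chol_marker[sel & tp$atom_name %in% ent$chol_marker & tp$is_heavy] <- TRUE
    }
  }
  check_role_counts(tp)
  tp
}

check_role_counts <- function(tp) {
  is_pl <- tp$lipid_type %in% c("DPPC", "POPC", "POPG")
  if (any(is_pl)) {
    np <- tapply(tp$role_phosphorus[is_pl], tp$mol_id[is_pl], sum)
    if (any(np != 1L)) {
      stop("phospholipid molecule(s) with ", paste(unique(np[np != 1L]), collapse = "/"),
           " phosphorus atoms (expected exactly 1): mol_id ",
           paste(utils::head(names(np)[np != 1L], 5), collapse = ", "))
    }
    nc <- tapply(tp$role_chain_marker[is_pl], tp$mol_id[is_pl], sum)
    if (any(nc != 2L)) {
      stop("phospholipid molecule(s) without exactly 2 chain markers: mol_id ",
           paste(utils::head(names(nc)[nc != 2L], 5), collapse = ", "))
    }
  }
  is_chol <- tp$lipid_type %in% "CHOL"
  if (any(is_chol)) {
    nk <- tapply(tp$role_chol_marker[is_chol], tp$mol_id[is_chol], sum)
    if (any(nk != 1L)) {
      stop("CHOL molecule(s) without exactly 1 marker atom: mol_id ",
           paste(utils::head(names(nk)[nk != 1L], 5), collapse = ", "))
    }
  }
  invisible(tp)
}

#' Partition molecules into upper and lower leaflets
#'
#' Phosphorus z coordinates are split into two populations (1D two-means);
#' each phospholipid goes to the leaflet on its phosphorus' side of the
#' midpoint between the two population means. Molecules without phosphorus
#' (cholesterol, proteins) are assigned to the population whose mean is
#' nearest their heavy-atom mean z. A unimodal phosphorus distribution is a
#' configuration error unless `single_leaflet = TRUE`.
#'
#' @param frame frame whose z coordinates are used.
#' @param topology role-assigned `topology`.
#' @param single_leaflet treat the whole system as one (upper) leaflet.
#' @return topology with a `leaflet` column (`"upper"`/`"lower"`).
#' @export
assign_leaflets <- function(frame, topology, single_leaflet = FALSE) {
  tp <- topology
  if (single_leaflet) {
    tp$leaflet <- "upper"
    return(tp)
  }
  pz <- frame$xyz[tp$role_phosphorus, 3]
  if (length(pz) < 2L) stop("need at least one phosphorus per leaflet")
  thr <- mean(range(pz))
  for (i in 1:50) {
    up <- pz > thr
    if (!any(up) || all(up)) break
    new_thr <- (mean(pz[up]) + mean(pz[!up])) / 2
    if (abs(new_thr - thr) < 1e-12) { thr <- new_thr; break }
    thr <- new_thr
  }
  up <- pz > thr
  if (!any(up) || all(up)) {
    stop("unimodal phosphorus z distribution: single leaflet? ",
         "(use single_leaflet = TRUE)")
  }
  m_up <- mean(pz[up]); m_lo <- mean(pz[!up])
  s_up <- stats::sd(pz[up]); s_lo <- stats::sd(pz[!up])
  spread <- sum(c(s_up, s_lo), na.rm = TRUE)
  if ((m_up - m_lo) <= 2 * spread) {
    stop("phosphorus z populations not separable into two leaflets ",
         "(use single_leaflet = TRUE for one monolayer)")
  }
  mol_p <- tp$mol_id[tp$role_phosphorus]
  leaf_by_mol <- stats::setNames(ifelse(up, "upper", "lower"), mol_p)
  tp$leaflet <- leaf_by_mol[as.character(tp$mol_id)]
  # phosphorus-free molecules: nearest population by mean heavy-atom z
  no_p <- is.na(tp$leaflet)
  if (any(no_p)) {
    mz <- tapply(frame$xyz[no_p & tp$is_heavy, 3],
                 tp$mol_id[no_p & tp$is_heavy], mean)
    leaf2 <- ifelse(abs(mz - m_up) <= abs(mz - m_lo), "upper", "lower")
    names(leaf2) <- names(mz)
    tp$leaflet[no_p] <- leaf2[as.character(tp$mol_id[no_p])]
  }
  tp
}

# Atomic mass (u) guessed from the element implied by an atom name.
atom_masses <- function(atom_name) {
  el <- sub("^[0-9]+", "", atom_name)
  el <- substr(el, 1L, 1L)
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
  out <- m[el]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Outward monolayer normal sign per leaflet
#'
#' In a two-monolayer slab with water in the middle, the outward (air-side)
#' normal is +z for the upper leaflet and -z for the lower one.
#'
#' @param leaflet character vector of `"upper"`/`"lower"`.
#' @return numeric +1/-1.
#' @export
outward_sign <- function(leaflet) ifelse(leaflet == "upper", 1, -1)
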