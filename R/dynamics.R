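#' Default reference-atom rule for tracking molecular motion
#'
#' Phospholipids are tracked by their phosphorus, cholesterol by its
#' hydroxyl oxygen and proteins by their heavy-atom center of mass.
#'
#' @return named list: per lipid type either an atom name or `"COM"`.
#' @export
default_reference_rule <- function() {
  list(DPPC = "P", POPC = "P", POPG = "P", CHOL = "O3", PROTEIN = "COM")
}

#' Lateral displacements over a lag time
#'
#' Builds per-molecule reference-atom tracks, unwraps them through the
#' periodic boundaries (consecutive-frame jumps must be below half a box
#' edge), optionally subtracts each leaflet's center-of-mass drift, and
#' returns the 2D displacement magnitude of every molecule over every
#' non-overlapping lag window. Non-overlapping windows keep the
#' displacements approximately independent so the standard errors of the
#' subsequent fit are valid without autocorrelation corrections.
#'
#' @param trajectory `md_trajectory` (see [read_gro_frames()]).
#' @param topology role- and leaflet-assigned topology.
#' @param lag lag time (ns); if not a multiple of the frame spacing the
#'   nearest frame multiple is used and recorded.
#' @param drift_correction subtract per-leaflet mean displacement.
#' @param reference_rule see [default_reference_rule()].
#' @param types lipid types to include.
#' @return numeric vector of displacement magnitudes (nm) with attributes
#'   `lag` (actual lag used, ns) and `n_molecules`.
#' @export
lateral_displacements <- function(trajectory, topology, lag = 10,
                                  drift_correction = TRUE,
                                  reference_rule = default_reference_rule(),
                                  types = c("DPPC", "POPC", "POPG", "CHOL")) {
  times <- trajectory$times
  nf <- length(trajectory$frames)
  if (nf < 2L) stop("trajectory too short")
  dt <- stats::median(diff(times))
  k <- max(1L, as.integer(round(lag / dt)))
  if (k + 1L > nf) stop("trajectory span shorter than the lag time")
  lag_actual <- k * dt
  if (abs(lag_actual - lag) > 1e-9) {
    message("frame spacing does not divide the lag; using ", lag_actual, " ns")
  }
  box <- trajectory$frames[[1]]$box[1:2]
  # reference-atom row per molecule
  mol_rows <- list()
  leaf <- character(0)
  for (ty in types) {
    rule <- reference_rule[[ty]]
    sel <- which(topology$lipid_type %in% ty & topology$atom_name == rule)
    if (!length(sel)) next
    mol_rows <- c(mol_rows, as.list(sel))
    leaf <- c(leaf, topology$leaflet[sel])
  }
  if (!length(mol_rows)) stop("no reference atoms matched")
  rows <- unlist(mol_rows)
  nm <- length(rows)
  # unwrap xy tracks
  tracks <- array(0, dim = c(nf, nm, 2))
  tracks[1, , ] <- trajectory$frames[[1]]$xyz[rows, 1:2]
  for (fi in 2:nf) {
    step <- min_image(trajectory$frames[[fi]]$xyz[rows, 1:2, drop = FALSE] -
                        trajectory$frames[[fi - 1]]$xyz[rows, 1:2, drop = FALSE],
                      box)
    tracks[fi, , ] <- tracks[fi - 1, , ] + step
  }
  if (drift_correction) {
    for (lf in unique(leaf)) {
      m <- leaf == lf
      for (ax in 1:2) {
        drift <- rowMeans(tracks[, m, ax, drop = FALSE][, , 1])
        tracks[, m, ax] <- tracks[, m, ax] - (drift - drift[1])
      }
    }
  }
  starts <- seq(1L, nf - k, by = k)
  disp <- c(vapply(starts, function(s) {
    d <- tracks[s + k, , ] - tracks[s, , ]
    sqrt(d[, 1]^2 + d[, 2]^2)
  }, numeric(nm)))
  structure(disp, lag = lag_actual, n_molecules = nm)
}

#' Fit a diffusion coefficient to a displacement distribution
#'
#' For free 2D diffusion the displacement magnitude over lag `t` follows
#' `p(r) = (r / (2 D t)) exp(-r^2 / (4 D t))`; the maximum-likelihood
#' estimate is `D = sum(r^2) / (4 t n)` with standard error `D / sqrt(n)`.
#' A Kolmogorov-Smirnov distance between the empirical displacement CDF
#' and the fitted model is attached as a goodness-of-fit diagnostic.
#'
#' @param r displacement magnitudes (nm), nonnegative.
#' @param lag lag time (ns).
#' @return data.frame of class `diffusion_estimate`: `lag`, `D` (nm^2/ns),
#'   `se_D`, `n`, `ks_distance`.
#' @export
fit_diffusion <- function(r, lag = attr(r, "lag")) {
  if (any(r < 0)) stop("negative displacement magnitude")
  n <- length(r)
  stopifnot(n >= 2, lag > 0)
  D <- sum(r^2) / (4 * lag * n)
  ks <- if (D > 0) {
    Fhat <- stats::ecdf(r)
    rg <- sort(unique(r))
    Fmod <- 1 - exp(-rg^2 / (4 * D * lag))
    max(abs(Fhat(rg) - Fmod), abs(c(0, Fhat(rg)[-length(rg)]) - Fmod))
  } else NA_real_
  structure(data.frame(lag = lag, D = D, se_D = D / sqrt(n), n = n,
                       ks_distance = ks),
            class = c("diffusion_estimate", "data.frame"))
}

#' Diffusion coefficients relative to a reference pressure regime
#'
#' Divides every estimate by the reference-regime estimate of its system,
#' e.g. to display trends normalized to unity at 0-15 mN/m.
#'
#' @param estimates data.frame with columns `regime`, `D` and optionally
#'   `system`.
#' @param reference_regime regime label used as the unit.
#' @return the input with a `D_rel` column added.
#' @export
relative_diffusion <- function(estimates, reference_regime = "0-15") {
  if (is.null(estimates$system)) estimates$system <- "system"
  out <- estimates
  out$D_rel <- NA_real_
  for (sys in unique(out$system)) {
    sel <- out$system == sys
    ref <- out$D[sel & out$regime == reference_regime]
    if (length(ref) != 1L || is.na(ref)) {
      stop("reference regime '", reference_regime, "' missing for system ", sys)
    }
    if (ref == 0) stop("reference diffusion coefficient is zero for system ", sys)
    out$D_rel[sel] <- out$D[sel] / ref
  }
  out
}

#' Percent slowdown of diffusion caused by a protein
#'
#' `100 * (1 - D_protein / D_reference)`: positive values are slowdown,
#' negative values speedup.
#'
#' @param D_protein,D_reference diffusion coefficients (same units).
#' @return percent.
#' @export
slowdown_percent <- function(D_protein, D_reference) {
  stopifnot(D_reference > 0)
  100 * (1 - D_protein / D_reference)
}

#' Root-mean-square deviation, optionally after superposition
#'
#' With `superpose = TRUE` the coordinates are first fitted onto the
#' reference by the optimal least-squares rigid transformation
#' (rotation + translation); without it the raw deviation is reported.
#'
#' @param coords,reference n x 3 coordinate matrices, rows matched.
#' @param superpose least-squares fit before measuring.
#' @return RMSD in the coordinate units.
#' @export
rmsd <- function(coords, reference, superpose = TRUE) {
  x <- as.matrix(coords)
  y <- as.matrix(reference)
  stopifnot(all(dim(x) == dim(y)), ncol(x) == 3L)
  if (!superpose) {
    return(sqrt(mean(rowSums((x - y)^2))))
  }
  if (nrow(x) < 3L) stop("superposition needs at least 3 points")
  # Kabsch: optimal rotation from the SVD of the covariance of the
  # centred coordinate sets, with the reflection branch removed
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(t(yc) %*% xc)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((xc %*% rot - yc)^2)))
}
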