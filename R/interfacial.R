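#' Surface tension from pressure-tensor components
#'
#' For a slab with `n_interfaces` interfaces normal to z,
#' `gamma = 0.1 * (Lz / n_interfaces) * (Pzz - (Pxx + Pyy)/2)`,
#' with pressures in bar, `Lz` in nm and the factor 0.1 converting
#' bar nm to mN/m.
#'
#' @param Pxx,Pyy,Pzz pressure components (bar); vectorized.
#' @param Lz box height (nm).
#' @param n_interfaces 1 or 2 (two for the usual double-monolayer slab).
#' @return surface tension (mN/m).
#' @export
surface_tension <- function(Pxx, Pyy, Pzz, Lz, n_interfaces = 2) {
  stopifnot(n_interfaces %in% c(1, 2))
  0.1 * (Lz / n_interfaces) * (Pzz - (Pxx + Pyy) / 2)
}

#' Surface pressure of a film
#'
#' `Pi = gamma0 - gamma`, the reduction of the clean-interface tension by
#' the monolayer. Negative values (film tension above the clean interface)
#' are passed through with a message, not clipped.
#'
#' @param gamma film surface tension (mN/m); vectorized.
#' @param gamma0 clean-interface (water-air) tension (mN/m); e.g. 71.7 at
#'   298 K, 69.4 at 310 K.
#' @return surface pressure (mN/m).
#' @export
surface_pressure <- function(gamma, gamma0) {
  stopifnot(gamma0 > 0)
  pi_v <- gamma0 - gamma
  if (any(pi_v < 0)) {
    message(sum(pi_v < 0), " negative surface-pressure value(s) passed through")
  }
  pi_v
}

#' Area per lipid
#'
#' `APL = 100 * Lx * Ly / n_lipids_per_leaflet` in Angstrom^2 (box edges in
#' nm). Protein area is never subtracted.
#'
#' @param Lx,Ly lateral box edges (nm); vectorized.
#' @param n_lipids_per_leaflet lipid count of one leaflet.
#' @return area per lipid (Angstrom^2).
#' @export
area_per_lipid <- function(Lx, Ly, n_lipids_per_leaflet) {
  stopifnot(n_lipids_per_leaflet >= 1)
  100 * Lx * Ly / n_lipids_per_leaflet
}

#' Windowed surface pressure-area isotherm
#'
#' Bins aligned APL and surface-pressure series into consecutive
#' non-overlapping time windows and reports per-window means, spreads and
#' standard errors. Compression runs are out of equilibrium, so windowing
#' in time (not by frame count) is what makes the isotherm well defined.
#' A trailing partial window is kept and flagged.
#'
#' @param times time stamps (ns), increasing.
#' @param apl area per lipid series (Angstrom^2).
#' @param pi_series surface pressure series (mN/m).
#' @param window window length (ns).
#' @return data.frame of class `isotherm` with columns
#'   `window_center_time`, `apl_mean`, `apl_sd`, `pi_mean`, `pi_se`,
#'   `n_samples`, `partial`.
#' @export
windowed_isotherm <- function(times, apl, pi_series, window = 100) {
  if (!length(times)) stop("empty series")
  stopifnot(window > 0, length(apl) == length(times),
            length(pi_series) == length(times))
  ids <- sort(unique(floor((times - times[1]) / window)))
  idx <- factor(floor((times - times[1]) / window), levels = ids)
  t0 <- times[1]
  agg <- function(x, f) as.numeric(tapply(x, idx, f))
  n <- as.integer(tapply(times, idx, length))
  span <- max(times) - t0
  rec <- data.frame(
    window_center_time = t0 + (ids + 0.5) * window,
    apl_mean = agg(apl, mean),
    apl_sd = agg(apl, function(x) if (length(x) > 1) stats::sd(x) else 0),
    pi_mean = agg(pi_series, mean),
    pi_se = agg(pi_series, function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0),
    n_samples = n
  )
  rec$partial <- ids == max(ids) & (span %% window) > 1e-9 * window
  class(rec) <- c("isotherm", "data.frame")
  rec
}

#' Vertical shift between two isotherms
#'
#' Interpolates both isotherms linearly in APL onto the overlapping part of
#' `apl_range` and averages the pointwise surface-pressure difference
#' (test minus reference). Grid points are the test-isotherm window APL
#' values falling in the overlap, so each contributes one (nearly)
#' independent window.
#'
#' @param iso_ref,iso_test `isotherm` tables (see [windowed_isotherm()]).
#' @param apl_range APL interval (Angstrom^2) over which to average; the
#'   default avoids the collapse and over-expanded extremes.
#' @return list with `delta_mean` and `delta_se` (mN/m) and `n_points`.
#' @export
isotherm_shift <- function(iso_ref, iso_test, apl_range = c(50, 85)) {
  lo <- max(min(iso_ref$apl_mean), min(iso_test$apl_mean), apl_range[1])
  hi <- min(max(iso_ref$apl_mean), max(iso_test$apl_mean), apl_range[2])
  grid <- iso_test$apl_mean[iso_test$apl_mean >= lo & iso_test$apl_mean <= hi]
  if (length(grid) < 3L) {
    stop("insufficient overlap between isotherms over APL range [",
         apl_range[1], ", ", apl_range[2], "]")
  }
  f_ref <- stats::approx(iso_ref$apl_mean, iso_ref$pi_mean, xout = grid, ties = mean)$y
  f_test <- stats::approx(iso_test$apl_mean, iso_test$pi_mean, xout = grid, ties = mean)$y
  d <- f_test - f_ref
  list(delta_mean = mean(d),
       delta_se = stats::sd(d) / sqrt(length(d)),
       n_points = length(d))
}

#' Default surface-pressure regimes
#'
#' The four stratification ranges used throughout: 0-15, 15-30, 30-45 and
#' >45 mN/m.
#'
#' @return data.frame with `label`, `lower`, `upper` (mN/m).
#' @export
pressure_regimes <- function() {
  reg <- data.frame(label = c("0-15", "15-30", "30-45", ">45"),
                    lower = c(0, 15, 30, 45),
                    upper = c(15, 30, 45, Inf),
                    stringsAsFactors = FALSE)
  validate_regimes(reg)
}

validate_regimes <- function(regimes) {
  stopifnot(all(c("label", "lower", "upper") %in% names(regimes)),
            all(regimes$lower < regimes$upper))
  o <- order(regimes$lower)
  r <- regimes[o, ]
  if (nrow(r) > 1 && any(r$upper[-nrow(r)] > r$lower[-1] + 1e-12)) {
    stop("pressure regimes overlap")
  }
  regimes
}

#' Map surface pressures to regime labels
#'
#' A value belongs to the regime with `lower <= Pi < upper`; values outside
#' every regime get `NA`.
#'
#' @param pi_values surface pressures (mN/m).
#' @param regimes regime table, see [pressure_regimes()].
#' @return character vector of regime labels (NA outside all regimes).
#' @export
assign_regime <- function(pi_values, regimes = pressure_regimes()) {
  validate_regimes(regimes)
  out <- rep(NA_character_, length(pi_values))
  for (i in seq_len(nrow(regimes))) {
    sel <- pi_values >= regimes$lower[i] & pi_values < regimes$upper[i]
    out[sel] <- regimes$label[i]
  }
  out
}
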