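#' Pipeline configuration
#'
#' Collects every tunable of the analysis stages with the conventional
#' defaults: 100 ns isotherm windows, DBSCAN at eps 0.55 nm / min_pts 4 /
#' min_cluster_size 10, 0.3 nm heavy-atom contact cutoff, 10 ns diffusion
#' lag with leaflet drift correction, the four standard pressure regimes,
#' and a clean-interface tension of 69.4 mN/m (water-air at 310 K; use
#' 71.7 at 298 K).
#'
#' @param gamma0 clean-interface tension (mN/m).
#' @param window isotherm window (ns).
#' @param eps,min_pts,min_cluster_size DBSCAN parameters.
#' @param contact_cutoff heavy-atom contact distance (nm).
#' @param lag diffusion lag (ns).
#' @param drift_correction subtract leaflet drift before displacements.
#' @param regimes surface-pressure regime table.
#' @param distance_bins protein-distance bin edges (nm).
#' @param z_bins density-profile bin edges (nm).
#' @param n_lipids_per_leaflet lipid count used for APL when the pressure
#'   series lacks an `apl` column.
#' @param seed RNG seed recorded in the report.
#' @return list of class `run_config`.
#' @export
run_config <- function(gamma0 = 69.4, window = 100,
                       eps = 0.55, min_pts = 4, min_cluster_size = 10,
                       contact_cutoff = 0.3, lag = 10,
                       drift_correction = TRUE,
                       regimes = pressure_regimes(),
                       distance_bins = seq(0, 8, by = 0.5),
                       z_bins = seq(-4, 3, by = 0.1),
                       n_lipids_per_leaflet = NULL,
                       seed = 1L) {
  stopifnot(gamma0 > 0, window > 0, eps > 0, min_pts >= 1,
            min_cluster_size >= 1, contact_cutoff > 0, lag > 0)
  validate_regimes(regimes)
  structure(list(gamma0 = gamma0, window = window, eps = eps,
                 min_pts = min_pts, min_cluster_size = min_cluster_size,
                 contact_cutoff = contact_cutoff, lag = lag,
                 drift_correction = drift_correction, regimes = regimes,
                 distance_bins = distance_bins, z_bins = z_bins,
                 n_lipids_per_leaflet = n_lipids_per_leaflet,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full monolayer analysis pipeline
#'
#' Orchestrates every stage over a trajectory plus pressure series:
#' windowed isotherm, per-frame surface pressure and regime, phase
#' detection per leaflet, condensed fraction versus protein distance,
#' phosphorus-aligned density map with extents, heavy-atom contacts,
#' displacement-based diffusion per regime, and protein RMSD against the
#' first frame. Tab-separated tables and a JSON run report are written to
#' `out_dir`; on a stage failure all partial outputs are removed and the
#' error names the stage. Protein-dependent stages are skipped (with the
#' reason logged in the report) for protein-free systems.
#'
#' @param topology role- and leaflet-assigned topology (or not; roles are
#'   assigned with the default map when missing).
#' @param trajectory `md_trajectory`, e.g. from [read_gro_frames()] or a
#'   [generate_compression_stack()].
#' @param pressure_series `pressure_series` table (or data.frame with
#'   `time`, `Pxx`, `Pyy`, `Pzz`, `Lz` and optionally `apl`).
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed.
#' @return (invisibly) list with every stage table and the report.
#' @export
run_pipeline <- function(topology, trajectory, pressure_series,
                         config = run_config(), out_dir = "psurf_out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       dec = ".")
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()
  skipped <- list()
  if (is.null(topology$role_phosphorus)) topology <- assign_roles(topology)
  if (is.null(topology$leaflet)) {
    topology <- assign_leaflets(trajectory$frames[[1]], topology)
  }
  has_protein <- any(topology$role_protein)

  # isotherm from the pressure series
  res$isotherm <- stage("isotherm", {
    ps <- pressure_series
    gam <- surface_tension(ps$Pxx, ps$Pyy, ps$Pzz, ps$Lz)
    pi_v <- surface_pressure(gam, config$gamma0)
    apl <- if (!is.null(ps$apl)) ps$apl else {
      if (is.null(config$n_lipids_per_leaflet)) {
        stop("pressure series has no apl column and config lacks n_lipids_per_leaflet")
      }
      # fall back to the trajectory's box areas, interpolated in time
      areas <- vapply(trajectory$frames, function(fr) fr$box[1] * fr$box[2],
                      numeric(1))
      a <- stats::approx(trajectory$times, areas, xout = ps$time, rule = 2)$y
      100 * a / config$n_lipids_per_leaflet
    }
    windowed_isotherm(ps$time, apl, pi_v, window = config$window)
  })
  emit(res$isotherm, "isotherm.tsv")

  # per-frame surface pressure: window-mean of the containing window
  times <- trajectory$times
  iso <- res$isotherm
  widx <- findInterval(times, iso$window_center_time - config$window / 2)
  widx[widx < 1L] <- 1L
  widx[widx > nrow(iso)] <- nrow(iso)
  pi_frame <- iso$pi_mean[widx]
  regime_frame <- assign_regime(pi_frame, config$regimes)

  # phases per frame and leaflet
  res$phases <- stage("phases", {
    rows <- list()
    for (fi in seq_along(trajectory$frames)) {
      for (lf in unique(topology$leaflet[topology$role_chain_marker |
                                           topology$role_chol_marker])) {
        lab <- phase_labels(trajectory$frames[[fi]], topology, lf,
                            eps = config$eps, min_pts = config$min_pts,
                            min_cluster_size = config$min_cluster_size)
        lab$frame <- fi
        lab$time <- times[fi]
        lab$leaflet <- lf
        lab$pressure <- pi_frame[fi]
        lab$regime <- regime_frame[fi]
        rows[[length(rows) + 1L]] <- as.data.frame(lab)
      }
    }
    do.call(rbind, rows)
  })
  emit(res$phases, "phases.tsv")

  # condensed fraction vs distance from protein
  if (has_protein) {
    res$lc_vs_distance <- stage("lc_vs_distance", {
      rows <- list()
      for (fi in seq_along(trajectory$frames)) {
        fr <- trajectory$frames[[fi]]
        for (lf in unique(topology$leaflet[topology$role_protein])) {
          psel <- topology$role_protein & topology$leaflet == lf
          lab <- res$phases[res$phases$frame == fi & res$phases$leaflet == lf, ]
          class(lab) <- c("phase_labeling", "data.frame")
          prof <- lc_fraction_vs_distance(
            lab, wrap_coords(fr$xyz[psel, 1:2, drop = FALSE], fr$box[1:2]),
            box_xy = fr$box[1:2], bin_edges = config$distance_bins)
          prof$frame <- fi
          prof$leaflet <- lf
          prof$regime <- regime_frame[fi]
          rows[[length(rows) + 1L]] <- prof
        }
      }
      do.call(rbind, rows)
    })
    emit(res$lc_vs_distance, "lc_vs_distance.tsv")
  } else {
    skipped$lc_vs_distance <- "no protein atoms in topology"
  }

  # density map and extents
  res$density <- stage("density", {
    density_profile(trajectory$frames, topology,
                    z_bins = config$z_bins,
                    pressure_per_frame = pi_frame,
                    regimes = config$regimes)
  })
  dm <- res$density
  dens_long <- do.call(rbind, lapply(dimnames(dm$density)[[1]], function(sp) {
    do.call(rbind, lapply(dm$regimes, function(rg) {
      data.frame(species = sp, regime = rg, z = dm$z_mid,
                 density = dm$density[sp, , rg], stringsAsFactors = FALSE)
    }))
  }))
  emit(dens_long, "density_map.tsv")
  emit(dm$extents, "extents.tsv")

  # contacts
  if (has_protein) {
    res$contacts <- stage("contacts", {
      per_frame <- lapply(trajectory$frames, function(fr) {
        count_contacts(fr, topology, cutoff = config$contact_cutoff)
      })
      lf_prot <- topology$leaflet[topology$role_protein][1]
      by_type <- stratify_by_regime(
        lapply(per_frame, function(cc) {
          stats::aggregate(count ~ lipid_type, data = cc, FUN = sum)
        }), pi_frame, config$regimes, value = "count")
      norm0 <- normalize_contacts(per_frame[[1]], topology, leaflet = lf_prot)
      by_type$normalized <- by_type$mean / norm0$abundance[by_type$lipid_type]
      by_res <- stratify_by_regime(per_frame, pi_frame, config$regimes,
                                   value = "count")
      list(by_type = by_type, by_residue = by_res)
    })
    emit(res$contacts$by_type, "contacts_by_type.tsv")
    emit(res$contacts$by_residue, "contacts_by_residue.tsv")
  } else {
    skipped$contacts <- "no protein atoms in topology"
  }

  # diffusion per pressure regime
  res$diffusion <- stage("diffusion", {
    rows <- list()
    for (rg in unique(stats::na.omit(regime_frame))) {
      fsel <- which(regime_frame == rg)
      if (length(fsel) < 2L) next
      sub <- structure(list(times = times[fsel],
                            frames = trajectory$frames[fsel]),
                       class = "md_trajectory")
      span <- diff(range(sub$times))
      lag_use <- min(config$lag, span)
      d <- try(lateral_displacements(sub, topology, lag = lag_use,
                                     drift_correction = config$drift_correction),
               silent = TRUE)
      if (inherits(d, "try-error")) next
      est <- fit_diffusion(d)
      est$regime <- rg
      rows[[length(rows) + 1L]] <- est
    }
    if (!length(rows)) NULL else {
      df <- do.call(rbind, rows)
      relative_diffusion(df, reference_regime = df$regime[1])
    }
  })
  if (is.null(res$diffusion)) {
    skipped$diffusion <- "no pressure regime contains at least two frames"
    res$diffusion <- NULL
  } else {
    emit(res$diffusion, "diffusion.tsv")
  }

  # protein RMSD vs first frame
  if (has_protein) {
    res$rmsd <- stage("rmsd", {
      psel <- topology$role_protein
      ref <- trajectory$frames[[1]]$xyz[psel, , drop = FALSE]
      data.frame(time = times,
                 rmsd = vapply(trajectory$frames, function(fr) {
                   rmsd(fr$xyz[psel, , drop = FALSE], ref)
                 }, numeric(1)))
    })
    emit(res$rmsd, "rmsd.tsv")
  } else {
    skipped$rmsd <- "no protein atoms in topology"
  }

  report <- list(
    parameters = config[setdiff(names(config), "regimes")],
    regimes = config$regimes,
    seed = config$seed,
    n_frames = length(trajectory$frames),
    has_protein = has_protein,
    skipped = skipped,
    records = lapply(res[c("isotherm", "phases", "lc_vs_distance",
                           "diffusion")], function(x) {
      if (is.data.frame(x)) nrow(x) else NULL
    }),
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("psurftools"))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  res$report <- report
  invisible(res)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Write a self-consistent synthetic fixture set
#'
#' Generates a compression stack and matching pressure series and writes
#' them in the formats the pipeline reads: a multi-frame GRO trajectory,
#' an XVG pressure series whose APL ramp matches the stack, and
#' ground-truth phase-label TSVs. The fixture directory can be fed back
#' through [read_gro_frames()] / [read_xvg()] / [run_pipeline()] without
#' edits, and the same spec and seed always reproduce identical files.
#'
#' @param spec base [monolayer_spec()].
#' @param out_dir output directory.
#' @param apl_grid APL values of the stack (Angstrom^2).
#' @param f_lc_grid planted condensed fractions (nonincreasing in APL).
#' @param gamma0 clean-interface tension for the planted schedule (mN/m).
#' @param pi_of_apl function mapping APL to target surface pressure
#'   (mN/m); the default is a linear rise from 0 at the largest APL to
#'   55 at the smallest.
#' @param t_end total time span (ns).
#' @return (invisibly) list with the generated objects and file paths.
#' @export
synth_fixtures <- function(spec = monolayer_spec(), out_dir,
                           apl_grid = c(90, 65, 55),
                           f_lc_grid = c(0, 0.3, 0.7),
                           gamma0 = 69.4,
                           pi_of_apl = NULL,
                           t_end = 1000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(pi_of_apl)) {
    pi_of_apl <- function(a) {
      55 * (max(apl_grid) - a) / (max(apl_grid) - min(apl_grid))
    }
  }
  times <- (seq_along(apl_grid) - 0.5) / length(apl_grid) * t_end
  stack <- generate_compression_stack(spec, apl_grid, f_lc_grid, times = times)
  gro <- file.path(out_dir, "trajectory.gro")
  unlink(gro)
  for (i in seq_along(stack$frames)) {
    write_gro(stack$topology, stack$frames[[i]], gro, append = i > 1L)
  }
  n <- spec$n_lipids_per_leaflet
  apl_of_t <- function(t) {
    e0 <- sqrt(max(apl_grid)); e1 <- sqrt(min(apl_grid))
    (e0 + (e1 - e0) * t / t_end)^2
  }
  ps <- generate_pressure_series(
    function(t) gamma0 - pi_of_apl(apl_of_t(t)),
    gamma0 = gamma0, noise_sd = 0, t_end = t_end, dt = 1,
    apl_ramp = c(max(apl_grid), min(apl_grid)), seed = spec$seed)
  xvg <- file.path(out_dir, "pressure.xvg")
  write_xvg(ps[, c("time", "Pxx", "Pyy", "Pzz", "Lz", "apl")], xvg,
            title = "planted pressure series")
  truth_paths <- character(0)
  for (i in seq_along(stack$truths)) {
    p <- file.path(out_dir, sprintf("truth_frame%02d.tsv", i))
    utils::write.table(stack$truths[[i]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_paths <- c(truth_paths, p)
  }
  invisible(list(stack = stack, pressure_series = ps,
                 paths = list(gro = gro, xvg = xvg, truth = truth_paths)))
}
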