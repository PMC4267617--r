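# Occupancy, residence-time kinetics, binding-distance statistics and
# multi-atom pocket ("ion trap") detection.
#
# A site (single atom or atom group) is occupied at a frame when at least
# one ion of the species lies within the cutoff of at least one site atom
# (minimum-image distances).  An ion may contribute to several sites at
# once; group occupancy is the union over member atoms.

#' Default binding cutoffs by species
#'
#' Direct (first-shell) cutoffs: Na+ 3.0 A, K+ 3.5 A, Mg2+ 5.0 A
#' (hexahydrated); water-mediated binding: 6.0 A for all species.
#'
#' @param species species label.
#' @param mode `"direct"` or `"mediated"`.
#' @return cutoff in A.
#' @export
default_cutoff <- function(species, mode = c("direct", "mediated")) {
  mode <- match.arg(mode)
  if (mode == "mediated") return(6.0)
  switch(species, "Na+" = 3.0, "K+" = 3.5, "Mg2+" = 5.0, 3.0)
}

#' Binary occupancy trace of a binding site
#'
#' @param traj a `Trajectory`.
#' @param site integer vector of site-atom indices.
#' @param species ion species label.
#' @param cutoff distance cutoff (A); defaults to the species' direct cutoff.
#' @param window time window (ps); default: the whole trajectory after
#'   discarding the leading 1/6 (data-collection convention).  Use
#'   `window = FALSE` for all frames.
#' @return object of class `OccupancyTrace`: binary vector `p`, `times`,
#'   `dt`, `site`, `species`, `cutoff`.
#' @export
occupancy_trace <- function(traj, site, species, cutoff = NULL, window = NULL) {
  if (!length(site)) stop("site selection is empty")
  cutoff <- cutoff %||% default_cutoff(species)
  if (cutoff < 0) stop("cutoff must be >= 0")
  if (is.null(window)) window <- collection_window(traj)
  frames <- if (identical(window, FALSE)) seq_len(traj$n_frames)
            else window_frames(traj, window)
  idx <- species_indices(traj, species)
  occ <- rep(FALSE, length(frames))
  for (i in idx) {
    qi <- t(traj$coords[i, , frames, drop = FALSE][1, , ])
    for (s in site) {
      if (all(occ)) break
      qs <- t(traj$coords[s, , frames, drop = FALSE][1, , ])
      occ <- occ | (min_image_distance(qs, qi, traj$box) < cutoff)
    }
  }
  structure(list(p = as.integer(occ), times = traj$times[frames],
                 dt = traj$dt, site = site, species = species,
                 cutoff = cutoff),
            class = "OccupancyTrace")
}

#' Occupancy percentage of a trace
#'
#' 100 times the fraction of frames in which the site is occupied.
#'
#' @param trace an `OccupancyTrace` (or plain binary vector).
#' @return percent in `[0, 100]`.
#' @export
occupancy_fraction <- function(trace) {
  p <- if (inherits(trace, "OccupancyTrace")) trace$p else trace
  if (!length(p)) stop("empty occupancy trace")
  100 * mean(p)
}

#' Occupancy by sequence position and region
#'
#' Per-nucleotide, per-region occupancy table.  The second strand is
#' reported 5'->3' (reverse spatial order) so that converged ion
#' distributions show mirror symmetry between the two strand blocks.
#'
#' @param traj a `Trajectory` with a duplex.
#' @param species ion species label.
#' @param cutoff distance cutoff (A), default the species' direct cutoff.
#' @param window time window (ps), as in [occupancy_trace()].
#' @param regions region labels to tabulate.
#' @return data.frame with columns `strand`, `position` (5'->3' within the
#'   strand), `residue` (global index), `base`, `region`, `occupancy`
#'   (percent).
#' @export
occupancy_by_sequence <- function(traj, species, cutoff = NULL, window = NULL,
                                  regions = c("major", "minor",
                                              "backbone_Oprime", "phosphate")) {
  top <- traj$topology
  a <- top$atoms
  nuc <- !is.na(a$base)
  chains <- unique(a$chain[nuc])
  rows <- list()
  for (ch in chains) {
    res <- sort(unique(a$residue[nuc & a$chain == ch]))
    for (k in seq_along(res)) {
      r <- res[k]
      for (reg in regions) {
        sel <- select_atoms(top, residue = r, region = reg)
        occ <- if (length(sel)) {
          occupancy_fraction(occupancy_trace(traj, sel, species, cutoff, window))
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          strand = ch, position = k, residue = r,
          base = a$base[nuc & a$residue == r][1],
          region = reg, occupancy = occ, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  # display convention: second strand in reverse spatial order (its own 5'->3')
  out
}

#' Residence time from the occupancy autocorrelation
#'
#' Computes `C(t) = <p(t0) p(t0 + t)>` over all valid time origins on a lag
#' grid (default 10 ps to 1 ns in 10 ps steps), normalizes by `C(0)`, and
#' fits a single exponential by weighted log-linear least squares to obtain
#' the residence time `tau_R`.
#'
#' For a stationary occupancy trace `C(t)/C(0)` decays to the mean occupancy
#' rather than to zero; by default that plateau (estimated by the trace
#' mean) is subtracted before the fit and the fitted rate is rescaled by
#' `(1 - mean(p))`, which makes `tau_R` estimate the mean bound duration
#' exactly for a two-state Markov (telegraph) process at any occupancy.
#' `plateau = "none"` fits the unsubtracted curve.  The fit is weighted by
#' the (subtracted) correlation and restricted to the initial decay, where
#' the kinetic signal dominates the sampling noise.
#'
#' @param trace an `OccupancyTrace`.
#' @param lag_min,lag_max,lag_step lag grid (ps).
#' @param plateau `"subtract"` (default) or `"none"`.
#' @param censor_ratio censor when `C(lag_max)/C(0)` exceeds this (0.9).
#' @return object of class `ResidenceResult`: `lags` (ps), `C` (normalized),
#'   `tau_R` (ns), `fit_r2`, `censored`, `mean_occupancy`.
#' @export
residence_time <- function(trace, lag_min = 10, lag_max = 1000, lag_step = 10,
                           plateau = c("subtract", "none"),
                           censor_ratio = 0.9) {
  plateau <- match.arg(plateau)
  p <- trace$p
  dt <- trace$dt
  n <- length(p)
  if (sum(p) == 0) stop("site never occupied; residence time undefined")
  lags_ps <- seq(lag_min, lag_max, by = lag_step)
  lags_fr <- unique(round(lags_ps / dt))
  lags_fr <- lags_fr[lags_fr >= 1 & lags_fr < n]
  if (!length(lags_fr)) stop("trace too short for the requested lag grid")
  lags_ps <- lags_fr * dt
  c0 <- mean(p)
  C <- vapply(lags_fr, function(l) {
    mean(p[seq_len(n - l)] * p[(l + 1L):n])
  }, 0) / c0
  pbar <- mean(p)
  censored <- C[length(C)] > censor_ratio || pbar >= 1 - 1e-12
  tau <- NA_real_
  r2 <- NA_real_
  if (!censored) {
    y <- if (plateau == "subtract") C - pbar else C
    # fit only the initial decay: lags where the subtracted correlation has
    # fallen below ~20% of its first-lag value are dominated by noise and
    # bias the log-linear slope
    keep <- y > max(1e-8, 0.2 * y[1])
    if (sum(keep) >= 3L) {
      fit <- lm(log(y[keep]) ~ lags_ps[keep], weights = y[keep])
      slope <- unname(coef(fit)[2])
      if (is.finite(slope) && slope < 0) {
        rate <- -slope                       # 1/ps
        if (plateau == "subtract") rate <- rate * (1 - pbar)
        tau <- 1 / rate / 1000               # ns
        r2 <- summary(fit)$r.squared
      } else {
        censored <- TRUE
      }
    } else {
      censored <- TRUE
    }
  }
  structure(list(lags = lags_ps, C = C, tau_R = tau, fit_r2 = r2,
                 censored = censored, mean_occupancy = pbar,
                 plateau = plateau),
            class = "ResidenceResult")
}

#' @export
print.ResidenceResult <- function(x, ...) {
  if (x$censored) {
    cat("<ResidenceResult> censored (no decay over the lag grid)\n")
  } else {
    cat(sprintf("<ResidenceResult> tau_R = %.3g ns (fit R^2 = %.3f, mean occupancy %.1f%%)\n",
                x$tau_R, x$fit_r2, 100 * x$mean_occupancy))
  }
  invisible(x)
}

#' Binding-distance statistics for a site atom
#'
#' Over frames with at least one bound ion, the distance of the nearest
#' bound ion to the site atom; unbound frames are excluded.
#'
#' @param traj a `Trajectory`.
#' @param site_atom single atom index.
#' @param species ion species label.
#' @param cutoff binding cutoff (A), default the species' direct cutoff.
#' @param window time window (ps); default the trailing 10 ns of the
#'   trajectory (or all of it when shorter).
#' @return object of class `BindingDistanceStats`: `mean`, `sd` (A),
#'   `n_bound_frames`, `window`, logical `undefined` when no frame is bound.
#' @export
binding_distance_stats <- function(traj, site_atom, species, cutoff = NULL,
                                   window = NULL) {
  stopifnot(length(site_atom) == 1L)
  cutoff <- cutoff %||% default_cutoff(species)
  if (is.null(window)) {
    t1 <- traj$times[traj$n_frames]
    window <- c(max(traj$times[1], t1 - 10000), t1)
  }
  frames <- if (identical(window, FALSE)) seq_len(traj$n_frames)
            else window_frames(traj, window)
  idx <- species_indices(traj, species)
  qs <- t(traj$coords[site_atom, , frames, drop = FALSE][1, , ])
  dmin <- rep(Inf, length(frames))
  for (i in idx) {
    qi <- t(traj$coords[i, , frames, drop = FALSE][1, , ])
    dmin <- pmin(dmin, min_image_distance(qs, qi, traj$box))
  }
  bound <- dmin < cutoff
  n <- sum(bound)
  structure(list(
    mean = if (n) mean(dmin[bound]) else NA_real_,
    sd = if (n > 1) sd(dmin[bound]) else if (n == 1) 0 else NA_real_,
    n_bound_frames = n, window = window, cutoff = cutoff,
    undefined = n == 0L), class = "BindingDistanceStats")
}

#' Detect multi-atom binding pockets ("ion traps")
#'
#' Maximal time intervals during which a single ion stays within the direct
#' cutoff of at least `min_sites` duplex electronegative atoms (O and N)
#' simultaneously.  The reported member set is the intersection over the
#' interval, so every member is within the cutoff in every frame of the
#' dwell.
#'
#' @param traj a `Trajectory`.
#' @param species ion species label.
#' @param cutoff direct cutoff (A), default by species.
#' @param min_sites minimum number of coordinating atoms (>= 2).
#' @param min_dwell minimum dwell (ps) for a pocket to be reported.
#' @param window time window (ps), default all frames.
#' @return list of `Pocket` objects: `ion` (atom index), `members` (atom
#'   indices), `member_names` (e.g. `O2 x2, O2' x2`), `frames`
#'   (first, last), `dwell` (ps).
#' @export
detect_pockets <- function(traj, species, cutoff = NULL, min_sites = 2,
                           min_dwell = 0, window = NULL) {
  if (min_sites < 2) stop("min_sites must be >= 2")
  cutoff <- cutoff %||% default_cutoff(species)
  frames <- window_frames(traj, window)
  idx <- species_indices(traj, species)
  a <- traj$topology$atoms
  cand <- which(!is.na(a$base) & a$element %in% c("O", "N"))
  if (!length(cand)) return(list())
  pockets <- list()
  for (ion in idx) {
    qi <- t(traj$coords[ion, , frames, drop = FALSE][1, , ])
    bound <- matrix(FALSE, length(frames), length(cand))
    for (j in seq_along(cand)) {
      qs <- t(traj$coords[cand[j], , frames, drop = FALSE][1, , ])
      bound[, j] <- min_image_distance(qs, qi, traj$box) < cutoff
    }
    k <- 1L
    while (k <= length(frames)) {
      members <- which(bound[k, ])
      if (length(members) < min_sites) { k <- k + 1L; next }
      end <- k
      cur <- members
      while (end < length(frames)) {
        nxt <- intersect(cur, which(bound[end + 1L, ]))
        if (length(nxt) < min_sites) break
        cur <- nxt
        end <- end + 1L
      }
      dwell <- (end - k + 1L) * traj$dt
      if (dwell >= min_dwell) {
        nm <- table(paste0(a$name[cand[cur]], "(", a$base[cand[cur]], ")"))
        pockets[[length(pockets) + 1L]] <- structure(list(
          ion = ion, members = cand[cur],
          member_names = paste(sprintf("%s x%d", names(nm), as.integer(nm)),
                               collapse = ", "),
          frames = c(frames[k], frames[end]), dwell = dwell),
          class = "Pocket")
      }
      k <- end + 1L
    }
  }
  pockets
}
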