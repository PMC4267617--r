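# Spatial distribution statistics: cylindrical distribution functions (ion
# molarity vs distance from the helix axis), radial distribution functions
# g(r) around duplex atoms, coordination numbers, cumulative charge
# neutralization and time-window convergence series.

distribution_result <- function(bin_edges, values, raw_counts, n_frames,
                                species, kind, stderr = NULL, meta = list()) {
  stopifnot(all(diff(bin_edges) > 0))
  structure(list(bin_edges = bin_edges, values = values,
                 raw_counts = raw_counts, n_frames = n_frames,
                 species = species, kind = kind, stderr = stderr,
                 meta = meta),
            class = "DistributionResult")
}

#' @export
print.DistributionResult <- function(x, ...) {
  cat("<DistributionResult> kind=", x$kind, " species=", x$species,
      " bins=", length(x$values), " [", x$bin_edges[1], ", ",
      x$bin_edges[length(x$bin_edges)], "] A, n_frames=", x$n_frames,
      "\n", sep = "")
  invisible(x)
}

bin_centers <- function(d) (head(d$bin_edges, -1) + tail(d$bin_edges, -1)) / 2

hist_counts <- function(x, edges) {
  i <- findInterval(x, edges)
  nb <- length(edges) - 1L
  keep <- i >= 1L & i <= nb & x < edges[nb + 1L]
  tabulate(i[keep], nb)
}

# frames-per-block for the block-averaged standard error (block in ps)
block_ids <- function(n_frames, dt, block) {
  fpb <- max(1L, round(block / dt))
  ((seq_len(n_frames) - 1L) %/% fpb) + 1L
}

block_stderr <- function(per_frame, ids) {
  # per_frame: n_frames x n_bins matrix of per-frame values
  blocks <- rowsum(per_frame, ids) / as.vector(table(ids))
  nb <- nrow(blocks)
  if (nb < 2L) return(rep(NA_real_, ncol(per_frame)))
  apply(blocks, 2, sd) / sqrt(nb)
}

# cylindrical radius and axial coordinate of a set of atoms in one frame,
# min-imaged relative to the axis origin
cyl_coords_frame <- function(traj, idx, f, hf) {
  p <- traj$coords[idx, , f, drop = FALSE][, , 1, drop = TRUE]
  p <- as_coord_matrix(p)
  v <- min_image_disp(sweep(p, 2, hf$origin), traj$box)
  v <- as_coord_matrix(v)
  z <- drop(v %*% hf$direction)
  list(r = sqrt(pmax(rowSums(v * v) - z^2, 0)), z = z)
}

axial_bounds <- function(hf, box, axial) {
  if (axial == "duplex") {
    hf$axial_extent
  } else {
    h <- sum(abs(hf$direction) * box)
    c(-h / 2, h / 2)
  }
}

#' Cylindrical distribution function (CDF)
#'
#' Average molar concentration of an ion species in cylindrical shells
#' around the helical axis.  Shells are bounded axially either by the
#' fitted axial extent of the duplex (default) or by the full box height.
#'
#' @param traj a `Trajectory`.
#' @param species species label (e.g. `"Na+"`).
#' @param hf a `HelixFrame` or a per-frame list (see [helix_frames()]).
#' @param r_max outer radius (A); profiles should normally extend to >= 30 A.
#' @param dr radial bin width (A); default 0.5.
#' @param window optional `c(t_start, t_end)` time window (ps).
#' @param axial `"duplex"` (axial extent of the axis fit) or `"box"`.
#' @param block block length (ps) for the block-averaged standard error.
#' @return `DistributionResult` with values in mol/L; `meta$mean_count` is
#'   the mean number of ions inside the full cylinder (mass-conservation
#'   oracle), `meta$h` the axial height used for shell volumes.
#' @export
compute_cdf <- function(traj, species, hf, r_max = 30, dr = 0.5,
                        window = NULL, axial = c("duplex", "box"),
                        block = 1000) {
  axial <- match.arg(axial)
  frames <- window_frames(traj, window)
  hfs <- expand_helix_frames(hf, frames)
  # a species with no atoms gives an all-zero profile (not an error)
  idx <- traj$species[[species]] %||% integer(0)
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  warnings <- character()
  if (r_max > min(traj$box) / 2) {
    warnings <- c(warnings, sprintf(
      "r_max = %g A exceeds half the smallest box edge (%g A); outer shells sample periodic images",
      r_max, min(traj$box) / 2))
  }
  counts <- matrix(0, length(frames), nb)
  hvec <- numeric(length(frames))
  incyl <- numeric(length(frames))
  for (k in seq_along(frames)) {
    hfk <- hfs[[k]]
    cc <- cyl_coords_frame(traj, idx, frames[k], hfk)
    zb <- axial_bounds(hfk, traj$box, axial)
    keep <- cc$z >= zb[1] & cc$z <= zb[2]
    counts[k, ] <- hist_counts(cc$r[keep], edges)
    hvec[k] <- diff(zb)
    incyl[k] <- sum(keep & cc$r <= r_max)
  }
  h <- mean(hvec)
  shell_vol <- pi * diff(edges^2) * h
  conc_per_frame <- sweep(counts, 2, AVOGADRO * shell_vol * 1e-27, "/")
  values <- colMeans(conc_per_frame)
  se <- block_stderr(conc_per_frame, block_ids(length(frames), traj$dt, block))
  distribution_result(edges, values, colSums(counts), length(frames),
                      species, "cdf", stderr = se,
                      meta = list(h = h, shell_vol = shell_vol,
                                  mean_count = mean(incyl), axial = axial,
                                  warnings = warnings))
}

#' Radial distribution function g(r) around selected duplex atoms
#'
#' Pair density of an ion species around the site atoms, normalized by the
#' bulk density (species count over box volume) so that g = 1 is bulk-like.
#' Minimum-image distances; averaged over frames and site atoms.
#'
#' @param traj a `Trajectory`.
#' @param species ion species label.
#' @param sites integer vector of site-atom indices (see [select_atoms()]).
#' @param r_max,dr binning (A); default 10 A by 0.1 A.
#' @param window optional time window (ps).
#' @param block block length (ps) for the standard error.
#' @return `DistributionResult` with dimensionless `values`; `meta` carries
#'   `rho_bulk` (1/A^3), `n_sites` and the spherical shell volumes.
#' @export
compute_rdf <- function(traj, species, sites, r_max = 10, dr = 0.1,
                        window = NULL, block = 1000) {
  if (!length(sites)) stop("site selection is empty")
  frames <- window_frames(traj, window)
  idx <- species_indices(traj, species)
  rho_bulk <- length(idx) / prod(traj$box)
  if (rho_bulk <= 0) stop("bulk density is zero for species '", species, "'")
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  counts <- matrix(0, length(frames), nb)
  d <- pair_distance_array(traj, sites, idx, frames)
  for (k in seq_along(frames)) {
    counts[k, ] <- hist_counts(as.vector(d[, , k]), edges)
  }
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  norm <- length(sites) * rho_bulk * shell_vol
  g_per_frame <- sweep(counts, 2, norm, "/")
  values <- colMeans(g_per_frame)
  se <- block_stderr(g_per_frame, block_ids(length(frames), traj$dt, block))
  distribution_result(edges, values, colSums(counts), length(frames),
                      species, "rdf", stderr = se,
                      meta = list(rho_bulk = rho_bulk, n_sites = length(sites),
                                  shell_vol = shell_vol))
}

#' First peak of a distribution profile
#'
#' Location of the first local maximum whose height exceeds a prominence
#' threshold.  Within the first contiguous above-threshold run the highest
#' bin is reported (robust to bin noise on a rising flank).  When no bin
#' qualifies a `none` result is returned rather than an error.
#'
#' @param dist a `DistributionResult` of kind `rdf` or `cdf`.
#' @param threshold minimum height for a qualifying peak (default 1.5,
#'   appropriate for g(r)).
#' @return list with `r_peak` (A, bin center), `height`, and logical `none`.
#' @export
first_peak <- function(dist, threshold = 1.5) {
  stopifnot(dist$kind %in% c("rdf", "cdf"))
  v <- dist$values
  ctr <- bin_centers(dist)
  above <- which(v > threshold)
  if (!length(above)) return(list(r_peak = NA_real_, height = NA_real_, none = TRUE))
  run_end <- above[1]
  while (run_end < length(v) && v[run_end + 1L] > threshold) run_end <- run_end + 1L
  run <- seq(above[1], run_end)
  i <- run[which.max(v[run])]
  # a maximum in the very first bin has no rising flank: monotone decay,
  # not a peak
  if (i == 1L) return(list(r_peak = NA_real_, height = NA_real_, none = TRUE))
  list(r_peak = ctr[i], height = v[i], none = FALSE)
}

#' First minimum after the first peak
#'
#' First local minimum following the first qualifying peak that falls below
#' `floor_value`; used to delimit the first coordination shell.
#'
#' @param dist a `DistributionResult` of kind `rdf`.
#' @param threshold passed to [first_peak()].
#' @param floor_value a minimum must fall below this value (default 1).
#' @return list with `r_min` (A) and `value`, or `none = TRUE`.
#' @export
first_minimum <- function(dist, threshold = 1.5, floor_value = 1) {
  pk <- first_peak(dist, threshold)
  if (pk$none) return(list(r_min = NA_real_, value = NA_real_, none = TRUE))
  v <- dist$values
  ctr <- bin_centers(dist)
  i0 <- which.min(abs(ctr - pk$r_peak))
  for (i in seq(i0 + 1L, length(v) - 1L)) {
    if (v[i] <= v[i - 1L] && v[i] <= v[i + 1L] && v[i] < floor_value) {
      return(list(r_min = ctr[i], value = v[i], none = FALSE))
    }
  }
  list(r_min = NA_real_, value = NA_real_, none = TRUE)
}

#' Coordination number from an RDF
#'
#' Integrates `rho_bulk * g(r)` over spherical shells up to `r_cut`;
#' equals the mean number of neighbors within `r_cut` of a site.
#'
#' @param dist a `DistributionResult` of kind `rdf`.
#' @param r_cut integration limit (A), within the binned range.
#' @return mean neighbor count.
#' @export
coordination_number <- function(dist, r_cut) {
  stopifnot(dist$kind == "rdf")
  edges <- dist$bin_edges
  if (r_cut <= edges[1] || r_cut > edges[length(edges)] + 1e-9) {
    stop("r_cut = ", r_cut, " A outside the binned range [",
         edges[1], ", ", edges[length(edges)], "]")
  }
  nb <- length(edges) - 1L
  full <- which(edges[-1] <= r_cut + 1e-9)
  n <- sum(dist$meta$rho_bulk * dist$values[full] * dist$meta$shell_vol[full])
  # fractional last shell
  part <- if (length(full)) max(full) + 1L else 1L
  if (part <= nb && r_cut > edges[part]) {
    vol <- 4 / 3 * pi * (r_cut^3 - edges[part]^3)
    n <- n + dist$meta$rho_bulk * dist$values[part] * vol
  }
  n
}

#' Cumulative ionic charge around the helical axis
#'
#' Total ionic charge (counterions + co-ions) within cylindrical radius r of
#' the axis, normalized by the magnitude of the duplex net charge; the
#' profile is cumulative (not a binned density).
#'
#' @param traj a `Trajectory` whose duplex has nonzero net formal charge.
#' @param hf a `HelixFrame` or per-frame list.
#' @param species_charges named vector, label -> charge (e); defaults to the
#'   standard ion charges.  Any trajectory species absent from the map is an
#'   error.
#' @param r_max,dr radial grid (A).
#' @param window optional time window (ps).
#' @param axial `"duplex"` span or full `"box"` height (see [compute_cdf()]).
#' @param block block length (ps) for the standard error.
#' @return `DistributionResult` of kind `charge`; `values[i]` is Q(r) at the
#'   right edge of bin i.
#' @export
charge_accumulation <- function(traj, hf, species_charges = NULL, r_max = 30,
                                dr = 0.5, window = NULL,
                                axial = c("duplex", "box"), block = 1000) {
  axial <- match.arg(axial)
  charges <- species_charges %||% ION_CHARGES
  qnet <- traj$topology$net_charge
  if (is.null(qnet) || qnet == 0) stop("duplex net charge is zero; cannot normalize")
  labels <- names(traj$species)
  missing <- setdiff(labels, names(charges))
  if (length(missing)) {
    stop("species with undefined charge: ", paste(missing, collapse = ", "))
  }
  labels <- labels[charges[labels] != 0]
  frames <- window_frames(traj, window)
  hfs <- expand_helix_frames(hf, frames)
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  qcum <- matrix(0, length(frames), nb)
  raw <- rep(0L, nb)
  for (lab in labels) {
    idx <- species_indices(traj, lab)
    z <- charges[[lab]]
    for (k in seq_along(frames)) {
      hfk <- hfs[[k]]
      cc <- cyl_coords_frame(traj, idx, frames[k], hfk)
      zb <- axial_bounds(hfk, traj$box, axial)
      r <- cc$r[cc$z >= zb[1] & cc$z <= zb[2]]
      cnt <- hist_counts(r, edges)
      raw <- raw + cnt
      qcum[k, ] <- qcum[k, ] + z * cumsum(cnt)
    }
  }
  qcum <- qcum / abs(qnet)
  values <- colMeans(qcum)
  se <- block_stderr(qcum, block_ids(length(frames), traj$dt, block))
  distribution_result(edges, values, raw, length(frames), "all-ions",
                      "charge", stderr = se,
                      meta = list(net_charge = qnet, axial = axial,
                                  species = labels))
}

#' Convergence of a distribution over growing time windows
#'
#' Recomputes a profile over windows sharing a common start time with
#' increasing end times and reports the sup-norm difference between
#' consecutive profiles; a non-decreasing difference trend (Spearman rho
#' >= 0) flags non-stationarity.
#'
#' @param traj a `Trajectory`.
#' @param windows list of `c(t_start, t_end)` (ps) sharing `t_start`, with
#'   strictly increasing `t_end`.
#' @param fun profile function `function(traj, window) -> DistributionResult`;
#'   when omitted, a [compute_cdf()] closure built from `species`, `hf` and
#'   `...` is used.
#' @param species,hf,... passed to [compute_cdf()] when `fun` is `NULL`.
#' @return list of class `ConvergenceSeries`: `windows`, `profiles`,
#'   `sup_diffs` (length `length(windows) - 1`), `trend_rho` and logical
#'   `non_shrinking`.
#' @export
convergence_series <- function(traj, windows, fun = NULL, species = NULL,
                               hf = NULL, ...) {
  if (length(windows) < 2L) stop("need at least 2 windows")
  starts <- vapply(windows, `[`, 0, 1)
  ends <- vapply(windows, `[`, 0, 2)
  if (max(starts) - min(starts) > 1e-9) stop("windows must share t_start")
  if (any(diff(ends) <= 0)) stop("window end times must be strictly increasing")
  if (is.null(fun)) {
    fun <- function(traj, window) compute_cdf(traj, species, hf, window = window, ...)
  }
  profiles <- lapply(windows, function(w) fun(traj, w))
  sup_diffs <- vapply(seq_len(length(profiles) - 1L), function(i) {
    max(abs(profiles[[i + 1L]]$values - profiles[[i]]$values))
  }, 0)
  rho <- if (length(sup_diffs) >= 2L) {
    suppressWarnings(cor(seq_along(sup_diffs), sup_diffs, method = "spearman"))
  } else NA_real_
  structure(list(windows = windows, profiles = profiles,
                 sup_diffs = sup_diffs, trend_rho = rho,
                 non_shrinking = is.na(rho) || rho >= 0),
            class = "ConvergenceSeries")
}
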