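# Helical-axis construction and cylindrical coordinates.
#
# The global axis of a frame is the total-least-squares line through the
# base-pair reference centers; a strand's reference point for a pair is the
# midpoint of its C1' atom and its glycosidic-reference base nitrogen
# (purine N9; pyrimidine N4 by the literal convention, N1 optionally).

#' Base-pair reference centers
#'
#' One 3-vector per base pair: the midpoint of the two strands' reference
#' points, each being the midpoint of the strand's C1' and its reference
#' nitrogen.
#'
#' @param coords n_atoms x 3 coordinate matrix of a single frame (A).
#' @param top a [topology()] with a pairing map.
#' @param pyrimidine_ref reference nitrogen used for pyrimidines: `"N4"`
#'   (default, the literal axis-definition convention) or `"N1"` (the
#'   glycosidic nitrogen).
#' @return matrix n_pairs x 3 of centers (A), ordered by strand-1 residue.
#' @export
pair_reference_centers <- function(coords, top, pyrimidine_ref = c("N4", "N1")) {
  pyrimidine_ref <- match.arg(pyrimidine_ref)
  if (is.null(top$pairing)) stop("topology has no Watson-Crick pairing map")
  coords <- as_coord_matrix(coords)
  a <- top$atoms
  ref_point <- function(res) {
    sel <- which(a$residue == res)
    base <- a$base[sel][1]
    nref <- if (base %in% c("A", "G")) "N9" else pyrimidine_ref
    i1 <- sel[a$name[sel] == "C1'"]
    i2 <- sel[a$name[sel] == nref]
    if (!length(i1)) stop("residue ", res, ": missing reference atom C1'")
    if (!length(i2)) stop("residue ", res, ": missing reference atom ", nref)
    (coords[i1[1], ] + coords[i2[1], ]) / 2
  }
  centers <- t(apply(top$pairing, 1, function(p) {
    (ref_point(p[["res1"]]) + ref_point(p[["res2"]])) / 2
  }))
  centers
}

#' Fit the global helical axis through base-pair centers
#'
#' Total-least-squares line (first principal component of the centered
#' points).  The direction sign points from the first toward the last center
#' (increasing strand-1 residue index); the axial extent is the interval of
#' the first and last centers' projections onto the axis.
#'
#' @param centers n x 3 matrix of base-pair centers (n >= 2).
#' @return a `HelixFrame`: list with `origin`, unit `direction`,
#'   `pair_centers`, `axial_extent` (`c(z_min, z_max)` relative to the
#'   origin) and `max_residual`, the largest point-to-line distance (A), a
#'   bend diagnostic.
#' @export
fit_axis <- function(centers) {
  centers <- as_coord_matrix(centers)
  if (nrow(centers) < 2L) stop("need at least 2 centers to fit an axis")
  origin <- colMeans(centers)
  x <- sweep(centers, 2, origin)
  if (max(abs(x)) < 1e-9) stop("all centers coincide; axis undefined")
  s <- svd(x, nu = 0, nv = 3)
  direction <- s$v[, 1]
  span <- centers[nrow(centers), ] - centers[1, ]
  if (sum(direction * span) < 0) direction <- -direction
  z <- drop(x %*% direction)
  perp <- sqrt(pmax(rowSums(x * x) - z^2, 0))
  extent <- c(z[1], z[length(z)])
  if (extent[1] >= extent[2]) extent <- range(z)
  helix_frame(origin, direction, extent, pair_centers = centers,
              max_residual = max(perp))
}

#' Construct a helix frame directly
#'
#' Mostly useful for synthetic systems where the axis is known (e.g. the box
#' z-axis for an ideal-gas control).
#'
#' @param origin point on the axis (A).
#' @param direction axis direction (normalized internally).
#' @param axial_extent `c(z_min, z_max)` along the axis relative to
#'   `origin` (A), with `z_min < z_max`.
#' @param pair_centers optional matrix of base-pair centers.
#' @param max_residual optional bend diagnostic (A).
#' @return object of class `HelixFrame`.
#' @export
helix_frame <- function(origin, direction, axial_extent,
                        pair_centers = NULL, max_residual = NA_real_) {
  stopifnot(length(origin) == 3L, length(direction) == 3L,
            length(axial_extent) == 2L, axial_extent[1] < axial_extent[2])
  structure(list(origin = as.numeric(origin), direction = unitv(direction),
                 axial_extent = as.numeric(axial_extent),
                 pair_centers = pair_centers, max_residual = max_residual),
            class = "HelixFrame")
}

#' Per-frame helix axes for a trajectory
#'
#' @param traj a `Trajectory` containing a duplex.
#' @param frames frame indices (default all).
#' @param pyrimidine_ref see [pair_reference_centers()].
#' @param trim_ends number of base pairs to drop from each end before the
#'   axis fit (default 0: terminal pairs included).
#' @return list of `HelixFrame`, one per requested frame.
#' @export
helix_frames <- function(traj, frames = NULL, pyrimidine_ref = c("N4", "N1"),
                         trim_ends = 0) {
  frames <- frames %||% seq_len(traj$n_frames)
  pyrimidine_ref <- match.arg(pyrimidine_ref)
  lapply(frames, function(f) {
    centers <- pair_reference_centers(frame_coords(traj, f), traj$topology,
                                      pyrimidine_ref)
    if (trim_ends > 0) {
      keep <- seq(trim_ends + 1L, nrow(centers) - trim_ends)
      centers <- centers[keep, , drop = FALSE]
    }
    fit_axis(centers)
  })
}

#' Perpendicular distance from points to the helix axis
#'
#' @param points length-3 vector or n x 3 matrix (A).
#' @param hf a `HelixFrame`.
#' @return numeric vector of radial distances (A).
#' @export
cylindrical_r <- function(points, hf) {
  p <- as_coord_matrix(points)
  v <- sweep(p, 2, hf$origin)
  z <- drop(v %*% hf$direction)
  sqrt(pmax(rowSums(v * v) - z^2, 0))
}

# axial coordinate along the helix direction, relative to the origin
cylindrical_z <- function(points, hf) {
  p <- as_coord_matrix(points)
  drop(sweep(p, 2, hf$origin) %*% hf$direction)
}

# expand a single HelixFrame (or list) to one entry per requested frame
expand_helix_frames <- function(hf, frames) {
  if (inherits(hf, "HelixFrame")) {
    rep(list(hf), length(frames))
  } else {
    stopifnot(is.list(hf))
    if (length(hf) == length(frames)) hf else hf[frames]
  }
}
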