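# Shared fixtures (all built in code) and independent oracles.

ION_DF <- function(n, species = "Na+") {
  rn <- switch(species, "Na+" = "NA", "K+" = "K", "Mg2+" = "MG",
               "Cl-" = "CL", species)
  data.frame(name = rep(rn, n), element = rep(rn, n), residue = seq_len(n),
             base = NA_character_, chain = "I",
             charge = switch(species, "Na+" = 1, "K+" = 1, "Mg2+" = 2,
                             "Cl-" = -1, 0),
             resname = rn, stringsAsFactors = FALSE)
}

# trajectory of ions at fixed positions (n x 3 matrix), or moving
# (n x 3 x n_frames array)
ion_traj <- function(pos, n_frames = NULL, box = c(82, 82, 82), dt = 10,
                     species = "Na+") {
  if (length(dim(pos)) == 2L) {
    stopifnot(!is.null(n_frames))
    pos <- array(rep(as.numeric(pos), n_frames), c(nrow(pos), 3L, n_frames))
  }
  n <- dim(pos)[1]
  trajectory(topology(ION_DF(n, species)), pos, box, dt = dt,
             species = setNames(list(seq_len(n)), species))
}

# static duplex plus an ion trajectory, on a common time grid
duplex_system <- function(ions, form = "B-DNA", n_frames = ions$n_frames,
                          dt = ions$dt) {
  dup <- build_duplex(duplex_spec(form))
  merge_trajectories(static_trajectory(dup, n_frames, dt = dt, box = ions$box),
                     ions)
}

# --- independent oracles -------------------------------------------------

# minimum-image distance by explicit enumeration of the 27 periodic images
brute_min_image <- function(p, q, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  min(apply(shifts, 1, function(s) sqrt(sum((p - (q + s * box))^2))))
}

# signed dihedral by the projection formulation (independent of atan2 route)
cross_prod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
dihedral_oracle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  proj <- function(v) v - sum(v * b2) / sum(b2 * b2) * b2
  v1 <- proj(p1 - p2)
  v2 <- proj(p4 - p3)
  ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  s <- sign(sum(cross_prod(v1, v2) * b2))
  deg <- ang * 180 / pi * if (s == 0) 1 else s
  if (deg <= -180) deg + 360 else deg
}

# frame-by-frame occupancy by explicit loops
occupancy_oracle <- function(traj, site, idx, cutoff, frames) {
  vapply(frames, function(f) {
    any(vapply(site, function(s) {
      any(vapply(idx, function(i) {
        min_image_distance(traj$coords[s, , f], traj$coords[i, , f],
                           traj$box) < cutoff
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
}

# occupancy autocorrelation by explicit double summation, normalized by C(0)
autocorr_oracle <- function(p, lag_frames) {
  n <- length(p)
  vapply(lag_frames, function(l) {
    s <- 0
    for (t0 in seq_len(n - l)) s <- s + p[t0] * p[t0 + l]
    s / (n - l)
  }, 0) / mean(p)
}

rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
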