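# Stochastic ground-truth generators: telegraph (two-state Markov) binding,
# Brownian ion dynamics, ideal-gas ion clouds and hydration-shell point
# sets.  All generators consume a mandatory seed and a single RNG stream,
# so identical specs give bit-identical trajectories.

ion_atoms <- function(n, species) {
  rn <- species_resname(species)
  data.frame(name = rep(rn, n), element = rep(rn, n),
             residue = seq_len(n), base = NA_character_,
             chain = rep("I", n), charge = rep(unname(ION_CHARGES[species]), n),
             resname = rep(rn, n), stringsAsFactors = FALSE)
}

#' Telegraph (two-state binding) simulator specification
#'
#' Alternating exponential unbound/bound durations with rates `k_on` and
#' `k_off` (mean bound duration `1/k_off` ns); bound frames place the ion
#' with a Gaussian jitter about the site (truncated at the direct cutoff so
#' the ground-truth state and the distance criterion agree exactly), and
#' unbound frames place it uniformly in the box, outside the cutoff.
#'
#' @param k_on,k_off rates (1/ns); both > 0 (k_on = 0 allowed: never binds).
#' @param dt frame interval (ps), at most 10.
#' @param T trace length (ns); at least ~100/k_off recommended.
#' @param seed RNG seed (mandatory).
#' @param site site position (A), default the box center.
#' @param sigma bound-position jitter (A).
#' @param box cubic box edge (A).
#' @param species ion species label (sets the default cutoff).
#' @param cutoff guaranteed separation cutoff (A), default the species'
#'   direct cutoff.
#' @return list of class `TelegraphSpec`.
#' @export
telegraph_spec <- function(k_on, k_off, dt = 10, T = 100, seed,
                           site = NULL, sigma = 0.5, box = 82,
                           species = "Na+", cutoff = NULL) {
  stopifnot(k_on >= 0, k_off > 0, dt <= 10, dt > 0, T > 0)
  if (missing(seed)) stop("seed is mandatory")
  cutoff <- cutoff %||% default_cutoff(species)
  stopifnot(sigma < cutoff)
  structure(list(k_on = k_on, k_off = k_off, dt = dt, T = T, seed = seed,
                 site = site %||% rep(box / 2, 3), sigma = sigma, box = box,
                 species = species, cutoff = cutoff),
            class = "TelegraphSpec")
}

#' Simulate a telegraph binding trajectory
#'
#' @param spec a [telegraph_spec()].
#' @return list: `traj` (a 2-atom `Trajectory`: static `SITE` pseudo-atom
#'   plus one ion), `events` (data.frame `state`, `t_start`, `t_end`,
#'   `duration` in ps, last event truncated at `T`), `spec`.
#' @export
simulate_telegraph <- function(spec) {
  stopifnot(inherits(spec, "TelegraphSpec"))
  set.seed(spec$seed)
  T_ps <- spec$T * 1000
  kon_ps <- spec$k_on / 1000
  koff_ps <- spec$k_off / 1000
  t <- 0
  state <- 0L                      # start unbound
  st <- numeric(0); t0 <- numeric(0); t1 <- numeric(0)
  while (t < T_ps) {
    dur <- if (state == 0L) {
      if (kon_ps == 0) Inf else rexp(1, kon_ps)
    } else rexp(1, koff_ps)
    st <- c(st, state); t0 <- c(t0, t); t1 <- c(t1, min(t + dur, T_ps))
    t <- t + dur
    state <- 1L - state
  }
  events <- data.frame(state = st, t_start = t0, t_end = t1,
                       duration = t1 - t0)
  nf <- floor(T_ps / spec$dt) + 1L
  times <- (seq_len(nf) - 1L) * spec$dt
  p <- st[findInterval(times, t0)]
  nb <- sum(p == 1L)
  pos <- matrix(runif(3L * nf, 0, spec$box), nf, 3L)
  if (nb > 0) {
    jit <- matrix(rnorm(3L * nb, 0, spec$sigma), nb, 3L)
    bad <- sqrt(rowSums(jit^2)) >= 0.999 * spec$cutoff
    tries <- 0L
    while (any(bad)) {
      jit[bad, ] <- rnorm(3L * sum(bad), 0, spec$sigma)
      bad <- sqrt(rowSums(jit^2)) >= 0.999 * spec$cutoff
      tries <- tries + 1L
      if (tries > 1000L) stop("bound-position truncation failed")
    }
    pos[p == 1L, ] <- sweep(jit, 2, spec$site, "+")
  }
  if (any(p == 0L)) {
    ub <- which(p == 0L)
    d <- min_image_distance(pos[ub, , drop = FALSE],
                            matrix(spec$site, length(ub), 3, byrow = TRUE),
                            rep(spec$box, 3))
    bad <- which(d <= 1.001 * spec$cutoff)
    tries <- 0L
    while (length(bad)) {
      pos[ub[bad], ] <- runif(3L * length(bad), 0, spec$box)
      d <- min_image_distance(pos[ub[bad], , drop = FALSE],
                              matrix(spec$site, length(bad), 3, byrow = TRUE),
                              rep(spec$box, 3))
      bad <- bad[d <= 1.001 * spec$cutoff]
      tries <- tries + 1L
      if (tries > 1000L) stop("unbound-position rejection failed")
    }
  }
  site_atom <- data.frame(name = "SITE", element = "X", residue = 1L,
                          base = NA_character_, chain = "X", charge = 0,
                          resname = "SIT", stringsAsFactors = FALSE)
  top <- topology(rbind(site_atom, transform(ion_atoms(1L, spec$species),
                                             residue = 2L)))
  coords <- array(NA_real_, c(2L, 3L, nf))
  coords[1L, , ] <- spec$site
  coords[2L, , ] <- t(pos)
  traj <- trajectory(top, coords, rep(spec$box, 3), dt = spec$dt,
                     species = setNames(list(2L), spec$species))
  list(traj = traj, events = events, spec = spec)
}

#' Brownian ion dynamics specification
#'
#' Overdamped Euler-Maruyama steps (per-axis step s.d. `sqrt(2 D dt)`) with
#' periodic wrapping, optionally drifting in Gaussian attractive wells
#' (`U(r) = -depth * exp(-|r - pos|^2 / (2 width^2))` in kT units, drift
#' `-D grad(U) dt`).
#'
#' @param n number of ions.
#' @param D diffusion coefficient (A^2/ps), >= 0.
#' @param box cubic box edge (A).
#' @param dt step (ps).
#' @param T length (ns).
#' @param seed RNG seed (mandatory).
#' @param wells optional list of `list(pos, depth, width)` wells.
#' @param species ion species label.
#' @return list of class `BrownianSpec`.
#' @export
brownian_spec <- function(n = 1, D = 0.1, box = 82, dt = 1, T = 1, seed,
                          wells = NULL, species = "Na+") {
  stopifnot(n >= 1, D >= 0, dt > 0, T > 0)
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(wells)) {
    for (w in wells) stopifnot(w$width > 0)
  }
  structure(list(n = n, D = D, box = box, dt = dt, T = T, seed = seed,
                 wells = wells, species = species),
            class = "BrownianSpec")
}

#' Simulate Brownian ions
#'
#' @param spec a [brownian_spec()].
#' @return a `Trajectory` of `n` ions.
#' @export
simulate_brownian <- function(spec) {
  stopifnot(inherits(spec, "BrownianSpec"))
  sigma <- sqrt(2 * spec$D * spec$dt)
  if (sigma > spec$box / 4) {
    stop("step sigma (", signif(sigma, 3), " A) exceeds box/4; reduce dt or D")
  }
  set.seed(spec$seed)
  nf <- floor(spec$T * 1000 / spec$dt) + 1L
  n <- spec$n
  x0 <- matrix(runif(3L * n, 0, spec$box), n, 3L)
  coords <- array(NA_real_, c(n, 3L, nf))
  if (is.null(spec$wells)) {
    for (k in seq_len(n)) {
      steps <- matrix(rnorm(3L * (nf - 1L), 0, sigma), nf - 1L, 3L)
      x <- rbind(x0[k, ], sweep(apply(steps, 2, cumsum), 2, x0[k, ], "+"))
      coords[k, , ] <- t(x %% spec$box)
    }
  } else {
    x <- x0
    coords[, , 1L] <- x
    for (f in 2L:nf) {
      drift <- matrix(0, n, 3L)
      for (w in spec$wells) {
        d <- sweep(x, 2, w$pos)
        d <- min_image_disp(d, rep(spec$box, 3))
        d <- as_coord_matrix(d)
        e <- exp(-rowSums(d^2) / (2 * w$width^2))
        drift <- drift - spec$D * spec$dt * w$depth / w$width^2 * d * e
      }
      x <- (x + drift + matrix(rnorm(3L * n, 0, sigma), n, 3L)) %% spec$box
      coords[, , f] <- x
    }
  }
  trajectory(topology(ion_atoms(n, spec$species)), coords,
             rep(spec$box, 3), dt = spec$dt,
             species = setNames(list(seq_len(n)), spec$species))
}

#' Ideal-gas ion cloud
#'
#' Ions redrawn uniformly in the box at every frame (spatially uncorrelated
#' control for distribution estimators).
#'
#' @param n number of ions.
#' @param n_frames number of frames.
#' @param species species label.
#' @param box cubic box edge (A).
#' @param dt frame interval (ps).
#' @param seed RNG seed (mandatory).
#' @return a `Trajectory` of `n` ions.
#' @export
simulate_ion_gas <- function(n, n_frames, species = "Na+", box = 82, dt = 10,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  coords <- array(runif(3L * n * n_frames, 0, box), c(n, 3L, n_frames))
  trajectory(topology(ion_atoms(n, species)), coords, rep(box, 3), dt = dt,
             species = setNames(list(seq_len(n)), species))
}

#' Sample a hydration shell around a central ion
#'
#' `n_shell` first-shell "water oxygens" at radii `Gaussian(d0, sigma)` with
#' uniform angular placement (pairwise overlaps below 2 A rejected), plus
#' uniform bulk points outside `1.5 * d0`.
#'
#' @param n_shell first-shell point count (>= 0).
#' @param d0 mean first-shell distance (A), > 0 (2.43 A emulates the
#'   Na+-water first shell).
#' @param sigma radial spread (A).
#' @param rho_bulk bulk number density (1/A^3).
#' @param box cubic box edge (A); the ion sits at the center.
#' @param seed RNG seed, or `NULL` to continue the current stream.
#' @return list: `center` (ion position), `points` (m x 3 matrix),
#'   `n_shell`, `n_bulk`.
#' @export
generate_hydration_shell <- function(n_shell = 6, d0 = 2.43, sigma = 0.05,
                                     rho_bulk = 0, box = 20, seed = NULL) {
  stopifnot(d0 > 0, n_shell >= 0, rho_bulk >= 0)
  if (!is.null(seed)) set.seed(seed)
  center <- rep(box / 2, 3)
  shell <- matrix(numeric(0), 0, 3)
  if (n_shell > 0) {
    for (attempt in 1:500) {
      r <- rnorm(n_shell, d0, sigma)
      u <- matrix(rnorm(3L * n_shell), n_shell, 3L)
      u <- u / sqrt(rowSums(u^2))
      shell <- u * r
      ok <- n_shell == 1L || min(dist(shell)) >= 2
      if (ok && all(r > 0)) break
      if (attempt == 500) stop("hydration-shell overlap rejection failed")
    }
    shell <- sweep(shell, 2, center, "+")
  }
  n_bulk <- round(rho_bulk * box^3)
  bulk <- matrix(numeric(0), 0, 3)
  if (n_bulk > 0) {
    bulk <- matrix(runif(3L * n_bulk, 0, box), n_bulk, 3L)
    d <- min_image_distance(bulk, matrix(center, n_bulk, 3, byrow = TRUE),
                            rep(box, 3))
    bad <- which(d < 1.5 * d0)
    tries <- 0L
    while (length(bad)) {
      bulk[bad, ] <- runif(3L * length(bad), 0, box)
      d <- min_image_distance(bulk[bad, , drop = FALSE],
                              matrix(center, length(bad), 3, byrow = TRUE),
                              rep(box, 3))
      bad <- bad[d < 1.5 * d0]
      tries <- tries + 1L
      if (tries > 1000L) stop("bulk-point rejection failed")
    }
  }
  list(center = center, points = rbind(shell, bulk),
       n_shell = n_shell, n_bulk = n_bulk)
}

#' Repeated hydration-shell samples as a trajectory
#'
#' Stacks independent [generate_hydration_shell()] draws as frames of a
#' trajectory (central ion static, waters resampled), ready for
#' [compute_rdf()] / [coordination_number()].
#'
#' @param n_frames number of independent shell samples.
#' @param ion_species central ion label (default `"Mg2+"`).
#' @param seed RNG seed (mandatory).
#' @inheritParams generate_hydration_shell
#' @return a `Trajectory`: atom 1 the central ion, the rest `WAT-O`.
#' @export
hydration_trajectory <- function(n_frames, n_shell = 6, d0 = 2.43,
                                 sigma = 0.05, rho_bulk = 0, box = 20,
                                 ion_species = "Mg2+", seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  first <- generate_hydration_shell(n_shell, d0, sigma, rho_bulk, box)
  m <- nrow(first$points)
  coords <- array(NA_real_, c(1L + m, 3L, n_frames))
  coords[1L, , ] <- first$center
  coords[-1L, , 1L] <- first$points
  if (n_frames > 1L) {
    for (f in 2L:n_frames) {
      g <- generate_hydration_shell(n_shell, d0, sigma, rho_bulk, box)
      coords[-1L, , f] <- g$points
    }
  }
  wat <- data.frame(name = rep("O", m), element = rep("O", m),
                    residue = 1L + seq_len(m), base = NA_character_,
                    chain = rep("W", m), charge = 0,
                    resname = rep("HOH", m), stringsAsFactors = FALSE)
  top <- topology(rbind(ion_atoms(1L, ion_species), wat))
  trajectory(top, coords, rep(box, 3), dt = 10,
             species = setNames(list(1L + seq_len(m), 1L),
                                c("WAT-O", ion_species)))
}
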