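# Trajectory container: topology + time-ordered frames + periodic box +
# species map (label -> atom indices).

# residue-name synonyms for ion/water species labelling
SPECIES_RESNAMES <- list(
  "Na+"   = c("NA", "NA+", "SOD"),
  "K+"    = c("K", "K+", "POT"),
  "Mg2+"  = c("MG", "MG2", "MG2+"),
  "Cl-"   = c("CL", "CL-", "CLA"),
  "WAT-O" = c("HOH", "WAT", "TIP3", "SPC")
)

infer_species_map <- function(top) {
  a <- top$atoms
  rn <- toupper(a$resname %||% "")
  sp <- list()
  for (label in names(SPECIES_RESNAMES)) {
    idx <- which(rn %in% SPECIES_RESNAMES[[label]])
    if (label == "WAT-O") idx <- idx[a$element[idx] == "O"]
    if (length(idx)) sp[[label]] <- idx
  }
  sp
}

#' Construct a trajectory
#'
#' @param top a [topology()].
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames` (A).
#' @param box length-3 vector of orthorhombic box edges (A).
#' @param dt sampling interval (ps); ignored when `times` is given.
#' @param times optional vector of frame times (ps), strictly increasing and
#'   uniformly spaced within tolerance.
#' @param species optional named list mapping species labels (e.g. `"Na+"`)
#'   to atom index vectors; inferred from residue names when omitted.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(top, coords, box, dt = 1, times = NULL, species = NULL) {
  stopifnot(inherits(top, "Topology"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != top$n_atoms) {
    stop("coordinate count (", dim(coords)[1], ") does not match topology atom count (",
         top$n_atoms, ")")
  }
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive edge lengths")
  }
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf) stop("times must have one entry per frame")
  if (nf > 1L) {
    d <- diff(times)
    if (any(d <= 0)) stop("frame times must be strictly increasing")
    if (max(d) - min(d) > 1e-6 * max(d)) stop("frame times must be uniformly spaced")
    dt <- d[1]
  }
  if (is.null(species)) species <- infer_species_map(top)
  structure(list(
    topology = top, coords = coords, box = as.numeric(box),
    times = as.numeric(times), dt = dt, n_frames = nf, species = species
  ), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("<Trajectory> ", x$topology$n_atoms, " atoms x ", x$n_frames,
      " frames, dt = ", x$dt, " ps, box = [",
      paste(signif(x$box, 4), collapse = ", "), "] A\n", sep = "")
  if (length(x$species)) {
    cat("  species:", paste(sprintf("%s (%d)", names(x$species),
                                    lengths(x$species)), collapse = ", "), "\n")
  }
  invisible(x)
}

frame_coords <- function(traj, f) traj$coords[, , f, drop = FALSE][, , 1]

species_indices <- function(traj, species) {
  idx <- traj$species[[species]]
  if (is.null(idx) || !length(idx)) stop("no atoms for species '", species, "'")
  idx
}

# frame indices whose times fall in window = c(t_start, t_end) (ps, closed)
window_frames <- function(traj, window = NULL) {
  if (is.null(window)) return(seq_len(traj$n_frames))
  stopifnot(length(window) == 2L, window[1] <= window[2])
  f <- which(traj$times >= window[1] & traj$times <= window[2])
  if (!length(f)) {
    stop("window [", window[1], ", ", window[2], "] ps contains no frames")
  }
  f
}

# default data-collection window: discard the leading 1/6 of the trajectory
# (analysis restricted to the equilibrated tail, as for 120 ns runs where the
# last 100 ns are analysed)
collection_window <- function(traj, discard_frac = 1 / 6) {
  t0 <- traj$times[1]
  t1 <- traj$times[traj$n_frames]
  c(t0 + (t1 - t0) * discard_frac, t1)
}

# min-image distances between atoms `ia` (length A) and `ib` (length B) for
# the given frames; returns array A x B x F
pair_distance_array <- function(traj, ia, ib, frames) {
  out <- array(NA_real_, c(length(ia), length(ib), length(frames)))
  for (j in seq_along(ib)) {
    qb <- t(traj$coords[ib[j], , frames, drop = FALSE][1, , ])
    for (i in seq_along(ia)) {
      qa <- t(traj$coords[ia[i], , frames, drop = FALSE][1, , ])
      out[i, j, ] <- min_image_distance(qa, qb, traj$box)
    }
  }
  out
}

#' Merge two trajectories sharing box and time grid
#'
#' Concatenates the atom dimension (e.g. a static duplex plus a simulated
#' ion cloud); species maps are re-indexed.
#'
#' @param a,b `Trajectory` objects with identical frame times and box.
#' @return merged `Trajectory`.
#' @export
merge_trajectories <- function(a, b) {
  stopifnot(inherits(a, "Trajectory"), inherits(b, "Trajectory"))
  if (a$n_frames != b$n_frames || max(abs(a$times - b$times)) > 1e-9) {
    stop("trajectories must share the same frame times")
  }
  if (max(abs(a$box - b$box)) > 1e-9) stop("trajectories must share the same box")
  atoms <- rbind(a$topology$atoms, b$topology$atoms)
  atoms$residue <- c(a$topology$atoms$residue,
                     b$topology$atoms$residue + max(a$topology$atoms$residue, 0))
  top <- topology(atoms, pairing = a$topology$pairing %||% b$topology$pairing)
  coords <- array(NA_real_, c(nrow(atoms), 3L, a$n_frames))
  coords[seq_len(a$topology$n_atoms), , ] <- a$coords
  coords[a$topology$n_atoms + seq_len(b$topology$n_atoms), , ] <- b$coords
  species <- a$species
  for (s in names(b$species)) {
    species[[s]] <- c(species[[s]], b$species[[s]] + a$topology$n_atoms)
  }
  trajectory(top, coords, a$box, dt = a$dt, times = a$times, species = species)
}

#' Repeat a static structure as a trajectory
#'
#' @param dup result of [build_duplex()] (or any list with `topology`,
#'   `coords`, `box`).
#' @param n_frames number of identical frames.
#' @param dt sampling interval (ps).
#' @param box optional box override (A).
#' @return `Trajectory` with `n_frames` copies of the structure.
#' @export
static_trajectory <- function(dup, n_frames = 1, dt = 10, box = NULL) {
  box <- rep(box %||% dup$box, length.out = 3L)
  coords <- array(rep(as.numeric(dup$coords), n_frames),
                  c(nrow(dup$coords), 3L, n_frames))
  trajectory(dup$topology, coords, box, dt = dt)
}
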