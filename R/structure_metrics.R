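# Per-residue conformational descriptors: glycosidic angle chi with
# anti/syn classification, and sugar pucker by pseudorotation
# (phase/amplitude from the five endocyclic torsions).

PUCKER_CLASSES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                    "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

#' Classify a glycosidic angle
#'
#' Default bands: anti for chi in (-180, -90] or (90, 180], syn for chi in
#' (-90, 90], with an `intermediate` band of +/- `band` degrees around the
#' +/-90 boundaries.
#'
#' @param chi angle(s) in degrees, (-180, 180].
#' @param band half-width of the intermediate band (degrees).
#' @return character vector: `"anti"`, `"syn"` or `"intermediate"`.
#' @export
chi_class <- function(chi, band = 10) {
  out <- ifelse(abs(chi) > 90, "anti", "syn")
  out[abs(abs(chi) - 90) <= band] <- "intermediate"
  out
}

#' Classify a pseudorotation phase
#'
#' 36-degree sectors of P starting at 0 (C3'-endo).
#'
#' @param P phase(s) in degrees, `[0, 360)`.
#' @return character vector of conformer names.
#' @export
pucker_class <- function(P) {
  PUCKER_CLASSES[(floor((P %% 360) / 36) %% 10) + 1L]
}

residue_atom <- function(coords, top, res, name) {
  sel <- which(top$atoms$residue == res & top$atoms$name == normalize_atom_name(name))
  if (!length(sel)) {
    stop("residue ", res, ": missing atom ", name)
  }
  coords[sel[1], ]
}

#' Glycosidic torsion angle and rotamer class of a residue
#'
#' chi is O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines.
#'
#' @param coords n_atoms x 3 coordinate matrix of one frame (A).
#' @param top a [topology()].
#' @param residue global residue index.
#' @param band intermediate band for [chi_class()].
#' @return list with `chi` (degrees) and `class`.
#' @export
glycosidic_angle <- function(coords, top, residue, band = 10) {
  coords <- as_coord_matrix(coords)
  base <- top$atoms$base[top$atoms$residue == residue][1]
  if (is.na(base)) stop("residue ", residue, " is not a nucleotide")
  purine <- base %in% c("A", "G")
  at <- function(n) residue_atom(coords, top, residue, n)
  chi <- if (purine) {
    dihedral(at("O4'"), at("C1'"), at("N9"), at("C4"))
  } else {
    dihedral(at("O4'"), at("C1'"), at("N1"), at("C2"))
  }
  list(chi = chi, class = chi_class(chi, band))
}

# the five endocyclic torsions nu0..nu4 of a furanose ring, in degrees
ring_torsions <- function(ring) {
  # ring: 5 x 3 matrix in order C1', C2', C3', C4', O4'
  g <- function(i1, i2, i3, i4) dihedral(ring[i1, ], ring[i2, ], ring[i3, ], ring[i4, ])
  c(nu0 = g(4, 5, 1, 2),  # C4'-O4'-C1'-C2'
    nu1 = g(5, 1, 2, 3),  # O4'-C1'-C2'-C3'
    nu2 = g(1, 2, 3, 4),  # C1'-C2'-C3'-C4'
    nu3 = g(2, 3, 4, 5),  # C2'-C3'-C4'-O4'
    nu4 = g(3, 4, 5, 1))  # C3'-C4'-O4'-C1'
}

pseudorotation <- function(nu) {
  den <- 2 * nu[["nu2"]] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  num <- (nu[["nu4"]] + nu[["nu1"]]) - (nu[["nu3"]] + nu[["nu0"]])
  P <- rad2deg(atan2(num, den)) %% 360
  tau_m <- nu[["nu2"]] / cos(deg2rad(P))
  if (tau_m < 0) { # numerical guard; amplitude is nonnegative by convention
    P <- (P + 180) %% 360
    tau_m <- -tau_m
  }
  c(P = P, tau_m = tau_m)
}

#' Sugar pucker pseudorotation of a residue
#'
#' Phase P and amplitude from the standard linear combination of the five
#' endocyclic torsions; conformer class by 36-degree sector.  A flat ring
#' (amplitude < 1 degree) yields an undefined class flag.
#'
#' @param coords n_atoms x 3 coordinate matrix of one frame (A).
#' @param top a [topology()].
#' @param residue global residue index.
#' @return list of class `PuckerResult`: `P` (deg, `[0,360)`), `amplitude`
#'   (deg), `class`, logical `undefined`.
#' @export
sugar_pucker <- function(coords, top, residue) {
  coords <- as_coord_matrix(coords)
  at <- function(n) residue_atom(coords, top, residue, n)
  ring <- rbind(at("C1'"), at("C2'"), at("C3'"), at("C4'"), at("O4'"))
  res <- try(ring_torsions(ring), silent = TRUE)
  if (inherits(res, "try-error")) {
    return(structure(list(P = NA_real_, amplitude = 0, class = NA_character_,
                          undefined = TRUE), class = "PuckerResult"))
  }
  pr <- pseudorotation(res)
  undef <- pr[["tau_m"]] < 1
  structure(list(P = pr[["P"]], amplitude = pr[["tau_m"]],
                 class = if (undef) NA_character_ else pucker_class(pr[["P"]]),
                 undefined = undef), class = "PuckerResult")
}

#' Generate furanose ring coordinates from a target pucker
#'
#' Inverse of [sugar_pucker()]: builds a closed 5-ring whose estimated
#' pseudorotation phase and amplitude match the targets (numerically, to
#' well under 0.5 degrees).  The ring is produced as out-of-plane
#' displacements of a regular pentagon, with the two puckering degrees of
#' freedom solved against the pseudorotation estimator itself.
#'
#' @param P target phase (degrees).
#' @param tau_m target amplitude (degrees); must be > 0.
#' @param bond pentagon edge length (A).
#' @return 5 x 3 matrix in ring order C1', C2', C3', C4', O4'.
#' @export
ring_from_pucker <- function(P, tau_m, bond = 1.52) {
  stopifnot(tau_m > 0)
  R <- bond / (2 * sin(pi / 5))
  gen <- function(q, phi) {
    j <- 0:4
    ang <- 2 * pi * j / 5
    cbind(R * cos(ang), R * sin(ang),
          sqrt(2 / 5) * q * cos(deg2rad(phi) + 4 * pi * j / 5))
  }
  est <- function(q, phi) pseudorotation(ring_torsions(gen(q, phi)))
  q <- tau_m / 102.5
  phi <- P
  e0 <- est(q, phi)
  phi <- phi + (P - e0[["P"]])
  for (it in 1:50) {
    e <- est(q, phi)
    dP <- ((P - e[["P"]] + 180) %% 360) - 180
    phi <- phi + dP
    q <- q * tau_m / e[["tau_m"]]
    if (abs(dP) < 1e-8 && abs(e[["tau_m"]] - tau_m) < 1e-8) break
  }
  gen(q, phi)
}

#' Per-frame, per-residue conformational table
#'
#' @param traj a `Trajectory` with a duplex.
#' @param frames frame indices (default all).
#' @return data.frame: `frame`, `residue`, `base`, `chain`, `chi`,
#'   `chi_class`, `P`, `amplitude`, `pucker_class`.
#' @export
structure_table <- function(traj, frames = NULL) {
  frames <- frames %||% seq_len(traj$n_frames)
  a <- traj$topology$atoms
  res <- sort(unique(a$residue[!is.na(a$base)]))
  rows <- list()
  for (f in frames) {
    xyz <- frame_coords(traj, f)
    for (r in res) {
      g <- glycosidic_angle(xyz, traj$topology, r)
      pk <- sugar_pucker(xyz, traj$topology, r)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, residue = r,
        base = a$base[a$residue == r][1],
        chain = a$chain[a$residue == r][1],
        chi = g$chi, chi_class = g$class,
        P = pk$P, amplitude = pk$amplitude, pucker_class = pk$class %||% NA,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
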