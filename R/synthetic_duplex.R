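# Idealized (CG)n duplex builder.
#
# Templates are idealized, not crystallographic: correct topology,
# handedness, sugar-pucker and glycosidic classes and approximate groove
# geometry are guaranteed; sub-angstrom atomic accuracy is not.  Bases are
# built as fused regular polygons, sugars from the pseudorotation target,
# and backbone atoms by internal-coordinate placement.  Each Watson-Crick
# pair is assembled in a local frame whose origin is the pair's axis
# reference center, then propagated along z by per-step rise and twist, so
# an unbent build has its helical axis exactly on the global z-axis.

# planar base template: heavy atoms, glycosidic N at origin, reference atom
# (purine C4 / pyrimidine C2) on +x, ring plane z = 0
make_base_template <- function(base) {
  hex_s <- 1.39
  rot2 <- function(xy, th) {
    cbind(cos(th) * xy[, 1] - sin(th) * xy[, 2],
          sin(th) * xy[, 1] + cos(th) * xy[, 2])
  }
  hex <- cbind(hex_s * cos(2 * pi * (0:5) / 6), hex_s * sin(2 * pi * (0:5) / 6))
  rownames(hex) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  exo <- function(xy, at, len) xy[at, ] * (1 + len / sqrt(sum(xy[at, ]^2)))
  if (base == "G") {
    # fuse a regular pentagon on the C4-C5 edge, outside the hexagon
    s5 <- sqrt(sum((hex["C4", ] - hex["C5", ])^2))
    mid <- (hex["C4", ] + hex["C5", ]) / 2
    a5 <- s5 / (2 * tan(pi / 5))
    out_dir <- mid / sqrt(sum(mid^2))
    ctr5 <- mid + a5 * out_dir
    rot_about <- function(p, th) ctr5 + drop(rot2(rbind(p - ctr5), th))
    step <- 2 * pi / 5
    cand <- rot_about(hex["C4", ], step)
    if (sqrt(sum((cand - hex["C5", ])^2)) > 1e-6) step <- -step
    pent <- rbind(N7 = rot_about(hex["C4", ], 2 * step),
                  C8 = rot_about(hex["C4", ], 3 * step),
                  N9 = rot_about(hex["C4", ], 4 * step))
    xy <- rbind(hex, pent,
                O6 = exo(hex, "C6", 1.23),
                N2 = exo(hex, "C2", 1.34))
    n_at <- "N9"; ref <- "C4"; ref2 <- "C5"
  } else if (base == "C") {
    xy <- rbind(hex,
                O2 = exo(hex, "C2", 1.24),
                N4 = exo(hex, "C4", 1.34))
    n_at <- "N1"; ref <- "C2"; ref2 <- "N3"
  } else {
    stop("base templates limited to C and G")
  }
  xy <- sweep(xy, 2, xy[n_at, ])
  th <- -atan2(xy[ref, 2], xy[ref, 1])
  xy <- rot2(xy, th)
  list(names = rownames(xy), xyz = cbind(xy, 0),
       n_at = n_at, ref = ref, ref2 = ref2)
}

# side of the ring mean plane a point falls on (+1/-1)
ring_side <- function(ring, p) {
  ctr <- colMeans(ring)
  s <- svd(sweep(ring, 2, ctr))
  sign(sum((p - ctr) * s$v[, 3]))
}

# substituent placement with a choice of +/-120 deg face, matched to (or
# away from) a reference point's side of the ring plane
place_face <- function(a, b, c, r, theta, phi0, ring, ref_point, same_side) {
  p1 <- place_atom(a, b, c, r, theta, phi0 + 120)
  p2 <- place_atom(a, b, c, r, theta, phi0 - 120)
  sref <- ring_side(ring, ref_point)
  if ((ring_side(ring, p1) == sref) == same_side) p1 else p2
}

# full heavy-atom nucleotide in a local frame
build_nucleotide <- function(base, P, tau_m, chi, rna) {
  ring <- ring_from_pucker(P, tau_m)
  rownames(ring) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  nu <- ring_torsions(ring)
  C1p <- ring["C1'", ]; C2p <- ring["C2'", ]; C3p <- ring["C3'", ]
  C4p <- ring["C4'", ]; O4p <- ring["O4'", ]
  n_pos <- place_atom(C4p, O4p, C1p, 1.47, 108, nu[["nu0"]] + 120)
  c5p <- place_face(C2p, C3p, C4p, 1.51, 110, nu[["nu3"]], ring, n_pos, TRUE)
  o3p <- place_face(C1p, C2p, C3p, 1.42, 110, nu[["nu2"]], ring, n_pos, FALSE)
  o5p <- place_atom(C3p, C4p, c5p, 1.44, 110, 54)
  p_at <- place_atom(C4p, c5p, o5p, 1.60, 120, 180)
  op1 <- place_atom(c5p, o5p, p_at, 1.48, 108, 60)
  op2 <- place_atom(c5p, o5p, p_at, 1.48, 108, 180)
  tpl <- make_base_template(base)
  i_ref2 <- match(tpl$ref2, tpl$names)
  i_ref <- match(tpl$ref, tpl$names)
  d_ref <- sqrt(sum(tpl$xyz[i_ref, ]^2))   # template N-ref bond length
  ref_pos <- place_atom(O4p, C1p, n_pos, d_ref, 126, chi)
  v1 <- tpl$xyz[i_ref2, ] - tpl$xyz[i_ref, ]
  r22 <- sqrt(sum(v1^2))
  ang <- rad2deg(acos(sum(-tpl$xyz[i_ref, ] * v1) / d_ref / r22))
  ref2_pos <- place_atom(C1p, n_pos, ref_pos, r22, ang, 180)
  i_n <- match(tpl$n_at, tpl$names)
  fitfun <- rigid_fit(tpl$xyz[c(i_n, i_ref, i_ref2), ],
                      rbind(n_pos, ref_pos, ref2_pos))
  base_xyz <- fitfun(tpl$xyz)
  names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
             "C2'", if (rna) "O2'", "C1'", tpl$names)
  xyz <- rbind(p_at, op1, op2, o5p, c5p, C4p, O4p, C3p, o3p, C2p,
               if (rna) place_face(O4p, C1p, C2p, 1.41, 110, nu[["nu1"]],
                                   ring, n_pos, FALSE),
               C1p, base_xyz)
  rownames(xyz) <- NULL
  list(names = names, xyz = xyz, glyco_n = tpl$n_at)
}

# per-form template parameters; Z forms: syn-G / anti-C, C3'-endo G /
# C2'-endo C, alternating negative twist (left-handed)
FORM_DEFAULTS <- list(
  "B-DNA" = list(twist = 36,  rise = 3.38, rna = FALSE,
                 G = list(P = 162, chi = -112), C = list(P = 162, chi = -112)),
  "A-RNA" = list(twist = 32.7, rise = 2.81, rna = TRUE,
                 G = list(P = 18, chi = -160), C = list(P = 18, chi = -160)),
  "Z-DNA" = list(twist = c(-9, -51), rise = 3.7, rna = FALSE,
                 G = list(P = 18, chi = 60), C = list(P = 162, chi = -150)),
  "Z-RNA" = list(twist = c(-9, -51), rise = 3.7, rna = TRUE,
                 G = list(P = 18, chi = 60), C = list(P = 162, chi = -150))
)

#' Specification for an idealized duplex build
#'
#' @param form one of `"B-DNA"`, `"A-RNA"`, `"Z-DNA"`, `"Z-RNA"`.
#' @param sequence strand-1 sequence 5'->3', alternating C/G letters, even
#'   length; default the (CG)6 dodecamer.
#' @param rise per-step rise (A); form default when `NULL` (B 3.38, A 2.81,
#'   Z 3.7).
#' @param twist per-step twist (degrees); one value, or two alternating
#'   values for the Z forms (defaults B +36, A +32.7, Z -9/-51).
#' @param displacement x-displacement of the pair from the axis (A).
#' @param tau_m sugar pucker amplitude (degrees).
#' @param box cubic box edge (A) recorded with the build.
#' @return list of class `DuplexSpec`.
#' @export
duplex_spec <- function(form = c("B-DNA", "A-RNA", "Z-DNA", "Z-RNA"),
                        sequence = "CGCGCGCGCGCG", rise = NULL, twist = NULL,
                        displacement = 0, tau_m = 38, box = 82) {
  form <- match.arg(form)
  def <- FORM_DEFAULTS[[form]]
  structure(list(form = form, sequence = toupper(sequence),
                 rise = rise %||% def$rise, twist = twist %||% def$twist,
                 displacement = displacement, tau_m = tau_m, box = box,
                 rna = def$rna, params = def[c("G", "C")]),
            class = "DuplexSpec")
}

build_pair_template <- function(base1, spec) {
  comp <- c(G = "C", C = "G")
  lambda <- deg2rad(54.5)
  c1_t <- c(-5.25, 0, 0)
  n_t <- c1_t + 1.47 * c(cos(lambda), sin(lambda), 0)
  # in-plane base-reference direction, pointing toward the pair center
  back <- atan2(c1_t[2] - n_t[2], c1_t[1] - n_t[1])
  cand <- c(back + deg2rad(126), back - deg2rad(126))
  ra <- cand[which.max(cos(cand))]
  place_nt <- function(base) {
    pp <- spec$params[[base]]
    nt <- build_nucleotide(base, pp$P, spec$tau_m, pp$chi, spec$rna)
    i_c1 <- match("C1'", nt$names)
    i_n <- match(nt$glyco_n, nt$names)
    tplb <- make_base_template(base)
    i_ref <- match(tplb$ref, tplb$names) # index within base block
    base_off <- length(nt$names) - length(tplb$names)
    src <- nt$xyz[c(i_c1, i_n, base_off + i_ref), ]
    d_nr <- sqrt(sum((src[3, ] - src[2, ])^2))  # built N-ref bond
    ref_t <- n_t + d_nr * c(cos(ra), sin(ra), 0)
    nt$xyz <- rigid_fit(src, rbind(c1_t, n_t, ref_t))(nt$xyz)
    nt
  }
  nt1 <- place_nt(base1)
  nt2 <- place_nt(comp[[base1]])
  # antiparallel partner: two-fold rotation about the in-plane y axis
  nt2$xyz <- nt2$xyz %*% diag(c(-1, 1, -1))
  # center each pair on the glycosidic (C1' + N9/N1) reference midpoint:
  # this convention is symmetric under the pair dyad, so an unbent build
  # has collinear pair centers and base-independent backbone radii
  ref_center <- function(nt) {
    (nt$xyz[match("C1'", nt$names), ] +
       nt$xyz[match(nt$glyco_n, nt$names), ]) / 2
  }
  ctr <- (ref_center(nt1) + ref_center(nt2)) / 2
  nt1$xyz <- sweep(nt1$xyz, 2, ctr)
  nt2$xyz <- sweep(nt2$xyz, 2, ctr)
  list(nt1 = nt1, nt2 = nt2, base1 = base1, base2 = comp[[base1]])
}

#' Build an idealized duplex
#'
#' Constructs the full heavy-atom duplex (backbone P/OP1/OP2/O5'/C5'/C4'/
#' O4'/C3'/O3'/C2'/C1', plus O2' for RNA, plus the groove atoms of the C
#' and G bases), with antiparallel Watson-Crick pairing, -1e formal charge
#' per phosphate, and 5'-terminal residues lacking the phosphate group (a
#' 12-bp duplex thus has 22 phosphates and net charge -22e).
#'
#' @param spec a [duplex_spec()] (a bare form string is also accepted).
#' @return list of class `Duplex`: `topology`, `coords` (n x 3, A), `box`,
#'   `form`, `spec`.
#' @export
build_duplex <- function(spec = duplex_spec()) {
  if (is.character(spec)) spec <- duplex_spec(spec)
  seqc <- strsplit(spec$sequence, "")[[1]]
  n <- length(seqc)
  if (n < 2L || n %% 2L != 0L) stop("sequence must have even length >= 2")
  if (!all(seqc %in% c("C", "G"))) {
    stop("templates limited to C/G sequences; got: ", spec$sequence)
  }
  if (any(seqc[-1] == seqc[-n])) {
    stop("sequence must alternate C and G")
  }
  tpls <- list(G = build_pair_template("G", spec),
               C = build_pair_template("C", spec))
  steps <- rep(spec$twist, length.out = n - 1L)
  theta <- c(0, cumsum(steps))
  zoff <- (seq_len(n) - 1L) * spec$rise
  zoff <- zoff - mean(zoff)   # center the duplex at the origin
  res1 <- vector("list", n)
  res2 <- vector("list", n)
  for (k in seq_len(n)) {
    tpl <- tpls[[seqc[k]]]
    R <- rot_z(theta[k])
    move <- function(x) {
      sweep(sweep(x, 2, c(spec$displacement, 0, 0), "+") %*% t(R),
            2, c(0, 0, zoff[k]), "+")
    }
    res1[[k]] <- list(names = tpl$nt1$names, xyz = move(tpl$nt1$xyz),
                      base = tpl$base1)
    res2[[k]] <- list(names = tpl$nt2$names, xyz = move(tpl$nt2$xyz),
                      base = tpl$base2)
  }
  rows <- list()
  add_res <- function(nt, chain, chain_res, global_res, drop_phos) {
    keep <- if (drop_phos) !(nt$names %in% c("P", "OP1", "OP2")) else
      rep(TRUE, length(nt$names))
    nm <- nt$names[keep]
    data.frame(name = nm,
               element = substr(nm, 1, 1),
               residue = global_res, base = nt$base, chain = chain,
               charge = ifelse(nm == "P", -1, 0),
               resname = base_resname(nt$base, spec$rna),
               x = nt$xyz[keep, 1], y = nt$xyz[keep, 2], z = nt$xyz[keep, 3],
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(n)) {  # chain A: strand 1, residue k = pair k
    rows[[length(rows) + 1L]] <- add_res(res1[[k]], "A", k, k, k == 1L)
  }
  for (j in seq_len(n)) {  # chain B residue j sits at pair n + 1 - j
    rows[[length(rows) + 1L]] <- add_res(res2[[n + 1L - j]], "B", j, n + j,
                                         j == 1L)
  }
  atoms <- do.call(rbind, rows)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(coords) <- NULL
  top <- topology(atoms[, c("name", "element", "residue", "base", "chain",
                            "charge", "resname")],
                  pairing = data.frame(res1 = seq_len(n),
                                       res2 = n + rev(seq_len(n))))
  structure(list(topology = top, coords = coords, box = spec$box,
                 form = spec$form, spec = spec),
            class = "Duplex")
}

#' @export
print.Duplex <- function(x, ...) {
  cat("<Duplex> ", x$form, " ", x$spec$sequence, " (",
      x$topology$n_atoms, " atoms, net charge ",
      x$topology$net_charge, "e)\n", sep = "")
  invisible(x)
}
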