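# Topology: the atom table of a solvated duplex system, formal charges,
# Watson-Crick pairing map and the groove/backbone region vocabulary.

NUC_BASES <- c("A", "C", "G", "U", "T")

# Region convention for the CG duplex (identical for right- and left-handed
# forms): cytosine O2/N1 and guanine N2/N3/N9 line the minor groove; cytosine
# N4 and guanine O6/N7 line the major groove.  OP1/OP2 are the anionic
# phosphate oxygens; O5'/O4'/O3' (plus O2' in RNA) are the O' oxygens.
REGION_MAJOR <- list(G = c("O6", "N7"), C = c("N4"))
REGION_MINOR <- list(G = c("N2", "N3", "N9"), C = c("O2", "N1"))
REGION_OPRIME <- c("O5'", "O4'", "O3'", "O2'")
REGION_PHOSPHATE <- c("OP1", "OP2")
REGION_LEVELS <- c("major", "minor", "backbone_Oprime", "phosphate", "other")

#' Normalize a PDB atom name
#'
#' Accepts primed (`O5'`), typographic-prime (`O5′`) and starred (`O5*`)
#' spellings, plus the legacy `O1P`/`O2P` phosphate names, and maps them to
#' the PDBv3 convention used internally (`O5'`, `OP1`, ...).
#'
#' @param name character vector of atom names.
#' @return character vector of normalized names.
#' @export
normalize_atom_name <- function(name) {
  x <- gsub("′", "'", trimws(name), fixed = TRUE)
  x <- gsub("*", "'", x, fixed = TRUE)
  x[x == "O1P"] <- "OP1"
  x[x == "O2P"] <- "OP2"
  x
}

infer_element <- function(name) {
  key <- toupper(sub("[^A-Za-z].*$", "", name))
  two <- c(NA2 = "NA", CL = "CL", MG = "MG", BR = "BR")
  ifelse(key %in% two, substr(key, 1, 2),
         substr(key, 1, 1))
}

#' Assemble a topology
#'
#' A topology is an ordered atom table together with the duplex net formal
#' charge and (when the system contains a duplex) the antiparallel
#' Watson-Crick pairing map: residue *i* of chain 1 pairs residue
#' *N + 1 - i* of chain 2.
#'
#' Formal charges follow the residue-template convention: each phosphate
#' group carries -1 (assigned to the P atom), nucleotide atoms are otherwise
#' neutral, and ion charges come from the species label.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue`
#'   (global 1-based residue index), `base` (one of A/C/G/U/T, or `NA` for
#'   non-nucleotide residues), `chain`, `charge`, and optionally `resname`.
#' @param pairing optional data.frame with columns `res1`, `res2` giving the
#'   global residue indices of paired nucleotides.  Computed automatically
#'   for two equal-length nucleotide chains when omitted.
#' @return object of class `Topology`.
#' @export
topology <- function(atoms, pairing = NULL) {
  required <- c("name", "element", "residue", "base", "chain", "charge")
  if (!all(required %in% names(atoms))) {
    stop("atoms must have columns: ", paste(required, collapse = ", "))
  }
  atoms$name <- normalize_atom_name(atoms$name)
  if (is.null(atoms$resname)) atoms$resname <- atoms$base
  bad <- !is.na(atoms$base) & !(atoms$base %in% NUC_BASES)
  if (any(bad)) stop("unknown base(s): ", paste(unique(atoms$base[bad]), collapse = ", "))
  nuc <- !is.na(atoms$base)
  if (is.null(pairing) && any(nuc)) {
    chains <- unique(atoms$chain[nuc])
    if (length(chains) == 2L) {
      r1 <- sort(unique(atoms$residue[nuc & atoms$chain == chains[1]]))
      r2 <- sort(unique(atoms$residue[nuc & atoms$chain == chains[2]]))
      if (length(r1) == length(r2) && length(r1) > 0L) {
        pairing <- data.frame(res1 = r1, res2 = rev(r2))
      }
    }
  }
  structure(list(
    atoms = atoms,
    n_atoms = nrow(atoms),
    pairing = pairing,
    net_charge = sum(atoms$charge[nuc])
  ), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  nuc <- !is.na(x$atoms$base)
  cat("<Topology> ", x$n_atoms, " atoms, ",
      length(unique(x$atoms$residue[nuc])), " nucleotide residues, ",
      "duplex net charge ", x$net_charge, "e\n", sep = "")
  invisible(x)
}

#' Classify a duplex atom into its groove/backbone region
#'
#' Deterministic mapping from (atom name, base) to one of `major`, `minor`,
#' `backbone_Oprime`, `phosphate` or `other`; identical convention for
#' right- and left-handed duplex forms.  Vectorized.
#'
#' @param name atom name(s), any accepted spelling (see
#'   [normalize_atom_name()]).
#' @param base base letter(s) (`A`, `C`, `G`, `U`, `T`).
#' @return character vector over the region labels.
#' @examples
#' classify_region("O6", "G")  # major
#' classify_region("O2", "C")  # minor
#' @export
classify_region <- function(name, base) {
  name <- normalize_atom_name(name)
  if (any(!(base %in% NUC_BASES))) {
    stop("unknown base(s): ", paste(unique(base[!(base %in% NUC_BASES)]), collapse = ", "))
  }
  n <- max(length(name), length(base))
  name <- rep_len(name, n)
  base <- rep_len(base, n)
  out <- rep("other", n)
  out[name %in% REGION_PHOSPHATE] <- "phosphate"
  out[name %in% REGION_OPRIME] <- "backbone_Oprime"
  for (b in c("G", "C")) {
    sel <- base == b
    out[sel & name %in% REGION_MAJOR[[b]]] <- "major"
    out[sel & name %in% REGION_MINOR[[b]]] <- "minor"
  }
  out
}

#' Select atom indices from a topology
#'
#' All filters are optional and combined with logical AND.
#'
#' @param top a `Topology`.
#' @param name,base,chain,residue,element,region vectors of accepted values
#'   (`region` uses [classify_region()] labels and implies nucleotide atoms).
#' @param nucleotide if `TRUE`, keep only nucleotide atoms.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(top, name = NULL, base = NULL, chain = NULL,
                         residue = NULL, element = NULL, region = NULL,
                         nucleotide = FALSE) {
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% normalize_atom_name(name)
  if (!is.null(base)) keep <- keep & !is.na(a$base) & a$base %in% base
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residue)) keep <- keep & a$residue %in% residue
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (nucleotide || !is.null(region)) keep <- keep & !is.na(a$base)
  if (!is.null(region)) {
    lab <- rep(NA_character_, nrow(a))
    nuc <- !is.na(a$base)
    lab[nuc] <- classify_region(a$name[nuc], a$base[nuc])
    keep <- keep & !is.na(lab) & lab %in% region
  }
  which(keep)
}
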