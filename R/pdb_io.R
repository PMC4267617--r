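# Multi-model PDB (MODEL/ENDMDL + CRYST1) and XYZ-per-frame I/O.
# Only orthorhombic boxes are supported; triclinic input is rejected.

base_resname <- function(base, rna) {
  if (rna) base else paste0("D", base)
}

species_resname <- function(label) {
  switch(label, "Na+" = "NA", "K+" = "K", "Mg2+" = "MG", "Cl-" = "CL",
         "WAT-O" = "HOH", label)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, with a `CRYST1` record carrying the
#' orthorhombic box.  Coordinates are written with PDB precision (1e-3 A).
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  ion <- is.na(a$base)
  rec <- ifelse(ion, "HETATM", "ATOM")
  resname <- a$resname %||% a$base
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1], traj$box[2], traj$box[3], 90, 90, 90), con)
  # per-chain residue numbering as in PDB files
  chain_res <- stats::ave(a$residue, a$chain, FUN = function(r) match(r, sort(unique(r))))
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4), paste0(" ", a$name))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, seq_len(nrow(a)) %% 100000L, name4, "",
                       substr(resname, 1, 3), substr(a$chain, 1, 1),
                       chain_res %% 10000L, "",
                       xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

parse_pdb_atom_lines <- function(lines) {
  sub_f <- function(l, a, b) trimws(substr(l, a, b))
  data.frame(
    name = sub_f(lines, 13, 16),
    resname = sub_f(lines, 18, 20),
    chain = sub_f(lines, 22, 22),
    resseq = as.integer(sub_f(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    element = sub_f(lines, 77, 78),
    stringsAsFactors = FALSE
  )
}

NUC_RESNAMES <- c(DA = "A", DC = "C", DG = "G", DT = "T",
                  A = "A", C = "C", G = "G", U = "U", T = "T",
                  RA = "A", RC = "C", RG = "G", RU = "U")

read_pdb_trajectory <- function(path, dt = 1, species = NULL, box = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("parse error: '", path, "' is empty")
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry)) {
    v <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                      substr(cry[1], 25, 33)))
    ang <- as.numeric(c(substr(cry[1], 34, 40), substr(cry[1], 41, 47),
                        substr(cry[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3)) {
      stop("triclinic box rejected: only orthorhombic boxes are supported")
    }
    box <- v
  }
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("parse error: unbalanced MODEL/ENDMDL records")
    }
    blocks <- mapply(function(s, e) {
      idx <- seq(s, e)
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  if (!length(blocks[[1]])) stop("parse error: no ATOM records in '", path, "'")
  if (is.null(box)) {
    stop("missing box: no CRYST1 record (frame 1) and no box supplied")
  }
  n_atoms <- length(blocks[[1]])
  nf <- length(blocks)
  bad <- which(lengths(blocks) != n_atoms)
  if (length(bad)) {
    stop("atom-count mismatch across models: frame ", bad[1], " has ",
         length(blocks[[bad[1]]]), " atoms, expected ", n_atoms)
  }
  first <- parse_pdb_atom_lines(lines[blocks[[1]]])
  rn <- toupper(first$resname)
  base <- unname(NUC_RESNAMES[rn])
  elem <- toupper(ifelse(nchar(first$element) > 0, first$element,
                         infer_element(first$name)))
  two_letter <- elem %in% c("NA", "CL", "MG", "BR")
  elem[!two_letter] <- substr(elem[!two_letter], 1, 1)
  # global residue index: unique (chain, resseq) in order of appearance
  key <- paste(first$chain, first$resseq)
  residue <- match(key, unique(key))
  atoms <- data.frame(
    name = first$name, element = elem,
    residue = residue, base = base, chain = first$chain,
    charge = 0, resname = rn, stringsAsFactors = FALSE
  )
  atoms$charge[normalize_atom_name(atoms$name) == "P" & !is.na(atoms$base)] <- -1
  top <- topology(atoms)
  sp <- species %||% infer_species_map(top)
  for (label in names(sp)) {
    z <- ION_CHARGES[label]
    if (!is.na(z)) top$atoms$charge[sp[[label]]] <- z
  }
  coords <- array(NA_real_, c(n_atoms, 3L, nf))
  for (f in seq_len(nf)) {
    p <- parse_pdb_atom_lines(lines[blocks[[f]]])
    coords[, , f] <- cbind(p$x, p$y, p$z)
  }
  trajectory(top, coords, box, dt = dt, species = sp)
}

read_xyz_trajectory <- function(path, top, box, dt = 1, species = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("parse error: '", path, "' is empty")
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("parse error: expected atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("parse error: truncated frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4, drop = FALSE]), ncol = 3L)
    i <- i + 2L + n
  }
  n_atoms <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 1L) != n_atoms)) {
    stop("atom-count mismatch across XYZ frames")
  }
  if (is.null(box)) stop("missing box: xyz_frames requires box in the sidecar")
  if (is.null(top)) stop("xyz_frames dialect requires a companion topology")
  if (top$n_atoms != n_atoms) {
    stop("topology atom count (", top$n_atoms, ") does not match XYZ frames (", n_atoms, ")")
  }
  coords <- array(unlist(frames), c(n_atoms, 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory(top, coords, box, dt = dt, species = species)
}

#' Load a trajectory from disk
#'
#' Two dialects are supported: multi-model PDB (`MODEL`/`ENDMDL` blocks,
#' box from the `CRYST1` record) and plain XYZ-per-frame with a JSON sidecar
#' (`<path>.json` by default) supplying `box`, `dt` and optionally a species
#' map and topology description.
#'
#' @param path input file.
#' @param dialect `"pdb_multimodel"` or `"xyz_frames"`.
#' @param topology companion [topology()] (required for `xyz_frames` unless
#'   the sidecar describes one).
#' @param sidecar path to the JSON sidecar for `xyz_frames` (and optional
#'   box/dt override for PDB input).
#' @param dt sampling interval (ps) when not given by a sidecar.
#' @param species optional species map override (named list of atom indices).
#' @return a `Trajectory`.
#' @export
load_structure <- function(path, dialect = c("pdb_multimodel", "xyz_frames"),
                           topology = NULL, sidecar = NULL, dt = 1,
                           species = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  side <- NULL
  sidecar <- sidecar %||% if (file.exists(paste0(path, ".json"))) paste0(path, ".json")
  if (!is.null(sidecar) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  dt <- side$dt %||% dt
  box <- side$box
  if (!is.null(side$species)) {
    species <- lapply(side$species, as.integer)
  }
  if (dialect == "pdb_multimodel") {
    read_pdb_trajectory(path, dt = dt, species = species, box = box)
  } else {
    if (is.null(topology) && !is.null(side$atoms)) {
      topology <- topology(as.data.frame(side$atoms))
    }
    read_xyz_trajectory(path, topology, box, dt = dt, species = species)
  }
}
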