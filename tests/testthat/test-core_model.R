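# core_model: topology, region classification, periodic geometry, I/O

test_that("built duplex has the documented charge bookkeeping", {
  dup <- build_duplex(duplex_spec("B-DNA"))
  a <- dup$topology$atoms
  expect_equal(length(unique(a$residue)), 24)
  expect_equal(sum(a$name == "P"), 22)
  expect_equal(dup$topology$net_charge, -22)
  # pairing map is an involution
  p <- dup$topology$pairing
  back <- setNames(p$res1, p$res2)
  expect_equal(unname(back[as.character(p$res2)]), p$res1)
})

test_that("multi-model PDB writer/reader round-trips a synthetic trajectory", {
  dup <- build_duplex(duplex_spec("A-RNA"))
  traj <- static_trajectory(dup, n_frames = 3, dt = 10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, f)
  t2 <- load_structure(f, "pdb_multimodel", dt = 10)
  expect_equal(t2$n_frames, 3)
  expect_equal(t2$topology$n_atoms, traj$topology$n_atoms)
  expect_lt(max(abs(t2$coords - traj$coords)), 1e-3)  # PDB precision
  expect_equal(t2$topology$net_charge, -22)
  expect_equal(t2$box, traj$box)
  expect_equal(t2$topology$atoms$name, traj$topology$atoms$name)
})

test_that("PDB parse errors are informative", {
  f <- withr::local_tempfile(fileext = ".pdb")
  file.create(f)
  expect_error(load_structure(f, "pdb_multimodel"), "empty")
  # missing box
  writeLines(c("MODEL     1",
               "ATOM      1  O6   DG A   1       1.000   2.000   3.000  1.00  0.00           O",
               "ENDMDL"), f)
  expect_error(load_structure(f, "pdb_multimodel"), "missing box")
  # atom-count mismatch across models
  writeLines(c("CRYST1   82.000   82.000   82.000  90.00  90.00  90.00 P 1           1",
               "MODEL     1",
               "ATOM      1  O6   DG A   1       1.000   2.000   3.000  1.00  0.00           O",
               "ENDMDL",
               "MODEL     2",
               "ATOM      1  O6   DG A   1       1.000   2.000   3.000  1.00  0.00           O",
               "ATOM      2  N7   DG A   1       2.000   2.000   3.000  1.00  0.00           N",
               "ENDMDL"), f)
  expect_error(load_structure(f, "pdb_multimodel"), "atom-count mismatch.*frame 2")
  # triclinic rejected
  writeLines(c("CRYST1   82.000   82.000   82.000  90.00  95.00  90.00 P 1           1",
               "MODEL     1",
               "ATOM      1  O6   DG A   1       1.000   2.000   3.000  1.00  0.00           O",
               "ENDMDL"), f)
  expect_error(load_structure(f, "pdb_multimodel"), "triclinic")
})

test_that("XYZ dialect reads frames with a JSON sidecar", {
  f <- withr::local_tempfile(fileext = ".xyz")
  lines <- unlist(lapply(1:3, function(k) {
    c("1", paste("frame", k), sprintf("Na %.3f %.3f %.3f", k * 1.0, 2, 3))
  }))
  writeLines(lines, f)
  jsonlite::write_json(list(box = c(20, 20, 20), dt = 5,
                            species = list("Na+" = 1L)),
                       paste0(f, ".json"), auto_unbox = TRUE)
  top <- topology(ION_DF(1, "Na+"))
  t3 <- load_structure(f, "xyz_frames", topology = top)
  expect_equal(t3$n_frames, 3)
  expect_equal(t3$dt, 5)
  expect_equal(t3$coords[1, 1, ], c(1, 2, 3))
  expect_equal(t3$species[["Na+"]], 1L)
  # empty file errors
  f2 <- withr::local_tempfile()
  file.create(f2)
  expect_error(load_structure(f2, "xyz_frames", topology = top), "empty")
})

test_that("region classification follows the groove-atom convention", {
  expect_equal(classify_region("O6", "G"), "major")
  expect_equal(classify_region("N7", "G"), "major")
  expect_equal(classify_region("N4", "C"), "major")
  expect_equal(classify_region("O2", "C"), "minor")
  expect_equal(classify_region("N1", "C"), "minor")
  expect_equal(classify_region(c("N2", "N3", "N9"), "G"),
               rep("minor", 3))
  expect_equal(classify_region("O4'", "G"), "backbone_Oprime")
  expect_equal(classify_region(c("O5'", "O3'", "O2'"), "C"),
               rep("backbone_Oprime", 3))
  expect_equal(classify_region(c("OP1", "OP2"), "G"), rep("phosphate", 2))
  expect_error(classify_region("O6", "X"), "unknown base")
  # identical convention for left- and right-handed forms: classification
  # depends only on (name, base), never on geometry
  for (form in c("B-DNA", "Z-DNA", "A-RNA", "Z-RNA")) {
    dup <- build_duplex(duplex_spec(form))
    a <- dup$topology$atoms
    lab <- classify_region(a$name, a$base)
    expect_true(all(lab %in% c("major", "minor", "backbone_Oprime",
                               "phosphate", "other")))
    # the named groove atoms and backbone oxygens partition into exactly
    # one non-'other' label each, per base
    expected <- function(name, base) {
      if (name %in% c("OP1", "OP2")) return("phosphate")
      if (name %in% c("O5'", "O4'", "O3'", "O2'")) return("backbone_Oprime")
      if (base == "G" && name %in% c("O6", "N7")) return("major")
      if (base == "G" && name %in% c("N2", "N3", "N9")) return("minor")
      if (base == "C" && name == "N4") return("major")
      if (base == "C" && name %in% c("O2", "N1")) return("minor")
      "other"
    }
    expect_equal(lab, mapply(expected, a$name, a$base, USE.NAMES = FALSE))
  }
})

test_that("atom-name normalization accepts dialect spellings", {
  expect_equal(normalize_atom_name(c("O5'", "O5′", "O5*")),
               rep("O5'", 3))
  expect_equal(normalize_atom_name(c("O1P", "O2P")), c("OP1", "OP2"))
})

test_that("min_image_distance agrees with 27-image brute force", {
  box <- c(82, 82, 82)
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), box), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(81, 0, 0), box), 1)
  set.seed(42)
  box2 <- c(10, 18, 25)
  for (i in 1:100) {
    p <- runif(3, 0, 1) * box2
    q <- runif(3, 0, 1) * box2
    expect_equal(min_image_distance(p, q, box2), brute_min_image(p, q, box2),
                 tolerance = 1e-10)
  }
  # properties: symmetry, nonnegativity, bounded by half box diagonal
  for (i in 1:50) {
    p <- runif(3, 0, 10); q <- runif(3, 0, 10)
    d1 <- min_image_distance(p, q, box2)
    expect_equal(d1, min_image_distance(q, p, box2))
    expect_gte(d1, 0)
    expect_lte(d1, sqrt(sum((box2 / 2)^2)))
  }
})
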