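test_that("parsing populates chains, residues and ligand instances", {
  x <- parse_structure(fixture_dimer_text())
  expect_s3_class(x, "allonet_structure")
  expect_equal(length(unique(x$residues$chain)), 2)
  expect_equal(nrow(x$residues), 6)
  expect_equal(nrow(x$ligands), 1)
  expect_equal(x$ligands$het_code, "XYZ")
  expect_equal(x$ligands$n_atoms, 2)
})

test_that("parse errors on missing ATOM records and malformed coordinates", {
  expect_error(parse_structure("HEADER    EMPTY"), "no ATOM records")
  bad <- fixture_dimer_text()
  bad[3] <- sub("^(.{30}).{8}", "\\1  badxyz ", bad[3])
  expect_error(parse_structure(bad), "malformed coordinate")
})

test_that("waters are discarded at parse time", {
  x <- parse_structure(fixture_dimer_text(n_waters = 3))
  expect_equal(nrow(x$ligands), 1)
  expect_false(any(x$atoms$resid == "HOH"))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    "HEADER    ALT",
    pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0.8, 0, element = "N"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 0.5, 0, 0, occ = 0.6,
             element = "C", altloc = "A"),
    pdb_line("ATOM", 3, "CA", "GLY", "A", 1, 2.5, 0, 0, occ = 0.4,
             element = "C", altloc = "B"),
    pdb_line("ATOM", 4, "C", "GLY", "A", 1, 1.2, 0.8, 0, element = "C"),
    "END")
  x <- preprocess(parse_structure(lines))
  ca <- x$atoms[x$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 0.5)

  # tie goes to altloc A
  lines_tie <- sub("  0.60", "  0.40", lines)
  x2 <- preprocess(parse_structure(lines_tie))
  expect_equal(x2$atoms$x[x2$atoms$elety == "CA"], 0.5)
})

test_that("peptide-category ligands are removed and preprocess is idempotent", {
  cats <- rbind(default_ligand_categories(),
                data.frame(het_code = "XYZ", category = "peptide"))
  x <- parse_structure(fixture_dimer_text())
  x1 <- preprocess(x, cats)
  expect_equal(nrow(x1$ligands), 0)
  x2 <- preprocess(preprocess(x))
  expect_identical(preprocess(x)$atoms, x2$atoms)
})

test_that("residue center of mass matches an independent mass-weighted average", {
  atoms <- data.frame(
    element = c("N", "C", "C", "O", "C"),
    x = c(1.204, 0.000, -1.250, -1.350, 0.120),
    y = c(0.850, 0.000, 0.801, -0.310, -1.310),
    z = c(-0.033, 0.420, 0.110, -0.480, 1.210))
  # frozen value from an independent numpy computation with standard masses
  expect_equal(residue_com(atoms), c(-0.277210, 0.012609, 0.193180),
               tolerance = 1e-3)
  # single atom and symmetric two-atom cases
  expect_equal(residue_com(data.frame(element = "C", x = 1, y = 2, z = 3)),
               c(1, 2, 3))
  two <- data.frame(element = c("C", "C"), x = c(0, 2), y = 0, z = 0)
  expect_equal(residue_com(two), c(1, 0, 0))
  # hydrogens are excluded
  withH <- rbind(atoms, data.frame(element = "H", x = 99, y = 99, z = 99))
  expect_equal(residue_com(withH), residue_com(atoms))
  expect_error(residue_com(data.frame(element = "H", x = 0, y = 0, z = 0)),
               "heavy")
})

test_that("coarse-graining gives one bead per residue in both modes", {
  x <- preprocess(parse_structure(fixture_dimer_text()))
  ca <- coarse_grain(x, "CA")
  com <- coarse_grain(x, "COM")
  expect_equal(nrow(ca), nrow(x$residues))
  expect_equal(nrow(com), nrow(x$residues))
  expect_equal(ca$res_key, com$res_key)
  expect_false(isTRUE(all.equal(ca$x, com$x)))
  # COM beads equal a direct per-residue recomputation
  at <- x$atoms[x$atoms$is_polymer, ]
  for (i in seq_len(nrow(com))) {
    expect_equal(unlist(com[i, c("x", "y", "z")], use.names = FALSE),
                 residue_com(at[at$res_key == com$res_key[i], ]),
                 tolerance = 1e-9)
  }
})

test_that("CA mode errors listing residues that lack a C-alpha", {
  lines <- c("HEADER    NOCA",
             pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
             pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 4, 0, 0, element = "C"),
             "END")
  x <- preprocess(parse_structure(lines))
  expect_error(coarse_grain(x, "CA"), "A\\|1\\|")
})

test_that("parse -> write -> parse round-trip preserves the structure", {
  x <- parse_structure(fixture_dimer_text())
  y <- parse_structure(write_pdb_text(x))
  expect_equal(nrow(y$residues), nrow(x$residues))
  expect_equal(unique(y$residues$chain), unique(x$residues$chain))
  expect_equal(y$atoms$x, x$atoms$x, tolerance = 1e-3)
  expect_equal(y$atoms$y, x$atoms$y, tolerance = 1e-3)
  expect_equal(y$atoms$z, x$atoms$z, tolerance = 1e-3)
})

test_that("chain sequences derive from polymer residues", {
  x <- parse_structure(fixture_dimer_text())
  expect_equal(unname(chain_sequences(x)), c("GGG", "GGG"))
})
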