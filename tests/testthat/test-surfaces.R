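atom_df <- function(xyz, element = "C") {
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = rep_len(element, nrow(xyz)))
}

test_that("an isolated atom has the closed-form sphere area", {
  s <- sasa(atom_df(matrix(0, 1, 3), "S"), probe = 1.4)  # r = 1.8
  expect_equal(s$total, 4 * pi * 3.2^2, tolerance = 0.02)
  # a custom radius via the radii table
  s2 <- sasa(atom_df(matrix(0, 1, 3), "C"), probe = 1.4,
             radii = c(C = 1.9))
  expect_equal(s2$total, 4 * pi * 3.3^2, tolerance = 0.02)
})

test_that("well-separated atoms contribute independent areas", {
  xyz <- rbind(c(0, 0, 0), c(20, 0, 0))
  s <- sasa(atom_df(xyz, "C"), probe = 1.4)
  iso <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s$per_atom, c(iso, iso), tolerance = 0.02)
})

test_that("two overlapping spheres match the analytic spherical-cap area", {
  for (d in c(2.0, 3.0, 4.5)) {
    got <- sasa(atom_df(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "O")),
                probe = 1.4)$total
    want <- bf_two_sphere_sasa(1.7, 1.52, d, 1.4)
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("unknown elements without a radius are an error", {
  expect_error(sasa(atom_df(matrix(0, 1, 3), "QQ")), "radius")
})

test_that("SASA is exactly translation invariant and stable under rotation", {
  set.seed(3)
  xyz <- matrix(rnorm(30, sd = 3), ncol = 3)
  a1 <- sasa(atom_df(xyz), n_points = 480)
  a2 <- sasa(atom_df(sweep(xyz, 2, c(13, -7, 2), "+")), n_points = 480)
  expect_identical(a1$per_atom, a2$per_atom)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  a3 <- sasa(atom_df(xyz %*% rot), n_points = 480)
  expect_equal(a1$total, a3$total, tolerance = 0.02)
})

test_that("interface area of a monomer is zero and separated chains bury nothing", {
  mono <- preprocess(parse_structure(c(
    "HEADER    MONO",
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 4, 0, 0, element = "C"),
    "END")))
  ar <- interface_area(mono, n_points = 480)
  expect_equal(ar$I, 0)
  expect_equal(ar$rho, 0)
  # fixture dimer chains are 20 A apart: no burial
  x <- preprocess(parse_structure(fixture_dimer_text()))
  ar2 <- interface_area(x, n_points = 480)
  expect_equal(ar2$I, 0, tolerance = 1e-9)
  expect_equal(interface_residues(x, n_points = 480), character())
})

test_that("interface area equals the definitional per-chain recomputation", {
  out <- generate_complex(synthetic_spec(seed = 4))
  x <- preprocess(parse_structure(out$pdb))
  ar <- interface_area(x, n_points = 480)
  at <- x$atoms[x$atoms$is_polymer & !(x$atoms$element %in% c("H", "D")), ]
  full <- sasa(at, n_points = 480)
  manual_I <- 0
  for (ch in c("A", "B")) {
    iso <- sasa(at[at$chain == ch, ], n_points = 480)$total
    incpx <- sum(full$per_atom[at$chain == ch])
    manual_I <- manual_I + iso - incpx
  }
  expect_equal(ar$I, manual_I, tolerance = 1e-9)
  expect_true(ar$I > 0)          # the packed seam buries surface
  expect_equal(ar$rho, ar$I / ar$S)
  # burial is never negative beyond quadrature tolerance
  expect_true(all(ar$per_chain$interface > -1e-9))
})

test_that("interface residues shrink as the burial threshold grows", {
  out <- generate_complex(synthetic_spec(seed = 4))
  x <- preprocess(parse_structure(out$pdb))
  r1 <- interface_residues(x, tol = 0.1, n_points = 480)
  r2 <- interface_residues(x, tol = 5, n_points = 480)
  r3 <- interface_residues(x, tol = Inf, n_points = 480)
  expect_true(all(r2 %in% r1))
  expect_equal(r3, character())
  expect_true(length(r1) > 0)
})

test_that("relative solvent accessibility is bounded below by zero and uses the reference table", {
  out <- generate_complex(synthetic_spec(seed = 4))
  x <- preprocess(parse_structure(out$pdb))
  rsa <- relative_solvent_accessibility(x, n_points = 480)
  expect_true(all(rsa$rsa >= 0))
  expect_equal(rsa$reference,
               unname(reference_tripeptide_sasa()[rsa$resid]))
  # unknown residue types error without a fallback, pass with one
  x2 <- x
  x2$residues$resid[1] <- "XXX"
  expect_error(relative_solvent_accessibility(x2, n_points = 480), "XXX")
  rsa2 <- relative_solvent_accessibility(x2, fallback = 200, n_points = 480)
  expect_equal(rsa2$reference[1], 200)
})

test_that("an isolated extended residue approaches full relative accessibility", {
  # one GLY alone: its SASA over the GLY tripeptide reference should be
  # near or above 1 (no flanking neighbours at all)
  mono <- preprocess(parse_structure(c(
    "HEADER    GLY",
    pdb_line("ATOM", 1, "N", "GLY", "A", 1, -1.2, 0.8, 0, element = "N"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 0, 0, 0.4, element = "C"),
    pdb_line("ATOM", 3, "C", "GLY", "A", 1, 1.2, 0.8, 0, element = "C"),
    pdb_line("ATOM", 4, "O", "GLY", "A", 1, 1.4, -0.8, -0.3, element = "O"),
    "END")))
  rsa <- relative_solvent_accessibility(mono)
  expect_true(rsa$rsa > 1)  # no neighbours: more exposed than in a tripeptide
})

test_that("subunit flexibility is the SASA over the mass power law", {
  out <- generate_complex(synthetic_spec(seed = 4))
  x <- preprocess(parse_structure(out$pdb))
  fl <- subunit_flexibility(x, "A", n_points = 480)
  expect_equal(fl$expected, 6.3 * fl$mass^0.73)
  expect_equal(fl$A_rel, fl$sasa_isolated / fl$expected)
  expect_true(fl$A_rel > 0)
  # doubling c halves A_rel
  fl2 <- subunit_flexibility(x, "A", c = 12.6, n_points = 480)
  expect_equal(fl2$A_rel, fl$A_rel / 2)
  expect_error(subunit_flexibility(x, "Q"), "no atoms")
})

test_that("total in-complex SASA never exceeds the sum of isolated chains", {
  for (seed in c(2, 5)) {
    out <- generate_complex(synthetic_spec(seed = seed))
    x <- preprocess(parse_structure(out$pdb))
    ar <- interface_area(x, n_points = 480)
    expect_true(sum(ar$per_chain$sasa_in_complex) <=
                  sum(ar$per_chain$sasa_isolated) + 1e-9)
  }
})
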