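#' Default van der Waals radii
#'
#' Packaged table of element radii (Angstrom, Bondi-style values plus common
#' metals) used by the surface-area routines.
#'
#' @return named numeric vector, element symbol to radius.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    ZN = 1.39, MG = 1.73, CA = 2.31, "NA" = 2.27, K = 2.75, FE = 2.00,
    MN = 2.00, CU = 1.40, CO = 2.00, NI = 1.63, CD = 1.58, MO = 2.00, W = 2.00)
}

# deterministic near-uniform points on the unit sphere (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-spiral quadrature: each atom's
#' solvent-expanded sphere is sampled at `n_points` points and a point counts
#' as accessible when it lies outside every neighbouring atom's expanded
#' sphere. Deterministic for fixed `n_points`; accuracy is ~1-2% at the
#' default 960 points.
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `element`.
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points quadrature points per atom.
#' @param radii named radius table, see [default_vdw_radii()].
#' @return list with `per_atom` (numeric vector, Angstrom^2) and `total`.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960,
                 radii = default_vdw_radii()) {
  atoms <- heavy_atoms(atoms)
  n <- nrow(atoms)
  if (!n) stop("no atoms")
  r <- unname(radii[atoms$element])
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$element[is.na(r)]), collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rs <- r + probe
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rs[i] + rs)^2 & seq_len(n) != i)
    p <- pts * rs[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rs[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- mean(acc) * 4 * pi * rs[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

polymer_atoms <- function(x, chain = NULL) {
  at <- heavy_atoms(x$atoms[x$atoms$is_polymer, , drop = FALSE])
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  at
}

#' Interface and surface areas of a complex
#'
#' For every chain the SASA is computed in isolation and in the context of the
#' full complex; the per-chain interface area is the difference of the two.
#' The total interface area I is the sum of per-chain differences (not
#' halved), the total surface S is the in-complex SASA summed over chains, and
#' the relative interface area is rho = I/S. Polymer heavy atoms only.
#'
#' @param x a preprocessed `allonet_structure`.
#' @inheritParams sasa
#' @return list of class `allonet_areas`: `per_chain` data.frame
#'   (`chain`, `sasa_isolated`, `sasa_in_complex`, `interface`), `I`, `S`,
#'   `rho`.
#' @export
interface_area <- function(x, probe = 1.4, n_points = 960) {
  at <- polymer_atoms(x)
  chains <- unique(at$chain)
  full <- sasa(at, probe, n_points)
  in_complex <- vapply(chains, function(ch)
    sum(full$per_atom[at$chain == ch]), 0)
  isolated <- vapply(chains, function(ch)
    sasa(at[at$chain == ch, , drop = FALSE], probe, n_points)$total, 0)
  per_chain <- data.frame(chain = chains, sasa_isolated = isolated,
                          sasa_in_complex = in_complex,
                          interface = isolated - in_complex,
                          stringsAsFactors = FALSE, row.names = NULL)
  S <- sum(in_complex)
  I <- sum(per_chain$interface)
  structure(list(per_chain = per_chain, I = I, S = S, rho = I / S),
            class = "allonet_areas")
}

per_residue_sasa <- function(at, probe, n_points) {
  s <- sasa(at, probe, n_points)
  rowsum(s$per_atom, at$res_key)[, 1]
}

#' Protein-protein interface residues
#'
#' Residues whose SASA drops by more than `tol` between the isolated-chain and
#' in-complex contexts.
#'
#' @param x a preprocessed `allonet_structure`.
#' @param tol burial threshold in Angstrom^2.
#' @inheritParams sasa
#' @return character vector of residue keys (`chain|resno|insert`).
#' @export
interface_residues <- function(x, tol = 0.1, probe = 1.4, n_points = 960) {
  at <- polymer_atoms(x)
  chains <- unique(at$chain)
  if (length(chains) < 2) return(character())
  in_complex <- per_residue_sasa(at, probe, n_points)
  out <- character()
  for (ch in chains) {
    iso <- per_residue_sasa(at[at$chain == ch, , drop = FALSE],
                            probe, n_points)
    drop_area <- iso - in_complex[names(iso)]
    out <- c(out, names(iso)[drop_area > tol])
  }
  sort(out)
}

#' Reference tripeptide SASA values
#'
#' Theoretical maximum per-residue SASA of residue X in an extended Gly-X-Gly
#' tripeptide, used to normalize RSA. Packaged data; editable.
#'
#' @return named numeric vector (Angstrom^2) over the 20 amino acids.
#' @export
reference_tripeptide_sasa <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Relative solvent accessibility
#'
#' Per-residue SASA computed on the entire complex (so interface-buried
#' residues can score zero) divided by the reference tripeptide value for the
#' residue type.
#'
#' @param x a preprocessed `allonet_structure`.
#' @param reference named reference table; see [reference_tripeptide_sasa()].
#' @param fallback reference value for residue types absent from the table
#'   (`NA` to error on unknown types).
#' @inheritParams sasa
#' @return data.frame with `res_key`, `resid`, `sasa`, `reference`, `rsa`.
#' @export
relative_solvent_accessibility <- function(x,
                                           reference = reference_tripeptide_sasa(),
                                           fallback = NA_real_,
                                           probe = 1.4, n_points = 960) {
  at <- polymer_atoms(x)
  per_res <- per_residue_sasa(at, probe, n_points)
  res <- x$residues
  ref <- unname(reference[res$resid])
  if (anyNA(ref)) {
    if (is.na(fallback)) {
      stop("no reference SASA for residue type(s): ",
           paste(unique(res$resid[is.na(ref)]), collapse = ", "))
    }
    ref[is.na(ref)] <- fallback
  }
  s <- unname(per_res[res$res_key])
  s[is.na(s)] <- 0
  data.frame(res_key = res$res_key, resid = res$resid, sasa = s,
             reference = ref, rsa = s / ref,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Subunit flexibility from relative surface area
#'
#' The isolated-chain SASA is compared with the surface expected for a compact
#' globular monomer of the same mass, A0 = c * M^d; the ratio
#' A_rel = A_s / A0 is a proxy for how extended (flexible) the subunit is.
#'
#' @param x a preprocessed `allonet_structure`.
#' @param chain chain identifier.
#' @param c,d scaling constants of the mass-area power law (defaults
#'   6.3 * M^0.73, the classical monomer relation).
#' @inheritParams sasa
#' @return list: `chain`, `mass` (Da), `sasa_isolated`, `expected`, `A_rel`.
#' @export
subunit_flexibility <- function(x, chain, c = 6.3, d = 0.73,
                                probe = 1.4, n_points = 960) {
  at <- polymer_atoms(x, chain)
  if (!nrow(at)) stop("no atoms in chain ", chain)
  mass <- sum(atom_masses(at$element))
  if (mass <= 0) stop("zero-mass chain")
  a_s <- sasa(at, probe, n_points)$total
  a0 <- c * mass^d
  list(chain = chain, mass = mass, sasa_isolated = a_s,
       expected = a0, A_rel = a_s / a0)
}

#' @export
print.allonet_areas <- function(x, ...) {
  cat(sprintf("interface I = %.1f A^2, surface S = %.1f A^2, rho = %.4f\n",
              x$I, x$S, x$rho))
  invisible(x)
}
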