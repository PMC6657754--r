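#' @useDynLib allonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

WATER_CODES <- c("HOH", "WAT", "DOD", "H2O", "OH2")

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records into an `allonet_structure`: a table of atoms plus
#' derived polymer-residue and ligand-instance tables. HETATM groups are treated
#' as ligand instances keyed by (component id, chain, residue number, insertion
#' code); water molecules are discarded. Nonstandard HETATM residues that carry
#' a C-alpha atom (e.g. selenomethionine) are kept as polymer residues.
#'
#' @param pdb_text character scalar or vector of PDB-format lines.
#' @param pdb_id identifier; defaults to the HEADER id code when present.
#' @return An object of class `allonet_structure` with elements `atoms`
#'   (one row per atom), `residues` (polymer residues), `ligands` (one row per
#'   ligand instance), `resolution` (Angstrom, `NA` when absent) and `pdb_id`.
#' @seealso [preprocess()], [coarse_grain()], [read_structure()]
#' @export
parse_structure <- function(pdb_text, pdb_id = NULL) {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n", fixed = TRUE))
  if (!any(startsWith(lines, "ATOM"))) {
    stop("no ATOM records found: not a parseable structure")
  }
  coord_lines <- grep("^(ATOM|HETATM)", lines)
  bad <- coord_lines[is.na(suppressWarnings(
    as.numeric(substr(lines[coord_lines], 31, 38))))]
  if (length(bad)) {
    stop(sprintf("malformed coordinate field at line %d: '%s'",
                 bad[1], lines[bad[1]]))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  ele <- at$elesy
  blank <- is.na(ele) | ele == ""
  if (any(blank)) ele[blank] <- bio3d::atom2ele(at$elety[blank])
  at$element <- toupper(ele)
  at <- at[!(at$resid %in% WATER_CODES), , drop = FALSE]

  at$res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  # HETATM groups with a carbon C-alpha are polymer (MODRES-style residues)
  has_ca <- tapply(at$elety == "CA" & at$element == "C", at$res_key, any)
  at$is_polymer <- at$type == "ATOM" | unname(has_ca[at$res_key])

  if (is.null(pdb_id)) {
    hdr <- lines[startsWith(lines, "HEADER")]
    pdb_id <- if (length(hdr) && nzchar(trimws(substr(hdr[1], 63, 66)))) {
      trimws(substr(hdr[1], 63, 66))
    } else "unknown"
  }
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  resolution <- NA_real_
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) resolution <- as.numeric(m)
  }
  structure(
    list(atoms = at, pdb_id = pdb_id, resolution = resolution,
         residues = residue_table(at), ligands = ligand_table(at)),
    class = "allonet_structure")
}

#' Read a PDB file from disk
#' @param path file path.
#' @param ... passed to [parse_structure()].
#' @return An `allonet_structure`.
#' @export
read_structure <- function(path, ...) {
  parse_structure(readLines(path, warn = FALSE), ...)
}

residue_table <- function(at) {
  pol <- at[at$is_polymer, , drop = FALSE]
  if (!nrow(pol)) {
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      res_key = character(), stringsAsFactors = FALSE))
  }
  first <- pol[!duplicated(pol$res_key), , drop = FALSE]
  res <- data.frame(chain = first$chain, resno = first$resno,
                    insert = first$insert, resid = first$resid,
                    res_key = first$res_key, stringsAsFactors = FALSE)
  res[order_residues(res), , drop = FALSE]
}

ligand_table <- function(at, categories = default_ligand_categories()) {
  lig <- at[!at$is_polymer, , drop = FALSE]
  if (!nrow(lig)) {
    return(data.frame(het_code = character(), chain = character(),
                      resno = integer(), insert = character(),
                      res_key = character(), category = character(),
                      n_atoms = integer(), stringsAsFactors = FALSE))
  }
  first <- lig[!duplicated(lig$res_key), , drop = FALSE]
  n_atoms <- as.integer(table(lig$res_key)[first$res_key])
  out <- data.frame(het_code = first$resid, chain = first$chain,
                    resno = first$resno, insert = first$insert,
                    res_key = first$res_key,
                    category = ligand_category(first$resid, categories),
                    n_atoms = n_atoms, stringsAsFactors = FALSE)
  out[order_residues(out), , drop = FALSE]
}

# deterministic residue order: chain in order of first appearance in the file,
# then numeric residue number, then insertion code
order_residues <- function(res) {
  order(match(res$chain, unique(res$chain)), res$resno, res$insert)
}

#' Default ligand-component categories
#'
#' Packaged, editable table assigning PDB chemical-component ids to the
#' categories `metal`, `cofactor` or `peptide`; anything absent is `other`.
#' Peptide-category ligands are removed by [preprocess()].
#'
#' @return data.frame with columns `het_code`, `category`.
#' @export
default_ligand_categories <- function() {
  metals <- c("ZN", "MG", "MN", "FE", "FE2", "CA", "NA", "K", "CU", "CU1",
              "NI", "CO", "CD", "HG", "MO", "W")
  cofactors <- c("ATP", "ADP", "AMP", "GTP", "GDP", "NAD", "NAI", "NAP",
                 "NDP", "FAD", "FMN", "HEM", "HEC", "PLP", "TPP", "COA",
                 "SAM", "SAH", "B12")
  data.frame(
    het_code = c(metals, cofactors),
    category = c(rep("metal", length(metals)),
                 rep("cofactor", length(cofactors))),
    stringsAsFactors = FALSE)
}

ligand_category <- function(het_code, categories) {
  i <- match(het_code, categories$het_code)
  ifelse(is.na(i), "other", categories$category[i])
}

#' Preprocess a parsed structure
#'
#' Applies the two preprocessing rules used before network analysis: ligands of
#' category `peptide` are removed, and for residues with alternate-location
#' conformers only the conformer with the highest total occupancy is retained
#' (ties resolved towards altloc 'A', then lexicographically). Idempotent.
#'
#' @param x an `allonet_structure`.
#' @param ligand_categories table as from [default_ligand_categories()];
#'   supply a custom table to mark additional component ids as `peptide`.
#' @return The cleaned `allonet_structure`.
#' @export
preprocess <- function(x, ligand_categories = default_ligand_categories()) {
  stopifnot(inherits(x, "allonet_structure"))
  at <- x$atoms
  lig <- ligand_table(at, ligand_categories)
  pep <- lig$res_key[lig$category == "peptide"]
  at <- at[!(at$res_key %in% pep), , drop = FALSE]

  keep <- rep(TRUE, nrow(at))
  for (key in unique(at$res_key[at$alt != ""])) {
    idx <- which(at$res_key == key)
    alts <- setdiff(unique(at$alt[idx]), "")
    if (length(alts) < 2 && !any(at$alt[idx] == "")) next
    if (length(alts) == 0) next
    occ <- vapply(alts, function(a) sum(at$o[idx][at$alt[idx] == a]), 0)
    best <- alts[occ == max(occ)]
    chosen <- if ("A" %in% best) "A" else sort(best)[1]
    keep[idx] <- at$alt[idx] %in% c("", chosen)
  }
  at <- at[keep, , drop = FALSE]
  at$alt <- ""
  x$atoms <- at
  x$residues <- residue_table(at)
  x$ligands <- ligand_table(at, ligand_categories)
  x
}

heavy_atoms <- function(at) at[!(at$element %in% c("H", "D")), , drop = FALSE]

.allonet_cache <- new.env(parent = emptyenv())

# standard atomic masses from bio3d's periodic-table data
atom_masses <- function(element) {
  if (is.null(.allonet_cache$elements)) {
    e <- new.env()
    utils::data("elements", package = "bio3d", envir = e)
    .allonet_cache$elements <- e$elements
  }
  tab <- .allonet_cache$elements
  m <- tab$mass[match(toupper(element), toupper(tab$symb))]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]),
                                       collapse = ", "))
  }
  m
}

#' Residue center of mass
#'
#' Mass-weighted mean of heavy-atom coordinates (hydrogens excluded), using
#' standard atomic masses.
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `element`.
#' @return numeric length-3 coordinate in Angstrom.
#' @export
residue_com <- function(atoms) {
  h <- heavy_atoms(atoms)
  if (!nrow(h)) stop("residue has no heavy atoms")
  m <- atom_masses(h$element)
  c(sum(m * h$x), sum(m * h$y), sum(m * h$z)) / sum(m)
}

#' Coarse-grain a structure to a bead model
#'
#' One bead per polymer residue, in deterministic order (chain order of first
#' appearance, then residue number, then insertion code). `CA` mode places the
#' bead on the C-alpha atom; `COM` mode on the residue heavy-atom center of
#' mass. Ligand atoms never become beads.
#'
#' @param x a preprocessed `allonet_structure`.
#' @param mode `"CA"` or `"COM"`.
#' @return data.frame of class `allonet_beads` with columns `chain`, `resno`,
#'   `insert`, `resid`, `res_key`, `x`, `y`, `z`; attributes `mode`, `source`.
#' @export
coarse_grain <- function(x, mode = c("COM", "CA")) {
  stopifnot(inherits(x, "allonet_structure"))
  mode <- match.arg(mode)
  res <- x$residues
  at <- x$atoms[x$atoms$is_polymer, , drop = FALSE]
  if (mode == "CA") {
    ca <- at[at$elety == "CA" & at$element == "C", , drop = FALSE]
    i <- match(res$res_key, ca$res_key)
    if (anyNA(i)) {
      stop("residues lacking a C-alpha atom in CA mode: ",
           paste(res$res_key[is.na(i)], collapse = ", "))
    }
    xyz <- cbind(ca$x[i], ca$y[i], ca$z[i])
  } else {
    xyz <- t(vapply(res$res_key, function(k) {
      residue_com(at[at$res_key == k, , drop = FALSE])
    }, numeric(3)))
  }
  out <- data.frame(chain = res$chain, resno = res$resno, insert = res$insert,
                    resid = res$resid, res_key = res$res_key,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("allonet_beads", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "source") <- x$pdb_id
  out
}

format_pdb_lines <- function(record, eleno, elety, resid, chain, resno,
                             x, y, z, o = 1, b = 0, element = "") {
  name4 <- ifelse(nchar(elety) < 4, sprintf(" %-3s", elety),
                  sprintf("%-4s", elety))
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, name4, resid, chain, resno, x, y, z, o, b, element)
}

#' Write a structure or bead model as PDB text
#'
#' Bead models are written with one pseudo-atom (CA) per residue so they remain
#' readable by standard PDB tools.
#'
#' @param x an `allonet_structure` or `allonet_beads` object.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of PDB lines, invisibly when `path` is given.
#' @export
write_pdb_text <- function(x, path = NULL) {
  if (inherits(x, "allonet_structure")) {
    at <- x$atoms
    lines <- format_pdb_lines(at$type, seq_len(nrow(at)), at$elety, at$resid,
                              at$chain, at$resno, at$x, at$y, at$z, at$o,
                              ifelse(is.na(at$b), 0, at$b), at$element)
  } else if (inherits(x, "allonet_beads")) {
    lines <- format_pdb_lines("ATOM", seq_len(nrow(x)), "CA", x$resid,
                              x$chain, x$resno, x$x, x$y, x$z, element = "C")
  } else stop("unsupported object")
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write a bead model as TSV
#' @param beads an `allonet_beads` object.
#' @param path output file.
#' @export
write_bead_tsv <- function(beads, path) {
  utils::write.table(as.data.frame(beads), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' One-letter sequences per chain
#' @param x an `allonet_structure`.
#' @return named character vector, one sequence per chain.
#' @export
chain_sequences <- function(x) {
  res <- x$residues
  aa1 <- vapply(res$resid, function(r) {
    a <- suppressWarnings(bio3d::aa321(r))
    if (is.na(a)) "X" else a
  }, "")
  vapply(split(aa1, factor(res$chain, levels = unique(res$chain))),
         paste, "", collapse = "")
}

#' @export
print.allonet_structure <- function(x, ...) {
  cat(sprintf("allonet structure '%s': %d chains, %d residues, %d ligands",
              x$pdb_id, length(unique(x$residues$chain)), nrow(x$residues),
              nrow(x$ligands)))
  if (!is.na(x$resolution)) cat(sprintf(", %.2f A", x$resolution))
  cat("\n")
  invisible(x)
}
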