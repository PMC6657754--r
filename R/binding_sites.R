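#' Ligand-binding-site residues
#'
#' Residues with at least one heavy atom within `cutoff` (inclusive) of any
#' heavy atom of the ligand instance.
#'
#' @param x a preprocessed `allonet_structure`.
#' @param ligand_key ligand instance key (`chain|resno|insert`, a row of
#'   `x$ligands$res_key`).
#' @param cutoff contact distance in Angstrom (default 4.0; the stricter 3.0
#'   pocket-similarity convention can be selected instead).
#' @return list of class `allonet_site`: `ligand` (ligand row), `residues`
#'   (character keys), `chains_touched`, `cutoff_used`, `empty` flag.
#' @export
find_binding_site <- function(x, ligand_key, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  lig_row <- x$ligands[x$ligands$res_key == ligand_key, , drop = FALSE]
  if (!nrow(lig_row)) stop("no such ligand instance: ", ligand_key)
  lat <- heavy_atoms(x$atoms[x$atoms$res_key == ligand_key, , drop = FALSE])
  if (!nrow(lat)) stop("ligand has no heavy atoms")
  pat <- polymer_atoms(x)
  lxyz <- as.matrix(lat[, c("x", "y", "z")])
  pxyz <- as.matrix(pat[, c("x", "y", "z")])
  # min distance from each polymer atom to any ligand atom
  d2min <- rep(Inf, nrow(pxyz))
  for (k in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1] - lxyz[k, 1])^2 + (pxyz[, 2] - lxyz[k, 2])^2 +
      (pxyz[, 3] - lxyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  hit <- d2min <= cutoff^2
  residues <- sort(unique(pat$res_key[hit]))
  chains <- sort(unique(pat$chain[hit]))
  structure(list(ligand = lig_row, residues = residues,
                 chains_touched = chains, cutoff_used = cutoff,
                 empty = !length(residues)),
            class = "allonet_site")
}

#' Classify a binding site as multichain or single-chain
#'
#' A site is MBS when at least two chains each contribute at least
#' `min_minor_chain_residues` residues; otherwise SBS.
#'
#' @param site an `allonet_site` from [find_binding_site()].
#' @param min_minor_chain_residues minimum residues a chain must contribute to
#'   count (default 1: any residue from a second chain makes the site MBS).
#' @return `"MBS"` or `"SBS"`.
#' @export
classify_site <- function(site, min_minor_chain_residues = 1) {
  stopifnot(inherits(site, "allonet_site"))
  if (!length(site$residues)) stop("empty binding site cannot be classified")
  ch <- sub("\\|.*", "", site$residues)
  n_per_chain <- table(ch)
  if (sum(n_per_chain >= min_minor_chain_residues) >= 2) "MBS" else "SBS"
}

#' Classify a complex from its classified sites
#'
#' A complex is MBS when any of its binding sites is MBS.
#'
#' @param site_classes character vector of `"MBS"`/`"SBS"` site calls.
#' @return `"MBS"` or `"SBS"`.
#' @export
classify_complex <- function(site_classes) {
  if (!length(site_classes)) stop("no classified sites")
  stopifnot(all(site_classes %in% c("MBS", "SBS")))
  if (any(site_classes == "MBS")) "MBS" else "SBS"
}

#' Assign a ligand's functional role
#'
#' Looks the ligand key up in a table of known allosteric modulators
#' (activator/inhibitor/regulator); ligands absent from the table are
#' classified as orthosteric.
#'
#' @param ligand_key component id or externally supplied chemical key.
#' @param modulator_table data.frame with columns `ligand_key`, `role`
#'   (values among activator/inhibitor/regulator), e.g. from
#'   [read_modulator_table()].
#' @return one of `"activator"`, `"inhibitor"`, `"regulator"`,
#'   `"orthosteric"`.
#' @export
assign_ligand_role <- function(ligand_key, modulator_table) {
  if (is.null(modulator_table) || !nrow(modulator_table)) return("orthosteric")
  stopifnot(all(c("ligand_key", "role") %in% names(modulator_table)))
  i <- match(ligand_key, modulator_table$ligand_key)
  if (is.na(i)) "orthosteric" else modulator_table$role[i]
}

#' Read a modulator table from TSV
#' @param path two-column TSV (`ligand_key`, `role`).
#' @return data.frame.
#' @export
read_modulator_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
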