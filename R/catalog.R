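SYMMETRY_HIERARCHY <- c("Dihedral", "CyclicN", "Cyclic2", "Monomeric",
                        "Asymmetric")

#' Quaternary-structure class of a protein
#'
#' Hierarchical rule over all PDB entries of one protein: heteromer if any
#' entry is heteromeric, else homomer if any entry is homomeric, else monomer.
#'
#' @param quaternary character vector of per-entry classes
#'   (`heteromer`/`homomer`/`monomer`).
#' @return single class label.
#' @export
classify_quaternary <- function(quaternary) {
  if (!length(quaternary)) stop("empty entry list")
  stopifnot(all(quaternary %in% c("heteromer", "homomer", "monomer")))
  if (any(quaternary == "heteromer")) return("heteromer")
  if (any(quaternary == "homomer")) return("homomer")
  "monomer"
}

#' Aggregate per-entry symmetry labels
#'
#' Returns the highest-ranked label present under the hierarchy
#' Dihedral > CyclicN > Cyclic2 > Monomeric > Asymmetric.
#'
#' @param symmetries character vector of per-entry symmetry labels.
#' @return single label.
#' @export
aggregate_symmetry <- function(symmetries) {
  if (!length(symmetries)) stop("empty symmetry list")
  unknown <- setdiff(symmetries, SYMMETRY_HIERARCHY)
  if (length(unknown)) {
    stop("unknown symmetry label(s): ", paste(unknown, collapse = ", "))
  }
  SYMMETRY_HIERARCHY[min(match(symmetries, SYMMETRY_HIERARCHY))]
}

#' Select the representative entry of a complex
#'
#' Decision tree: restrict to entries with resolution better than 2.8 A (the
#' filter is skipped when none qualify); then the entry with the largest
#' number of proteins and chains; then the largest ligand (most heavy atoms);
#' then the best (smallest) resolution; remaining ties broken by `pdb_id`.
#'
#' @param entries data.frame with columns `pdb_id`, `resolution`,
#'   `n_proteins`, `n_chains`, `largest_ligand_atoms`.
#' @param resolution_limit strict upper bound in Angstrom.
#' @return the selected row of `entries`.
#' @export
select_representative <- function(entries, resolution_limit = 2.8) {
  if (!nrow(entries)) stop("empty entry list")
  ok <- !is.na(entries$resolution) & entries$resolution < resolution_limit
  if (any(ok)) entries <- entries[ok, , drop = FALSE]
  o <- order(-entries$n_proteins, -entries$n_chains,
             -entries$largest_ligand_atoms, entries$resolution,
             entries$pdb_id)
  entries[o[1], , drop = FALSE]
}

#' Pair apo and holo entries of the same study
#'
#' Within each `study_id`, every apo entry (no ligand) is paired with holo
#' entries (ligand present) subject to the printed rules: both resolutions
#' strictly better than 2.8 A, identical chain counts, structure sequence
#' lengths differing by at most 10% of the apo length, and at most one holo
#' structure per ligand role per apo.
#'
#' @param entries data.frame with columns `pdb_id`, `study_id`, `has_ligand`,
#'   `resolution`, `n_chains`, `seq_length`, and for holo entries
#'   `ligand_role` (orthosteric/activator/inhibitor/regulator) plus the
#'   [select_representative()] columns.
#' @param resolution_limit strict bound in Angstrom.
#' @param max_length_diff maximum |len_holo - len_apo| / len_apo.
#' @return data.frame of pairs (`study_id`, `apo_id`, `holo_id`,
#'   `ligand_role`); zero rows when nothing qualifies.
#' @export
pair_apo_holo <- function(entries, resolution_limit = 2.8,
                          max_length_diff = 0.10) {
  stopifnot(all(c("pdb_id", "study_id", "has_ligand", "resolution",
                  "n_chains", "seq_length") %in% names(entries)))
  if (!"ligand_role" %in% names(entries)) entries$ligand_role <- "orthosteric"
  out <- list()
  ok_res <- !is.na(entries$resolution) & entries$resolution < resolution_limit
  entries <- entries[ok_res, , drop = FALSE]
  for (sid in unique(entries$study_id)) {
    e <- entries[entries$study_id == sid, , drop = FALSE]
    apo <- e[!e$has_ligand, , drop = FALSE]
    holo <- e[e$has_ligand, , drop = FALSE]
    if (!nrow(apo) || !nrow(holo)) next
    a <- if (nrow(apo) > 1) select_representative(apo) else apo
    for (role in unique(holo$ligand_role)) {
      h <- holo[holo$ligand_role == role, , drop = FALSE]
      h <- if (nrow(h) > 1) select_representative(h) else h
      if (h$n_chains != a$n_chains) next
      if (abs(h$seq_length - a$seq_length) / a$seq_length > max_length_diff) next
      out[[length(out) + 1]] <- data.frame(
        study_id = sid, apo_id = a$pdb_id, holo_id = h$pdb_id,
        ligand_role = role, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(study_id = character(), apo_id = character(),
                      holo_id = character(), ligand_role = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
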