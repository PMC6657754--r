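#' Map per-position scores onto structure residues
#'
#' Globally aligns the structure-derived sequence to the reference sequence
#' the scores were computed on (BLOSUM62, affine gaps) and carries each
#' reference position's score over to the aligned structure position.
#' Structure positions aligned to reference gaps (insertions) carry no score;
#' aligned positions whose residues differ still inherit the reference score
#' but are flagged as mismatches.
#'
#' @param structure_seq one-letter sequence derived from coordinates (see
#'   [chain_sequences()]).
#' @param full_seq reference sequence the scores index into.
#' @param scores numeric vector, one value per reference position; scores are
#'   conventionally 1/rate so larger means more conserved.
#' @param min_identity minimum alignment identity; below it the pairing is
#'   considered wrong and an error is thrown.
#' @param gap_opening,gap_extension affine gap penalties (score units).
#' @return data.frame of class `allonet_track`: `structure_pos`, `ref_pos`
#'   (`NA` for insertions), `structure_aa`, `ref_aa`, `score`, `mismatch`;
#'   attribute `coverage` is the scored fraction of structure positions.
#' @export
map_scores_to_structure <- function(structure_seq, full_seq, scores,
                                    min_identity = 0.30,
                                    gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(structure_seq) || !nzchar(full_seq)) stop("empty sequence")
  if (!length(scores)) stop("empty score list")
  if (length(scores) != nchar(full_seq)) {
    stop("scores must have one value per reference position")
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for sequence mapping")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(structure_seq), Biostrings::AAString(full_seq),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  aligned <- pat != "-" & sub != "-"
  identity <- sum(pat == sub & aligned) / sum(pat != "-")
  if (identity < min_identity) {
    stop(sprintf("alignment identity %.2f below %.2f: likely wrong pairing",
                 identity, min_identity))
  }
  spos <- cumsum(pat != "-")
  rpos <- cumsum(sub != "-")
  keep <- pat != "-"
  out <- data.frame(
    structure_pos = spos[keep],
    ref_pos = ifelse(sub[keep] != "-", rpos[keep], NA_integer_),
    structure_aa = pat[keep],
    ref_aa = ifelse(sub[keep] != "-", sub[keep], NA_character_),
    stringsAsFactors = FALSE, row.names = NULL)
  out$score <- ifelse(is.na(out$ref_pos), NA_real_, scores[out$ref_pos])
  out$mismatch <- !is.na(out$ref_aa) & out$ref_aa != out$structure_aa
  attr(out, "coverage") <- mean(!is.na(out$score))
  attr(out, "identity") <- identity
  class(out) <- c("allonet_track", "data.frame")
  out
}

#' Standardize evolutionary-coupling scores within domains
#'
#' Divides every residue-pair coupling score by the standard deviation of the
#' scores within its domain, correcting for between-domain scale differences.
#' Applied exactly once: tables already standardized are refused.
#'
#' @param couplings data.frame with columns `domain`, `pos_i`, `pos_j`,
#'   `score`.
#' @return the table with an added `score_std` column and attribute
#'   `standardized = TRUE`.
#' @export
standardize_couplings <- function(couplings) {
  stopifnot(all(c("domain", "pos_i", "pos_j", "score") %in% names(couplings)))
  if (isTRUE(attr(couplings, "standardized"))) {
    stop("couplings are already standardized")
  }
  n_per <- table(couplings$domain)
  if (any(n_per < 2)) {
    stop("domain(s) with fewer than 2 pairs: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  sds <- tapply(couplings$score, couplings$domain, stats::sd)
  if (any(sds == 0)) {
    stop("zero score SD in domain(s): ",
         paste(names(sds)[sds == 0], collapse = ", "))
  }
  couplings$score_std <- couplings$score / as.numeric(sds[couplings$domain])
  attr(couplings, "standardized") <- TRUE
  couplings
}

#' Read a two-column score TSV (position, value)
#' @param path file path.
#' @return numeric vector indexed by position.
#' @export
read_score_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stats::setNames(tab[[2]], tab[[1]])
}
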