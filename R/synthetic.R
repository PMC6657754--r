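# Synthetic two-chain bead complexes with planted rigid clusters.
#
# Each chain is a compact "main" cluster (2 x 2 x k lattice of residues,
# 4 A spacing) plus a 6-residue interface plate, joined by a thin layer of
# contacts that forms the planted community boundary (and the seat of the
# critical residues). The two chains are related by an exact C2 rotation
# about z. In the apo form of both pocket modes the inter-chain seam is
# packed: the two plates form one rigid unit spanning the chains. Ligand
# binding at an interface (MBS) pocket sits in the seam and keeps it
# locked, whereas binding at a single-chain (SBS) pocket on the outer face
# of each main cluster releases the seam, decoupling the subunits — the
# planted apo-holo class contrast.
# Residues are written as alternating GLY/ALA with idealized N/CA/C/O(/CB)
# local geometry so both CA and center-of-mass coarse-graining, SASA and
# contact detection are well defined.

# local heavy-atom offsets (A) from the residue center
RES_ATOM_OFFSETS <- list(
  N  = c(-1.2,  0.9,  0.0),
  CA = c( 0.0,  0.0,  0.4),
  C  = c( 1.2,  0.9,  0.0),
  O  = c( 1.4, -0.8, -0.3),
  CB = c(-0.3, -1.1,  1.1))

LATTICE_SPACING <- 4.0
SEAM_GAP_OPEN <- 9.5     # A; released seam: ENM-coupled but no contacts
SEAM_GAP_CLOSED <- 3.6   # A; packed seam: plates in contact across chains

# evaluate expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic complex
#'
#' @param n_chains number of chains (the generator produces C2 dimers).
#' @param residues_per_chain total residues per chain; 6 form the interface
#'   plate and the rest (>= 8, a multiple of 4) the main cluster, so valid
#'   values are 14, 18, 22, ...
#' @param cluster_spacing gap (A) between the main cluster face and the
#'   interface plate within a chain; at the default the two are joined by a
#'   thin layer of contacts, giving the planted community boundary.
#' @param intra_cluster_jitter SD (A) of the isotropic jitter applied to
#'   residue centers.
#' @param pocket_mode `"interface"` (ligand spans the chain seam; MBS ground
#'   truth) or `"single_chain"` (one ligand copy per chain; SBS).
#' @param holo include the ligand and the pocket stiffening atoms; in
#'   single-chain mode the holo form additionally releases the inter-chain
#'   seam. `FALSE` gives the apo form, whose seam is packed in both modes.
#' @param holo_stiffening number of extra pocket-facing side-chain atoms per
#'   pocket residue in the holo form (0 disables).
#' @param seed integer; fully determines the output.
#' @return list of class `allonet_synth_spec`.
#' @export
synthetic_spec <- function(n_chains = 2, residues_per_chain = 14,
                           cluster_spacing = 7.0, intra_cluster_jitter = 0.3,
                           pocket_mode = c("interface", "single_chain"),
                           holo = TRUE, holo_stiffening = 1, seed = 1) {
  pocket_mode <- match.arg(pocket_mode)
  if (n_chains != 2) stop("the generator produces C2 dimers (n_chains = 2)")
  if (residues_per_chain < 14 || (residues_per_chain - 6) %% 4 != 0) {
    stop("residues_per_chain must be 6 + a multiple of 4, at least 14")
  }
  if (cluster_spacing < 5) stop("infeasible geometry: clusters would overlap")
  structure(list(n_chains = n_chains,
                 residues_per_chain = residues_per_chain,
                 cluster_spacing = cluster_spacing,
                 intra_cluster_jitter = intra_cluster_jitter,
                 pocket_mode = pocket_mode, holo = holo,
                 holo_stiffening = holo_stiffening, seed = seed),
            class = "allonet_synth_spec")
}

# residue centers of one chain in its local frame (plate face towards +x).
# The main cluster is a compact 2 x 2 x k lattice; the interface plate is a
# 2 x 3 sheet flat against the seam.
chain_template <- function(spec) {
  n_main <- spec$residues_per_chain - 6
  k <- n_main / 4
  main <- expand.grid(z = c(-2, 2), y = c(-2, 2),
                      x = LATTICE_SPACING * (seq_len(k) - 1))[, c("x", "y", "z")]
  plate_x <- LATTICE_SPACING * (k - 1) + spec$cluster_spacing
  plate <- expand.grid(z = c(-4, 0, 4), y = c(-2, 2),
                       x = plate_x)[, c("x", "y", "z")]
  centers <- rbind(main, plate)
  cluster <- c(rep(1L, n_main), rep(2L, 6))
  list(centers = as.matrix(centers), cluster = cluster, plate_x = plate_x,
       n_main = n_main)
}

rot_c2_z <- function(xyz) cbind(-xyz[, 1], -xyz[, 2], xyz[, 3])

ligand_atoms <- function(center) {
  off <- rbind(c(0, 0, 0), c(1.2, 0, 0.4), c(-1.2, 0, 0.4),
               c(0, 1.2, -0.4), c(0, -1.2, -0.4))
  ele <- c("C", "C", "O", "N", "C")
  nm <- c("C1", "C2", "O1", "N1", "C3")
  list(xyz = sweep(off, 2, center, "+"), element = ele, name = nm)
}

#' Generate a synthetic complex with known ground truth
#'
#' @param spec an `allonet_synth_spec` from [synthetic_spec()].
#' @return list: `pdb` (character vector of PDB lines) and `truth`
#'   (`residue_cluster` named by residue key, `expected_site_class`,
#'   `expected_mcc_clusters`, `pocket_residues`, `pocket_mode`, `holo`,
#'   `seed`).
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "allonet_synth_spec"))
  tpl <- chain_template(spec)
  seam_closed <- !spec$holo || spec$pocket_mode == "interface"
  seam <- if (seam_closed) SEAM_GAP_CLOSED else SEAM_GAP_OPEN
  # global frame: chain A plate face at x = -seam/2, chain B is C2(z) image
  shiftA <- -(tpl$plate_x + seam / 2)
  n_res <- nrow(tpl$centers)
  jitter <- with_seed(spec$seed,
                      matrix(stats::rnorm(n_res * 3,
                                          sd = spec$intra_cluster_jitter),
                             ncol = 3))
  centersA <- tpl$centers
  centersA[, 1] <- centersA[, 1] + shiftA
  centersA <- centersA + jitter
  # chain B is the exact C2 image of chain A (jitter included), so the
  # complex has exact two-fold symmetry
  centersB <- rot_c2_z(centersA)
  centers <- rbind(centersA, centersB)
  chain <- rep(c("A", "B"), each = n_res)
  resno <- rep(seq_len(n_res), 2)
  cluster <- c(tpl$cluster, tpl$cluster + 2L)
  res_key <- paste(chain, resno, "", sep = "|")

  # pocket definition and ligand placement
  if (spec$pocket_mode == "interface") {
    pocket <- which(cluster %in% c(2L, 4L))       # both interface plates
    lig_centers <- matrix(c(0, 0, 6.0), ncol = 3) # above the seam middle
    lig_chain <- "A"
  } else {
    faceA <- which(cluster == 1L & tpl$centers[, 1][resno] <= 1e-9 &
                     chain == "A")
    pocket <- c(faceA, which(chain == "B")[faceA])  # C2 image on chain B
    cA <- c(shiftA - 3.5, 0, 0)
    lig_centers <- rbind(cA, c(-cA[1], 0, 0))
    lig_chain <- c("A", "B")
  }
  pocket_dirs <- pocket_directions(centers, pocket, spec, lig_centers)

  # chain A atoms are built explicitly; chain B (and its ligand copy in
  # single-chain mode) is the exact C2(z) image of every chain A atom, so
  # the complex is two-fold symmetric at atomic resolution
  recs_A <- list()
  for (i in which(chain == "A")) {
    resid <- if (resno[i] %% 2 == 1) "GLY" else "ALA"
    atoms <- RES_ATOM_OFFSETS[if (resid == "GLY") 1:4 else 1:5]
    for (nm in names(atoms)) {
      recs_A[[length(recs_A) + 1]] <- list(
        rec = "ATOM", name = nm, resid = resid, chain = "A",
        resno = resno[i], xyz = centers[i, ] + atoms[[nm]],
        element = substr(nm, 1, 1))
    }
    if (spec$holo && spec$holo_stiffening > 0 && i %in% pocket) {
      for (s in seq_len(spec$holo_stiffening)) {
        recs_A[[length(recs_A) + 1]] <- list(
          rec = "ATOM", name = paste0("CG", s), resid = resid, chain = "A",
          resno = resno[i],
          xyz = centers[i, ] + (1.5 + 0.8 * (s - 1)) *
            pocket_dirs[[as.character(i)]],
          element = "C")
      }
    }
  }
  if (spec$holo && spec$pocket_mode == "single_chain") {
    lg <- ligand_atoms(lig_centers[1, ])
    for (k in seq_along(lg$name)) {
      recs_A[[length(recs_A) + 1]] <- list(
        rec = "HETATM", name = lg$name[k], resid = "LIG", chain = "A",
        resno = 900L, xyz = lg$xyz[k, ], element = lg$element[k])
    }
  }
  recs_B <- lapply(recs_A, function(r) {
    r$chain <- "B"
    r$xyz <- c(-r$xyz[1], -r$xyz[2], r$xyz[3])
    r
  })
  records <- c(recs_A, recs_B)
  if (spec$holo && spec$pocket_mode == "interface") {
    lg <- ligand_atoms(lig_centers[1, ])
    for (k in seq_along(lg$name)) {
      records[[length(records) + 1]] <- list(
        rec = "HETATM", name = lg$name[k], resid = "LIG", chain = "A",
        resno = 900L, xyz = lg$xyz[k, ], element = lg$element[k])
    }
  }
  lines <- vapply(seq_along(records), function(k) {
    r <- records[[k]]
    format_pdb_lines(r$rec, k, r$name, r$resid, r$chain, r$resno,
                     r$xyz[1], r$xyz[2], r$xyz[3], element = r$element)
  }, "")
  lines <- c(sprintf("%-62sSYNT", "HEADER    SYNTHETIC COMPLEX"),
             "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.", lines, "END")

  planted <- cluster
  expected_mcc <- integer()
  if (seam_closed) {
    planted[planted == 4L] <- 2L   # the packed plates form one community
    expected_mcc <- 2L
  }
  truth <- list(residue_cluster = stats::setNames(planted, res_key),
                chains = stats::setNames(chain, res_key),
                pocket_residues = res_key[pocket],
                expected_site_class =
                  if (spec$pocket_mode == "interface") "MBS" else "SBS",
                expected_mcc_clusters = expected_mcc,
                pocket_mode = spec$pocket_mode, holo = spec$holo,
                seed = spec$seed)
  list(pdb = lines, truth = truth)
}

# unit vectors from each pocket residue towards the nearest ligand center
pocket_directions <- function(centers, pocket, spec, lig_centers) {
  out <- list()
  for (i in pocket) {
    d <- sqrt(rowSums(sweep(lig_centers, 2, centers[i, ])^2))
    v <- lig_centers[which.min(d), ] - centers[i, ]
    out[[as.character(i)]] <- v / sqrt(sum(v^2))
  }
  out
}

#' Generate a cohort of synthetic complexes
#'
#' Per-complex seeds are derived deterministically from the master seed, so
#' the same call always reproduces the same files.
#'
#' @param n_mbs,n_sbs number of interface-pocket and single-chain-pocket
#'   complexes (each >= 1).
#' @param dir output directory (created if needed).
#' @param base_spec template [synthetic_spec()]; its `pocket_mode`,
#'   `residues_per_chain` and `seed` are overridden per complex.
#' @param seed master seed.
#' @param size_cycle chain sizes cycled over the cohort, so complexes vary
#'   in size as real cohorts do (`NULL` keeps `base_spec`'s size).
#' @return manifest data.frame (`id`, `file`, `pocket_mode`,
#'   `expected_site_class`, `seed`), invisibly written to
#'   `manifest.tsv`/`manifest.json` in `dir` alongside the PDB files.
#' @export
generate_cohort <- function(n_mbs, n_sbs, dir, base_spec = synthetic_spec(),
                            seed = 1, size_cycle = c(14, 18)) {
  if (n_mbs < 1 || n_sbs < 1) stop("need at least one complex of each class")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modes <- c(rep("interface", n_mbs), rep("single_chain", n_sbs))
  if (is.null(size_cycle)) size_cycle <- base_spec$residues_per_chain
  manifest <- data.frame(id = sprintf("synth%03d", seq_along(modes)),
                         file = sprintf("synth%03d.pdb", seq_along(modes)),
                         pocket_mode = modes,
                         expected_site_class = ifelse(modes == "interface",
                                                      "MBS", "SBS"),
                         residues_per_chain =
                           rep_len(size_cycle, length(modes)),
                         seed = (seed + 7919L * seq_along(modes)) %% 2147483647L,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    sp <- base_spec
    sp$pocket_mode <- manifest$pocket_mode[i]
    sp$residues_per_chain <- manifest$residues_per_chain[i]
    sp$seed <- manifest$seed[i]
    out <- generate_complex(sp)
    writeLines(out$pdb, file.path(dir, manifest$file[i]))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}

#' Generate synthetic apo-holo pairs
#'
#' Every pair shares one geometry seed, so apo and holo coordinates
#' correspond residue by residue; the holo form adds the ligand and pocket
#' stiffening and, in interface mode, closes the chain seam. A planted class
#' effect follows: ligand binding changes the community structure across
#' chains only in interface (MBS) pockets.
#'
#' @param n_mbs,n_sbs number of orthosteric/activator pairs per class.
#' @param n_inhibitor additional pairs labelled `inhibitor` (alternating
#'   class); these are meant to exercise the exclusion rule of the apo-holo
#'   ANCOVA.
#' @param dir output directory.
#' @param base_spec template [synthetic_spec()].
#' @param seed master seed.
#' @return pairs data.frame (`study_id`, `apo_id`, `holo_id`, `apo_file`,
#'   `holo_file`, `ligand_role`, `pocket_mode`), also written to
#'   `pairs.tsv` in `dir`.
#' @export
generate_apo_holo_pairs <- function(n_mbs, n_sbs, n_inhibitor = 0, dir,
                                    base_spec = synthetic_spec(), seed = 1,
                                    size_cycle = c(14, 18)) {
  if (n_mbs < 1 || n_sbs < 1) stop("need at least one pair of each class")
  modes <- c(rep("interface", n_mbs), rep("single_chain", n_sbs),
             rep_len(c("interface", "single_chain"), n_inhibitor))
  roles <- c(rep_len(c("orthosteric", "activator"), n_mbs + n_sbs),
             rep("inhibitor", n_inhibitor))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(size_cycle)) size_cycle <- base_spec$residues_per_chain
  pairs <- data.frame(study_id = sprintf("study%03d", seq_along(modes)),
                      apo_id = sprintf("pair%03d_apo", seq_along(modes)),
                      holo_id = sprintf("pair%03d_holo", seq_along(modes)),
                      apo_file = sprintf("pair%03d_apo.pdb", seq_along(modes)),
                      holo_file = sprintf("pair%03d_holo.pdb", seq_along(modes)),
                      ligand_role = roles, pocket_mode = modes,
                      residues_per_chain = rep_len(size_cycle, length(modes)),
                      seed = (seed + 104729L * seq_along(modes)) %% 2147483647L,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    sp <- base_spec
    sp$pocket_mode <- pairs$pocket_mode[i]
    sp$residues_per_chain <- pairs$residues_per_chain[i]
    sp$seed <- pairs$seed[i]
    sp$holo <- FALSE
    writeLines(generate_complex(sp)$pdb, file.path(dir, pairs$apo_file[i]))
    sp$holo <- TRUE
    writeLines(generate_complex(sp)$pdb, file.path(dir, pairs$holo_file[i]))
  }
  utils::write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(pairs)
}
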