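#' Pipeline configuration
#'
#' All tunable parameters of the analysis in one place, with the package
#' defaults: residue center-of-mass coarse-graining, 4.0 A binding-site
#' contacts, 15 A elastic-network springs, 4.5 A residue-contact edges, all
#' nontrivial modes, the >10% multichain-community rule, minimum community
#' size 5 and a 1.4 A solvent probe.
#'
#' @param mode coarse-graining mode, `"COM"` or `"CA"`.
#' @param cutoff_bs binding-site contact cutoff (A).
#' @param cutoff_enm elastic-network spring cutoff (A).
#' @param contact_cutoff residue-contact edge cutoff (A).
#' @param n_modes modes retained (`NULL`: all nontrivial up to 2000 beads).
#' @param mcc_threshold tau of the multichain-community rule.
#' @param min_community_size communities smaller than this are merged.
#' @param min_minor_chain_residues MBS rule minor-chain minimum.
#' @param probe solvent probe radius (A).
#' @param n_points SASA quadrature points per atom.
#' @param seed seed for any stochastic downstream step.
#' @return list of class `allonet_config`.
#' @export
allonet_config <- function(mode = c("COM", "CA"), cutoff_bs = 4.0,
                           cutoff_enm = 15, contact_cutoff = 4.5,
                           n_modes = NULL, mcc_threshold = 0.10,
                           min_community_size = 5,
                           min_minor_chain_residues = 1,
                           probe = 1.4, n_points = 960, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(cutoff_bs > 0, cutoff_enm > 0, contact_cutoff > 0,
            mcc_threshold >= 0, mcc_threshold <= 0.5)
  structure(list(mode = mode, cutoff_bs = cutoff_bs, cutoff_enm = cutoff_enm,
                 contact_cutoff = contact_cutoff, n_modes = n_modes,
                 mcc_threshold = mcc_threshold,
                 min_community_size = min_community_size,
                 min_minor_chain_residues = min_minor_chain_residues,
                 probe = probe, n_points = n_points, seed = seed),
            class = "allonet_config")
}

stage <- function(name, id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] stage '%s' failed: %s", id, name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Analyze one complex end to end
#'
#' Runs parse, preprocess, coarse-grain, elastic-network modes, residue
#' cross-correlations, contact-network construction, community detection,
#' critical-residue identification, multichain-community classification,
#' surface/interface metrics and binding-site classification, and returns
#' everything in one classed object. Deterministic for a fixed configuration.
#'
#' @param pdb path to a PDB file, PDB text, or an `allonet_structure`.
#' @param config an [allonet_config()].
#' @param modulator_table optional table mapping ligand component ids to
#'   allosteric roles (see [assign_ligand_role()]).
#' @return object of class `allonet_analysis`: `summary` (one-row
#'   data.frame), `per_residue` table, plus the intermediate `structure`,
#'   `beads`, `correlations`, `graph`, `partition`, `critical`, `areas`,
#'   `sites` and the `config`.
#' @export
analyze_complex <- function(pdb, config = allonet_config(),
                            modulator_table = NULL) {
  if (inherits(pdb, "allonet_structure")) {
    x <- pdb
  } else if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    x <- stage("parse", pdb, read_structure(pdb))
  } else {
    x <- stage("parse", "text", parse_structure(pdb))
  }
  id <- x$pdb_id
  x <- stage("preprocess", id, preprocess(x))
  beads <- stage("coarse_grain", id, coarse_grain(x, config$mode))
  enm <- stage("elastic_network", id,
               build_hessian(beads, cutoff_enm = config$cutoff_enm))
  modes <- stage("normal_modes", id, normal_modes(enm, config$n_modes))
  C <- stage("correlations", id, cross_correlations(modes))
  g <- stage("contact_network", id,
             build_network(x, beads, C, config$contact_cutoff))
  part <- stage("communities", id,
                detect_communities(g, config$min_community_size,
                                   config$mcc_threshold))
  crit <- stage("critical_residues", id, find_critical_residues(g, part))
  areas <- stage("surfaces", id,
                 interface_area(x, config$probe, config$n_points))
  iface <- stage("interface_residues", id,
                 interface_residues(x, probe = config$probe,
                                    n_points = config$n_points))
  sites <- stage("binding_sites", id, lapply(x$ligands$res_key, function(k) {
    s <- find_binding_site(x, k, config$cutoff_bs)
    cls <- if (s$empty) NA_character_ else
      classify_site(s, config$min_minor_chain_residues)
    role <- assign_ligand_role(
      x$ligands$het_code[x$ligands$res_key == k], modulator_table)
    list(site = s, class = cls, role = role)
  }))
  site_classes <- vapply(sites, function(s)
    if (is.na(s$class)) "SBS" else s$class, "")
  site_class <- if (length(site_classes)) classify_complex(site_classes)
                else NA_character_
  summ <- summarize_complex(part, crit, iface)
  summary <- data.frame(
    pdb_id = id, mode = config$mode, site_class = site_class,
    n_chains = length(unique(x$residues$chain)),
    n_residues = nrow(x$residues), n_ligands = nrow(x$ligands),
    n_communities = summ$n_communities, n_mcc = summ$n_mcc,
    has_mcc = summ$has_mcc,
    mcc_residue_fraction = summ$mcc_residue_fraction,
    n_critical = summ$n_critical,
    critical_in_interface_fraction = summ$critical_in_interface_fraction,
    I = areas$I, S = areas$S, rho = areas$rho,
    stringsAsFactors = FALSE)
  memb <- part$membership[beads$res_key]
  per_residue <- data.frame(
    chain = beads$chain, resno = beads$resno, insert = beads$insert,
    resid = beads$resid, res_key = beads$res_key,
    community = unname(memb),
    is_mcc = unname(part$is_mcc[as.character(memb)]),
    is_critical = beads$res_key %in% crit$residues,
    is_interface = beads$res_key %in% iface,
    stringsAsFactors = FALSE)
  structure(list(summary = summary, per_residue = per_residue,
                 structure = x, beads = beads, correlations = C, graph = g,
                 partition = part, critical = crit, areas = areas,
                 sites = sites, config = config),
            class = "allonet_analysis")
}

#' Analyze a cohort and compare MBS vs SBS complexes
#'
#' Analyzes every PDB file in `dir` and, when both binding-site classes are
#' present, reports the class comparisons: Wilcoxon rank-sum tests on the
#' fraction of residues in multichain communities and on the fraction of
#' critical residues in interfaces, a test of proportions on the presence of
#' any multichain community, and a covariate summary of the metrics against
#' relative interface area rho.
#'
#' @param dir directory of PDB files.
#' @param config an [allonet_config()].
#' @param alternative alternative hypothesis for the class comparisons
#'   (`"greater"` tests MBS > SBS).
#' @param modulator_table optional, see [analyze_complex()].
#' @return list of class `allonet_cohort`: `summaries` (one row per
#'   complex), `stats` (list of test results, `NULL` for single-class
#'   cohorts).
#' @export
run_cohort <- function(dir, config = allonet_config(),
                       alternative = "two.sided", modulator_table = NULL) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  if (!length(files)) stop("no PDB files in ", dir)
  summaries <- do.call(rbind, lapply(sort(files), function(f) {
    s <- analyze_complex(f, config, modulator_table)$summary
    s$file <- basename(f)
    s
  }))
  cls <- summaries$site_class
  stats_out <- NULL
  if (length(unique(stats::na.omit(cls))) < 2) {
    warning("cohort contains a single binding-site class; ",
            "comparative statistics skipped")
  } else {
    mbs <- summaries[cls %in% "MBS", , drop = FALSE]
    sbs <- summaries[cls %in% "SBS", , drop = FALSE]
    cif_mbs <- stats::na.omit(mbs$critical_in_interface_fraction)
    cif_sbs <- stats::na.omit(sbs$critical_in_interface_fraction)
    stats_out <- list(
      mcc_fraction = wilcoxon_rank_sum(mbs$mcc_residue_fraction,
                                       sbs$mcc_residue_fraction,
                                       alternative = alternative),
      critical_in_interface = if (length(cif_mbs) && length(cif_sbs)) {
        wilcoxon_rank_sum(cif_mbs, cif_sbs, alternative = alternative)
      },
      has_mcc = test_proportions(sum(mbs$has_mcc), nrow(mbs),
                                 sum(sbs$has_mcc), nrow(sbs),
                                 alternative = if (alternative == "two.sided")
                                   "two.sided" else "greater"),
      rho_covariate = summarize_rho_covariate(summaries))
  }
  structure(list(summaries = summaries, stats = stats_out, config = config),
            class = "allonet_cohort")
}

summarize_rho_covariate <- function(summaries) {
  out <- lapply(c("mcc_residue_fraction", "critical_in_interface_fraction"),
                function(metric) {
    ok <- !is.na(summaries[[metric]]) & !is.na(summaries$rho)
    if (sum(ok) < 4 ||
        length(unique(summaries$site_class[ok])) < 2 ||
        stats::var(summaries$rho[ok]) == 0) {
      return(NULL)
    }
    # synthetic cohorts can sit exactly on the fitted plane; the perfect-fit
    # warning from the F machinery is expected there
    fit <- suppressWarnings(
      ancova(summaries[[metric]][ok], summaries$rho[ok],
             factor(summaries$site_class[ok], c("SBS", "MBS"))))
    data.frame(metric = metric, slope_rho = fit$coefficients[["slope"]],
               class_offset = fit$coefficients[["group_offset"]],
               p_class = fit$p_value, n = fit$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Apo-holo comparison with a planted-class ANCOVA
#'
#' For every pair the apo and holo structures are analyzed in both CA and COM
#' modes; per mode, the holo fraction of residues in multichain communities
#' is modelled as `holo ~ apo + class` (ordinary ANCOVA), excluding pairs
#' whose holo ligand has the inhibitor role. The binding-site class of each
#' pair is taken from the analysis of its holo structure.
#'
#' @param pairs data.frame with columns `apo_file`, `holo_file`,
#'   `ligand_role` (e.g. from [generate_apo_holo_pairs()] or
#'   [pair_apo_holo()] joined to files).
#' @param dir directory holding the structure files.
#' @param config an [allonet_config()]; both modes are run regardless of
#'   `config$mode`.
#' @param modulator_table optional, see [analyze_complex()].
#' @return list of class `allonet_apo_holo`: `pairs` (per-pair fractions per
#'   mode and class), `ancova` (per-mode `allonet_ancova` results),
#'   `excluded_rows`.
#' @export
run_apo_holo <- function(pairs, dir, config = allonet_config(),
                         modulator_table = NULL) {
  if (!nrow(pairs)) stop("empty pair table")
  stopifnot(all(c("apo_file", "holo_file", "ligand_role") %in% names(pairs)))
  missing <- c(pairs$apo_file, pairs$holo_file)
  missing <- missing[!file.exists(file.path(dir, missing))]
  if (length(missing)) {
    stop("structure file(s) not found: ", paste(missing, collapse = ", "))
  }
  res <- list()
  for (mode in c("COM", "CA")) {
    cfg <- config
    cfg$mode <- mode
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      apo <- analyze_complex(file.path(dir, pairs$apo_file[i]), cfg,
                             modulator_table)
      holo <- analyze_complex(file.path(dir, pairs$holo_file[i]), cfg,
                              modulator_table)
      data.frame(apo_file = pairs$apo_file[i],
                 holo_file = pairs$holo_file[i],
                 ligand_role = pairs$ligand_role[i],
                 class = holo$summary$site_class, mode = mode,
                 apo_fraction = apo$summary$mcc_residue_fraction,
                 holo_fraction = holo$summary$mcc_residue_fraction,
                 stringsAsFactors = FALSE)
    })
    res[[mode]] <- do.call(rbind, rows)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  fits <- lapply(stats::setNames(nm = c("COM", "CA")), function(mode) {
    d <- tab[tab$mode == mode, , drop = FALSE]
    ancova(d$holo_fraction, d$apo_fraction,
           factor(d$class, c("SBS", "MBS")),
           exclude = d$ligand_role == "inhibitor")
  })
  structure(list(pairs = tab, ancova = fits,
                 excluded_rows = fits$COM$excluded_rows),
            class = "allonet_apo_holo")
}

#' @export
print.allonet_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("allonet analysis of '%s' (%s mode)\n", s$pdb_id, s$mode))
  cat(sprintf("  %d chains, %d residues, %d ligand(s), site class: %s\n",
              s$n_chains, s$n_residues, s$n_ligands, s$site_class))
  cat(sprintf("  %d communities (%d multichain), MCC residue fraction %.3f\n",
              s$n_communities, s$n_mcc, s$mcc_residue_fraction))
  cat(sprintf("  %d critical residue(s), fraction in interfaces: %s\n",
              s$n_critical,
              ifelse(is.na(s$critical_in_interface_fraction), "NA",
                     sprintf("%.3f", s$critical_in_interface_fraction))))
  cat(sprintf("  interface I = %.1f A^2, surface S = %.1f A^2, rho = %.4f\n",
              s$I, s$S, s$rho))
  invisible(x)
}

#' @export
summary.allonet_analysis <- function(object, ...) object$summary

#' Plot the residue cross-correlation matrix with community blocks
#' @param x an `allonet_analysis`.
#' @param ... passed to [graphics::image()].
#' @export
plot.allonet_analysis <- function(x, ...) {
  C <- unclass(x$correlations)
  o <- order(x$partition$membership[x$beads$res_key])
  graphics::image(seq_len(nrow(C)), seq_len(ncol(C)), C[o, o],
                  zlim = c(-1, 1), xlab = "residue (community order)",
                  ylab = "residue (community order)",
                  main = "residue cross-correlations", ...)
  b <- cumsum(rle(as.vector(x$partition$membership[x$beads$res_key][o]))$lengths)
  graphics::abline(h = b + 0.5, v = b + 0.5, col = "grey30")
  invisible(x)
}

#' @export
print.allonet_cohort <- function(x, ...) {
  cat(sprintf("allonet cohort: %d complexes (%d MBS, %d SBS)\n",
              nrow(x$summaries), sum(x$summaries$site_class %in% "MBS"),
              sum(x$summaries$site_class %in% "SBS")))
  if (!is.null(x$stats)) {
    cat(sprintf("  MCC fraction Wilcoxon p = %.3g; has-MCC proportion test p = %.3g\n",
                x$stats$mcc_fraction$p_value, x$stats$has_mcc$p_value))
  }
  invisible(x)
}

#' @export
print.allonet_apo_holo <- function(x, ...) {
  cat(sprintf("apo-holo comparison: %d pairs, %d excluded (inhibitor role)\n",
              nrow(x$pairs) / 2, x$excluded_rows))
  for (mode in names(x$ancova)) {
    f <- x$ancova[[mode]]
    cat(sprintf("  %s mode: class offset = %.4f, p = %.3g\n", mode,
                f$coefficients[["group_offset"]], f$p_value))
  }
  invisible(x)
}
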