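#' Correlation-weighted residue contact network
#'
#' Nodes are residues (beads); an edge joins two residues when any heavy-atom
#' pair between them is within `contact_cutoff`. Each edge carries an affinity
#' \eqn{a_{ij}=|C_{ij}|} (correlation strength) and a length-like weight
#' \eqn{w_{ij}=-\log|C_{ij}|}, so strongly correlated contacts are short
#' paths. Affinities are floored at 1e-6 (weight cap ~13.8).
#'
#' @param x a preprocessed `allonet_structure`.
#' @param beads bead model the correlation matrix is indexed by.
#' @param C correlation matrix from [cross_correlations()].
#' @param contact_cutoff heavy-atom contact distance in Angstrom.
#' @return igraph object of class `allonet_graph`; vertices named by residue
#'   key with a `chain` attribute, edges with `weight` and `affinity`.
#' @export
build_network <- function(x, beads, C, contact_cutoff = 4.5) {
  n <- nrow(beads)
  if (!all(dim(C) == c(n, n))) {
    stop("correlation matrix dimension does not match bead count")
  }
  at <- polymer_atoms(x)
  if (!all(at$res_key %in% beads$res_key)) {
    stop("bead model and structure residues are inconsistent")
  }
  idx <- match(at$res_key, beads$res_key)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  contact <- d <= contact_cutoff
  # minimum heavy-atom distance aggregated to residue pairs
  adj <- matrix(FALSE, n, n)
  hit <- which(contact, arr.ind = TRUE)
  hit <- hit[idx[hit[, 1]] != idx[hit[, 2]], , drop = FALSE]
  adj[cbind(idx[hit[, 1]], idx[hit[, 2]])] <- TRUE
  adj <- adj | t(adj)
  pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  a <- pmax(abs(C[pairs]), 1e-6)
  g <- igraph::graph_from_edgelist(
    cbind(beads$res_key[pairs[, 1]], beads$res_key[pairs[, 2]]),
    directed = FALSE)
  missing <- setdiff(beads$res_key, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  g <- igraph::permute(g, match(igraph::V(g)$name, beads$res_key))
  igraph::E(g)$affinity <- a
  # length-like weight; floored at a small positive value for |C| ~ 1 edges
  # (betweenness needs strictly positive lengths comfortably above the
  # solver's numerical epsilon)
  igraph::E(g)$weight <- pmax(-log(a), 1e-6)
  igraph::V(g)$chain <- beads$chain[match(igraph::V(g)$name, beads$res_key)]
  g <- igraph::set_graph_attr(g, "contact_cutoff", contact_cutoff)
  class(g) <- c("allonet_graph", class(g))
  g
}

# deterministic argmax: first index attaining the maximum after ordering by
# the supplied keys
pick_max_edge <- function(eb, ends) {
  cand <- which(eb >= max(eb) - 1e-12)
  if (length(cand) == 1) return(cand)
  keys <- apply(ends[cand, , drop = FALSE], 1,
                function(z) paste(sort(z), collapse = "~"))
  cand[order(keys)][1]
}

girvan_newman_component <- function(g_full, vids) {
  sub <- igraph::induced_subgraph(g_full, vids)
  n <- igraph::vcount(sub)
  memb_best <- rep(1L, n)
  names(memb_best) <- igraph::V(sub)$name
  if (n == 1 || igraph::ecount(sub) == 0) {
    return(list(membership = memb_best,
                Q = local_modularity(sub, memb_best)))
  }
  q_best <- local_modularity(sub, memb_best)
  work <- sub
  while (igraph::ecount(work) > 0) {
    eb <- igraph::edge_betweenness(work, weights = igraph::E(work)$weight)
    k <- pick_max_edge(eb, igraph::ends(work, igraph::E(work)))
    work <- igraph::delete_edges(work, k)
    memb <- igraph::components(work)$membership
    q <- local_modularity(sub, memb[igraph::V(sub)$name])
    if (q > q_best + 1e-12) {
      q_best <- q
      memb_best <- memb[igraph::V(sub)$name]
    }
  }
  list(membership = memb_best, Q = q_best)
}

local_modularity <- function(g, membership) {
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, membership, weights = igraph::E(g)$affinity)
}

merge_small_communities <- function(g, membership, min_size) {
  if (is.null(min_size) || min_size <= 1) return(membership)
  ends <- igraph::ends(g, igraph::E(g))
  aff <- igraph::E(g)$affinity
  repeat {
    sizes <- table(membership)
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    # process the smallest community first (deterministic by label)
    small <- small[order(sizes[small], small)]
    merged <- FALSE
    for (cid in small) {
      members <- names(membership)[membership == cid]
      e1 <- ends[, 1] %in% members
      e2 <- ends[, 2] %in% members
      cross <- xor(e1, e2)
      if (!any(cross)) next
      other <- ifelse(e1[cross], ends[cross, 2], ends[cross, 1])
      other_comm <- membership[other]
      gain <- tapply(aff[cross], other_comm, sum)
      target <- names(gain)[order(-gain, names(gain))][1]
      membership[members] <- target
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  membership
}

#' Detect dynamical communities (Girvan-Newman)
#'
#' Divisive partitioning of the residue graph: the edge of maximal weighted
#' betweenness (weights `w = -log|C|` as path lengths) is removed iteratively
#' and, of the intermediate partitions so produced, the one maximizing the
#' affinity-weighted modularity Q is returned. Disconnected graphs are
#' partitioned per connected component. Communities smaller than `min_size`
#' are then merged into the neighbouring community with the greatest total
#' edge affinity.
#'
#' @param g an `allonet_graph` from [build_network()].
#' @param min_size minimum community size (`1` disables merging).
#' @param mcc_threshold fraction tau of the multichain-community rule; a
#'   community is MCC when at least two chains each hold strictly more than
#'   `tau * size` of its residues.
#' @return list of class `allonet_partition`: `membership` (named integer),
#'   `communities` (list of residue-key sets), `Q`, `is_mcc`,
#'   `per_chain_counts`, `n_communities`.
#' @export
detect_communities <- function(g, min_size = 5, mcc_threshold = 0.10) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  comp <- igraph::components(g)
  membership <- integer(igraph::vcount(g))
  names(membership) <- igraph::V(g)$name
  offset <- 0L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    res <- girvan_newman_component(g, vids)
    membership[names(res$membership)] <- res$membership + offset
    offset <- offset + max(res$membership)
  }
  membership <- merge_small_communities(g, membership, min_size)
  # relabel 1..k in order of first appearance along the deterministic
  # vertex order
  membership <- stats::setNames(
    match(membership, unique(membership[igraph::V(g)$name])),
    names(membership))
  communities <- split(names(membership), membership)
  chains <- stats::setNames(igraph::V(g)$chain, igraph::V(g)$name)
  per_chain <- lapply(communities, function(m) table(chains[m]))
  is_mcc <- vapply(communities, classify_mcc, TRUE, threshold = mcc_threshold)
  structure(list(membership = membership, communities = communities,
                 Q = local_modularity(g, membership),
                 is_mcc = is_mcc, per_chain_counts = per_chain,
                 n_communities = length(communities),
                 mcc_threshold = mcc_threshold),
            class = "allonet_partition")
}

#' Multichain-community rule
#'
#' A community is multichain (MCC) when its residues are distributed over at
#' least two chains and strictly more than `threshold` (10% by default) of
#' its residues fall on each of those chains. A 99/1 split of a 100-residue
#' community is therefore not an MCC, nor is an exact 90/10 split.
#'
#' @param residues character vector of residue keys (`chain|resno|insert`),
#'   or any vector whose chain is the prefix before the first `|`.
#' @param threshold fraction tau in [0, 0.5].
#' @return logical flag.
#' @export
classify_mcc <- function(residues, threshold = 0.10) {
  if (!length(residues)) stop("empty community")
  ch <- sub("\\|.*", "", residues)
  frac <- table(ch) / length(residues)
  sum(frac > threshold) >= 2
}

#' Interior critical residues
#'
#' For every pair of communities joined by at least one contact edge of the
#' original graph, the inter-community edge(s) of maximal weighted edge
#' betweenness (computed on the full pre-removal graph; ties keep all tied
#' edges) are selected and both endpoints are marked critical — these are the
#' bottlenecks through which inter-community motion is transmitted.
#'
#' @param g the `allonet_graph` the partition was computed on.
#' @param partition an `allonet_partition`.
#' @return list of class `allonet_critical`: `residues` (character keys),
#'   `linking` (residue -> community pairs it connects), `edges` data.frame
#'   with betweenness values.
#' @export
find_critical_residues <- function(g, partition) {
  memb <- partition$membership
  if (length(unique(memb)) < 2) {
    return(structure(list(residues = character(), linking = list(),
                          edges = data.frame()),
                     class = "allonet_critical"))
  }
  eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
  ends <- igraph::ends(g, igraph::E(g))
  c1 <- memb[ends[, 1]]
  c2 <- memb[ends[, 2]]
  inter <- which(c1 != c2)
  if (!length(inter)) {
    return(structure(list(residues = character(), linking = list(),
                          edges = data.frame()),
                     class = "allonet_critical"))
  }
  pair_id <- paste(pmin(c1[inter], c2[inter]), pmax(c1[inter], c2[inter]),
                   sep = "-")
  sel <- integer()
  for (p in sort(unique(pair_id))) {
    cand <- inter[pair_id == p]
    mx <- max(eb[cand])
    sel <- c(sel, cand[eb[cand] >= mx - 1e-9 * max(mx, 1)])
  }
  sel <- sort(unique(sel))
  edges <- data.frame(from = ends[sel, 1], to = ends[sel, 2],
                      comm_from = unname(memb[ends[sel, 1]]),
                      comm_to = unname(memb[ends[sel, 2]]),
                      betweenness = eb[sel],
                      stringsAsFactors = FALSE, row.names = NULL)
  res <- sort(unique(c(edges$from, edges$to)))
  linking <- lapply(stats::setNames(res, res), function(r) {
    e <- edges[edges$from == r | edges$to == r, , drop = FALSE]
    unique(paste(pmin(e$comm_from, e$comm_to),
                 pmax(e$comm_from, e$comm_to), sep = "-"))
  })
  structure(list(residues = res, linking = linking, edges = edges),
            class = "allonet_critical")
}

#' Per-complex community summary
#'
#' @param partition an `allonet_partition`.
#' @param critical an `allonet_critical` (may be empty).
#' @param interface_res character vector of interface residue keys from
#'   [interface_residues()].
#' @return list: `mcc_residue_fraction` (residues in MCC communities over all
#'   partitioned residues), `critical_in_interface_fraction` (`NA` when there
#'   are no critical residues), `has_mcc`, `n_communities`, `n_mcc`,
#'   `n_critical`.
#' @export
summarize_complex <- function(partition, critical, interface_res = character()) {
  sizes <- lengths(partition$communities)
  mcc_frac <- sum(sizes[partition$is_mcc]) / sum(sizes)
  n_crit <- length(critical$residues)
  cif <- if (n_crit) {
    sum(critical$residues %in% interface_res) / n_crit
  } else NA_real_
  list(mcc_residue_fraction = mcc_frac,
       critical_in_interface_fraction = cif,
       has_mcc = any(partition$is_mcc),
       n_communities = partition$n_communities,
       n_mcc = sum(partition$is_mcc),
       n_critical = n_crit)
}

#' @export
print.allonet_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities (%d MCC), Q = %.4f\n",
              x$n_communities, sum(x$is_mcc), x$Q))
  invisible(x)
}
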