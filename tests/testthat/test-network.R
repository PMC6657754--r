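test_that("contact edges match a brute-force all-atom distance scan", {
  out <- generate_complex(synthetic_spec(seed = 9))
  x <- preprocess(parse_structure(out$pdb))
  beads <- coarse_grain(x, "COM")
  C <- cross_correlations(normal_modes(build_hessian(beads)))
  g <- build_network(x, beads, C, contact_cutoff = 4.5)
  at <- x$atoms[x$atoms$is_polymer & !(x$atoms$element %in% c("H", "D")), ]
  # brute force: residue pairs with any atom pair within the cutoff
  expected <- character()
  keys <- beads$res_key
  for (i in 1:(length(keys) - 1)) for (j in (i + 1):length(keys)) {
    ai <- at[at$res_key == keys[i], c("x", "y", "z")]
    aj <- at[at$res_key == keys[j], c("x", "y", "z")]
    dmin <- min(sqrt(outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
                       outer(ai$z, aj$z, "-")^2))
    if (dmin <= 4.5) expected <- c(expected, paste(keys[i], keys[j]))
  }
  got <- apply(igraph::ends(g, igraph::E(g)), 1, function(e)
    paste(sort(match(e, keys)) |> (\(ix) keys[ix])(), collapse = " "))
  expect_setequal(got, expected)
  # weights follow w = -log|C|
  ends <- igraph::ends(g, igraph::E(g))
  i <- match(ends[, 1], keys); j <- match(ends[, 2], keys)
  expect_equal(igraph::E(g)$weight,
               pmax(-log(pmax(abs(C[cbind(i, j)]), 1e-6)), 1e-6))
  expect_true(all(igraph::E(g)$weight > 0))
  # the affinity floor caps the weight near -log(1e-6) ~ 13.8
  expect_true(all(igraph::E(g)$weight <= -log(1e-6) + 1e-9))
})

test_that("index mismatch between correlations and beads is an error", {
  out <- generate_complex(synthetic_spec(seed = 2))
  x <- preprocess(parse_structure(out$pdb))
  beads <- coarse_grain(x, "COM")
  C <- cross_correlations(normal_modes(build_hessian(beads)))
  expect_error(build_network(x, beads, C[-1, -1]), "dimension")
})

test_that("weighted edge betweenness agrees with exhaustive path enumeration", {
  # barbell: two 5-cliques joined by a 2-node path
  edges <- rbind(clique_edges(1:5), clique_edges(8:12),
                 c(5, 6), c(6, 7), c(7, 8))
  set.seed(4)
  aff <- runif(nrow(edges), 0.4, 0.95)
  g <- toy_graph(edges, 12, affinity = aff)
  eb_pkg <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
  # map igraph edge order onto the input edge order
  keys <- igraph::V(g)$name
  ends <- igraph::ends(g, igraph::E(g))
  ord <- match(paste(pmin(match(ends[, 1], keys), match(ends[, 2], keys)),
                     pmax(match(ends[, 1], keys), match(ends[, 2], keys))),
               paste(pmin(edges[, 1], edges[, 2]),
                     pmax(edges[, 1], edges[, 2])))
  eb_oracle <- bf_edge_betweenness(edges, -log(aff), 12)
  expect_equal(eb_pkg, eb_oracle[ord], tolerance = 1e-9)
})

test_that("Girvan-Newman recovers two cliques joined by a bridge, at the exhaustive-maximum Q", {
  edges <- rbind(clique_edges(1:6), clique_edges(7:12), c(6, 7))
  g <- toy_graph(edges, 12, chains = rep(c("A", "B"), each = 6))
  part <- detect_communities(g, min_size = 1)
  memb <- part$membership[paste(rep(c("A", "B"), each = 6), 1:12, "",
                                sep = "|")]
  expect_equal(length(unique(memb)), 2)
  expect_equal(unname(memb), rep(unique(memb), each = 6))
  # modularity equals the exhaustive maximum over all 4.2M partitions
  oracle <- allonet:::exhaustive_modularity_max(edges[, 1], edges[, 2],
                                                rep(1, nrow(edges)), 12)
  expect_equal(part$Q, oracle$Q, tolerance = 1e-12)
  # and the definitional modularity of the returned partition agrees
  expect_equal(part$Q, bf_modularity(edges, rep(1, nrow(edges)),
                                     unname(memb)), tolerance = 1e-12)
})

test_that("a uniform complete graph stays a single community", {
  g <- toy_graph(clique_edges(1:8), 8)
  part <- detect_communities(g, min_size = 1)
  expect_equal(part$n_communities, 1)
  expect_equal(part$Q, 0)
})

test_that("a ring of four cliques yields the four planted communities", {
  cliques <- list(1:5, 6:10, 11:15, 16:20)
  edges <- do.call(rbind, lapply(cliques, clique_edges))
  edges <- rbind(edges, c(5, 6), c(10, 11), c(15, 16), c(20, 1))
  g <- toy_graph(edges, 20)
  part <- detect_communities(g, min_size = 1)
  expect_equal(part$n_communities, 4)
  planted <- rep(1:4, each = 5)
  keys <- paste("A", 1:20, "", sep = "|")
  tab <- table(part$membership[keys], planted)
  expect_true(all(apply(tab > 0, 1, sum) == 1))
})

test_that("critical residues are the endpoints of maximal-betweenness bridge edges", {
  # barbell: the two path nodes 6 and 7 carry all inter-community traffic
  edges <- rbind(clique_edges(1:5), clique_edges(8:12),
                 c(5, 6), c(6, 7), c(7, 8))
  g <- toy_graph(edges, 12)
  part <- detect_communities(g, min_size = 1)
  crit <- find_critical_residues(g, part)
  expect_true(all(c("A|6|", "A|7|") %in% crit$residues))
  # betweenness of the selected edges matches exhaustive enumeration
  # (uniform weights: any positive constant gives the same betweenness)
  eb_oracle <- bf_edge_betweenness(edges, rep(1, nrow(edges)), 12)
  expect_equal(max(crit$edges$betweenness), max(eb_oracle), tolerance = 1e-9)
})

test_that("tied inter-community edges make all four endpoints critical", {
  # two 5-cliques joined by two symmetric edges
  edges <- rbind(clique_edges(1:5), clique_edges(6:10), c(1, 6), c(5, 10))
  g <- toy_graph(edges, 10)
  part <- detect_communities(g, min_size = 1)
  expect_equal(part$n_communities, 2)
  crit <- find_critical_residues(g, part)
  expect_setequal(crit$residues, c("A|1|", "A|5|", "A|6|", "A|10|"))
})

test_that("a single-community partition has no critical residues", {
  g <- toy_graph(clique_edges(1:6), 6)
  part <- detect_communities(g)
  crit <- find_critical_residues(g, part)
  expect_equal(length(crit$residues), 0)
})

test_that("the multichain-community rule uses a strict >10% threshold", {
  keys <- function(nA, nB) c(paste("A", seq_len(nA), "", sep = "|"),
                             paste("B", seq_len(nB), "", sep = "|"))
  expect_false(classify_mcc(keys(99, 1)))     # stated worked example
  expect_false(classify_mcc(keys(90, 10)))    # exactly 10%: strict
  expect_true(classify_mcc(keys(89, 11)))
  expect_true(classify_mcc(keys(50, 50)))
  expect_error(classify_mcc(character()), "empty")
  # relabeling chains never changes the flag
  swapped <- sub("^A", "C", keys(50, 50))
  expect_equal(classify_mcc(swapped), classify_mcc(keys(50, 50)))
})

test_that("lowering tau never decreases the MCC residue fraction", {
  out <- generate_complex(synthetic_spec(seed = 6))
  x <- preprocess(parse_structure(out$pdb))
  fracs <- vapply(c(0.4, 0.25, 0.10, 0), function(tau) {
    a <- analyze_complex(x, allonet_config(mcc_threshold = tau))
    a$summary$mcc_residue_fraction
  }, 0)
  expect_true(all(diff(fracs) >= -1e-12))
})

test_that("complex summaries follow the worked arithmetic", {
  part <- structure(list(
    membership = NULL,
    communities = list("1" = paste("A", 1:60, "", sep = "|"),
                       "2" = c(paste("A", 61:80, "", sep = "|"),
                               paste("B", 1:20, "", sep = "|"))),
    is_mcc = c("1" = FALSE, "2" = TRUE),
    n_communities = 2, Q = 0.5), class = "allonet_partition")
  crit <- structure(list(residues = c("A|1|", "B|1|")),
                    class = "allonet_critical")
  s <- summarize_complex(part, crit, interface_res = "A|1|")
  expect_equal(s$mcc_residue_fraction, 0.40)
  expect_equal(s$critical_in_interface_fraction, 0.50)
  expect_true(s$has_mcc)
  # no critical residues -> fraction is absent, not zero
  s2 <- summarize_complex(part, structure(list(residues = character()),
                                          class = "allonet_critical"))
  expect_true(is.na(s2$critical_in_interface_fraction))
})

test_that("communities partition the node set exactly", {
  out <- generate_complex(synthetic_spec(seed = 8))
  a <- analysis_of(out)
  all_nodes <- sort(unlist(a$partition$communities, use.names = FALSE))
  expect_equal(all_nodes, sort(a$beads$res_key))
  expect_equal(sum(lengths(a$partition$communities)), nrow(a$beads))
  expect_true(a$partition$Q >= 0)   # at least the trivial partition
})
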