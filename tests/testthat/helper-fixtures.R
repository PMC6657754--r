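# Fixture builders and independent brute-force oracles used across the suite.

# hand-rolled fixed-width PDB line (independent of the package's writer)
pdb_line <- function(record, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = "", altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, x, y, z, occ, b, element)
}

# two chains x three GLY residues, one 2-atom ligand, optional waters
fixture_dimer_text <- function(n_waters = 0) {
  k <- 0
  lines <- character()
  add <- function(...) {
    k <<- k + 1
    lines[length(lines) + 1] <<- pdb_line(..., serial = k)
  }
  for (ch in c("A", "B")) {
    xoff <- if (ch == "A") 0 else 20
    for (r in 1:3) {
      base <- c(xoff + 4 * (r - 1), 0, 0)
      add("ATOM", name = "N", resname = "GLY", chain = ch, resno = r,
          x = base[1] - 1.2, y = 0.8, z = 0, element = "N")
      add("ATOM", name = "CA", resname = "GLY", chain = ch, resno = r,
          x = base[1], y = 0, z = 0.4, element = "C")
      add("ATOM", name = "C", resname = "GLY", chain = ch, resno = r,
          x = base[1] + 1.2, y = 0.8, z = 0, element = "C")
      add("ATOM", name = "O", resname = "GLY", chain = ch, resno = r,
          x = base[1] + 1.4, y = -0.8, z = -0.3, element = "O")
    }
  }
  add("HETATM", name = "C1", resname = "XYZ", chain = "A", resno = 90,
      x = 5, y = 5, z = 0, element = "C")
  add("HETATM", name = "O1", resname = "XYZ", chain = "A", resno = 90,
      x = 6, y = 5, z = 0, element = "O")
  for (w in seq_len(n_waters)) {
    add("HETATM", name = "O", resname = "HOH", chain = "A", resno = 100 + w,
        x = 30 + w, y = 30, z = 30, element = "O")
  }
  c("HEADER    FIXTURE                                               TEST",
    lines, "END")
}

# igraph toy with the allonet edge/vertex attributes; residue keys are
# "<chain>|<i>|" so the chain prefix convention holds
toy_graph <- function(edges, n, chains = rep("A", n), affinity = NULL) {
  keys <- paste(chains, seq_len(n), "", sep = "|")
  if (is.null(affinity)) affinity <- rep(1, nrow(edges))
  g <- igraph::graph_from_edgelist(
    cbind(keys[edges[, 1]], keys[edges[, 2]]), directed = FALSE)
  missing <- setdiff(keys, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  g <- igraph::permute(g, match(igraph::V(g)$name, keys))
  igraph::E(g)$affinity <- affinity
  igraph::E(g)$weight <- pmax(-log(affinity), 1e-6)
  igraph::V(g)$chain <- chains
  g
}

clique_edges <- function(members) t(utils::combn(members, 2))

# ---- brute-force oracles ----------------------------------------------------

# weighted edge betweenness by exhaustive enumeration of all simple paths
# between every vertex pair (feasible for ~<= 12 nodes). Shortest paths with
# positive weights are simple, so this enumerates all candidates.
bf_edge_betweenness <- function(edges, weights, n) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, e))
    adj[[j]] <- rbind(adj[[j]], c(i, e))
  }
  eb <- numeric(nrow(edges))
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- list()
    walk <- function(v, visited, used_edges, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(len = len, edges = used_edges)
        return()
      }
      if (is.null(adj[[v]])) return()
      for (r in seq_len(nrow(adj[[v]]))) {
        nb <- adj[[v]][r, 1]; ed <- adj[[v]][r, 2]
        if (!visited[nb]) {
          vis <- visited; vis[nb] <- TRUE
          walk(nb, vis, c(used_edges, ed), len + weights[ed])
        }
      }
    }
    vis0 <- rep(FALSE, n); vis0[s] <- TRUE
    walk(s, vis0, integer(), 0)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, 0, "len")
    short <- which(lens <= min(lens) + 1e-9)
    for (p in short) {
      eb[paths[[p]]$edges] <- eb[paths[[p]]$edges] + 1 / length(short)
    }
  }
  eb
}

# weighted modularity of a given partition, from the definition
bf_modularity <- function(edges, weights, membership) {
  m <- sum(weights)
  deg <- numeric(length(membership))
  for (e in seq_len(nrow(edges))) {
    deg[edges[e, 1]] <- deg[edges[e, 1]] + weights[e]
    deg[edges[e, 2]] <- deg[edges[e, 2]] + weights[e]
  }
  intra <- sum(weights[membership[edges[, 1]] == membership[edges[, 2]]])
  intra / m - sum(tapply(deg, membership, sum)^2) / (2 * m)^2
}

# ANM Hessian assembled independently, element by element
bf_hessian <- function(xyz, cutoff, gamma = 1) {
  n <- nrow(xyz)
  h <- matrix(0, 3 * n, 3 * n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    dv <- xyz[j, ] - xyz[i, ]
    d <- sqrt(sum(dv^2))
    if (d > cutoff) next
    blk <- -gamma * outer(dv, dv) / d^2
    h[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- blk
    h[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <-
      h[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] - blk
  }
  h
}

# analytic SASA of two overlapping spheres (spherical caps removed)
bf_two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  # heights of the buried caps
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

analysis_of <- function(out, config = allonet_config()) {
  analyze_complex(preprocess(parse_structure(out$pdb)), config)
}
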