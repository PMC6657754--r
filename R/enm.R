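#' Anisotropic elastic-network Hessian
#'
#' Builds the standard ANM Hessian for a bead model: beads closer than
#' `cutoff_enm` are joined by springs of uniform constant `gamma`. The
#' off-diagonal 3x3 block for a spring (i,j) is \eqn{-\gamma\,u u^T} with
#' \eqn{u} the unit inter-bead vector; diagonal blocks are the negated sums of
#' the off-diagonal blocks of their row, so 3x3 block row sums vanish
#' (translation invariance).
#'
#' @param beads an `allonet_beads` object or data.frame with `x`, `y`, `z`.
#' @param cutoff_enm spring distance cutoff in Angstrom.
#' @param gamma uniform spring constant (arbitrary units).
#' @return list of class `allonet_enm`: `hessian` (3N x 3N), `springs`
#'   (two-column index matrix), `n_beads`, `connected` flag.
#' @export
build_hessian <- function(beads, cutoff_enm = 15, gamma = 1) {
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 beads")
  d <- as.matrix(stats::dist(xyz))
  if (any(d[upper.tri(d)] < 1e-6)) {
    stop("coincident beads (distance < 1e-6 A)")
  }
  pairs <- which(upper.tri(d) & d <= cutoff_enm, arr.ind = TRUE)
  hess <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    u <- (xyz[j, ] - xyz[i, ]) / d[i, j]
    blk <- -gamma * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    hess[ii, jj] <- blk
    hess[jj, ii] <- blk
    hess[ii, ii] <- hess[ii, ii] - blk
    hess[jj, jj] <- hess[jj, jj] - blk
  }
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  structure(list(hessian = hess, springs = unname(pairs), n_beads = n,
                 gamma = gamma, cutoff_enm = cutoff_enm,
                 connected = igraph::count_components(g) == 1),
            class = "allonet_enm")
}

#' Normal modes of an elastic network
#'
#' Diagonalizes the ANM Hessian. Near-zero modes (rigid-body motions) are
#' identified by the relative threshold \eqn{\lambda < 10^{-8}\lambda_{max}}
#' and excluded; a connected non-collinear 3-D network has exactly six. More
#' than six signals a disconnected network and is an error.
#'
#' @param enm result of [build_hessian()].
#' @param n_modes number of nontrivial modes to retain, or `NULL` for all
#'   nontrivial modes when N <= 2000 beads (the lowest 100 otherwise).
#' @param zero_tol relative eigenvalue threshold for the rigid-body nullspace.
#' @return list of class `allonet_modes`: `values` (ascending nontrivial
#'   eigenvalues), `vectors` (3N x k, orthonormal), `n_zero`, `n_beads`.
#' @export
normal_modes <- function(enm, n_modes = NULL, zero_tol = 1e-8) {
  stopifnot(inherits(enm, "allonet_enm"))
  eig <- eigen(enm$hessian, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  lam_max <- max(vals)
  n_zero <- sum(vals < zero_tol * lam_max)
  if (n_zero > 6) {
    stop(sprintf(paste0("elastic network is disconnected: %d near-zero modes",
                        " (expected 6); increase cutoff_enm"), n_zero))
  }
  keep <- seq.int(n_zero + 1, length(vals))
  if (is.null(n_modes)) {
    n_modes <- if (enm$n_beads <= 2000) length(keep) else min(100, length(keep))
  }
  keep <- keep[seq_len(min(n_modes, length(keep)))]
  structure(list(values = vals[keep], vectors = vecs[, keep, drop = FALSE],
                 n_zero = n_zero, n_beads = enm$n_beads),
            class = "allonet_modes")
}

#' Residue cross-correlation matrix from normal modes
#'
#' Pseudo-inverse covariance over the retained modes: the 3x3 covariance block
#' is \eqn{\Sigma_{ij}=\sum_k \lambda_k^{-1} V_{ik}V_{jk}^T}, and the
#' normalized correlation is
#' \eqn{C_{ij}=\mathrm{tr}\,\Sigma_{ij}/\sqrt{\mathrm{tr}\,\Sigma_{ii}\,
#' \mathrm{tr}\,\Sigma_{jj}}}, so \eqn{C_{ii}=1} and \eqn{|C_{ij}|\le 1}.
#'
#' @param modes result of [normal_modes()].
#' @return N x N matrix of class `allonet_corr` with attribute `n_modes_used`.
#' @export
cross_correlations <- function(modes) {
  stopifnot(inherits(modes, "allonet_modes"))
  if (!length(modes$values)) stop("no nontrivial modes")
  n <- modes$n_beads
  v <- modes$vectors
  w <- sweep(v, 2, sqrt(modes$values), "/")   # 3N x k, scaled by lambda^-1/2
  # trace of Sigma_ij = sum over the 3 coordinate rows of w_i %*% t(w_j)
  tr <- matrix(0, n, n)
  for (a in 1:3) {
    rows <- seq(a, 3 * n, by = 3)
    tr <- tr + tcrossprod(w[rows, , drop = FALSE])
  }
  dvar <- diag(tr)
  if (any(dvar <= 0)) stop("zero diagonal variance")
  C <- tr / sqrt(outer(dvar, dvar))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  attr(C, "n_modes_used") <- length(modes$values)
  class(C) <- c("allonet_corr", class(C))
  C
}

#' @export
print.allonet_enm <- function(x, ...) {
  cat(sprintf("ANM elastic network: %d beads, %d springs, cutoff %.1f A, %s\n",
              x$n_beads, nrow(x$springs), x$cutoff_enm,
              if (x$connected) "connected" else "DISCONNECTED"))
  invisible(x)
}
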