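#' Build the anisotropic-network Hessian of a structure
#'
#' Coarse-grains the protein as an elastic network: one node per residue at
#' its Calpha, springs between all pairs within `cutoff`. The off-diagonal
#' 3 x 3 block for a contact (i, j) is `-gamma * (d d^T) / |d|^2` with `d`
#' the Calpha displacement vector; diagonal blocks are minus the sum of the
#' row's off-diagonal blocks, so every 3 x 3 super-row block-sums to zero
#' (translational invariance).
#'
#' @param structure a `StructureModel`, or an N x 3 Calpha coordinate matrix.
#' @param cutoff contact cutoff in Angstrom (default 13).
#' @param gamma spring constant: a scalar, or a symmetric N x N matrix of
#'   per-pair constants (used by the fixture generator to emulate local
#'   stiffening/softening).
#' @return An object of class `Hessian`: list with `matrix` (3N x 3N),
#'   `cutoff`, `gamma`, `n`.
#' @export
build_hessian <- function(structure, cutoff = 13, gamma = 1) {
  xyz <- if (inherits(structure, "StructureModel")) structure$ca_xyz
         else as.matrix(structure)
  n <- nrow(xyz)
  if (n < 3L) stop("need at least 3 residues")
  if (cutoff <= 0) stop("cutoff must be positive")
  gmat <- if (is.matrix(gamma)) gamma else matrix(gamma, n, n)
  if (!identical(dim(gmat), c(n, n))) stop("gamma matrix must be N x N")

  D <- as.matrix(dist(xyz))
  adj <- D > 0 & D <= cutoff
  if (!network_connected(adj))
    stop("elastic network is disconnected at cutoff ", cutoff,
         " Angstrom; increase the cutoff")

  H <- matrix(0, 3L * n, 3L * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    d <- xyz[j, ] - xyz[i, ]
    blk <- -gmat[i, j] * tcrossprod(d) / sum(d * d)
    ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  structure(list(matrix = H, cutoff = cutoff, gamma = gamma, n = n),
            class = "Hessian")
}

# breadth-first connectivity of the contact graph
network_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Wrap a 3N x 3N matrix as a CovarianceMatrix
#'
#' @param m symmetric positive semi-definite 3N x 3N matrix (Angstrom^2).
#' @param provenance `"enm_pseudoinverse"` or `"ensemble_estimate"`.
#' @param check validate symmetry/PSD (default TRUE).
#' @return An object of class `CovarianceMatrix`.
#' @export
covariance_matrix <- function(m, provenance = c("enm_pseudoinverse",
                                                "ensemble_estimate"),
                              check = TRUE) {
  provenance <- match.arg(provenance)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || nrow(m) %% 3L != 0L)
    stop("covariance must be square 3N x 3N")
  if (check) {
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
      stop("covariance matrix is not symmetric")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * sum(diag(m)) / nrow(m))
      stop("covariance matrix is not positive semi-definite")
  }
  structure(list(matrix = (m + t(m)) / 2, provenance = provenance,
                 n_residues = nrow(m) %/% 3L, units = "A^2"),
            class = "CovarianceMatrix")
}

#' Equilibrium covariance from a Hessian (pseudo-inverse)
#'
#' Moore-Penrose pseudo-inverse of the network Hessian with the six
#' rigid-body (zero) modes projected out: eigenvalues below
#' `zero_tol * max(eigenvalue)` are treated as zero.
#'
#' @param h a `Hessian`.
#' @param zero_tol relative zero-mode tolerance (default 1e-10).
#' @return A `CovarianceMatrix` with provenance `"enm_pseudoinverse"`.
#' @export
covariance_from_hessian <- function(h, zero_tol = 1e-10) {
  stopifnot(inherits(h, "Hessian"))
  e <- eigen(h$matrix, symmetric = TRUE)
  lmax <- max(e$values)
  zero <- e$values < zero_tol * lmax
  if (sum(zero) > 6L)
    stop(sum(zero), " near-zero modes (expected 6): network is ",
         "disconnected or degenerate; increase the cutoff")
  if (sum(zero) < 6L)
    warning("only ", sum(zero), " near-zero modes detected (expected 6)")
  V <- e$vectors[, !zero, drop = FALSE]
  G <- V %*% (t(V) / e$values[!zero])
  covariance_matrix(G, "enm_pseudoinverse", check = FALSE)
}

# N x 3N indicator mapping residue blocks to rows
block_indicator <- function(n) {
  K <- matrix(0, n, 3L * n)
  K[cbind(rep(seq_len(n), each = 3L), seq_len(3L * n))] <- 1
  K
}

#' Perturbation response matrix
#'
#' Applies a unit force to each Calpha in turn and records the magnitude of
#' the fluctuation response at every residue, averaged over force
#' directions (random unit "Brownian kicks"). Entry (i, j) is
#' `|DR^j|_i = sqrt(<(DR)^2>)`, the root-mean-square displacement of
#' residue i over unit forces applied at residue j.
#'
#' In `closed_form` mode the sphere average is evaluated exactly: with B the
#' 3 x 3 block of the covariance G coupling residue i to residue j,
#' `E|B f|^2 = trace(B^T B) / 3` for f uniform on the unit sphere. In
#' `monte_carlo` mode `M` unit forces are drawn per perturbed site (seeded,
#' reproducible); it converges to the closed form as M grows.
#'
#' @param g a `CovarianceMatrix`.
#' @param force_model `"closed_form"` (default, deterministic) or
#'   `"monte_carlo"`.
#' @param M number of Monte-Carlo forces per perturbed site.
#' @param seed RNG seed for `monte_carlo` mode.
#' @return An object of class `ResponseMatrix` (N x N, all entries >= 0).
#' @export
response_matrix <- function(g, force_model = c("closed_form", "monte_carlo"),
                            M = 10000L, seed = 1L) {
  stopifnot(inherits(g, "CovarianceMatrix"))
  force_model <- match.arg(force_model)
  n <- g$n_residues
  K <- block_indicator(n)
  if (force_model == "closed_form") {
    A <- sqrt(K %*% (g$matrix^2) %*% t(K) / 3)
  } else {
    if (M < 1L) stop("M must be >= 1")
    A <- matrix(0, n, n)
    with_seed(seed, {
      for (j in seq_len(n)) {
        F <- matrix(rnorm(3L * M), 3L, M)
        F <- sweep(F, 2L, sqrt(colSums(F^2)), `/`)
        X <- g$matrix[, (3L * j - 2L):(3L * j), drop = FALSE] %*% F  # 3N x M
        A[, j] <- sqrt(rowMeans(K %*% X^2))
      }
    })
  }
  structure(list(matrix = unname(A), force_model = force_model,
                 M = if (force_model == "monte_carlo") M else NULL,
                 seed = if (force_model == "monte_carlo") seed else NULL),
            class = "ResponseMatrix")
}

#' Percentile rank of a score vector
#'
#' `rank_i = #(values <= value_i) / N`, so the least flexible residue of a
#' 10-residue protein gets 0.1 and the most flexible 1.0; ties share the
#' maximal rank (conservative for hinge calls).
#'
#' @param values numeric vector.
#' @return numeric vector of ranks in (0, 1].
#' @export
percentile_rank <- function(values) {
  if (length(values) < 1L) stop("empty value vector")
  rank(values, ties.method = "max") / length(values)
}

#' Dynamic flexibility index (DFI)
#'
#' `DFI_i = sum_j A_ij / sum_ij A_ij`: the fraction of the total
#' perturbation response concentrated at residue i when every site is
#' perturbed in turn. High DFI = flexible, low DFI = rigid. The profile
#' sums to 1 by construction. `%DFI` is the percentile rank of DFI within
#' the protein.
#'
#' @param a a `ResponseMatrix`.
#' @param label protein name carried into reports.
#' @return An object of class `FlexibilityProfile`: list with `dfi`,
#'   `pct_dfi`, `label`.
#' @export
dfi <- function(a, label = "protein") {
  stopifnot(inherits(a, "ResponseMatrix"))
  tot <- rowSums(a$matrix)
  s <- sum(tot)
  if (s <= 0) stop("all-zero response matrix: DFI undefined")
  v <- tot / s
  structure(list(dfi = v, pct_dfi = percentile_rank(v), label = label),
            class = "FlexibilityProfile")
}

#' @export
print.FlexibilityProfile <- function(x, ...) {
  cat(sprintf("FlexibilityProfile '%s': %d residues, DFI range [%.3g, %.3g]\n",
              x$label, length(x$dfi), min(x$dfi), max(x$dfi)))
  invisible(x)
}

#' Dynamic coupling index (DCI) to a functional set
#'
#' `DCI_i = (sum_{j in functional} A_ij / |functional|) /
#'          (sum_{j=1..N} A_ij / N)`:
#' the response of residue i to perturbations of the functional set,
#' relative to its response to perturbations everywhere. Values above 1
#' indicate preferential coupling to the functional sites.
#'
#' @param a a `ResponseMatrix`.
#' @param functional 1-based residue indices of the functional set.
#' @return An object of class `CouplingProfile`: list with `dci`, `pct_dci`,
#'   `functional`.
#' @export
dci <- function(a, functional) {
  stopifnot(inherits(a, "ResponseMatrix"))
  n <- nrow(a$matrix)
  functional <- as.integer(functional)
  if (length(functional) == 0L) stop("functional set is empty")
  if (any(functional < 1L | functional > n))
    stop("functional indices out of range 1..", n)
  v <- rowMeans(a$matrix[, functional, drop = FALSE]) / rowMeans(a$matrix)
  structure(list(dci = v, pct_dci = percentile_rank(v),
                 functional = functional),
            class = "CouplingProfile")
}

#' Pairwise dynamic coupling index matrix
#'
#' Entry (i, j) is `DCI_i^j = A_ij / (sum_j A_ij / N)`: the coupling of
#' responder i to a perturbation at site j, normalised so each row has mean
#' exactly 1.
#'
#' @param a a `ResponseMatrix`.
#' @return N x N numeric matrix.
#' @export
pairwise_dci <- function(a) {
  stopifnot(inherits(a, "ResponseMatrix"))
  a$matrix / rowMeans(a$matrix)
}

#' Percentile-rank a pairwise DCI matrix
#'
#' For mutation-set selection, couplings are compared by percentile rank
#' (%DCI). With `scope = "perturbed"` (default) responders are ranked
#' within each perturbed site, i.e. column-wise over `DCI_i^j`; with
#' `scope = "all"` the whole matrix is ranked jointly.
#'
#' @param d pairwise DCI matrix from [pairwise_dci()].
#' @param scope `"perturbed"` or `"all"`.
#' @return matrix of the same shape with entries in (0, 1].
#' @export
pairwise_dci_percentile <- function(d, scope = c("perturbed", "all")) {
  scope <- match.arg(scope)
  if (scope == "perturbed") apply(d, 2L, percentile_rank)
  else matrix(percentile_rank(c(d)), nrow(d), ncol(d))
}

#' End-to-end ENM flexibility profile
#'
#' Convenience pipeline: Hessian -> covariance -> response -> DFI.
#'
#' @inheritParams build_hessian
#' @param label protein name.
#' @return A `FlexibilityProfile`.
#' @export
dfi_from_structure <- function(structure, cutoff = 13, gamma = 1,
                               label = NULL) {
  if (inherits(structure, "StructureModel") && is.null(label))
    label <- structure$label
  g <- covariance_from_hessian(build_hessian(structure, cutoff, gamma))
  dfi(response_matrix(g), label = label %||% "protein")
}
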