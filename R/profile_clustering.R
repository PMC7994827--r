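#' Assemble aligned %DFI profiles into a positions x proteins matrix
#'
#' Stores the percentile-ranked DFI profile of each protein in a column,
#' restricted to the positions aligned across *all* proteins (the common
#' core), so that an equal number of residues is compared per protein.
#'
#' @param profiles list of >= 2 `FlexibilityProfile`.
#' @param maps optional list of [align_sequences()] maps, one per profile,
#'   mapping reference positions (`posA`, the first profile) to each
#'   protein (`posB`). `NULL` entries (and the first profile) use the
#'   identity map. When `maps` is `NULL` entirely, all profiles must have
#'   equal length and the identity map is used throughout.
#' @return A `ProfileMatrix`: list with `matrix` (n x m of %DFI), `labels`,
#'   `positions` (retained reference positions), `masked` (dropped ones).
#' @export
build_profile_matrix <- function(profiles, maps = NULL) {
  m <- length(profiles)
  if (m < 2L) stop("need at least two profiles")
  labels <- vapply(seq_len(m), function(i)
    profiles[[i]]$label %||% paste0("protein_", i), character(1L))
  n_ref <- length(profiles[[1L]]$pct_dfi)
  idx <- matrix(NA_integer_, n_ref, m)      # protein position per ref position
  idx[, 1L] <- seq_len(n_ref)
  for (i in seq_len(m)[-1L]) {
    map <- if (is.null(maps)) NULL else maps[[i]]
    if (is.null(map)) {
      if (length(profiles[[i]]$pct_dfi) != n_ref)
        stop("profile ", i, " length differs from the reference; ",
             "supply an alignment map")
      idx[, i] <- seq_len(n_ref)
    } else {
      idx[map$posA, i] <- map$posB
    }
  }
  keep <- rowSums(is.na(idx)) == 0L
  if (!any(keep)) stop("no positions aligned across all proteins")
  X <- vapply(seq_len(m), function(i) profiles[[i]]$pct_dfi[idx[keep, i]],
              numeric(sum(keep)))
  colnames(X) <- labels
  structure(list(matrix = X, labels = labels,
                 positions = which(keep), masked = which(!keep)),
            class = "ProfileMatrix")
}

#' SVD-based dimensionality reduction of a profile matrix
#'
#' Decomposes the n x m profile matrix `X = U Sigma V^T` and projects the
#' proteins onto the `r` leading components: `X* = V* Sigma*` (m x r).
#' With `center = TRUE` (default) the row mean is subtracted first, which
#' is the standard PCA biplot; `center = FALSE` decomposes the raw matrix.
#' The sign of each component is fixed so that its largest-magnitude
#' loading (entry of U) is positive, making the embedding reproducible
#' bit-for-bit.
#'
#' @param pm a `ProfileMatrix`.
#' @param r number of components to retain (default 2).
#' @param center subtract the per-position mean across proteins first.
#' @return A `ReducedEmbedding`: list with `coords` (m x r), `singular`
#'   (retained singular values), `loadings` (n x r), `r`, `center`,
#'   `labels`.
#' @export
svd_reduce <- function(pm, r = 2L, center = TRUE) {
  stopifnot(inherits(pm, "ProfileMatrix"))
  X <- pm$matrix
  if (center) X <- X - rowMeans(X)
  if (r < 1L) stop("r must be >= 1")
  s <- svd(X)
  rank <- sum(s$d > max(s$d, 0) * 1e-10)
  if (max(s$d) == 0) rank <- min(dim(X))  # zero matrix: origin embedding
  if (r > rank)
    stop("r = ", r, " exceeds the matrix rank (", rank, ")")
  U <- s$u[, seq_len(r), drop = FALSE]
  V <- s$v[, seq_len(r), drop = FALSE]
  for (k in seq_len(r)) {           # deterministic sign convention
    if (U[which.max(abs(U[, k])), k] < 0) {
      U[, k] <- -U[, k]; V[, k] <- -V[, k]
    }
  }
  coords <- V %*% diag(s$d[seq_len(r)], r, r)
  rownames(coords) <- pm$labels
  structure(list(coords = coords, singular = s$d[seq_len(r)],
                 loadings = U, r = r, center = center, labels = pm$labels),
            class = "ReducedEmbedding")
}

#' Pairwise Euclidean distances between embedded proteins
#'
#' `d_lm = sqrt(sum_i (X_i^l - X_i^m)^2)` over the retained components.
#'
#' @param emb a `ReducedEmbedding`.
#' @return Symmetric m x m distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(emb) {
  stopifnot(inherits(emb, "ReducedEmbedding"))
  as.matrix(dist(emb$coords))
}

#' Hierarchical clustering of the embedded proteins
#'
#' Agglomerative clustering of the pairwise distance matrix (average
#' linkage by default). Ties are broken deterministically by input order
#' (smallest label pair first), as in [stats::hclust()].
#'
#' @param dist_matrix symmetric distance matrix, e.g. from
#'   [pairwise_distances()].
#' @param method linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An `hclust` merge tree.
#' @export
dendrogram_linkage <- function(dist_matrix, method = "average") {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) < 2L) stop("need at least two proteins to cluster")
  hclust(stats::as.dist(dist_matrix), method = method)
}

#' Export a merge tree as Newick text
#'
#' @param hc an `hclust` tree from [dendrogram_linkage()].
#' @param path optional file to write.
#' @return Newick string (invisibly when written to `path`).
#' @export
as_newick <- function(hc, path = NULL) {
  nw <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) { writeLines(nw, path); return(invisible(nw)) }
  nw
}
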