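#' Specification for a synthetic test fixture
#'
#' Deterministic toy structures with known ground-truth covariances so that
#' every pipeline stage (covariance estimation, DFI/DCI, hinge
#' classification, mutation-set selection, convergence diagnostics) can be
#' exercised without external data. "Mutants" are emulated by scaling the
#' spring constants of contacts touching selected positions: stiffening
#' (factor > 1) rigidifies a site, softening (factor < 1) makes it more
#' flexible, with a well-defined ground-truth covariance either way.
#'
#' @param topology `"chain"` (collinear trace with seeded jitter),
#'   `"helix"` (ideal alpha-helix: rise 1.5 A, 100 deg/residue,
#'   radius 2.3 A) or `"two_domain"` (two helices joined by an extended
#'   linker).
#' @param n_residues number of residues (>= 3).
#' @param spacing consecutive-residue spacing for chain/linker segments,
#'   Angstrom (default 3.8).
#' @param perturbation optional `list(positions =, factor =)` spring
#'   scaling applied to all contacts of the listed positions.
#' @param seed RNG seed for the jitter (chain topology).
#' @return A `FixtureSpec`.
#' @export
fixture_spec <- function(topology = c("helix", "chain", "two_domain"),
                         n_residues = 10L, spacing = 3.8,
                         perturbation = NULL, seed = 1L) {
  topology <- match.arg(topology)
  if (n_residues < 3L) stop("n_residues must be >= 3")
  if (spacing <= 0) stop("spacing must be > 0")
  if (!is.null(perturbation)) {
    stopifnot(is.list(perturbation),
              all(c("positions", "factor") %in% names(perturbation)))
    if (perturbation$factor <= 0) stop("perturbation factor must be > 0")
    if (any(perturbation$positions < 1L |
            perturbation$positions > n_residues))
      stop("perturbation positions outside 1..n_residues")
  }
  structure(list(topology = topology, n_residues = n_residues,
                 spacing = spacing, perturbation = perturbation,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

helix_coords <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                         origin = c(0, 0, 0)) {
  th <- (seq_len(n) - 1L) * twist * pi / 180
  cbind(radius * cos(th) + origin[1L], radius * sin(th) + origin[2L],
        rise * (seq_len(n) - 1L) + origin[3L])
}

#' Build the deterministic coordinates of a fixture
#'
#' @param spec a [fixture_spec()].
#' @return A `StructureModel`; the same spec and seed always produce
#'   identical coordinates.
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  n <- spec$n_residues
  xyz <- switch(spec$topology,
    chain = {
      # jitter breaks collinearity; ~1 A is enough to keep the elastic
      # network free of spurious zero modes at any chain length
      j <- with_seed(spec$seed, matrix(rnorm(2L * n, sd = 1.0), n, 2L))
      cbind((seq_len(n) - 1L) * spec$spacing, j)
    },
    helix = helix_coords(n),
    two_domain = {
      n1 <- n %/% 3L; nl <- n %/% 3L; n2 <- n - n1 - nl
      h1 <- helix_coords(n1)
      top <- h1[n1, ]
      # extended linker built as a wide-pitch helix: near-straight overall
      # but locally non-coplanar, so the network has no spurious zero modes
      ph <- seq_len(nl) * pi / 2
      link <- cbind(top[1L] + seq_len(nl) * spec$spacing * 0.30 + 1.2 * cos(ph),
                    top[2L] + seq_len(nl) * spec$spacing * 0.30 + 1.2 * sin(ph),
                    top[3L] + seq_len(nl) * spec$spacing * 0.80)
      h2 <- helix_coords(n2, origin = link[nl, ] + c(3, 0, 2))
      rbind(h1, link, h2)
    })
  aaseq <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  structure_model(xyz, aa = rep_len(aaseq, n),
                  label = sprintf("%s_%d", spec$topology, n))
}

# per-pair spring-constant matrix implementing the spec's perturbation
gamma_matrix <- function(spec, gamma = 1) {
  n <- spec$n_residues
  g <- matrix(gamma, n, n)
  if (!is.null(spec$perturbation)) {
    p <- spec$perturbation$positions
    g[p, ] <- g[p, ] * spec$perturbation$factor
    g[, p] <- g[, p] * spec$perturbation$factor
    # contacts between two perturbed positions scale once, not twice
    g[p, p] <- gamma * spec$perturbation$factor
  }
  g
}

#' Ground-truth ENM covariance of a fixture
#'
#' The exact equilibrium covariance of the fixture's elastic network, with
#' the spring-scaling perturbation (if any) applied to every contact of the
#' listed positions.
#'
#' @param spec a [fixture_spec()].
#' @param cutoff,gamma elastic network parameters (defaults 13 A, 1).
#' @return A `CovarianceMatrix` with provenance `"enm_pseudoinverse"`.
#' @export
make_ground_truth_covariance <- function(spec, cutoff = 13, gamma = 1) {
  strc <- make_structure(spec)
  covariance_from_hessian(
    build_hessian(strc, cutoff = cutoff, gamma = gamma_matrix(spec, gamma)))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9L), 3L, 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Sample a Gaussian coordinate ensemble with known covariance
#'
#' Draws frames `mean + e` with `e ~ N(0, G)` through the symmetric square
#' root of `G` over its nonzero modes, emulating equilibrium fluctuations
#' whose population covariance is exactly `G`. Optionally composes each
#' frame with a random rigid motion to exercise the superposition step
#' (which must remove the gauge).
#'
#' @param g a `CovarianceMatrix` (PSD).
#' @param mean a `StructureModel` providing the mean coordinates.
#' @param n_frames number of frames (>= 2).
#' @param frame_spacing ns per frame (default 1).
#' @param seed RNG seed.
#' @param rigid_motions apply a random rotation + translation per frame.
#' @param mean_shift optional N x 3 displacement added to the mean of every
#'   frame (used to emulate a basin hop in non-stationary fixtures).
#' @return An `EnsembleTrajectory` carrying Calpha atoms.
#' @export
sample_ensemble <- function(g, mean, n_frames, frame_spacing = 1, seed = 1L,
                            rigid_motions = FALSE, mean_shift = NULL) {
  stopifnot(inherits(g, "CovarianceMatrix"),
            inherits(mean, "StructureModel"))
  if (n_frames < 2L) stop("n_frames must be >= 2")
  n <- n_residues(mean)
  if (g$n_residues != n) stop("covariance and structure disagree on N")
  e <- eigen(g$matrix, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  if (any(e$values < -1e-8 * max(sum(e$values), 1)))
    stop("covariance is not positive semi-definite")
  L <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  mu <- mean$ca_xyz
  if (!is.null(mean_shift)) mu <- mu + mean_shift
  xyz <- array(NA_real_, dim = c(n_frames, n, 3L))
  with_seed(seed, {
    Z <- matrix(rnorm(ncol(L) * n_frames), ncol(L), n_frames)
    E <- L %*% Z                                  # 3N x frames
    for (f in seq_len(n_frames)) {
      fr <- mu + matrix(E[, f], n, 3L, byrow = TRUE)
      if (rigid_motions)
        fr <- sweep(fr %*% random_rotation(), 2L, runif(3L, -20, 20), `+`)
      xyz[f, , ] <- fr
    }
  })
  atom <- data.frame(resno = seq_len(n), elety = "CA", aa = mean$aa,
                     chain = mean$chain_id)
  ensemble_trajectory(xyz, atom, frame_spacing, structure = mean)
}

#' Concatenate ensembles into one trajectory
#'
#' Joins the frames of congruent ensembles end to end (same atoms, same
#' frame spacing); used to build non-stationary fixtures whose generating
#' distribution switches partway through.
#'
#' @param ... `EnsembleTrajectory` objects with identical atom tables.
#' @return An `EnsembleTrajectory`.
#' @export
concat_ensembles <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1L), "EnsembleTrajectory")))
  base <- parts[[1L]]
  for (p in parts[-1L]) {
    if (!identical(dim(p$xyz)[-1L], dim(base$xyz)[-1L]) ||
        abs(p$frame_spacing - base$frame_spacing) > 1e-12)
      stop("ensembles are not congruent")
  }
  xyz <- do.call(abind3, lapply(parts, function(p) p$xyz))
  ensemble_trajectory(xyz, base$atom, base$frame_spacing,
                      structure = base$structure)
}

# bind 3-D arrays along the first (frame) dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  total <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1L)))
  out <- array(NA_real_, dim = c(total, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Hinge-shift fixture pair
#'
#' A desk-scale re-enactment of the hinge-shift mechanism: an "ancestor"
#' (the unperturbed helix) and a "descendant" whose elastic network is
#' stiffened by `factor` on a contiguous moderately-flexible block adjacent
#' to one hinge core and softened by `1/factor` on the other hinge core.
#' The stiffened positions gain hinge status (%DFI drops below the hinge
#' threshold) and the softened ones lose it, while the fold (coordinates)
#' is untouched. Sequences differ exactly at the perturbed positions, so
#' the hinge shifts are sequentially non-conserved, as the mutation-set
#' rules require.
#'
#' @param n_residues helix length (default 40; the default perturbed
#'   blocks assume this).
#' @param stiffen,soften 1-based positions whose contacts are scaled by
#'   `factor` and `1/factor` respectively.
#' @param factor spring scaling (default 10).
#' @param cutoff,gamma elastic network parameters.
#' @return List with `structureA`/`structureB` (`StructureModel`, identical
#'   coordinates, sequences differing at the perturbed positions),
#'   `covA`/`covB` (`CovarianceMatrix`), `stiffen`, `soften`.
#' @export
hinge_shift_pair <- function(n_residues = 40L, stiffen = 12:14,
                             soften = 30:33, factor = 10,
                             cutoff = 13, gamma = 1) {
  spec <- fixture_spec("helix", n_residues)
  sA <- make_structure(spec)
  sA$label <- "ancestor"
  gm <- matrix(gamma, n_residues, n_residues)
  gm[stiffen, ] <- gamma * factor; gm[, stiffen] <- gamma * factor
  gm[soften, ] <- gamma / factor; gm[, soften] <- gamma / factor
  gm[stiffen, soften] <- gamma; gm[soften, stiffen] <- gamma
  covA <- covariance_from_hessian(build_hessian(sA, cutoff, gamma))
  covB <- covariance_from_hessian(build_hessian(sA, cutoff, gm))
  sB <- sA
  sB$label <- "descendant"
  # substitute the perturbed positions so the shifts are non-conserved
  mut <- c(stiffen, soften)
  sB$aa[mut] <- ifelse(sA$aa[mut] == "V", "W", "V")
  list(structureA = sA, structureB = sB, covA = covA, covB = covB,
       stiffen = stiffen, soften = soften)
}
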