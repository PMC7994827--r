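#' Construct an EnsembleTrajectory
#'
#' An ordered set of coordinate frames congruent with a [structure_model()].
#' Frames may carry Calpha atoms only, or the four backbone heavy atoms per
#' residue (N, CA, C, O) so that superposition can fit on the backbone.
#'
#' @param xyz numeric array `n_frames x n_atoms x 3`.
#' @param atom data frame with one row per atom: `resno` (1-based residue
#'   ordinal), `elety` (atom name), `aa` (one-letter), `chain`.
#' @param frame_spacing time per frame in ns (metadata; > 0).
#' @param structure the congruent `StructureModel` (mean/reference).
#' @return An object of class `EnsembleTrajectory` with `ca_idx` (rows that
#'   are Calpha atoms) and `fit_idx` (backbone heavy atoms used for
#'   fitting).
#' @export
ensemble_trajectory <- function(xyz, atom, frame_spacing, structure = NULL) {
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[3L] == 3L)
  if (frame_spacing <= 0) stop("frame_spacing must be > 0")
  if (dim(xyz)[2L] != nrow(atom)) stop("frames and atom table disagree")
  if (dim(xyz)[1L] < 1L) stop("need at least one frame")
  ca_idx <- which(atom$elety == "CA")
  if (length(ca_idx) == 0L) stop("ensemble carries no CA atoms")
  fit_idx <- which(atom$elety %in% c("N", "CA", "C", "O"))
  structure(list(xyz = unname(xyz), atom = atom, ca_idx = ca_idx,
                 fit_idx = fit_idx, frame_spacing = frame_spacing,
                 structure = structure),
            class = "EnsembleTrajectory")
}

#' @export
print.EnsembleTrajectory <- function(x, ...) {
  cat(sprintf("EnsembleTrajectory: %d frames x %d atoms (%d residues), %.3g ns/frame\n",
              dim(x$xyz)[1L], dim(x$xyz)[2L], length(x$ca_idx),
              x$frame_spacing))
  invisible(x)
}

#' Number of frames
#' @param traj an `EnsembleTrajectory`.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1L]

#' Read a coordinate ensemble from a multi-model PDB file
#'
#' @param path multi-model PDB file.
#' @param chain chain identifier; default first chain.
#' @param frame_spacing time per frame in ns.
#' @param atoms `"backbone"` (N/CA/C/O, default) or `"calpha"`.
#' @return An `EnsembleTrajectory`.
#' @export
read_ensemble <- function(path, chain = NULL, frame_spacing = 1,
                          atoms = c("backbone", "calpha")) {
  atoms <- match.arg(atoms)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  chain <- chain %||% at$chain[keep][1L]
  want <- if (atoms == "backbone") c("N", "CA", "C", "O") else "CA"
  keep <- keep & at$chain == chain & at$elety %in% want
  if (!any(keep)) stop("no matching atoms in chain '", chain, "'")
  sel <- which(keep)
  nf <- nrow(pdb$xyz)
  xyz <- array(NA_real_, dim = c(nf, length(sel), 3L))
  for (f in seq_len(nf))
    xyz[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)[sel, ]
  resno_file <- at$resno[sel]
  atom <- data.frame(resno = match(resno_file, unique(resno_file)),
                     elety = at$elety[sel],
                     aa = bio3d::aa321(at$resid[sel]),
                     chain = at$chain[sel])
  strc <- read_structure(path, chain = chain, model = 1L)
  ensemble_trajectory(xyz, atom, frame_spacing, structure = strc)
}

#' Windowing scheme for trajectory covariance estimation
#'
#' @param window_length window size in ns.
#' @param lag spacing between window start points in ns (default 25).
#' @param burn_in initial trajectory span discarded to avoid relaxation
#'   artifacts, ns (default 100).
#' @return An object of class `WindowSpec`.
#' @export
window_spec <- function(window_length, lag = 25, burn_in = 100) {
  if (window_length <= 0) stop("window_length must be > 0")
  if (lag <= 0) stop("lag must be > 0")
  if (burn_in < 0) stop("burn_in must be >= 0")
  structure(list(window_length = window_length, lag = lag,
                 burn_in = burn_in), class = "WindowSpec")
}

# ns -> whole frame count; a non-integer count is an error, never rounded
ns_to_frames <- function(ns, frame_spacing, what) {
  f <- ns / frame_spacing
  if (abs(f - round(f)) > 1e-9)
    stop(what, " (", ns, " ns) is not a whole number of frames at ",
         frame_spacing, " ns/frame")
  as.integer(round(f))
}

#' Windowed covariance matrices from an ensemble
#'
#' Splits the trajectory (after discarding `burn_in`) into windows of
#' `window_length` ns whose start points are `lag` ns apart. Within each
#' window every frame is Kabsch-fit to the window's first frame using the
#' backbone heavy atoms, and the population covariance of the Calpha
#' coordinates about the window mean is computed. Fitting to the first
#' frame fixes the rotational gauge; fluctuations are taken about the mean,
#' where the harmonic formalism defines them.
#'
#' @param traj an `EnsembleTrajectory`.
#' @param spec a [window_spec()].
#' @return List of `CovarianceMatrix` (provenance `"ensemble_estimate"`),
#'   one per window, with attribute `starts_ns`.
#' @export
windowed_covariances <- function(traj, spec) {
  stopifnot(inherits(traj, "EnsembleTrajectory"),
            inherits(spec, "WindowSpec"))
  fs <- traj$frame_spacing
  wf <- ns_to_frames(spec$window_length, fs, "window_length")
  lf <- ns_to_frames(spec$lag, fs, "lag")
  bf <- ns_to_frames(spec$burn_in, fs, "burn_in")
  nf <- n_frames(traj)
  if (nf - bf < wf)
    stop("trajectory (", nf * fs, " ns) shorter than burn_in + window (",
         spec$burn_in + spec$window_length, " ns)")
  starts <- seq.int(bf + 1L, nf - wf + 1L, by = lf)
  covs <- lapply(starts, function(s) {
    idx <- s:(s + wf - 1L)
    ref <- traj$xyz[s, , ]
    X <- matrix(NA_real_, length(idx), 3L * length(traj$ca_idx))
    for (k in seq_along(idx)) {
      fit <- kabsch_superpose(traj$xyz[idx[k], , ], ref,
                              fit_atoms = traj$fit_idx)
      X[k, ] <- as.vector(t(fit$coords[traj$ca_idx, , drop = FALSE]))
    }
    Xc <- sweep(X, 2L, colMeans(X))
    covariance_matrix(crossprod(Xc) / nrow(Xc), "ensemble_estimate",
                      check = FALSE)
  })
  attr(covs, "starts_ns") <- (starts - 1L) * fs
  covs
}

#' Mean DFI profile per window size
#'
#' For each window size, computes one DFI profile per window covariance and
#' averages them elementwise (renormalised to sum 1). Profiles that agree
#' across window sizes indicate that all windows sample the same underlying
#' distribution, i.e. converged dynamics.
#'
#' @param traj an `EnsembleTrajectory`.
#' @param window_sizes window lengths in ns (default `c(25, 50, 75, 100)`).
#' @param lag,burn_in see [window_spec()].
#' @return Named list of `FlexibilityProfile`, one per window size.
#' @export
mean_dfi_by_window_size <- function(traj, window_sizes = c(25, 50, 75, 100),
                                    lag = 25, burn_in = 100) {
  out <- lapply(window_sizes, function(w) {
    covs <- windowed_covariances(traj, window_spec(w, lag, burn_in))
    profs <- vapply(covs, function(g) dfi(response_matrix(g))$dfi,
                    numeric(length(traj$ca_idx)))
    m <- rowMeans(profs)
    m <- m / sum(m)
    structure(list(dfi = m, pct_dfi = percentile_rank(m),
                   label = sprintf("window_%gns", w)),
              class = "FlexibilityProfile")
  })
  names(out) <- sprintf("%gns", window_sizes)
  out
}

#' Decide convergence from per-window-size mean DFI profiles
#'
#' Computes all pairwise Pearson correlations between the mean profiles;
#' the dynamics are declared converged when every pairwise correlation is
#' at or above `threshold`. A constant profile has an undefined correlation
#' and is reported as not converged with a diagnostic.
#'
#' @param profiles list of `FlexibilityProfile` (>= 2), e.g. from
#'   [mean_dfi_by_window_size()].
#' @param threshold minimum pairwise Pearson correlation (default 0.9).
#' @return An object of class `ConvergenceReport`: list with `correlations`
#'   (matrix), `converged`, `threshold`, `diagnostic`.
#' @export
check_convergence <- function(profiles, threshold = 0.9) {
  if (length(profiles) < 2L) stop("need at least two profiles")
  P <- vapply(profiles, function(p) p$dfi, numeric(length(profiles[[1L]]$dfi)))
  colnames(P) <- vapply(profiles, function(p) p$label, character(1L))
  diagnostic <- NULL
  if (any(apply(P, 2L, sd) == 0)) {
    diagnostic <- "constant profile: correlation undefined"
    cors <- suppressWarnings(cor(P))
    converged <- FALSE
  } else {
    cors <- cor(P)
    converged <- all(cors[lower.tri(cors)] >= threshold)
  }
  structure(list(correlations = cors, converged = converged,
                 threshold = threshold, diagnostic = diagnostic,
                 profiles = profiles),
            class = "ConvergenceReport")
}

#' @export
print.ConvergenceReport <- function(x, ...) {
  cat(sprintf("ConvergenceReport: %s (threshold %.2f, min pairwise r = %.3f)\n",
              if (x$converged) "converged" else "NOT converged", x$threshold,
              suppressWarnings(min(x$correlations[lower.tri(x$correlations)]))))
  if (!is.null(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  invisible(x)
}
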