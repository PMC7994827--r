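#' Construct a StructureModel
#'
#' A `StructureModel` is the Calpha-level coarse-grained representation used
#' by every other module: one node per residue, placed at the Calpha atom.
#' Backbone (N/CA/C/O) coordinates are carried along when available so that
#' ensemble superposition can fit on backbone heavy atoms.
#'
#' @param ca_xyz numeric N x 3 matrix of Calpha coordinates (Angstrom).
#' @param aa character vector of one-letter amino acids (length N).
#' @param author_resid integer residue numbers as in the source file
#'   (defaults to `1:N`).
#' @param chain_id chain identifier(s), recycled to length N.
#' @param backbone_xyz optional N x 4 x 3 array of N/CA/C/O coordinates
#'   (`NA` where an atom is missing).
#' @param label protein name used in reports.
#' @return An object of class `StructureModel` with fields `residue_index`
#'   (0-based ordinal), `author_resid`, `chain_id`, `aa`, `ca_xyz`,
#'   `backbone_xyz`, `label`.
#' @export
structure_model <- function(ca_xyz, aa = NULL, author_resid = NULL,
                            chain_id = "A", backbone_xyz = NULL,
                            label = "protein") {
  ca_xyz <- as.matrix(ca_xyz)
  if (ncol(ca_xyz) != 3L) stop("ca_xyz must be an N x 3 matrix")
  n <- nrow(ca_xyz)
  if (n < 3L) stop("a StructureModel needs at least 3 residues")
  if (!all(is.finite(ca_xyz))) stop("non-finite Calpha coordinates")
  aa <- aa %||% rep("A", n)
  author_resid <- as.integer(author_resid %||% seq_len(n))
  if (length(aa) != n || length(author_resid) != n)
    stop("aa/author_resid length must match the residue count")
  if (!is.null(backbone_xyz)) {
    backbone_xyz <- unname(backbone_xyz)
    if (!identical(dim(backbone_xyz), c(n, 4L, 3L)))
      stop("backbone_xyz must be an N x 4 x 3 array (N, CA, C, O)")
  }
  dimnames(ca_xyz) <- NULL
  structure(
    list(residue_index = 0:(n - 1L), author_resid = author_resid,
         chain_id = rep_len(as.character(chain_id), n), aa = as.character(aa),
         ca_xyz = ca_xyz, backbone_xyz = backbone_xyz, label = label),
    class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s': %d residues, chain(s) %s\n", x$label,
              nrow(x$ca_xyz), paste(unique(x$chain_id), collapse = ",")))
  invisible(x)
}

#' Number of residues of a StructureModel
#' @param x a `StructureModel`.
#' @export
n_residues <- function(x) nrow(x$ca_xyz)

# Resolve altlocs (highest occupancy, then first listed) within each
# (chain, resno, insert, elety) group of a bio3d atom table.
resolve_altloc <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  ord <- order(key, -occ, seq_len(nrow(atom)))
  keep <- ord[!duplicated(key[ord])]
  sort(keep)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM records of one chain/model into a [structure_model()].
#' Residues lacking a Calpha atom are skipped with a warning; alternate
#' locations are resolved by highest occupancy then first listed; insertion
#' codes are treated as distinct residues; HETATM records are ignored.
#'
#' @param path PDB file (single- or multi-model).
#' @param chain chain identifier; default: first chain in the file.
#' @param model 1-based model index for multi-model files.
#' @param label protein name; defaults to the file name.
#' @return A `StructureModel`.
#' @export
read_structure <- function(path, chain = NULL, model = 1L, label = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  atom_rows <- which(pdb$atom$type == "ATOM")
  if (length(atom_rows) == 0L) stop("no ATOM records in ", path)
  atom <- pdb$atom[atom_rows, , drop = FALSE]
  chain <- chain %||% atom$chain[1L]
  sel <- which(atom$chain == chain)
  if (length(sel) == 0L) stop("chain '", chain, "' not found in ", path)
  nmod <- nrow(pdb$xyz)
  if (model < 1L || model > nmod)
    stop("model ", model, " requested but file has ", nmod, " model(s)")

  atom <- atom[sel, , drop = FALSE]
  rownum <- atom_rows[sel]  # row index into the full coordinate table
  keep <- resolve_altloc(atom)
  atom <- atom[keep, , drop = FALSE]
  rownum <- rownum[keep]

  # coordinates of the requested model
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)[rownum, , drop = FALSE]

  ins <- ifelse(is.na(atom$insert), "", atom$insert)
  reskey <- paste(atom$resno, ins, sep = "|")
  resids <- unique(reskey)   # file order
  ca_row <- match(paste0(resids, ""), ifelse(atom$elety == "CA", reskey, NA))
  missing_ca <- is.na(ca_row)
  if (any(missing_ca)) {
    warning(sum(missing_ca), " residue(s) lack a CA atom and were skipped ",
            "(chain ", chain, "): ",
            paste(head(sub("\\|$", "", resids[missing_ca]), 5), collapse = ", "))
    resids <- resids[!missing_ca]
    ca_row <- ca_row[!missing_ca]
  }
  if (length(resids) == 0L) stop("no CA atoms found in chain '", chain, "'")

  n <- length(resids)
  bb <- array(NA_real_, dim = c(n, 4L, 3L))
  bb_names <- c("N", "CA", "C", "O")
  for (k in seq_along(bb_names)) {
    row_k <- match(resids, ifelse(atom$elety == bb_names[k], reskey, NA))
    ok <- !is.na(row_k)
    bb[ok, k, ] <- xyz[row_k[ok], , drop = FALSE]
  }
  if (all(is.na(bb[, c(1L, 3L, 4L), ]))) bb <- NULL  # CA-only file

  structure_model(
    ca_xyz = xyz[ca_row, , drop = FALSE],
    aa = bio3d::aa321(atom$resid[ca_row]),
    author_resid = atom$resno[ca_row],
    chain_id = chain,
    backbone_xyz = bb,
    label = label %||% sub("\\.pdb$", "", basename(path)))
}

#' Kabsch superposition of two coordinate sets
#'
#' Optimal least-squares rigid-body superposition (rotation with determinant
#' +1 and translation, no reflection) of `mobile` onto `reference`,
#' minimising the RMSD over `fit_atoms`.
#'
#' @param mobile,reference numeric n x 3 coordinate matrices with equal rows.
#' @param fit_atoms indices of the rows used for the fit (default: all).
#' @return A list with `coords` (all mobile rows, transformed), `rmsd`
#'   (over the fit atoms, Angstrom), `rotation` (3 x 3), `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, fit_atoms = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have identical dimensions")
  fit_atoms <- fit_atoms %||% seq_len(nrow(mobile))
  if (length(fit_atoms) < 3L) stop("need at least 3 fit atoms")
  X <- mobile[fit_atoms, , drop = FALSE]
  Y <- reference[fit_atoms, , drop = FALSE]
  cm <- colMeans(X); cr <- colMeans(Y)
  Xc <- sweep(X, 2L, cm); Yc <- sweep(Y, 2L, cr)
  # collinear (rank < 2) fit sets leave the rotation underdetermined
  if (sum(svd(Xc)$d > 1e-8 * max(1, max(abs(Xc)))) < 2L ||
      sum(svd(Yc)$d > 1e-8 * max(1, max(abs(Yc)))) < 2L)
    stop("degenerate (collinear) fit set: superposition underdetermined")
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$u) * det(s$v)); if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)     # row-vector convention: x %*% R
  coords <- sweep(sweep(mobile, 2L, cm) %*% R, 2L, cr, `+`)
  rmsd <- sqrt(mean(rowSums((coords[fit_atoms, , drop = FALSE] - Y)^2)))
  list(coords = coords, rmsd = rmsd, rotation = R, translation = cr - cm %*% R)
}

#' Write a PDB file with per-residue values in the B-factor column
#'
#' Every atom of residue i (backbone atoms when present, otherwise the
#' Calpha) carries `values[i]` in its B-factor field, the conventional way
#' to colour-map flexibility profiles onto a 3-D structure.
#'
#' @param structure a `StructureModel`.
#' @param values numeric vector, one finite value per residue.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(structure, values, path) {
  n <- n_residues(structure)
  if (length(values) != n) stop("values length (", length(values),
                                ") does not match residue count (", n, ")")
  if (!all(is.finite(values))) stop("values must be finite")
  aa3 <- bio3d::aa123(structure$aa)
  if (!is.null(structure$backbone_xyz)) {
    bbn <- c("N", "CA", "C", "O")
    res <- rep(seq_len(n), each = 4L)
    atm <- rep(bbn, n)
    xyz <- matrix(aperm(structure$backbone_xyz, c(2L, 1L, 3L)), ncol = 3L)
    ok <- stats::complete.cases(xyz)
    res <- res[ok]; atm <- atm[ok]; xyz <- xyz[ok, , drop = FALSE]
  } else {
    res <- seq_len(n); atm <- rep("CA", n)
    xyz <- structure$ca_xyz
  }
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   resno = structure$author_resid[res], resid = aa3[res],
                   elety = atm, chain = structure$chain_id[res],
                   o = rep(1, length(res)), b = values[res])
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param traj an [ensemble_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  nf <- dim(traj$xyz)[1L]
  flat <- t(apply(traj$xyz, 1L, function(m) as.vector(t(m))))
  if (nf == 1L) flat <- matrix(flat, nrow = 1L)
  bio3d::write.pdb(file = path, xyz = flat,
                   resno = traj$atom$resno, resid = bio3d::aa123(traj$atom$aa),
                   elety = traj$atom$elety, chain = traj$atom$chain,
                   o = rep(1, nrow(traj$atom)), b = rep(0, nrow(traj$atom)))
  invisible(path)
}
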