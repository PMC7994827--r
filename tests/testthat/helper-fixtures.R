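# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

helix10 <- function() cached("helix10",
  make_structure(fixture_spec("helix", 10)))
helix10_cov <- function() cached("helix10_cov",
  make_ground_truth_covariance(fixture_spec("helix", 10)))
helix10_resp <- function() cached("helix10_resp",
  response_matrix(helix10_cov()))
shift_pair <- function() cached("shift_pair", hinge_shift_pair())

# one fixed-width PDB ATOM record
pdb_atom_line <- function(eleno, elety, resid, chain, resno, xyz,
                          occ = 1, b = 0, alt = " ", insert = " ") {
  name <- if (nchar(elety) < 4L) sprintf(" %-3s", elety)
          else sprintf("%-4s", elety)
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          eleno, name, alt, resid, chain, resno, insert,
          xyz[1], xyz[2], xyz[3], occ, b)
}

# small hand-written PDB: one CA per residue at the given coordinates
write_toy_pdb <- function(coords, path, resno = seq_len(nrow(coords)),
                          resid = "ALA", chain = "A") {
  lines <- vapply(seq_len(nrow(coords)), function(i)
    pdb_atom_line(i, "CA", resid, chain, resno[i], coords[i, ]),
    character(1))
  writeLines(c(lines, "END"), path)
  path
}

# independent DFI oracle: per-force linear solves through a generalized
# inverse, exact sphere average over the three axis forces
dfi_linear_solve_oracle <- function(structure, cutoff = 13, gamma = 1) {
  h <- build_hessian(structure, cutoff, gamma)
  Hi <- MASS::ginv(h$matrix)
  n <- nrow(h$matrix) / 3L
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in 1:3) {
      f <- numeric(3L * n)
      f[3L * (j - 1L) + k] <- 1
      x <- Hi %*% f
      A[, j] <- A[, j] + colSums(matrix(x^2, nrow = 3L))
    }
  }
  A <- sqrt(A / 3)
  rowSums(A) / sum(A)
}

# enumeration oracle for set X, written as plain nested loops
oracle_set_X <- function(tab, dci_B, thr = 0.8) {
  pctB <- apply(dci_B, 2, function(col)
    rank(col, ties.method = "max") / length(col))
  nc_classes <- c("non_common_A", "non_common_B")
  partners_B <- tab$posB[tab$class %in% nc_classes]
  sel <- integer()
  for (r in seq_len(nrow(tab))) {
    if (!(tab$class[r] %in% nc_classes) || tab$conserved[r]) next
    others <- setdiff(partners_B, tab$posB[r])
    if (length(others) && any(pctB[tab$posB[r], others] >= thr))
      sel <- c(sel, tab$posA[r])
  }
  sel
}

# hand-buildable hinge table for the selection-rule unit tests
make_hinge_table <- function(posA, posB = posA, aaA, aaB,
                             pct_A, pct_B, hinge_threshold = 0.2) {
  tab <- data.frame(posA = posA, posB = posB, aaA = aaA, aaB = aaB,
                    conserved = aaA == aaB,
                    pct_dfi_A = pct_A, pct_dfi_B = pct_B,
                    hinge_A = pct_A < hinge_threshold,
                    hinge_B = pct_B < hinge_threshold)
  tab$class <- ifelse(tab$hinge_A & tab$hinge_B, "common_hinge",
               ifelse(tab$hinge_A, "non_common_A",
               ifelse(tab$hinge_B, "non_common_B", "non_hinge")))
  class(tab) <- c("HingeTable", "data.frame")
  tab
}

lower_tri <- function(m) m[lower.tri(m)]
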