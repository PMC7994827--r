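#' Pairwise global sequence alignment as a position map
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10 / extend 0.5)
#' of two amino-acid sequences, reduced to the map of aligned (ungapped)
#' position pairs. A precomputed mapping table can be supplied instead,
#' bypassing the alignment entirely.
#'
#' @param seqA,seqB amino-acid sequences (single strings) for proteins A
#'   (ancestor/design target) and B (descendant/reference).
#' @param mapping optional data frame with columns `posA`, `posB` (1-based
#'   residue indices); `aaA`/`aaB` are filled from the sequences.
#' @param gap_opening,gap_extension gap penalties (defaults 10 / 0.5).
#' @return An `AlignmentMap` data frame with columns `posA`, `posB`, `aaA`,
#'   `aaB`, `conserved` (identical amino acid), strictly monotone in both
#'   position columns.
#' @export
align_sequences <- function(seqA, seqB, mapping = NULL,
                            gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  a <- strsplit(seqA, "")[[1L]]
  b <- strsplit(seqB, "")[[1L]]
  if (is.null(mapping)) {
    aln <- Biostrings::pairwiseAlignment(
      seqA, seqB, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
    sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
    posA <- cumsum(pat != "-")
    posB <- cumsum(sub != "-")
    keep <- pat != "-" & sub != "-"
    mapping <- data.frame(posA = posA[keep], posB = posB[keep])
  } else {
    mapping <- as.data.frame(mapping)[, c("posA", "posB")]
    if (any(diff(mapping$posA) <= 0) || any(diff(mapping$posB) <= 0))
      stop("mapping must be strictly monotone in both position columns")
    if (any(mapping$posA < 1L | mapping$posA > length(a)) ||
        any(mapping$posB < 1L | mapping$posB > length(b)))
      stop("mapping positions outside the sequences")
  }
  mapping$aaA <- a[mapping$posA]
  mapping$aaB <- b[mapping$posB]
  mapping$conserved <- mapping$aaA == mapping$aaB
  class(mapping) <- c("AlignmentMap", "data.frame")
  mapping
}

#' Classify hinges across an aligned protein pair
#'
#' A residue is a hinge when its percentile-ranked DFI (%DFI) is below
#' `hinge_threshold`. Each aligned pair is classified as `common_hinge`
#' (hinge in both proteins), `non_common_A` (hinge in A only),
#' `non_common_B` (hinge in B only) or `non_hinge`.
#'
#' @param profA,profB `FlexibilityProfile` of proteins A and B.
#' @param map an [align_sequences()] map between them.
#' @param hinge_threshold %DFI below which a residue is a rigid hinge
#'   (default 0.2).
#' @return A `HingeTable` data frame: `posA`, `posB`, `aaA`, `aaB`,
#'   `conserved`, `pct_dfi_A`, `pct_dfi_B`, `hinge_A`, `hinge_B`, `class`.
#' @export
classify_hinges <- function(profA, profB, map, hinge_threshold = 0.2) {
  stopifnot(inherits(profA, "FlexibilityProfile"),
            inherits(profB, "FlexibilityProfile"))
  if (any(map$posA > length(profA$pct_dfi)) ||
      any(map$posB > length(profB$pct_dfi)))
    stop("alignment references positions missing from a profile")
  tab <- data.frame(map[, c("posA", "posB", "aaA", "aaB", "conserved")])
  tab$pct_dfi_A <- profA$pct_dfi[tab$posA]
  tab$pct_dfi_B <- profB$pct_dfi[tab$posB]
  tab$hinge_A <- tab$pct_dfi_A < hinge_threshold
  tab$hinge_B <- tab$pct_dfi_B < hinge_threshold
  tab$class <- ifelse(tab$hinge_A & tab$hinge_B, "common_hinge",
               ifelse(tab$hinge_A, "non_common_A",
               ifelse(tab$hinge_B, "non_common_B", "non_hinge")))
  attr(tab, "hinge_threshold") <- hinge_threshold
  class(tab) <- c("HingeTable", "data.frame")
  tab
}

new_mutation_set <- function(set_id, members, evidence, params) {
  stopifnot(!anyDuplicated(members$position))
  structure(list(set_id = set_id, members = members, evidence = evidence,
                 params = params), class = "MutationSet")
}

#' @export
print.MutationSet <- function(x, ...) {
  cat(sprintf("MutationSet %s: %d substitution(s)\n", x$set_id,
              nrow(x$members)))
  if (nrow(x$members))
    cat(sprintf("  %s%d%s\n", x$members$from_aa, x$members$position,
                x$members$to_aa), sep = "")
  invisible(x)
}

# rows of `table` that are non-common hinges (hinge in exactly one protein)
non_common_rows <- function(table) table$class %in% c("non_common_A",
                                                      "non_common_B")

# shared machinery: does candidate row i couple (>= thr, %DCI) to any
# partner row? `pct` is a percentile-ranked pairwise DCI matrix of the
# protein whose positions `pos_of` extracts.
coupling_partners <- function(pct, i_pos, partner_pos, thr) {
  p <- partner_pos[partner_pos != i_pos]
  if (length(p) == 0L) return(NULL)
  sc <- pct[i_pos, p]
  hit <- sc >= thr
  if (!any(hit)) return(NULL)
  data.frame(partner = p[hit], pct_dci = unname(sc[hit]))
}

#' Select mutation set X: non-common, non-conserved hinge-shift positions
#'
#' Candidates are aligned positions that are sequentially non-conserved and
#' are hinges in exactly one protein of the pair (hinge-loss or hinge-gain
#' through evolution). A candidate is selected when its percentile-ranked
#' pairwise coupling, evaluated in protein B's coupling matrix, to at least
#' one other non-common hinge is at or above `dci_threshold`. Selected
#' positions are substituted with protein B's amino acid.
#'
#' @param table a `HingeTable`.
#' @param pairwise_dci_B pairwise DCI matrix of protein B (full protein,
#'   from [pairwise_dci()]); percentile-ranked internally.
#' @param dci_threshold minimum %DCI (default 0.8).
#' @param dci_scope see [pairwise_dci_percentile()].
#' @return A `MutationSet` with `set_id = "X"`; positions are protein-A
#'   indices (`posA`), evidence lists the qualifying protein-B partners.
#' @export
select_set_X <- function(table, pairwise_dci_B, dci_threshold = 0.8,
                         dci_scope = "perturbed") {
  nc <- non_common_rows(table)
  if (!any(nc)) {
    warning("no non-common hinges in the pair: set X is empty")
    return(new_mutation_set("X", empty_members(), list(),
                            list(dci_threshold = dci_threshold)))
  }
  pct <- pairwise_dci_percentile(pairwise_dci_B, scope = dci_scope)
  cand <- which(nc & !table$conserved)
  partner_posB <- table$posB[nc]
  members <- empty_members(); evidence <- list()
  for (r in cand) {
    ev <- coupling_partners(pct, table$posB[r], partner_posB, dci_threshold)
    if (is.null(ev)) next
    members <- rbind(members, data.frame(
      position = table$posA[r], from_aa = table$aaA[r], to_aa = table$aaB[r]))
    evidence[[as.character(table$posA[r])]] <-
      data.frame(partner_posB = ev$partner, pct_dci = ev$pct_dci)
  }
  stopifnot(all(!table$conserved[match(members$position, table$posA)]))
  new_mutation_set("X", members, evidence,
                   list(dci_threshold = dci_threshold, dci_scope = dci_scope,
                        coupling_matrix = "protein_B"))
}

empty_members <- function() data.frame(position = integer(),
                                       from_aa = character(),
                                       to_aa = character())

#' Select mutation set Y: non-conserved common hinges coupled to hinge shifts
#'
#' Candidates are sequentially non-conserved positions that are hinges in
#' both proteins (common hinges). A candidate is selected when it shows
#' high pairwise coupling (%DCI >= `dci_threshold`, protein A's matrix) to
#' at least one sequentially non-conserved non-common hinge. A
#' `manual_include` list of protein-A positions is honoured for common-hinge
#' positions the designer wants regardless of the coupling count (flagged
#' in the evidence); a manual position that is not a non-conserved common
#' hinge is rejected with a warning.
#'
#' @param table a `HingeTable`.
#' @param pairwise_dci_A pairwise DCI matrix of protein A.
#' @param dci_threshold minimum %DCI (default 0.8).
#' @param manual_include optional protein-A positions to force-include.
#' @param dci_scope see [pairwise_dci_percentile()].
#' @return A `MutationSet` with `set_id = "Y"`.
#' @export
select_set_Y <- function(table, pairwise_dci_A, dci_threshold = 0.8,
                         manual_include = NULL, dci_scope = "perturbed") {
  pct <- pairwise_dci_percentile(pairwise_dci_A, scope = dci_scope)
  cand <- which(table$class == "common_hinge" & !table$conserved)
  partner_posA <- table$posA[non_common_rows(table) & !table$conserved]
  members <- empty_members(); evidence <- list()
  for (r in cand) {
    ev <- coupling_partners(pct, table$posA[r], partner_posA, dci_threshold)
    manual <- table$posA[r] %in% manual_include
    if (is.null(ev) && !manual) next
    members <- rbind(members, data.frame(
      position = table$posA[r], from_aa = table$aaA[r], to_aa = table$aaB[r]))
    evidence[[as.character(table$posA[r])]] <- list(
      partners = ev, manual = manual)
  }
  bad <- setdiff(manual_include, table$posA[cand])
  if (length(bad))
    warning("manual_include position(s) ", paste(bad, collapse = ", "),
            " are not non-conserved common hinges: rejected")
  new_mutation_set("Y", members, evidence,
                   list(dci_threshold = dci_threshold, dci_scope = dci_scope,
                        manual_include = manual_include,
                        coupling_matrix = "protein_A"))
}

#' Select mutation set Z: distal DARC spots
#'
#' DARC (dynamic allosteric coupling) spots are mid-flexibility residues,
#' `dfi_band[1] < %DFI < dfi_band[2]` (strict), that sit more than
#' `min_dist` Angstrom (minimum Calpha-Calpha distance) from every
#' active-site residue, yet show high pairwise coupling
#' (%DCI >= `dci_threshold`, protein A's matrix) to at least one
#' sequentially *conserved* non-common hinge. Substituting them perturbs
#' conserved hinge dynamics allosterically without touching the catalytic
#' machinery.
#'
#' @param profile `FlexibilityProfile` of protein A.
#' @param structure `StructureModel` of protein A.
#' @param pairwise_dci_A pairwise DCI matrix of protein A.
#' @param table a `HingeTable` for the pair.
#' @param active_site protein-A residue indices (1-based) of the
#'   catalytic/active-site residues.
#' @param dfi_band open %DFI band for mid-flexibility (default (0.3, 0.5)).
#' @param min_dist minimum Calpha distance to the active site, Angstrom
#'   (default 8; candidates must be strictly farther).
#' @param dci_threshold minimum %DCI (default 0.8).
#' @param dci_scope see [pairwise_dci_percentile()].
#' @return A `MutationSet` with `set_id = "Z"`; evidence records the
#'   active-site distance and coupling partners per member.
#' @export
select_set_Z <- function(profile, structure, pairwise_dci_A, table,
                         active_site, dfi_band = c(0.3, 0.5), min_dist = 8,
                         dci_threshold = 0.8, dci_scope = "perturbed") {
  if (length(active_site) == 0L) stop("active_site must be non-empty")
  n <- n_residues(structure)
  active_site <- as.integer(active_site)
  if (any(active_site < 1L | active_site > n))
    stop("active_site indices outside the structure")
  pct <- pairwise_dci_percentile(pairwise_dci_A, scope = dci_scope)
  partner_posA <- table$posA[non_common_rows(table) & table$conserved]

  # minimum CA-CA distance of every residue to the active site
  d_as <- apply(structure$ca_xyz, 1L, function(x)
    min(sqrt(colSums((t(structure$ca_xyz[active_site, , drop = FALSE]) - x)^2))))

  members <- empty_members(); evidence <- list()
  for (r in seq_len(nrow(table))) {
    pos <- table$posA[r]
    if (!(profile$pct_dfi[pos] > dfi_band[1L] &&
          profile$pct_dfi[pos] < dfi_band[2L])) next
    if (d_as[pos] <= min_dist) next
    ev <- coupling_partners(pct, pos, partner_posA, dci_threshold)
    if (is.null(ev)) next
    members <- rbind(members, data.frame(
      position = pos, from_aa = table$aaA[r], to_aa = table$aaB[r]))
    evidence[[as.character(pos)]] <- list(
      active_site_dist = d_as[pos],
      partners = data.frame(partner_posA = ev$partner, pct_dci = ev$pct_dci))
  }
  new_mutation_set("Z", members, evidence,
                   list(dfi_band = dfi_band, min_dist = min_dist,
                        dci_threshold = dci_threshold, dci_scope = dci_scope,
                        active_site = active_site,
                        coupling_matrix = "protein_A"))
}

#' Aggregate mutation sets into a design report
#'
#' Enforces that sets X, Y, Z are pairwise disjoint by position and builds
#' the union table with per-position provenance.
#'
#' @param setX,setY,setZ `MutationSet` objects (any may be empty).
#' @param table the `HingeTable` the sets were derived from.
#' @return A `DesignReport`: list with `mutations` (union data frame with a
#'   `set` column), `sets`, `hinge_table`, `n_substitutions`.
#' @export
design_report <- function(setX, setY, setZ, table) {
  sets <- list(setX, setY, setZ)
  stopifnot(all(vapply(sets, inherits, logical(1L), "MutationSet")))
  pos <- lapply(sets, function(s) s$members$position)
  for (i in 1:2) for (j in (i + 1):3) {
    clash <- intersect(pos[[i]], pos[[j]])
    if (length(clash))
      stop("sets ", sets[[i]]$set_id, " and ", sets[[j]]$set_id,
           " overlap at position(s) ", paste(clash, collapse = ", "))
  }
  mutations <- do.call(rbind, lapply(sets, function(s) {
    if (nrow(s$members) == 0L) return(NULL)
    cbind(s$members, set = s$set_id)
  }))
  if (is.null(mutations)) mutations <- cbind(empty_members(),
                                             set = character())
  structure(list(mutations = mutations, sets = sets, hinge_table = table,
                 n_substitutions = nrow(mutations)),
            class = "DesignReport")
}

#' @export
print.DesignReport <- function(x, ...) {
  cat(sprintf("DesignReport: %d substitution(s) [X=%d, Y=%d, Z=%d]\n",
              x$n_substitutions,
              nrow(x$sets[[1L]]$members), nrow(x$sets[[2L]]$members),
              nrow(x$sets[[3L]]$members)))
  invisible(x)
}

#' Serialise a design report to JSON
#'
#' @param report a `DesignReport`.
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
design_report_json <- function(report, path = NULL) {
  payload <- list(
    n_substitutions = report$n_substitutions,
    mutations = report$mutations,
    sets = lapply(report$sets, function(s)
      list(set_id = s$set_id, members = s$members, params = s$params,
           evidence = s$evidence)),
    hinge_classes = as.list(table(factor(
      report$hinge_table$class,
      levels = c("common_hinge", "non_common_A",
                 "non_common_B", "non_hinge")))))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
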