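test_that("alignment of identical and near-identical sequences", {
  m <- align_sequences("ACDEFGHIK", "ACDEFGHIK")
  expect_equal(m$posA, 1:9)
  expect_equal(m$posB, 1:9)
  expect_true(all(m$conserved))
  m2 <- align_sequences("ACDEFGHIK", "ACDEFGWIK")
  expect_equal(m2$posA, m2$posB)
  expect_equal(sum(!m2$conserved), 1L)
  expect_equal(m2$posA[!m2$conserved], 7L)
})

test_that("a deletion aligns to a gap, leaving the flanks paired", {
  m <- align_sequences("ACDEF", "ACEF")
  expect_equal(nrow(m), 4L)                    # D has no partner
  expect_equal(m$posA, c(1, 2, 4, 5))
  expect_equal(m$posB, 1:4)
  expect_true(all(m$conserved))
  expect_error(align_sequences("", "ACD"), "empty")
})

test_that("user-supplied mappings bypass alignment and are validated", {
  map <- align_sequences("ACDEF", "ACEF",
                         mapping = data.frame(posA = c(1, 3), posB = c(1, 2)))
  expect_equal(map$aaA, c("A", "D"))
  expect_equal(map$aaB, c("A", "C"))
  expect_equal(map$conserved, c(TRUE, FALSE))
  expect_error(align_sequences("ACDEF", "ACEF",
    mapping = data.frame(posA = c(3, 1), posB = c(1, 2))), "monotone")
  expect_error(align_sequences("ACDEF", "ACEF",
    mapping = data.frame(posA = 1, posB = 9)), "outside")
})

test_that("hinge classes partition aligned pairs and match enumeration", {
  prof <- function(v, lab) structure(
    list(dfi = v, pct_dfi = percentile_rank(v), label = lab),
    class = "FlexibilityProfile")
  set.seed(31)
  n <- 20
  pA <- prof(runif(n), "A"); pB <- prof(runif(n), "B")
  seq_ <- paste(rep("A", n), collapse = "")
  map <- align_sequences(seq_, seq_)
  tab <- classify_hinges(pA, pB, map, hinge_threshold = 0.2)
  # enumeration oracle
  cls <- character(n)
  for (i in 1:n) {
    hA <- pA$pct_dfi[i] < 0.2; hB <- pB$pct_dfi[i] < 0.2
    cls[i] <- if (hA && hB) "common_hinge" else if (hA) "non_common_A"
              else if (hB) "non_common_B" else "non_hinge"
  }
  expect_equal(tab$class, cls)
  expect_equal(sum(table(tab$class)), n)
  expect_true(all((tab$class == "common_hinge") == (tab$hinge_A & tab$hinge_B)))
  expect_true(all((tab$class == "non_common_A") == (tab$hinge_A & !tab$hinge_B)))
  # identical protein against itself: no non-common hinges
  self <- classify_hinges(pA, pA, map)
  expect_false(any(non_common <- self$class %in% c("non_common_A",
                                                   "non_common_B")))
  # threshold logic on a single pair
  one <- classify_hinges(prof(seq(0.1, 1, 0.1), "x"),
                         prof(seq(0.1, 1, 0.1), "y"),
                         align_sequences("AAAAAAAAAA", "AAAAAAAAAA"))
  expect_equal(one$class[1], "common_hinge")
  expect_equal(one$class[10], "non_hinge")
  expect_error(classify_hinges(prof(runif(3), "s"), pB, map), "missing")
})

test_that("set X selects coupled non-conserved hinge shifts only", {
  # 6 aligned positions; rows 1-2 are non-conserved non-common hinges of A,
  # rows 3 is a non-common hinge of B, row 4 conserved non-common, 5-6 none
  tab <- make_hinge_table(
    posA = 1:6, posB = 1:6,
    aaA = c("A", "C", "D", "E", "F", "G"),
    aaB = c("V", "W", "Y", "E", "F", "G"),
    pct_A = c(0.10, 0.15, 0.90, 0.12, 0.60, 0.80),
    pct_B = c(0.70, 0.90, 0.10, 0.75, 0.60, 0.80))
  # protein-B pairwise DCI (rows respond, columns perturbed), built so the
  # top-2 percentile slots of every column go to non-candidate rows 5-6,
  # except column 3 where candidate 1 carries the strongest response
  D <- 0.1 + 0.01 * outer(1:6, 1:6, "+")
  D[5, ] <- 2; D[6, ] <- 3
  D[1, 3] <- 10
  sx <- select_set_X(tab, D, dci_threshold = 0.8)
  expect_equal(sx$members$position, 1L)
  expect_equal(sx$members$from_aa, "A")
  expect_equal(sx$members$to_aa, "V")
  expect_equal(sx$evidence[["1"]]$partner_posB, 3)
  # conserved positions can never be selected
  expect_false(any(tab$conserved[match(sx$members$position, tab$posA)]))
  # matches the independent enumeration oracle
  expect_equal(sx$members$position, oracle_set_X(tab, D))
  # nothing above threshold: empty set with warning, not an error
  expect_warning(
    s0 <- select_set_X(make_hinge_table(1:3, 1:3, c("A", "C", "D"),
                                        c("A", "C", "D"),
                                        c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7)),
                       diag(3) + 0.1), "empty")
  expect_equal(nrow(s0$members), 0L)
})

test_that("set Y selects coupled non-conserved common hinges", {
  tab <- make_hinge_table(
    posA = 1:5, posB = 1:5,
    aaA = c("A", "C", "D", "E", "F"),
    aaB = c("V", "C", "Y", "E", "W"),
    pct_A = c(0.10, 0.15, 0.10, 0.60, 0.90),
    pct_B = c(0.10, 0.10, 0.90, 0.60, 0.10))
  # rows: 1 = non-conserved common hinge (candidate), 2 = conserved common
  # hinge, 3 = non-conserved non_common_A (partner), 5 = non-conserved
  # non_common_B (partner); top percentile slots go to non-candidate
  # rows 4-5 except column 3, where candidate 1 responds strongest
  D <- 0.1 + 0.01 * outer(1:5, 1:5, "+")
  D[4, ] <- 2; D[5, ] <- 3
  D[1, 3] <- 10
  sy <- select_set_Y(tab, D, dci_threshold = 0.8)
  expect_equal(sy$members$position, 1L)
  expect_equal(sy$members$to_aa, "V")
  # conserved common hinges alone yield an empty set
  tab2 <- make_hinge_table(1:3, 1:3, c("A", "C", "D"), c("A", "C", "D"),
                           c(0.1, 0.1, 0.9), c(0.1, 0.1, 0.9))
  expect_equal(nrow(select_set_Y(tab2, diag(3) + 5)$members), 0L)
  # manual include: honored for eligible positions, rejected otherwise
  D0 <- 0.1 + 0.01 * outer(1:5, 1:5, "+")
  D0[4, ] <- 2; D0[5, ] <- 3
  sy2 <- select_set_Y(tab, D0, manual_include = 1L)
  expect_equal(sy2$members$position, 1L)
  expect_true(sy2$evidence[["1"]]$manual)
  expect_warning(select_set_Y(tab, D0, manual_include = 4L), "rejected")
})

test_that("set Z applies band, distance and coupling filters jointly", {
  # chain along x, 5 A spacing; active site at position 1
  s <- structure_model(cbind((0:5) * 5, c(0, 1, 0, 1, 0, 1), 0),
                       aa = c("S", "A", "C", "D", "E", "F"))
  prof <- structure(list(dfi = rep(1 / 6, 6),
                         pct_dfi = c(0.05, 0.35, 0.40, 0.45, 0.10, 0.90),
                         label = "A"), class = "FlexibilityProfile")
  tab <- make_hinge_table(
    posA = 1:6, posB = 1:6,
    aaA = c("S", "A", "C", "D", "E", "F"),
    aaB = c("S", "V", "W", "Y", "E", "F"),
    pct_A = prof$pct_dfi,
    pct_B = c(0.05, 0.35, 0.40, 0.45, 0.90, 0.90))
  # position 5 is a conserved non-common hinge (hinge in A only): partner
  D <- 0.1 + 0.01 * outer(1:6, 1:6, "+")
  D[3, 5] <- 3; D[4, 5] <- 4   # candidates 3 and 4 couple to partner 5
  sz <- select_set_Z(prof, s, D, tab, active_site = 1, min_dist = 8)
  # candidates 3 (10 A from the active site) and 4 (15 A) pass all three
  # filters; candidate 2 sits 5 A away and fails distance (and coupling)
  expect_setequal(sz$members$position, c(3L, 4L))
  expect_true(all(vapply(sz$evidence, function(e) e$active_site_dist > 8,
                         logical(1))))
  # distance filter: shrink the chain so candidate 3 sits within 8 A
  s2 <- structure_model(cbind((0:5) * 3.6, c(0, 1, 0, 1, 0, 1), 0),
                        aa = s$aa)
  sz2 <- select_set_Z(prof, s2, D, tab, active_site = 1, min_dist = 8)
  expect_false(3L %in% sz2$members$position)   # excluded by distance
  expect_true(4L %in% sz2$members$position)
  # the band is open: %DFI exactly at the boundary is excluded
  prof3 <- prof; prof3$pct_dfi[3] <- 0.3
  sz3 <- select_set_Z(prof3, s, D, tab, active_site = 1, min_dist = 8)
  expect_false(3L %in% sz3$members$position)
  expect_error(select_set_Z(prof, s, D, tab, active_site = integer()),
               "non-empty")
  # members are never hinges of protein A: the band excludes them
  expect_true(all(prof$pct_dfi[sz$members$position] > 0.2))
})

test_that("raising hinge_threshold grows hinge sets monotonically", {
  hp <- shift_pair()
  pA <- dfi(response_matrix(hp$covA), "A")
  pB <- dfi(response_matrix(hp$covB), "B")
  map <- align_sequences(paste(hp$structureA$aa, collapse = ""),
                         paste(hp$structureB$aa, collapse = ""))
  prev_A <- prev_B <- integer()
  for (thr in c(0.1, 0.2, 0.35, 0.5)) {
    tab <- classify_hinges(pA, pB, map, hinge_threshold = thr)
    hA <- tab$posA[tab$hinge_A]; hB <- tab$posB[tab$hinge_B]
    expect_true(all(prev_A %in% hA))
    expect_true(all(prev_B %in% hB))
    prev_A <- hA; prev_B <- hB
  }
})

test_that("raising dci_threshold shrinks every mutation set", {
  hp <- shift_pair()
  aA <- response_matrix(hp$covA); aB <- response_matrix(hp$covB)
  pA <- dfi(aA, "A"); pB <- dfi(aB, "B")
  map <- align_sequences(paste(hp$structureA$aa, collapse = ""),
                         paste(hp$structureB$aa, collapse = ""))
  tab <- classify_hinges(pA, pB, map)
  DA <- pairwise_dci(aA); DB <- pairwise_dci(aB)
  prev_x <- prev_y <- prev_z <- NULL
  for (thr in c(0.95, 0.8, 0.6, 0.4)) {
    x <- select_set_X(tab, DB, dci_threshold = thr)$members$position
    y <- select_set_Y(tab, DA, dci_threshold = thr)$members$position
    z <- select_set_Z(pA, hp$structureA, DA, tab, active_site = 20,
                      dci_threshold = thr)$members$position
    if (!is.null(prev_x)) {
      expect_true(all(prev_x %in% x))
      expect_true(all(prev_y %in% y))
      expect_true(all(prev_z %in% z))
    }
    prev_x <- x; prev_y <- y; prev_z <- z
  }
})

test_that("design reports enforce disjointness and round-trip as JSON", {
  tab <- make_hinge_table(1:4, 1:4, c("A", "C", "D", "E"),
                          c("V", "W", "Y", "F"),
                          c(0.1, 0.1, 0.4, 0.9), c(0.9, 0.1, 0.4, 0.1))
  ms <- function(id, pos, from, to) structure(
    list(set_id = id,
         members = data.frame(position = pos, from_aa = from, to_aa = to),
         evidence = list(), params = list()), class = "MutationSet")
  rep0 <- design_report(ms("X", integer(), character(), character()),
                        ms("Y", integer(), character(), character()),
                        ms("Z", integer(), character(), character()), tab)
  expect_equal(rep0$n_substitutions, 0L)
  rep1 <- design_report(ms("X", c(1L, 4L), c("A", "E"), c("V", "F")),
                        ms("Y", 2L, "C", "W"),
                        ms("Z", 3L, "D", "Y"), tab)
  expect_equal(rep1$n_substitutions, 4L)
  expect_setequal(rep1$mutations$position, 1:4)
  expect_error(design_report(ms("X", 1L, "A", "V"), ms("Y", 1L, "A", "V"),
                             ms("Z", 3L, "D", "Y"), tab),
               "X and Y overlap.*1")
  js <- design_report_json(rep1)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$n_substitutions, 4L)
  expect_equal(sort(parsed$mutations$position), 1:4)
  expect_equal(unname(unlist(parsed$hinge_classes)), c(1, 1, 1, 1))
})
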