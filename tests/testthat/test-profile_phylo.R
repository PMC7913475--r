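test_that("alignment trimming keeps the occupied core", {
  aln <- alignment(c(a = "--QTVAG--", b = "AAQTVAGAA"))
  tr <- trim_alignment(aln, min_occupancy = 0.6)
  # hand count: only columns 2..6 (0-based) reach 60% occupancy
  expect_equal(tr$n_columns, 5L)
  expect_equal(unname(tr$rows["a"]), "QTVAG")
  expect_equal(unname(tr$rows["b"]), "QTVAG")

  full <- alignment(c(a = "QTVAG", b = "QTVAG"))
  expect_identical(trim_alignment(full, 0.5)$rows, full$rows)
  expect_error(trim_alignment(alignment(c(a = "---", b = "---")), 0.5),
               "occupancy")
})

test_that("trimming is idempotent", {
  set.seed(21)
  for (k in 1:10) {
    rows <- vapply(1:4, function(i) {
      s <- strsplit(random_protein(20), "")[[1]]
      s[sample(20, sample(0:12, 1))] <- "-"
      paste(s, collapse = "")
    }, character(1))
    names(rows) <- paste0("r", 1:4)
    aln <- alignment(rows)
    once <- tryCatch(trim_alignment(aln), error = function(e) NULL)
    if (is.null(once)) next
    expect_identical(trim_alignment(once)$rows, once$rows)
  }
})

test_that("information content matches the analytic values", {
  prof <- column_information(alignment(c(a = "Q", b = "Q", c = "Q",
                                         d = "Q")))
  expect_equal(prof$information_content, log2(20), tolerance = 1e-12)

  prof4 <- column_information(alignment(c(a = "A", b = "C", c = "D",
                                          d = "E")))
  expect_equal(prof4$information_content, log2(20) - 2, tolerance = 1e-12)

  # gaps are excluded from the frequencies, not from the gap fraction
  pg <- column_information(alignment(c(a = "Q", b = "-", c = "Q", d = "-")))
  expect_equal(pg$gap_fraction, 0.5)
  expect_equal(pg$information_content, log2(20), tolerance = 1e-12)
  expect_equal(unname(attr(pg, "frequencies")[1, "Q"]), 1)

  ag <- column_information(alignment(c(a = "-", b = "-")))
  expect_true(ag$all_gap)
  expect_true(is.na(ag$information_content))
})

test_that("IC decreases monotonically toward a uniform column", {
  residues <- c("A", "C", "D", "E", "F", "G", "H", "I")
  ics <- vapply(0:7, function(k) {
    col <- c(residues[seq_len(k)], rep("Q", 8 - k))
    aln <- alignment(setNames(col, paste0("r", 1:8)))
    column_information(aln)$information_content
  }, numeric(1))
  expect_true(all(diff(ics) < 0))
})

test_that("p-distances count mismatches over shared non-gap columns", {
  aln <- alignment(c(a = "QTVAG", b = "QTVAG"))
  expect_equal(p_distance_matrix(aln)["a", "b"], 0)
  aln2 <- alignment(c(a = "QTVAG", b = "QTVAA"))
  expect_equal(p_distance_matrix(aln2)["a", "b"], 0.2)
  # hand count with gaps: comparable columns are 1, 3, 5 only
  aln3 <- alignment(c(a = "Q-VAG", b = "QTV-A"))
  expect_equal(p_distance_matrix(aln3)["a", "b"], 1 / 3)
  expect_warning(p_distance_matrix(alignment(c(a = "Q-", b = "-T"))),
                 "no comparable")
})

test_that("neighbor joining recovers the 4-taxon additive tree", {
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  ls_fit <- four_taxon_ls_oracle(d)
  expect_setequal(ls_fit$split, c("A", "B"))  # AB | CD is the best split
  tree <- nj_tree(d)
  expect_equal(unname(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]),
               unname(d), tolerance = 1e-9)
  internal <- tree$edge.length[tree$edge[, 2] > 4]
  expect_equal(internal, ls_fit$internal, tolerance = 1e-9)
  expect_equal(internal, 2)  # 1 + i + 1 = 4 on the cross paths
})

test_that("the 3-taxon tree follows the closed-form three-point solution", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  lens <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                   tree$tip.label)
  # a = (AB + AC - BC) / 2, etc.
  expect_equal(unname(lens["A"]), (3 + 5 - 6) / 2)
  expect_equal(unname(lens["B"]), (3 + 6 - 5) / 2)
  expect_equal(unname(lens["C"]), (5 + 6 - 3) / 2)
})

test_that("identical sequences give a zero-length star", {
  aln <- alignment(c(a = "QTVAG", b = "QTVAG", c = "QTVAG"))
  tree <- nj_tree(p_distance_matrix(aln))
  expect_true(all(tree$edge.length == 0))
})

test_that("NJ is exact on random additive trees", {
  set.seed(99)
  for (k in 1:25) {
    tr <- random_additive_tree(sample(4:8, 1))
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(unname(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)]),
                 unname(d), tolerance = 1e-8)
  }
})

test_that("non-symmetric or tiny matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "3 taxa")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "symmetric")
})

test_that("fast-evolving subsets score long branches", {
  tree <- ape::read.tree(text = "((m1:5,m2:5):1,(f1:1,(f2:1,f3:1):1):1);")
  expect_gt(long_branch_score(tree, c("m1", "m2")), 1)
  even <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(long_branch_score(even, c("a", "b")), 1)
  expect_error(long_branch_score(even, c("a", "b", "c", "d")),
               "proper subset")
  expect_error(long_branch_score(even, character(0)), "nonempty")
})

test_that("a lineage mutated at 5x rate creates long branches via NJ", {
  base <- strsplit(strrep(TOY_STEFIN_50, 2), "")[[1]]
  mutate_at_rate <- function(rate) {
    ch <- base
    hit <- which(stats::runif(length(ch)) < rate)
    ch[hit] <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                      length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  wins <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    rows <- c(myx1 = mutate_at_rate(0.25), myx2 = mutate_at_rate(0.25),
              free1 = mutate_at_rate(0.05), free2 = mutate_at_rate(0.05),
              free3 = mutate_at_rate(0.05))
    tree <- nj_tree(p_distance_matrix(alignment(rows)))
    if (long_branch_score(tree, c("myx1", "myx2")) > 1) wins <- wins + 1
  }
  expect_equal(wins, 20L)
})
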