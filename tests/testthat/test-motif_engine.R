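toy_hits <- detect_motifs(TOY_STEFIN_50)
hit <- function(hits, motif) hits[hits$motif == motif, ]

test_that("all six motif calls on the stefin scaffold are exact", {
  expect_equal(hit(toy_hits, "G_trunk")$start, 3L)
  expect_equal(hit(toy_hits, "QxVxG")[, c("start", "end", "matched")],
               data.frame(start = 14L, end = 19L, matched = "QTVAG"),
               ignore_attr = TRUE)
  expect_equal(hit(toy_hits, "hairpin2_pair")[, c("start", "end", "matched",
                                                  "status")],
               data.frame(start = 36L, end = 38L, matched = "LP",
                          status = "canonical"), ignore_attr = TRUE)
  expect_equal(hit(toy_hits, "DxLxYF_cterm")[, c("start", "end", "matched",
                                                 "status")],
               data.frame(start = 44L, end = 50L, matched = "DALKYF",
                          status = "canonical"), ignore_attr = TRUE)
  # H sits exactly 7 before the pair, K exactly 8 before the conserved Y
  expect_equal(hit(toy_hits, "H_minus7")[, c("start", "status")],
               data.frame(start = 29L, status = "canonical"),
               ignore_attr = TRUE)
  expect_equal(hit(toy_hits, "K_minus8")[, c("start", "status")],
               data.frame(start = 40L, status = "canonical"),
               ignore_attr = TRUE)
})

test_that("an LP->LD replacement is reported substituted, all else intact", {
  ld <- sub("LP", "LD", TOY_STEFIN_50, fixed = TRUE)
  hits <- detect_motifs(ld)
  ph <- hit(hits, "hairpin2_pair")
  expect_equal(ph$matched, "LD")
  expect_equal(ph$status, "substituted")
  expect_equal(ph$start, 36L)
  others <- setdiff(MOTIF_NAMES <- unique(hits$motif), "hairpin2_pair")
  expect_identical(hits[hits$motif %in% others, ],
                   toy_hits[toy_hits$motif %in% others, ])
})

test_that("truncating the C-terminal region makes it absent", {
  trunc <- substr(TOY_STEFIN_50, 1, 44)  # drops "DALKYF"
  hits <- detect_motifs(trunc)
  expect_equal(hit(hits, "DxLxYF_cterm")$status, "absent")
  # and the lysine loses its anchor: no dangling offsets
  expect_equal(hit(hits, "K_minus8")$status, "absent")
})

test_that("anchored motifs vanish with their anchors", {
  # no Q anywhere: QxVxG absent, so the pair and H_minus7 are absent too
  s <- strrep("MASTNKEL", 5)
  hits <- detect_motifs(s)
  expect_equal(hit(hits, "QxVxG")$status, "absent")
  expect_equal(hit(hits, "hairpin2_pair")$status, "absent")
  expect_equal(hit(hits, "H_minus7")$status, "absent")
})

test_that("sequences too short for a domain are rejected", {
  expect_error(detect_motifs("MASGKTEEAQNAA"), "shorter than 30")
  expect_error(detect_motifs(TOY_STEFIN_50, mature_start = 60L), "beyond")
})

test_that("the pair catalogue assigns class and status as reported", {
  stefin_sub <- c("LD", "LS", "LY", "LR", "FK", "SA", "FD", "FS", "FA", "LK")
  cyst_sub <- c("AW", "RW", "SW", "KF", "GW", "PF", "PL")
  expect_equal(classify_pair("LP"),
               list(class = "stefin_class", status = "canonical"))
  expect_equal(classify_pair("PW"),
               list(class = "cystatin_class", status = "canonical"))
  for (v in stefin_sub) {
    expect_equal(classify_pair(v),
                 list(class = "stefin_class", status = "substituted"),
                 info = v)
  }
  for (v in cyst_sub) {
    expect_equal(classify_pair(v),
                 list(class = "cystatin_class", status = "substituted"),
                 info = v)
  }
  expect_equal(classify_pair("QQ")$class, "unassigned")
  expect_error(classify_pair("LPQ"), "two residues")
})

test_that("motif positions are invariant to a prepended signal peptide", {
  plain <- detect_motifs(TOY_STEFIN_50, mature_start = 0L)
  shifted <- detect_motifs(paste0(TOY_SIGNAL_PEPTIDE, TOY_STEFIN_50),
                           mature_start = nchar(TOY_SIGNAL_PEPTIDE))
  expect_identical(plain, shifted)
})

test_that("noise-free generator output is canonical at every planted motif", {
  for (s in 1:50) {
    fam <- make_family(family_config(
      n = c(classical_stefin = 1L, type2_cystatin = 1L),
      mutation_rate = 0, seed = s))
    for (k in seq_along(fam$proteins)) {
      f <- structural_features(fam$proteins[[k]])
      hits <- f$motif_hits
      core <- hits$motif %in% c("G_trunk", "QxVxG", "hairpin2_pair")
      expect_true(all(hits$status[core] == "canonical"),
                  info = paste("seed", s, fam$truth$label[k]))
      if (fam$truth$label[k] == "classical_stefin") {
        expect_true(all(hits$status == "canonical"))
      }
    }
  }
})

test_that("substitution tables count variants per group deterministically", {
  ld1 <- sub("LP", "LD", TOY_STEFIN_50, fixed = TRUE)
  recs <- list(seq_record("p1", ld1, lineage = "Porifera"),
               seq_record("p2", ld1, lineage = "Porifera"))
  ann <- annotate_records(recs)
  tab <- substitution_table(ann$motifs, c(p1 = "Porifera", p2 = "Porifera"))
  row <- tab[tab$motif == "hairpin2_pair", ]
  expect_equal(row$variant, "LD")
  expect_equal(row$count, 2L)
  expect_equal(row$group, "Porifera")

  # mixed variants in one lineage give one row per variant with counts
  ls1 <- sub("LP", "LS", TOY_STEFIN_50, fixed = TRUE)
  recs2 <- list(seq_record("m1", TOY_STEFIN_50, lineage = "Myxosporea"),
                seq_record("m2", ls1, lineage = "Myxosporea"),
                seq_record("m3", ls1, lineage = "Myxosporea"))
  ann2 <- annotate_records(recs2)
  tab2 <- substitution_table(ann2$motifs,
                             c(m1 = "Myxosporea", m2 = "Myxosporea",
                               m3 = "Myxosporea"))
  pair_rows <- tab2[tab2$motif == "hairpin2_pair", ]
  expect_equal(pair_rows$variant, c("LP", "LS"))
  expect_equal(pair_rows$count, c(1L, 2L))

  expect_equal(nrow(substitution_table(data.frame(), character(0))), 0L)
  expect_error(substitution_table(ann$motifs, c(p1 = "Porifera",
                                                ghost = "Porifera")),
               "lacking motif hits")
})
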