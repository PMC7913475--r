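# hand-built feature vectors let the decision rules be probed directly,
# independent of the sequence-level annotators
fake_features <- function(pair = "LP", pair_status = "canonical",
                          dxl = "canonical", dxl_matched = "DALKYF",
                          sp = FALSE, bridges = 0L, id = "fake",
                          lineage = "Synthetica") {
  mh <- data.frame(
    motif = c("G_trunk", "QxVxG", "hairpin2_pair", "DxLxYF_cterm",
              "H_minus7", "K_minus8"),
    start = c(3L, 14L, 36L, 44L, 29L, 40L),
    end = c(4L, 19L, 38L, 50L, 30L, 41L),
    matched = c("G", "QTVAG", pair, dxl_matched, "H", "K"),
    status = c("canonical", "canonical", pair_status, dxl, "canonical",
               "canonical"),
    stringsAsFactors = FALSE)
  if (is.na(pair)) {
    mh$status[3] <- "absent"; mh$matched[3] <- NA; mh$start[3] <- NA
  }
  if (dxl == "absent") {
    mh$matched[4] <- NA; mh$start[4] <- NA
  }
  structure(list(id = id, has_signal_peptide = sp,
                 cleavage_pos = if (sp) 15L else NA_integer_,
                 mature_start = if (sp) 15L else 0L,
                 disulfide_pairs = if (bridges > 0) {
                   lapply(seq_len(bridges), function(k) c(2L * k, 2L * k + 1L))
                 } else list(),
                 unpaired_cysteine = NULL, motif_hits = mh,
                 intron_count = NA_integer_, source = "heuristic",
                 lineage = lineage),
            class = "structural_features")
}

test_that("the four subtype architectures classify to their labels", {
  expect_equal(classify(structural_features(
    seq_record("s", TOY_STEFIN_50)))$label, "classical_stefin")
  expect_equal(classify(structural_features(
    seq_record("t", paste0(TOY_SIGNAL_PEPTIDE, TOY_TYPE2_MATURE))))$label,
    "type2_cystatin")
  expect_equal(classify(structural_features(
    seq_record("a1", TOY_ATYPICAL_MATURE)))$label, "atypical_stefin_type1")
  expect_equal(classify(structural_features(
    seq_record("a2", paste0(TOY_SIGNAL_PEPTIDE, TOY_ATYPICAL_MATURE))))$label,
    "atypical_stefin_type2")
})

test_that("a substituted stefin pair still carries its class", {
  # SA pair, no C-terminal region, no signal peptide: type 1 atypical stefin
  sa <- mutate_seq(TOY_ATYPICAL_MATURE, 37:38, to = c("S", "A"))
  call <- classify(structural_features(seq_record("sa", sa)))
  expect_equal(call$label, "atypical_stefin_type1")
  expect_true(any(grepl("pair_substituted:SA", call$notes)))
})

test_that("contradictory feature vectors are left unclassified", {
  # stefin pair but two bridges: no rule should force a guess
  call <- classify(fake_features(pair = "LP", dxl = "canonical",
                                 bridges = 2L))
  expect_equal(call$label, "unclassified")
  expect_true(length(call$rule_trace) > 0)
  # cystatin pair without a signal peptide is likewise contradictory
  expect_equal(classify(fake_features(pair = "PW", dxl = "absent",
                                      sp = FALSE, bridges = 2L))$label,
               "unclassified")
})

test_that("a C-terminus that lost its tyrosine still counts for stefins", {
  call <- classify(fake_features(dxl = "substituted",
                                 dxl_matched = "DALKHF"))
  expect_equal(call$label, "classical_stefin")
  expect_true(any(grepl("cterm_tyrosine:lost", call$notes)))
})

test_that("exactly one rule fires for any feature combination", {
  combos <- expand.grid(pair = c("LP", "SA", "PW", "AW", NA),
                        dxl = c("canonical", "substituted", "absent"),
                        sp = c(FALSE, TRUE), bridges = 0:2,
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    cmb <- combos[k, ]
    f <- fake_features(pair = cmb$pair,
                       pair_status = if (is.na(cmb$pair) ||
                                         cmb$pair %in% c("LP", "PW")) {
                         "canonical"
                       } else "substituted",
                       dxl = cmb$dxl, sp = cmb$sp, bridges = cmb$bridges)
    pair_class <- if (is.na(cmb$pair)) "unassigned"
                  else classify_pair(cmb$pair)$class
    dxl_present <- cmb$dxl != "absent"
    fired <- c(
      pair_class == "cystatin_class" && cmb$sp && cmb$bridges >= 1 &&
        !dxl_present,
      pair_class == "stefin_class" && dxl_present && !cmb$sp &&
        cmb$bridges == 0,
      pair_class == "stefin_class" && !dxl_present && !cmb$sp &&
        cmb$bridges == 0,
      pair_class == "stefin_class" && !dxl_present && cmb$sp &&
        cmb$bridges == 0)
    expect_lte(sum(fired), 1L)  # rules are mutually exclusive
    got <- classify(f)$label
    expected <- if (!any(fired)) "unclassified" else {
      c("type2_cystatin", "classical_stefin", "atypical_stefin_type1",
        "atypical_stefin_type2")[which(fired)]
    }
    expect_equal(got, expected, info = paste(unlist(cmb), collapse = "/"))
  }
})

test_that("labels survive motif-preserving mutation up to rate 0.1", {
  for (s in 1:6) {
    fam <- make_family(family_config(
      n = c(classical_stefin = 4L, atypical_stefin_type1 = 4L,
            atypical_stefin_type2 = 4L, type2_cystatin = 4L),
      mutation_rate = 0.1, seed = 100 + s))
    calls <- classify_records(annotate_records(fam$proteins)$features)
    expect_equal(calls$label, fam$truth$label)
  }
})

test_that("repertoire summaries collapse labels into family presence", {
  recs <- list(seq_record("p1", TOY_STEFIN_50, lineage = "Porifera"),
               seq_record("p2", TOY_STEFIN_50, lineage = "Porifera"))
  calls <- classify_records(annotate_records(recs)$features)
  m <- repertoire_summary(calls)
  expect_equal(unname(m["Porifera", ]), c(1L, 0L, 0L, 0L))

  # a purely atypical parasite family registers atypical only
  fam <- make_family(family_config(
    n = c(atypical_stefin_type1 = 2L, atypical_stefin_type2 = 2L),
    lineage = "Myxosporea", pair_variants = c("LS", "SA"), seed = 3))
  calls2 <- classify_records(annotate_records(fam$proteins)$features)
  m2 <- repertoire_summary(calls2)
  expect_equal(unname(m2["Myxosporea", ]), c(0L, 0L, 1L, 0L))

  empty <- repertoire_summary(data.frame(id = character(0),
                                         label = character(0),
                                         lineage = character(0)),
                              lineages = "Porifera")
  expect_true(all(empty == 0L))
})
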