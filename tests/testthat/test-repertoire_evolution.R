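basal_tree <- read_species_tree(cystakit_extdata("basal_metazoa.nwk"))
fig_matrix <- read_presence_matrix(cystakit_extdata("fig1_repertoire.tsv"))

test_that("Fitch counts match simple hand cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_min_changes(tr, c(A = 1, B = 1, C = 0, D = 0))$
                 min_changes, 1L)
  expect_equal(fitch_min_changes(tr, c(A = 1, B = 1, C = 1, D = 1))$
                 min_changes, 0L)

  pect <- ape::read.tree(
    text = "(Porifera,(Placozoa,(Ctenophora,(Staurozoa,(Myxozoa,Hydrozoa)))));")
  states <- c(Porifera = 0, Placozoa = 0, Ctenophora = 1, Staurozoa = 0,
              Myxozoa = 0, Hydrozoa = 1)
  expect_equal(fitch_min_changes(pect, states)$min_changes,
               fitch_bruteforce(pect, states))
})

test_that("Fitch equals exhaustive enumeration on random trees", {
  set.seed(41)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1) states[1] <- 1 - states[1]
    got <- fitch_min_changes(tr, states)$min_changes
    expect_equal(got, fitch_bruteforce(tr, states))
    # independent cross-check against phangorn's parsimony score
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(got, phangorn::parsimony(tr, pd))
  }
})

test_that("an optimal Fitch labeling realizes the reported count", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    res <- fitch_min_changes(tr, states)
    ns <- res$node_states
    realized <- sum(ns[res$tree$edge[, 1]] != ns[res$tree$edge[, 2]])
    expect_equal(realized, res$min_changes)
  }
})

test_that("Dollo places one gain above the MRCA and minimal losses", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  all1 <- dollo_reconstruction(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(all1$n_gains, 1L)
  expect_equal(all1$n_losses, 0L)
  expect_equal(all1$events$branch, "root")

  single <- dollo_reconstruction(tr, c(A = 0, B = 0, C = 1, D = 0))
  expect_equal(single$n_gains, 1L)
  expect_equal(single$n_losses, 0L)
  expect_equal(single$events$branch, "C")  # gain on the pendant branch

  none <- dollo_reconstruction(tr, c(A = 0, B = 0, C = 0, D = 0))
  expect_equal(none$n_gains, 0L)
  expect_equal(none$n_losses, 0L)
})

test_that("Dollo on the packaged repertoire reproduces the scenario-A losses", {
  states <- tip_states_from_matrix(fig_matrix, "type2_cystatin")
  rec <- dollo_reconstruction(basal_tree, states, "type2_cystatin")
  expect_equal(rec$n_gains, 1L)
  expect_equal(rec$events$branch[rec$events$type == "gain"], "root")
  losses <- rec$events$branch[rec$events$type == "loss"]
  expect_setequal(losses, c("Porifera", "Placozoa", "Staurozoa", "Myxozoa"))
  # the loss count is what exhaustive single-gain enumeration requires
  expect_equal(rec$n_losses,
               min_losses_bruteforce(basal_tree, states, g = 1))
})

test_that("Dollo cost is never below the Fitch optimum", {
  set.seed(43)
  for (k in 1:15) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (all(states == 0)) states[1] <- 1
    dollo <- dollo_reconstruction(tr, states)
    fitch <- fitch_min_changes(tr, states)$min_changes
    expect_gte(dollo$n_gains + dollo$n_losses, fitch)
  }
})

test_that("scenario enumeration brackets Dollo and Fitch", {
  states <- tip_states_from_matrix(fig_matrix, "type2_cystatin")
  dollo <- dollo_reconstruction(basal_tree, states, "type2_cystatin")

  # max_gains = 1 returns exactly the Dollo solution
  only1 <- enumerate_scenarios(basal_tree, states, max_gains = 1L,
                               character = "type2_cystatin")
  expect_length(only1, 1L)
  expect_equal(only1[[1]]$n_gains, 1L)
  expect_equal(only1[[1]]$n_losses, dollo$n_losses)
  expect_setequal(only1[[1]]$events$branch[only1[[1]]$events$type == "loss"],
                  dollo$events$branch[dollo$events$type == "loss"])

  # a prohibitive gain penalty collapses the ranking onto Dollo
  costly <- enumerate_scenarios(basal_tree, states, max_gains = 3L,
                                gain_penalty = 100)
  expect_equal(costly[[1]]$n_gains, 1L)
  expect_equal(costly[[1]]$n_losses, dollo$n_losses)

  # per-gain-count loss minima agree with brute force
  all3 <- enumerate_scenarios(basal_tree, states, max_gains = 3L)
  for (sc in all3) {
    expect_equal(sc$n_losses,
                 min_losses_bruteforce(basal_tree, states, g = sc$n_gains))
  }

  expect_error(enumerate_scenarios(basal_tree, states, max_gains = 0L),
               "max_gains")
})

test_that("with unit gain penalty the best scenario matches Fitch", {
  pect <- ape::read.tree(
    text = "(Porifera,(Placozoa,(Ctenophora,(Staurozoa,(Myxozoa,Hydrozoa)))));")
  states <- c(Porifera = 0, Placozoa = 0, Ctenophora = 1, Staurozoa = 0,
              Myxozoa = 0, Hydrozoa = 1)
  top <- enumerate_scenarios(pect, states, max_gains = 3L,
                             gain_penalty = 1)[[1]]
  expect_equal(top$cost, fitch_bruteforce(pect, states))
})

test_that("scenario events are consistent with node states", {
  states <- tip_states_from_matrix(fig_matrix, "type2_cystatin")
  for (sc in enumerate_scenarios(basal_tree, states, max_gains = 3L)) {
    tree <- sc$tree
    ns <- sc$node_states
    flips <- sum(ns[tree$edge[, 1]] != ns[tree$edge[, 2]]) +
      as.integer(ns[[length(tree$tip.label) + 1L]] == 1L)
    expect_equal(flips, sc$n_gains + sc$n_losses)
  }
})
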