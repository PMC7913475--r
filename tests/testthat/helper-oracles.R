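# Independent oracles used to check the package implementations. These are
# deliberately naive re-derivations (plain dynamic programs, exhaustive
# enumeration, closed forms) kept free of any package internals.

# --- Smith-Waterman score by plain Gotoh recursion (score only) ---------
sw_score_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  open <- gap_open + gap_extend
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - gap_extend)
      d <- H[i - 1, j - 1] + mat[ac[i - 1], bc[j - 1]]
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

random_protein <- function(len, alphabet = setdiff(rownames(blosum62()),
                                                   c("B", "J", "Z", "X",
                                                     "*"))) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- standard genetic code, written out independently -------------------
GENETIC_CODE_ORACLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

translate_oracle <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  paste(GENETIC_CODE_ORACLE[codons], collapse = "")
}

revcomp_oracle <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(dna, "")[[1]]]), collapse = "")
}

# --- exhaustive Fitch: minimum changes over all internal labelings ------
fitch_bruteforce <- function(tree, tip_states) {
  states <- cystakit::align_tip_states(tree, tip_states)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  edges <- tree$edge
  labelings <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  full <- cbind(matrix(rep(unname(states), each = nrow(labelings)),
                       nrow = nrow(labelings)), labelings)
  changes <- rowSums(full[, edges[, 1], drop = FALSE] !=
                     full[, edges[, 2], drop = FALSE])
  min(changes)
}

# minimum losses over labelings with exactly `g` gains, character absent
# below the root (a present root state counts as a root-branch gain)
min_losses_bruteforce <- function(tree, tip_states, g) {
  states <- cystakit::align_tip_states(tree, tip_states)
  n_int <- tree$Nnode
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  labelings <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  full <- cbind(matrix(rep(unname(states), each = nrow(labelings)),
                       nrow = nrow(labelings)), labelings)
  root_col <- n_tip + 1
  gains <- rowSums(full[, edges[, 1], drop = FALSE] == 0 &
                   full[, edges[, 2], drop = FALSE] == 1) +
           full[, root_col]
  losses <- rowSums(full[, edges[, 1], drop = FALSE] == 1 &
                    full[, edges[, 2], drop = FALSE] == 0)
  keep <- gains == g
  if (!any(keep)) return(Inf)
  min(losses[keep])
}

# --- random additive tree and its path-length distance matrix -----------
random_additive_tree <- function(n_tip) {
  tr <- ape::rtree(n_tip, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 2))
  tr
}

# least-squares branch lengths for the three 4-taxon topologies; returns
# the best topology's internal branch length and fit
four_taxon_ls_oracle <- function(d) {
  taxa <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  best <- NULL
  for (sp in splits) {
    pair1 <- sp; pair2 <- setdiff(1:4, sp)
    # tips a,b | c,d with internal branch i: 5 parameters, 6 distances
    X <- matrix(0, 6, 5)
    y <- numeric(6)
    row <- 0
    combs <- utils::combn(4, 2)
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]; j <- combs[2, k]
      row <- row + 1
      X[row, i] <- 1; X[row, j] <- 1
      same <- (i %in% pair1 && j %in% pair1) ||
              (i %in% pair2 && j %in% pair2)
      if (!same) X[row, 5] <- 1
      y[row] <- d[i, j]
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(split = taxa[pair1], lengths = fit$coefficients,
                   internal = unname(fit$coefficients[5]), rss = rss)
    }
  }
  best
}

# --- misc helpers -------------------------------------------------------
make_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

mutate_seq <- function(s, idx, to = NULL) {
  ch <- strsplit(s, "")[[1]]
  ch[idx] <- if (is.null(to)) ifelse(ch[idx] == "G", "P", "G") else to
  paste(ch, collapse = "")
}
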