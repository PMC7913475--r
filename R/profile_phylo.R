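# Alignment trimming, sequence-logo style conservation profiles, and a small
# p-distance + neighbor-joining toolkit. Information content per column is
# IC = log2(20) - H with H the Shannon entropy of the non-gap residue
# frequencies; no small-sample correction is applied by default so analytic
# test values are exact (a correction flag is available).

aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Trim low-occupancy alignment ends
#'
#' Removes columns before the first and after the last column whose non-gap
#' fraction reaches `min_occupancy` (the usual way to drop nonhomologous
#' leaders such as signal peptides, and ragged tails). Internal columns are
#' untouched, so the operation is idempotent.
#'
#' @param aln [alignment()].
#' @param min_occupancy minimum non-gap fraction for an anchor column.
#' @return trimmed [alignment()].
#' @export
trim_alignment <- function(aln, min_occupancy = 0.5) {
  m <- aln_char_matrix(aln)
  occ <- colMeans(m != "-")
  keep <- which(occ >= min_occupancy)
  if (!length(keep)) {
    stop("no column reaches occupancy ", min_occupancy)
  }
  lo <- keep[1L]; hi <- keep[length(keep)]
  rows <- vapply(aln$rows, function(r) substr(r, lo, hi), character(1L))
  alignment(rows)
}

#' Per-column conservation profile
#'
#' @param aln protein [alignment()].
#' @param small_sample_correction apply the WebLogo-style correction
#'   `(A-1) / (2 ln 2 n)` (A = 20) subtracted from the IC.
#' @return data.frame of class `conservation_profile`: `column` (0-based),
#'   `information_content` (bits, `NA` for all-gap columns), `consensus`,
#'   `gap_fraction`, `all_gap`; residue frequency matrix in
#'   `attr(, "frequencies")` (columns x residues, rows summing to 1 for
#'   scored columns).
#' @export
column_information <- function(aln, small_sample_correction = FALSE) {
  m <- aln_char_matrix(aln)
  n_col <- ncol(m)
  residues <- setdiff(PROTEIN_ALPHABET, "X")
  freqs <- matrix(0, nrow = n_col, ncol = 20L,
                  dimnames = list(NULL, residues))
  ic <- numeric(n_col)
  consensus <- character(n_col)
  gap_fraction <- numeric(n_col)
  all_gap <- logical(n_col)
  for (j in seq_len(n_col)) {
    col <- m[, j]
    gap_fraction[j] <- mean(col == "-")
    obs <- col[col != "-"]
    if (!length(obs)) {
      all_gap[j] <- TRUE
      ic[j] <- NA_real_
      consensus[j] <- NA_character_
      next
    }
    tab <- table(factor(obs, levels = residues))
    p <- as.numeric(tab) / sum(tab)
    freqs[j, ] <- p
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    val <- log2(20) - h
    if (small_sample_correction) {
      val <- val - (20 - 1) / (2 * log(2) * length(obs))
    }
    ic[j] <- max(val, 0)
    consensus[j] <- residues[which.max(p)]
  }
  out <- data.frame(column = seq_len(n_col) - 1L,
                    information_content = ic, consensus = consensus,
                    gap_fraction = gap_fraction, all_gap = all_gap,
                    stringsAsFactors = FALSE)
  attr(out, "frequencies") <- freqs
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Pairwise p-distance matrix
#'
#' `d(i, j)` is the fraction of mismatches over the columns where both rows
#' are non-gap (raw, uncorrected divergence). Pairs with zero comparable
#' positions get `NA` and a warning.
#'
#' @param aln [alignment()] with at least two rows.
#' @return symmetric numeric matrix with row ids as dimnames.
#' @export
p_distance_matrix <- function(aln) {
  m <- aln_char_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least two rows")
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) {
        warning("rows '", aln$ids[i], "' and '", aln$ids[j],
                "' share no comparable positions")
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- mean(m[i, both] != m[j, both])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via ape); negative branch lengths
#' are clamped to zero with a warning.
#'
#' @param d symmetric non-negative distance matrix (>= 3 taxa) with dimnames.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("clamping ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Relative tip-branch-length score for a taxon subset
#'
#' Mean pendant (tip) branch length inside the subset divided by the mean
#' outside; values above 1 indicate relatively long branches (e.g. for
#' fast-evolving parasite families).
#'
#' @param tree `phylo` tree with branch lengths.
#' @param tips character vector of tip labels; must be a nonempty proper
#'   subset.
#' @return the ratio; `NaN` with a warning when the outside mean is zero.
#' @export
long_branch_score <- function(tree, tips) {
  if (!length(tips)) stop("tip subset must be nonempty")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  }
  if (length(tips) >= length(tree$tip.label)) {
    stop("tip subset must be a proper subset")
  }
  pendant <- tree$edge.length[match(seq_along(tree$tip.label),
                                    tree$edge[, 2L])]
  inside <- pendant[match(tips, tree$tip.label)]
  outside <- pendant[-match(tips, tree$tip.label)]
  if (mean(outside) == 0) {
    warning("outside mean branch length is zero; score undefined")
    return(NaN)
  }
  mean(inside) / mean(outside)
}
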