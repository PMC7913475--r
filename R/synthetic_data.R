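# Ground-truth generator for every other module: cystatin protein families
# built from motif-bearing scaffolds, matching coding DNA with planted GT/AG
# introns, and presence/absence matrices evolved under a chosen gain/loss
# scenario. The scaffolds realize the subtype architectures: a classical
# stefin (trunk G, QxVxG, H at pair-7, LP pair, K at Y-8, D-x-L-x-Y-F), the
# atypical stefins lacking the C-terminal region (without/with a signal
# peptide), and a type 2 cystatin (signal peptide, PW pair, four cysteines,
# no stefin C-terminus).

#' Scaffold sequences used by the generator
#'
#' `TOY_STEFIN_50` is the 50-residue classical-stefin scaffold whose motif
#' coordinates anchor the motif-engine contract.
#' @name scaffolds
#' @export
TOY_STEFIN_50 <- "MASGKTEEAQNAAEQTVAGNLDAIKSEAIHQTMEASLPGEKSENDALKYF"

#' @rdname scaffolds
#' @export
TOY_SIGNAL_PEPTIDE <- "MKLLVLLALLALAQA"

#' @rdname scaffolds
#' @export
TOY_TYPE2_MATURE <- "GAPRQTVAGCNLDAIKSEAICQTMEASPWGEKSENCAASNECGGF"

#' @rdname scaffolds
#' @export
TOY_ATYPICAL_MATURE <-
  "MASGKTEEAQNAAEQTVAGNLDAIKSEAIHQTMEASLPGEKSENTQESGN"

# substitutions drawn from this alphabet can neither create nor extend
# hydrophobic signal-peptide cores, canonical pairs, C-terminal anchors nor
# cysteines, so planted labels survive any mutation rate the generator allows
MUTATION_ALPHABET <- c("D", "E", "K", "N", "Q", "R", "S", "T")

# deterministic reverse-translation table (one fixed codon per residue)
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Configuration for a synthetic cystatin family
#'
#' @param n named integer vector of sequences per subtype; names from
#'   `classical_stefin`, `atypical_stefin_type1`, `atypical_stefin_type2`,
#'   `type2_cystatin`.
#' @param lineage lineage tag applied to the family (e.g. `"Myxosporea"`).
#' @param pair_variants optional character vector of second-hairpin pair
#'   variants sampled per sequence (stefin-class variants such as
#'   `"LD"`, `"LS"`, `"SA"` apply to the stefin scaffolds, cystatin-class
#'   variants such as `"AW"` to the type 2 scaffold; canonical `"LP"` /
#'   `"PW"` may be included).
#' @param mutation_rate per-site substitution probability at unprotected
#'   positions, in `[0, 1)`.
#' @param intron_counts intron count per gene: `NULL` to sample 0-2,
#'   or an integer (recycled) in 0..2.
#' @param intron_length_range intron length bounds (defaults 8-200 nt).
#' @param seed RNG seed.
#' @return validated config list of class `family_config`.
#' @export
family_config <- function(n = c(classical_stefin = 1L),
                          lineage = "Synthetica", pair_variants = NULL,
                          mutation_rate = 0, intron_counts = NULL,
                          intron_length_range = c(8L, 200L), seed = 1L) {
  allowed <- c("classical_stefin", "atypical_stefin_type1",
               "atypical_stefin_type2", "type2_cystatin")
  if (is.null(names(n)) || !all(names(n) %in% allowed)) {
    stop("n must be named with subtypes: ", paste(allowed, collapse = ", "))
  }
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("mutation_rate must be in [0, 1)")
  }
  if (!is.null(intron_counts) && any(intron_counts < 0 | intron_counts > 2)) {
    stop("intron counts must be 0, 1 or 2")
  }
  if (intron_length_range[1L] < 8L) {
    stop("introns shorter than 8 nt are not generated")
  }
  structure(list(n = n, lineage = lineage, pair_variants = pair_variants,
                 mutation_rate = mutation_rate,
                 intron_counts = intron_counts,
                 intron_length_range = as.integer(intron_length_range),
                 seed = as.integer(seed)),
            class = "family_config")
}

scaffold_for <- function(label) {
  switch(label,
    classical_stefin = list(sp = "", mature = TOY_STEFIN_50),
    atypical_stefin_type1 = list(sp = "", mature = TOY_ATYPICAL_MATURE),
    atypical_stefin_type2 = list(sp = TOY_SIGNAL_PEPTIDE,
                                 mature = TOY_ATYPICAL_MATURE),
    type2_cystatin = list(sp = TOY_SIGNAL_PEPTIDE,
                          mature = TOY_TYPE2_MATURE),
    stop("unknown subtype '", label, "'"))
}

pair_class_of_label <- function(label) {
  if (label == "type2_cystatin") "cystatin_class" else "stefin_class"
}

#' Generate a synthetic cystatin gene family with ground truth
#'
#' Emits the protein sequences, matching coding DNA (deterministic reverse
#' translation plus a TAA stop), genomic sequences with planted GT/AG
#' introns, and a ground-truth table recording the planted label, signal
#' peptide, pair variant and intron coordinates for every record. Point
#' mutations are applied at unprotected sites only (protected sites: all
#' motif residues detected on the clean scaffold, the conserved H/K
#' positions, the signal-peptide region and all cysteines); a draw that
#' would still perturb the decision surface is rejected and resampled, so
#' planted labels are recoverable at any configured mutation rate.
#' Ground-truth intron coordinates are stored in the same canonical
#' (GT/AG-preferring, leftmost) sliding representation that
#' [map_introns()] reports.
#'
#' @param config [family_config()].
#' @return list with `proteins`, `cdna`, `genomic` (lists of
#'   [seq_record()]s sharing ids) and `truth` (data.frame).
#' @export
make_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  proteins <- list(); cdna <- list(); genomic <- list()
  truth <- list()
  counter <- 0L

  for (label in names(config$n)) {
    for (i in seq_len(config$n[[label]])) {
      counter <- counter + 1L
      id <- sprintf("syn_%s_%03d", label, i)
      built <- build_protein(label, config)
      prot <- seq_record(id, built$residues, "protein",
                         description = label, lineage = config$lineage)

      n_intr <- if (is.null(config$intron_counts)) {
        sample(0:2, 1L)
      } else {
        config$intron_counts[((counter - 1L) %%
                              length(config$intron_counts)) + 1L]
      }
      gene <- build_gene(built$residues, n_intr, config$intron_length_range)
      cdna[[id]] <- seq_record(id, gene$cdna, "dna", description = label,
                               lineage = config$lineage)
      genomic[[id]] <- seq_record(id, gene$genomic, "dna",
                                  description = label,
                                  lineage = config$lineage)
      proteins[[id]] <- prot
      truth[[id]] <- data.frame(
        id = id, label = label, lineage = config$lineage,
        pair_variant = built$pair_variant,
        signal_start = if (nzchar(built$sp)) 0L else NA_integer_,
        signal_end = if (nzchar(built$sp)) nchar(built$sp) else NA_integer_,
        mature_start = nchar(built$sp),
        pair_start = built$pair_start, pair_end = built$pair_start + 2L,
        n_introns = nrow(gene$introns),
        intron_coords = paste(sprintf("%d-%d", gene$introns$genomic_start,
                                      gene$introns$genomic_end),
                              collapse = ";"),
        intron_donors = paste(gene$introns$donor, collapse = ";"),
        intron_acceptors = paste(gene$introns$acceptor, collapse = ";"),
        intron_insertions = paste(gene$introns$cdna_insertion_point,
                                  collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(0))
  rownames(truth) <- NULL
  list(proteins = unname(proteins), cdna = unname(cdna),
       genomic = unname(genomic), truth = truth, config = config)
}

build_protein <- function(label, config) {
  sc <- scaffold_for(label)
  mature <- sc$mature
  clean_hits <- detect_motifs(mature, mature_start = 0L)
  pair_hit <- clean_hits[clean_hits$motif == "hairpin2_pair", ]
  pair_start <- pair_hit$start

  # plant a pair variant of the scaffold's class, when requested
  pair_variant <- pair_hit$matched
  if (!is.null(config$pair_variants)) {
    wanted <- pair_class_of_label(label)
    usable <- Filter(function(v) classify_pair(v)$class == wanted,
                     config$pair_variants)
    if (length(usable)) {
      pair_variant <- if (length(usable) == 1L) usable[[1L]]
                      else sample(unlist(usable), 1L)
      substr(mature, pair_start + 1L, pair_start + 2L) <- pair_variant
    }
  }

  full_clean <- paste0(sc$sp, mature)
  protected <- protected_positions(sc$sp, mature, clean_hits)

  mu <- config$mutation_rate
  if (mu == 0) {
    return(list(residues = full_clean, sp = sc$sp,
                pair_start = pair_start, pair_variant = pair_variant))
  }
  chars_clean <- strsplit(full_clean, "", fixed = TRUE)[[1L]]
  free <- setdiff(seq_along(chars_clean), protected + 1L)
  for (attempt in 1:25) {
    chars <- chars_clean
    hit <- free[stats::runif(length(free)) < mu]
    for (p in hit) {
      chars[p] <- sample(setdiff(MUTATION_ALPHABET, chars[p]), 1L)
    }
    candidate <- paste(chars, collapse = "")
    if (label_recoverable(candidate, label, pair_start, nchar(sc$sp))) {
      return(list(residues = candidate, sp = sc$sp,
                  pair_start = pair_start, pair_variant = pair_variant))
    }
  }
  stop("could not place mutations without disturbing the planted label")
}

protected_positions <- function(sp, mature, clean_hits) {
  off <- nchar(sp)
  pos <- if (off > 0L) 0:(off - 1L) else integer(0)
  for (k in seq_len(nrow(clean_hits))) {
    if (clean_hits$status[k] == "absent") next
    pos <- c(pos, (clean_hits$start[k]:(clean_hits$end[k] - 1L)) + off)
  }
  cys <- which(strsplit(mature, "", fixed = TRUE)[[1L]] == "C") - 1L
  pos <- c(pos, cys + off)
  sort(unique(pos))
}

label_recoverable <- function(residues, label, pair_start, sp_len) {
  rec <- seq_record("check", residues, "protein")
  feats <- structural_features(rec)
  if (classify(feats)$label != label) return(FALSE)
  ph <- feats$motif_hits[feats$motif_hits$motif == "hairpin2_pair", ]
  !is.na(ph$start) && ph$start == pair_start &&
    feats$mature_start == sp_len
}

build_gene <- function(residues, n_introns, length_range) {
  aa <- strsplit(residues, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(aa, names(CODON_OF))
  if (length(unknown)) stop("cannot reverse-translate residue ", unknown[1L])
  cdna <- paste0(paste(CODON_OF[aa], collapse = ""), "TAA")
  nC <- nchar(cdna)
  if (n_introns == 0L) {
    gch <- strsplit(cdna, "", fixed = TRUE)[[1L]]
    map <- build_intron_map("plant", gch, gch, list())
    return(list(cdna = cdna, genomic = cdna, introns = map$introns))
  }
  # keep insertion points apart (and off the gene ends) so every exon is a
  # realistic anchor; adjacent introns would make placement ambiguous
  repeat {
    positions <- sort(sample(10:(nC - 10L), n_introns))
    if (n_introns == 1L || min(diff(positions)) >= 16L) break
  }
  lengths <- sample(seq(length_range[1L], length_range[2L]), n_introns,
                    replace = TRUE)
  pieces <- character(0)
  prev <- 0L
  planted <- list()
  offset <- 0L
  for (k in seq_len(n_introns)) {
    pieces <- c(pieces, substr(cdna, prev + 1L, positions[k]))
    interior <- paste(sample(c("A", "C", "G", "T"), lengths[k] - 4L,
                             replace = TRUE), collapse = "")
    pieces <- c(pieces, paste0("GT", interior, "AG"))
    planted[[k]] <- c(positions[k] + offset, positions[k] + offset +
                        lengths[k])
    offset <- offset + lengths[k]
    prev <- positions[k]
  }
  pieces <- c(pieces, substr(cdna, prev + 1L, nC))
  genomic <- paste(pieces, collapse = "")
  gch <- strsplit(genomic, "", fixed = TRUE)[[1L]]
  cch <- strsplit(cdna, "", fixed = TRUE)[[1L]]
  canon <- canonicalize_introns(gch, planted, 60L)
  map <- build_intron_map("plant", gch, cch, canon)
  list(cdna = cdna, genomic = genomic, introns = map$introns)
}

#' Simulate a presence/absence matrix under a gain/loss scenario
#'
#' Tip states are produced by playing the scenario's gains and losses on the
#' tree: every gain turns a clade on, every loss turns the clade below the
#' named lineage's branch off. Losses falling outside any gained clade are
#' no-ops and are dropped. Three named scenarios for the type 2 cystatin
#' character are built in:
#' \itemize{
#'   \item `"A"`: one gain at the root, independent losses in Porifera,
#'     Placozoa, Staurozoa and Myxozoa.
#'   \item `"B"`: gain in the eumetazoan ancestor (MRCA of Ctenophora and
#'     Bilateria), later losses as above where applicable.
#'   \item `"C"`: independent gains in Ctenophora and in the ancestor of
#'     Cnidaria plus Bilateria, with secondary losses in Staurozoa and
#'     Myxozoa.
#' }
#' A custom scenario is given as `list(gains = ..., losses = ...)` where each
#' gain is `"root"` or a vector of tip labels (their MRCA clade is turned
#' on) and losses are lineage labels.
#'
#' @param tree rooted `phylo` with lineage-labelled tips.
#' @param scenario `"A"`, `"B"`, `"C"` or a custom list.
#' @param character character name for the matrix column.
#' @param seed recorded seed (the simulation itself is deterministic given
#'   tree and scenario).
#' @return [presence_matrix()] with one column.
#' @export
make_presence_scenario <- function(tree, scenario = "A",
                                   character = "type2_cystatin", seed = 1L) {
  tree <- prepare_tree(tree)
  if (is.character(scenario)) {
    scenario <- switch(toupper(scenario),
      A = list(gains = list("root"),
               losses = c("Porifera", "Placozoa", "Staurozoa", "Myxozoa")),
      B = list(gains = list(c("Ctenophora", "Bilateria")),
               losses = c("Porifera", "Placozoa", "Staurozoa", "Myxozoa")),
      C = list(gains = list("Ctenophora", c("Anthozoa", "Bilateria")),
               losses = c("Staurozoa", "Myxozoa")),
      stop("unknown scenario tag '", scenario, "'"))
  }
  n_tip <- length(tree$tip.label)
  states <- setNames(integer(n_tip), tree$tip.label)
  clade_tips <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  for (gain in scenario$gains) {
    if (identical(gain, "root")) {
      states[] <- 1L
    } else {
      idx <- match_lineage_tips(gain, tree)
      node <- if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
      states[clade_tips(node)] <- 1L
    }
  }
  for (loss in scenario$losses) {
    idx <- match_lineage_tips(loss, tree)
    states[tree$tip.label[idx]] <- 0L
  }
  m <- matrix(states, ncol = 1L,
              dimnames = list(tree$tip.label, character))
  attr(m, "seed") <- as.integer(seed)
  presence_matrix(m)
}
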