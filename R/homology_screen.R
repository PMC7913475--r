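# Six-frame translated local-alignment homology screen: a desk-scale stand-in
# for the iterative tBLASTn mining loop, with Karlin-Altschul style E-values
# used as a filter (constants are the ungapped BLOSUM62 defaults; the E-value
# is approximate and database-size dependent, so a raw-score threshold is
# offered as an alternative).

KA_LAMBDA <- 0.267
KA_K <- 0.041

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix as shipped with Biostrings.
#' @return numeric matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

#' Translate a nucleotide record in all six reading frames
#'
#' Standard genetic code; stop codons are rendered as `*`; frames -1..-3 are
#' read off the reverse complement; trailing partial codons are dropped.
#'
#' @param dna a dna [seq_record()] of length >= 3.
#' @return named list of six protein strings, names `+1,+2,+3,-1,-2,-3`.
#' @export
translate_six_frames <- function(dna) {
  res <- residues_of(dna)
  id <- if (inherits(dna, "seq_record")) dna$id else "dna"
  if (inherits(dna, "seq_record") && dna$moltype != "dna") {
    stop("record '", id, "' is not dna")
  }
  if (nchar(res) < 3L) stop("record '", id, "': need >= 3 nt to translate")
  fwd <- Biostrings::DNAString(res)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, offset) {
    len <- length(s) - offset
    len <- len - (len %% 3L)
    if (len < 3L) return("")
    codons <- Biostrings::subseq(s, start = offset + 1L, width = len)
    as.character(suppressWarnings(
      Biostrings::translate(codons, if.fuzzy.codon = "solve",
                            no.init.codon = TRUE)))
  }
  frames <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
              one(rev, 0L), one(rev, 1L), one(rev, 2L))
  setNames(as.list(frames), c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Gap of length k costs `gap_open + k * gap_extend`. Ties among optimal
#' alignments are broken toward the smallest subject (`b`) start, then the
#' shortest subject span. Spans are `NA` when no cell scores above zero.
#'
#' @param a,b protein residue strings (or [seq_record()]s).
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap parameters (BLAST-style 11/1).
#' @return list with `score`, `a_span`, `b_span` (0-based half-open
#'   two-vectors, `NA` when empty).
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1) {
  a <- residues_of(a); b <- residues_of(b)
  if (!nzchar(a) || !nzchar(b)) stop("local_align: both sequences must be nonempty")
  res <- sw_align_cpp(a, b, matrix, rownames(matrix), gap_open, gap_extend)
  list(score = res$score,
       a_span = c(res$a_start, res$a_end),
       b_span = c(res$b_start, res$b_end))
}

#' Karlin-Altschul approximate E-value and bit score
#'
#' `E = K * m * n * exp(-lambda * S)` with fixed ungapped BLOSUM62 constants
#' (`lambda` = 0.267, `K` = 0.041). A filter, not a statistical claim.
#'
#' @param score raw alignment score.
#' @param m,n query and subject lengths.
#' @param lambda,K Karlin-Altschul constants.
#' @return list with `evalue` and `bit_score`.
#' @export
approx_evalue <- function(score, m, n, lambda = KA_LAMBDA, K = KA_K) {
  list(evalue = K * m * n * exp(-lambda * score),
       bit_score = (lambda * score - log(K)) / log(2))
}

#' Screen subjects against queries with iterative query expansion
#'
#' Each subject (protein, or DNA routed through [translate_six_frames()]) is
#' locally aligned against every query; hits passing the E-value cutoff (or
#' the raw-score threshold, when given) are retained. With `iterate = TRUE`
#' the matched subject regions of accepted hits are appended to the query set
#' and screening repeats until no new subject gains a hit (a fixpoint, reached
#' in at most `length(subjects)` rounds). This mirrors repeated homology
#' searches that reuse first-round homologues from related species as
#' additional queries.
#'
#' @param queries list of protein [seq_record()]s (>= 1).
#' @param subjects list of protein or dna [seq_record()]s.
#' @param evalue_cutoff keep hits with approximate E-value at or below this.
#' @param iterate expand queries with accepted hit regions until fixpoint.
#' @param min_raw_score if non-`NULL`, threshold on raw score instead of
#'   E-value.
#' @param matrix,gap_open,gap_extend passed to [local_align()].
#' @return data.frame of hits: `query_id`, `subject_id`, `frame`,
#'   `raw_score`, `bit_score`, `approx_evalue`, `subject_start`,
#'   `subject_end` (0-based half-open, translated coordinates), sorted by
#'   subject, query, frame.
#' @export
screen <- function(queries, subjects, evalue_cutoff = 1e-5, iterate = TRUE,
                   min_raw_score = NULL, matrix = blosum62(), gap_open = 11,
                   gap_extend = 1) {
  if (inherits(queries, "seq_record")) queries <- list(queries)
  if (inherits(subjects, "seq_record")) subjects <- list(subjects)
  if (!length(queries)) stop("need at least one query")
  if (!length(subjects)) stop("empty subject set")

  # expand subjects into translated search entries
  entries <- list()
  for (s in subjects) {
    if (s$moltype == "dna") {
      frames <- translate_six_frames(s)
      for (fr in names(frames)) {
        if (nzchar(frames[[fr]])) {
          entries[[length(entries) + 1L]] <-
            list(subject_id = s$id, frame = fr, residues = frames[[fr]])
        }
      }
    } else {
      entries[[length(entries) + 1L]] <-
        list(subject_id = s$id, frame = NA_character_, residues = s$residues)
    }
  }

  query_pool <- setNames(
    lapply(queries, residues_of),
    record_ids(queries)
  )
  done_pairs <- character(0L)  # "query\rsubject_entry" already aligned
  hits <- list()
  hit_subjects <- character(0L)
  n_aux <- 0L

  repeat {
    new_hit_subject <- FALSE
    for (qid in names(query_pool)) {
      qres <- query_pool[[qid]]
      for (k in seq_along(entries)) {
        key <- paste(qid, k, sep = "\r")
        if (key %in% done_pairs) next
        done_pairs <- c(done_pairs, key)
        ent <- entries[[k]]
        al <- local_align(qres, ent$residues, matrix = matrix,
                          gap_open = gap_open, gap_extend = gap_extend)
        if (al$score <= 0) next
        ka <- approx_evalue(al$score, nchar(qres), nchar(ent$residues))
        pass <- if (is.null(min_raw_score)) ka$evalue <= evalue_cutoff
                else al$score >= min_raw_score
        if (!pass) next
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = qid, subject_id = ent$subject_id, frame = ent$frame,
          raw_score = al$score, bit_score = ka$bit_score,
          approx_evalue = ka$evalue, subject_start = al$b_span[1L],
          subject_end = al$b_span[2L], stringsAsFactors = FALSE)
        if (!(ent$subject_id %in% hit_subjects)) {
          hit_subjects <- c(hit_subjects, ent$subject_id)
          new_hit_subject <- TRUE
          if (iterate) {
            n_aux <- n_aux + 1L
            region <- substr(ent$residues, al$b_span[1L] + 1L, al$b_span[2L])
            aux_id <- paste0(ent$subject_id, "_hitregion", n_aux)
            query_pool[[aux_id]] <- region
          }
        }
      }
    }
    if (!iterate || !new_hit_subject) break
  }

  if (!length(hits)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      frame = character(0), raw_score = numeric(0),
                      bit_score = numeric(0), approx_evalue = numeric(0),
                      subject_start = integer(0), subject_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$subject_id, out$query_id, out$frame,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
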