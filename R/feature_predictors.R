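# Rule-based structural feature calls. The signal-peptide rule is a
# von-Heijne-style heuristic (charged n-region, hydrophobic h-region,
# small-residue A-x-A cleavage site) and the disulfide rule pairs cysteines
# sequentially along the fold; both are documented approximations of the
# neural predictors used on real data, and can be overridden with external
# annotations via `read_feature_overrides()`.

SP_HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "C")
SP_SMALL <- c("A", "G", "S")

#' Heuristic signal-peptide prediction
#'
#' Positive iff, within the first 40 residues, all three hold:
#' an n-region with at least one K/R in positions 0-5; an h-region of >= 6
#' consecutive hydrophobic residues (A,I,L,M,F,V,W,C) starting in positions
#' 2-12; and a small-residue (A/G/S at -3 and -1) cleavage site ending at
#' some position 14-35. The cleavage position is the first such site's end.
#' Sequences shorter than 20 residues return negative.
#'
#' @param seq protein [seq_record()] or residue string.
#' @return list with `has_signal_peptide` (logical) and `cleavage_pos`
#'   (0-based index of the first mature residue, or `NA`).
#' @export
predict_signal_peptide <- function(seq) {
  res <- residues_of(seq)
  negative <- list(has_signal_peptide = FALSE, cleavage_pos = NA_integer_)
  if (nchar(res) < 20L) return(negative)
  head40 <- substr(res, 1L, min(40L, nchar(res)))
  ch <- strsplit(head40, "", fixed = TRUE)[[1L]]
  n <- length(ch)

  # n-region: K/R among 0-based positions 0..5
  if (!any(ch[seq_len(min(6L, n))] %in% c("K", "R"))) return(negative)

  # h-region: >= 6 consecutive hydrophobics starting at 0-based 2..12
  hydro <- ch %in% SP_HYDROPHOBIC
  run_len <- function(start1) {
    k <- 0L
    while (start1 + k <= n && hydro[start1 + k]) k <- k + 1L
    k
  }
  h_ok <- FALSE
  for (s0 in 2L:12L) {
    if (s0 + 1L > n) break
    if (run_len(s0 + 1L) >= 6L) { h_ok <- TRUE; break }
  }
  if (!h_ok) return(negative)

  # c-region: small residues at p-3 and p-1 for cleavage position p in 14..35
  for (p in 14L:35L) {
    if (p > n) break
    if (ch[p - 2L] %in% SP_SMALL && ch[p] %in% SP_SMALL) {
      return(list(has_signal_peptide = TRUE, cleavage_pos = p))
    }
  }
  negative
}

#' Sequential disulfide-bridge inference
#'
#' Cysteines at or downstream of the end of the Q-x-V-x-G motif are paired
#' sequentially (1st-2nd, 3rd-4th, ...), the non-crossing topology of the
#' type 2 cystatin fold. An odd trailing cysteine is left unpaired and
#' reported.
#'
#' @param seq mature protein [seq_record()] or residue string.
#' @param qxvxg_end 0-based half-open end of the Q-x-V-x-G motif on the same
#'   coordinate system.
#' @return list with `pairs` (list of 0-based cysteine index pairs) and
#'   `unpaired` (0-based index or `NULL`).
#' @export
infer_disulfides <- function(seq, qxvxg_end) {
  res <- residues_of(seq)
  ch <- strsplit(res, "", fixed = TRUE)[[1L]]
  cys <- which(ch == "C") - 1L
  if (!is.na(qxvxg_end)) cys <- cys[cys >= qxvxg_end]
  n_pair <- length(cys) %/% 2L
  pairs <- lapply(seq_len(n_pair), function(k) {
    c(cys[2L * k - 1L], cys[2L * k])
  })
  unpaired <- if (length(cys) %% 2L == 1L) cys[length(cys)] else NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Compute the per-sequence structural feature vector
#'
#' Runs the signal-peptide heuristic, the motif grammar on the mature
#' sequence, and disulfide inference; external annotations (when supplied)
#' override the heuristic signal-peptide and disulfide calls.
#'
#' @param record protein [seq_record()].
#' @param windows [motif_windows()].
#' @param overrides optional data.frame from [read_feature_overrides()].
#' @param intron_count optional intron count carried from an intron map.
#' @return object of class `structural_features`: `id`, `has_signal_peptide`,
#'   `cleavage_pos`, `mature_start`, `disulfide_pairs`, `unpaired_cysteine`,
#'   `motif_hits`, `intron_count`, `source`, `lineage`.
#' @export
structural_features <- function(record, windows = motif_windows(),
                                overrides = NULL,
                                intron_count = NA_integer_) {
  stopifnot(inherits(record, "seq_record"))
  if (record$moltype != "protein") {
    stop("record '", record$id, "': structural features need a protein record")
  }
  source <- "heuristic"
  ov <- NULL
  if (!is.null(overrides) && record$id %in% overrides$id) {
    ov <- overrides[overrides$id == record$id, , drop = FALSE][1L, ]
    source <- "external"
  }

  if (!is.null(ov)) {
    has_sp <- as.logical(ov$has_signal_peptide)
    cleavage <- if (has_sp) as.integer(ov$cleavage_pos) else NA_integer_
  } else {
    sp <- predict_signal_peptide(record)
    has_sp <- sp$has_signal_peptide
    cleavage <- sp$cleavage_pos
  }
  if (!is.na(cleavage) && cleavage > 60L) {
    stop("record '", record$id, "': cleavage position ", cleavage,
         " exceeds 60")
  }
  mature_start <- if (has_sp) cleavage else 0L

  motifs <- detect_motifs(record, mature_start = mature_start,
                          windows = windows)

  if (!is.null(ov) && nzchar(ov$disulfide_pairs %||% "")) {
    pairs <- parse_disulfide_pairs(ov$disulfide_pairs)
    unpaired <- NULL
  } else {
    qx <- motifs[motifs$motif == "QxVxG", ]
    mature <- substr(record$residues, mature_start + 1L,
                     nchar(record$residues))
    ds <- infer_disulfides(mature, qx$end)
    pairs <- ds$pairs
    unpaired <- ds$unpaired
  }

  structure(
    list(id = record$id, has_signal_peptide = has_sp,
         cleavage_pos = cleavage, mature_start = mature_start,
         disulfide_pairs = pairs, unpaired_cysteine = unpaired,
         motif_hits = motifs, intron_count = intron_count, source = source,
         lineage = record$lineage),
    class = "structural_features"
  )
}

#' @export
print.structural_features <- function(x, ...) {
  cat(sprintf("<structural_features %s: SP=%s, %d bridge(s), %d motif rows>\n",
              x$id, x$has_signal_peptide, length(x$disulfide_pairs),
              nrow(x$motif_hits)))
  invisible(x)
}

#' Read external feature annotations (heuristic overrides)
#'
#' TSV columns: `id`, `has_signal_peptide` (0/1), `cleavage_pos`,
#' `disulfide_pairs` (semicolon-separated `i-j` 0-based cysteine index
#' pairs, empty for none).
#'
#' @param path TSV path.
#' @return data.frame of overrides.
#' @export
read_feature_overrides <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("id", "has_signal_peptide", "cleavage_pos", "disulfide_pairs")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("override file lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

parse_disulfide_pairs <- function(x) {
  if (is.na(x) || !nzchar(x)) return(list())
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  lapply(parts, function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1L]]))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
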