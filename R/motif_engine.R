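# Grammar-based detection of the conserved cystatin-domain regions:
#   G_trunk       glycine in the amino-terminal trunk
#   QxVxG         first hairpin-loop consensus
#   hairpin2_pair the two-residue LP (stefin) / PW (type 2 cystatin) pair
#   DxLxYF_cterm  the stefin carboxy-terminal D-x-L-x-Y-F region
#   H_minus7      conserved histidine 7 residues N-terminal of the pair
#   K_minus8      conserved lysine 8 residues N-terminal of the C-terminal Y
# All coordinates are 0-based half-open on the ungapped *mature* sequence.

MOTIF_NAMES <- c("G_trunk", "QxVxG", "hairpin2_pair", "DxLxYF_cterm",
                 "H_minus7", "K_minus8")

# second-hairpin pair catalogue; substituted variants observed per taxon group
PAIR_STEFIN_CANONICAL <- "LP"
PAIR_CYSTATIN_CANONICAL <- "PW"
PAIR_STEFIN_SUBSTITUTED <- c("LD", "LS", "LY", "LR", "FK", "SA", "FD", "FS",
                             "FA", "LK")
PAIR_CYSTATIN_SUBSTITUTED <- c("AW", "RW", "SW", "KF", "GW", "PF", "PL")

#' Motif search windows
#'
#' The trunk glycine is sought in the first `trunk` mature residues, the
#' second-hairpin pair `hairpin2_min`..`hairpin2_max` residues downstream of
#' the G of Q-x-V-x-G, and the C-terminal region within the last `cterm`
#' residues. Window bounds are conventions of this implementation, exposed
#' for tuning.
#'
#' @param trunk,hairpin2_min,hairpin2_max,cterm window bounds in residues.
#' @return named list of window parameters.
#' @export
motif_windows <- function(trunk = 10L, hairpin2_min = 15L, hairpin2_max = 30L,
                          cterm = 12L) {
  list(trunk = as.integer(trunk), hairpin2_min = as.integer(hairpin2_min),
       hairpin2_max = as.integer(hairpin2_max), cterm = as.integer(cterm))
}

# similarity of a two-residue pair to the canonical LP / PW pairs
pair_similarity_score <- function(pair) {
  m <- blosum62()
  p <- strsplit(pair, "", fixed = TRUE)[[1L]]
  max(m[p[1L], "L"] + m[p[2L], "P"], m[p[1L], "P"] + m[p[2L], "W"])
}

motif_hit_row <- function(motif, start, end, matched, status) {
  data.frame(motif = motif, start = start, end = end, matched = matched,
             status = status, stringsAsFactors = FALSE)
}

absent_hit <- function(motif) {
  motif_hit_row(motif, NA_integer_, NA_integer_, NA_character_, "absent")
}

#' Classify a second-hairpin two-residue pair
#'
#' `LP` is the canonical stefin pair and `PW` the canonical type 2 cystatin
#' pair; catalogued variants are scored as substituted members of their
#' class; anything else is unassigned.
#'
#' @param matched two-residue string.
#' @return list with `class` (`stefin_class`, `cystatin_class`,
#'   `unassigned`) and `status` (`canonical`, `substituted`, `none`).
#' @export
classify_pair <- function(matched) {
  if (!is.character(matched) || length(matched) != 1L ||
      nchar(matched) != 2L) {
    stop("classify_pair: need exactly two residues")
  }
  matched <- toupper(matched)
  if (matched == PAIR_STEFIN_CANONICAL) {
    list(class = "stefin_class", status = "canonical")
  } else if (matched == PAIR_CYSTATIN_CANONICAL) {
    list(class = "cystatin_class", status = "canonical")
  } else if (matched %in% PAIR_STEFIN_SUBSTITUTED) {
    list(class = "stefin_class", status = "substituted")
  } else if (matched %in% PAIR_CYSTATIN_SUBSTITUTED) {
    list(class = "cystatin_class", status = "substituted")
  } else {
    list(class = "unassigned", status = "none")
  }
}

#' Detect conserved cystatin-domain motifs
#'
#' Applies the motif grammar to the mature part of a protein sequence:
#' \itemize{
#'   \item `G_trunk`: first G within the first `trunk` mature residues.
#'   \item `QxVxG`: first `Q.V.G` match downstream of the trunk glycine.
#'   \item `hairpin2_pair`: pair starting `hairpin2_min`..`hairpin2_max`
#'     residues downstream of the QxVxG glycine; the leftmost canonical
#'     LP/PW is preferred, otherwise the leftmost catalogued substituted
#'     pair, otherwise absent.
#'   \item `DxLxYF_cterm`: `D.L.YF`-style 6-mer within the final `cterm`
#'     residues; a partial match keeping the tyrosine (plus one more anchor)
#'     or keeping both D and L anchors is reported as substituted.
#'   \item `H_minus7`: residue exactly 7 positions N-terminal of the pair's
#'     first residue (canonical when H, substituted otherwise).
#'   \item `K_minus8`: residue exactly 8 positions N-terminal of the
#'     C-terminal conserved Y (canonical when K); absent whenever the Y
#'     anchor is absent.
#' }
#' Offsets are exact ungapped-sequence offsets; anchored motifs are reported
#' absent, never at dangling positions, when their anchor is missing.
#'
#' @param seq protein [seq_record()] or residue string.
#' @param mature_start 0-based index of the first mature residue (0 when no
#'   signal peptide).
#' @param windows [motif_windows()] configuration.
#' @return data.frame with one row per motif: `motif`, `start`, `end`
#'   (0-based half-open on the mature sequence), `matched`, `status`
#'   (`canonical` / `substituted` / `absent`).
#' @export
detect_motifs <- function(seq, mature_start = 0L, windows = motif_windows()) {
  res <- residues_of(seq)
  id <- if (inherits(seq, "seq_record")) seq$id else "sequence"
  if (mature_start >= nchar(res)) {
    stop("record '", id, "': mature_start beyond sequence end")
  }
  mature <- substr(res, mature_start + 1L, nchar(res))
  L <- nchar(mature)
  if (L < 30L) {
    stop("record '", id, "': mature sequence shorter than 30 residues, ",
         "cystatin domain cannot be annotated")
  }
  ch <- strsplit(mature, "", fixed = TRUE)[[1L]]

  hits <- list()

  # --- trunk glycine ---
  g_pos <- which(ch[seq_len(min(windows$trunk, L))] == "G")
  if (length(g_pos)) {
    g0 <- g_pos[1L] - 1L
    hits$G_trunk <- motif_hit_row("G_trunk", g0, g0 + 1L, "G", "canonical")
  } else {
    g0 <- NA_integer_
    hits$G_trunk <- absent_hit("G_trunk")
  }

  # --- QxVxG ---
  q_from <- if (is.na(g0)) 1L else g0 + 2L  # 1-based, downstream of trunk G
  q_match <- regexpr("Q.V.G", substr(mature, q_from, L))
  if (q_match > 0L) {
    q0 <- q_from + q_match - 2L  # 0-based start
    hits$QxVxG <- motif_hit_row("QxVxG", q0, q0 + 5L,
                                substr(mature, q0 + 1L, q0 + 5L), "canonical")
    qg0 <- q0 + 4L  # position of the motif's G
  } else {
    hits$QxVxG <- absent_hit("QxVxG")
    qg0 <- NA_integer_
  }

  # --- second hairpin pair ---
  pair0 <- NA_integer_
  if (!is.na(qg0)) {
    lo <- qg0 + windows$hairpin2_min
    hi <- min(qg0 + windows$hairpin2_max, L - 2L)
    if (lo <= hi) {
      starts <- lo:hi
      pairs <- substr(rep(mature, length(starts)), starts + 1L, starts + 2L)
      canonical <- pairs %in% c(PAIR_STEFIN_CANONICAL,
                                PAIR_CYSTATIN_CANONICAL)
      substituted <- pairs %in% c(PAIR_STEFIN_SUBSTITUTED,
                                  PAIR_CYSTATIN_SUBSTITUTED)
      if (any(canonical)) {
        k <- which(canonical)[1L]
        pair0 <- starts[k]
        hits$hairpin2_pair <- motif_hit_row("hairpin2_pair", pair0,
                                            pair0 + 2L, pairs[k], "canonical")
      } else if (any(substituted)) {
        # best-scoring catalogued pair: BLOSUM62 similarity to the
        # canonical LP/PW pairs, leftmost on ties
        cand <- which(substituted)
        scores <- vapply(pairs[cand], pair_similarity_score, numeric(1L))
        k <- cand[which.max(scores)]
        pair0 <- starts[k]
        hits$hairpin2_pair <- motif_hit_row("hairpin2_pair", pair0,
                                            pair0 + 2L, pairs[k],
                                            "substituted")
      }
    }
  }
  if (is.na(pair0)) hits$hairpin2_pair <- absent_hit("hairpin2_pair")

  # --- C-terminal D-x-L-x-Y-F ---
  ct_from0 <- max(0L, L - windows$cterm)
  best <- NULL
  for (s0 in ct_from0:(L - 6L)) {
    w <- ch[(s0 + 1L):(s0 + 6L)]
    anchors <- c(D = w[1L] == "D", L = w[3L] == "L", Y = w[5L] == "Y",
                 F = w[6L] == "F")
    n_anchor <- sum(anchors)
    if (all(anchors)) {
      status <- "canonical"
    } else if ((anchors[["Y"]] && n_anchor >= 2L) ||
               (anchors[["D"]] && anchors[["L"]])) {
      status <- "substituted"
    } else {
      next
    }
    score <- n_anchor + 10L * (status == "canonical")
    if (is.null(best) || score > best$score) {
      best <- list(s0 = s0, w = paste(w, collapse = ""), status = status,
                   score = score, has_y = anchors[["Y"]])
    }
  }
  if (!is.null(best)) {
    hits$DxLxYF_cterm <- motif_hit_row("DxLxYF_cterm", best$s0, best$s0 + 6L,
                                       best$w, best$status)
    y0 <- if (best$has_y) best$s0 + 4L else NA_integer_
  } else {
    hits$DxLxYF_cterm <- absent_hit("DxLxYF_cterm")
    y0 <- NA_integer_
  }

  # --- H at pair - 7 ---
  if (!is.na(pair0) && pair0 - 7L >= 0L) {
    p <- pair0 - 7L
    hits$H_minus7 <- motif_hit_row("H_minus7", p, p + 1L, ch[p + 1L],
                                   if (ch[p + 1L] == "H") "canonical"
                                   else "substituted")
  } else {
    hits$H_minus7 <- absent_hit("H_minus7")
  }

  # --- K at conserved Y - 8 ---
  if (!is.na(y0) && y0 - 8L >= 0L) {
    p <- y0 - 8L
    hits$K_minus8 <- motif_hit_row("K_minus8", p, p + 1L, ch[p + 1L],
                                   if (ch[p + 1L] == "K") "canonical"
                                   else "substituted")
  } else {
    hits$K_minus8 <- absent_hit("K_minus8")
  }

  out <- do.call(rbind, hits[MOTIF_NAMES])
  rownames(out) <- NULL
  out
}

#' Tabulate motif variants per taxon group
#'
#' Counts the observed motif variants (`matched` strings) per group and
#' motif, reproducing the comparative substitution scheme as data.
#'
#' @param annotations long data.frame with columns `id`, `motif`, `matched`,
#'   `status` (one row per motif per record, as produced by
#'   [annotate_records()]).
#' @param groups named character vector mapping record id to its group
#'   (typically the lineage).
#' @return data.frame `group`, `motif`, `variant`, `status`, `count`,
#'   ordered by group, motif, variant.
#' @export
substitution_table <- function(annotations, groups) {
  empty <- data.frame(group = character(0), motif = character(0),
                      variant = character(0), status = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (is.null(annotations) || !nrow(annotations)) return(empty)
  missing_ids <- setdiff(names(groups), unique(annotations$id))
  if (length(missing_ids)) {
    stop("record(s) lacking motif hits: ", paste(missing_ids, collapse = ", "))
  }
  ungrouped <- setdiff(unique(annotations$id), names(groups))
  if (length(ungrouped)) {
    stop("record(s) without a group tag: ", paste(ungrouped, collapse = ", "))
  }
  df <- annotations[!is.na(annotations$matched), , drop = FALSE]
  if (!nrow(df)) return(empty)
  df$group <- unname(groups[df$id])
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(df))),
    by = list(group = df$group, motif = df$motif, variant = df$matched,
              status = df$status),
    FUN = sum)
  agg <- agg[order(agg$group, agg$motif, agg$variant, method = "radix"), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("group", "motif", "variant", "status", "count")]
}
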