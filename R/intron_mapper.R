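# Reconciles a genomic sequence with its cDNA to locate introns. Exons must
# match the cDNA exactly (the inputs are assumed verified at desk scale);
# the mapper finds the minimal number of internal introns, preferring
# placements with canonical GT..AG junctions and then the leftmost placement
# when repeated nucleotides allow the boundary to slide. A greedy
# block-matcher handles clean data; a full dynamic program is the fallback.

#' Map introns by genomic vs cDNA comparison
#'
#' @param genomic dna [seq_record()] (or string) containing the gene.
#' @param cdna dna [seq_record()] (or string); must be reconstructable from
#'   `genomic` by removing zero or more internal blocks.
#' @param min_intron minimum intron length (room for GT + AG).
#' @param max_slide bound on boundary sliding explored when canonicalizing.
#' @return object of class `intron_map`: `gene_id`, `introns` (data.frame
#'   `genomic_start`, `genomic_end`, `donor`, `acceptor`,
#'   `cdna_insertion_point`, `phase`, `canonical`), `exons` (data.frame
#'   `genomic_start`, `genomic_end`). All coordinates 0-based half-open.
#'   Noncanonical junctions are flagged and reported with a warning, not
#'   rejected.
#' @export
map_introns <- function(genomic, cdna, min_intron = 4L, max_slide = 60L) {
  g <- toupper(residues_of(genomic))
  cd <- toupper(residues_of(cdna))
  gene_id <- if (inherits(genomic, "seq_record")) genomic$id else "gene"
  if (nchar(g) < nchar(cd)) {
    stop("gene '", gene_id, "': genomic shorter than cDNA")
  }
  gch <- strsplit(g, "", fixed = TRUE)[[1L]]
  cch <- strsplit(cd, "", fixed = TRUE)[[1L]]

  introns <- greedy_intron_scan(gch, cch, min_intron)
  if (is.null(introns) || !splice_matches(gch, cch, introns)) {
    introns <- dp_intron_scan(gch, cch, min_intron, gene_id)
  }
  introns <- canonicalize_introns(gch, introns, max_slide)
  build_intron_map(gene_id, gch, cch, introns)
}

# longest common prefix length of g[gi..] and c[ci..] (0-based offsets)
lcp_len <- function(gch, gi, cch, ci, limit) {
  if (limit <= 0L) return(0L)
  gs <- gch[(gi + 1L):(gi + limit)]
  cs <- cch[(ci + 1L):(ci + limit)]
  neq <- which(gs != cs)
  if (length(neq)) neq[1L] - 1L else limit
}

greedy_intron_scan <- function(gch, cch, min_intron) {
  nG <- length(gch); nC <- length(cch)
  introns <- list()
  gi <- 0L; ci <- 0L
  repeat {
    m <- lcp_len(gch, gi, cch, ci, min(nC - ci, nG - gi))
    if (ci + m == nC && gi + m == nG) return(introns)
    if (ci + m == nC) {
      # cDNA exhausted but genomic remains: boundary must slide left so the
      # trailing genomic block becomes an internal intron
      if (nG - gi - m < min_intron) return(NULL)
      prev_e <- if (length(introns)) introns[[length(introns)]][2L] else 0L
      lim <- min(m, gi + m - prev_e - 1L)
      smax <- 0L
      while (smax < lim && gch[nG - smax] == gch[gi + m - smax]) {
        smax <- smax + 1L
      }
      if (smax == 0L) return(NULL)
      cand <- lapply(1L:smax, function(s) c(gi + m - s, nG - s))
      best <- pick_canonical(gch, cand)
      introns[[length(introns) + 1L]] <- best
      return(introns)
    }
    # divergence: open an intron, resume at next exact match of the
    # remaining cDNA (probe)
    pl <- min(nC - ci - m, 15L)
    probe <- cch[(ci + m + 1L):(ci + m + pl)]
    rest_len <- nC - ci - m
    j <- NA_integer_
    jj <- gi + m + min_intron
    while (jj <= nG - rest_len) {
      if (all(gch[(jj + 1L):(jj + pl)] == probe)) { j <- jj; break }
      jj <- jj + 1L
    }
    if (is.na(j)) return(NULL)
    # slide options: exon boundary moves left by s when the s characters
    # before the divergence point re-occur just before the resumption point
    smax <- 0L
    lim <- min(m, gi + m - ifelse(length(introns),
                                  introns[[length(introns)]][2L], 0L) - 1L)
    while (smax < lim && gch[j - smax] == gch[gi + m - smax]) {
      smax <- smax + 1L
    }
    cand <- lapply(0L:smax, function(s) c(gi + m - s, j - s))
    best <- pick_canonical(gch, cand)
    introns[[length(introns) + 1L]] <- best
    s <- gi + m - best[1L]
    ci <- ci + m - s
    gi <- j - s
    if (length(introns) > length(cch)) return(NULL)  # safety
  }
}

# minimal-intron dynamic program; errors with a longest-prefix diagnostic
# when the cDNA cannot be reconstructed
dp_intron_scan <- function(gch, cch, min_intron, gene_id) {
  nG <- length(gch); nC <- length(cch)
  INF <- Inf
  D <- matrix(INF, nrow = nC + 1L, ncol = nG + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(nC)) {
    prev <- D[i, ]
    # intron closure: allowed only internally (after >= 1 cDNA char and
    # before the last one)
    E <- prev
    if (i >= 2L) {
      cm <- cummin(prev)
      idx <- seq_len(nG + 1L) - min_intron  # source column for each target
      shifted <- rep(INF, nG + 1L)
      ok <- idx >= 1L
      shifted[ok] <- cm[idx[ok]] + 1
      E <- pmin(prev, shifted)
    }
    match <- c(FALSE, gch == cch[i])
    row <- rep(INF, nG + 1L)
    row[match] <- E[which(match) - 1L]
    D[i + 1L, ] <- row
  }
  if (!is.finite(D[nC + 1L, nG + 1L])) {
    reach <- which(apply(is.finite(D), 1L, any))
    stop("gene '", gene_id, "': cDNA is not reconstructable from the ",
         "genomic sequence (longest reconstructable cDNA prefix: ",
         max(reach) - 1L, " of ", nC, " nt)")
  }
  # traceback; D[i+1, j+1] means c[i] was matched against g[j-1] with the
  # stated number of introns placed before it
  introns <- list()
  i <- nC; j <- nG
  while (i > 0L) {
    v <- D[i + 1L, j + 1L]
    prev <- D[i, ]  # row for i-1 consumed cDNA chars
    if (is.finite(prev[j]) && prev[j] == v) {
      # plain match, no intron before this character
      i <- i - 1L; j <- j - 1L
    } else {
      # an intron ended just before the matched character at genomic j-1
      jp <- which(is.finite(prev) & prev == v - 1) - 1L  # consumed counts
      jp <- jp[jp <= j - 1L - min_intron]
      jprime <- jp[length(jp)]  # rightmost source = shortest intron
      introns[[length(introns) + 1L]] <- c(jprime, j - 1L)
      i <- i - 1L; j <- jprime
    }
  }
  rev(introns)
}

splice_matches <- function(gch, cch, introns) {
  keep <- rep(TRUE, length(gch))
  for (iv in introns) {
    if (iv[2L] <= iv[1L]) return(FALSE)
    keep[(iv[1L] + 1L):iv[2L]] <- FALSE
  }
  spliced <- gch[keep]
  length(spliced) == length(cch) && all(spliced == cch)
}

pick_canonical <- function(gch, candidates) {
  score <- vapply(candidates, function(iv) {
    donor <- paste0(gch[iv[1L] + 1L], gch[iv[1L] + 2L])
    acceptor <- paste0(gch[iv[2L] - 1L], gch[iv[2L]])
    (donor == "GT") + (acceptor == "AG")
  }, numeric(1L))
  starts <- vapply(candidates, `[`, numeric(1L), 1L)
  best <- which(score == max(score))
  candidates[[best[which.min(starts[best])]]]
}

# slide each intron within its repeated-content window to the
# GT/AG-maximizing, then leftmost, representative
canonicalize_introns <- function(gch, introns, max_slide) {
  if (!length(introns)) return(introns)
  nG <- length(gch)
  ord <- order(vapply(introns, `[`, numeric(1L), 1L))
  introns <- introns[ord]
  for (k in seq_along(introns)) {
    b <- introns[[k]][1L]; e <- introns[[k]][2L]
    prev_e <- if (k > 1L) introns[[k - 1L]][2L] else 0L
    next_b <- if (k < length(introns)) introns[[k + 1L]][1L] else nG
    # left slides
    sl <- 0L
    while (sl < max_slide && b - sl - 1L >= prev_e + 1L &&
           gch[b - sl] == gch[e - sl]) {
      sl <- sl + 1L
    }
    # right slides
    sr <- 0L
    while (sr < max_slide && e + sr + 1L <= next_b - 1L &&
           e + sr + 1L <= nG - 1L && gch[b + sr + 1L] == gch[e + sr + 1L]) {
      sr <- sr + 1L
    }
    cand <- lapply(seq(-sl, sr), function(s) c(b + s, e + s))
    introns[[k]] <- pick_canonical(gch, cand)
  }
  introns
}

build_intron_map <- function(gene_id, gch, cch, introns) {
  nG <- length(gch)
  if (!splice_matches(gch, cch, introns)) {
    stop("gene '", gene_id, "': internal error, spliced exons do not ",
         "reproduce the cDNA")
  }
  introns <- introns[order(vapply(introns, `[`, numeric(1L), 1L))]
  starts <- vapply(introns, `[`, numeric(1L), 1L)
  ends <- vapply(introns, `[`, numeric(1L), 2L)

  exon_starts <- c(0L, ends)
  exon_ends <- c(starts, nG)
  exons <- data.frame(genomic_start = as.integer(exon_starts),
                      genomic_end = as.integer(exon_ends))

  if (length(introns)) {
    exon_lens <- exon_ends - exon_starts
    insertion <- cumsum(exon_lens)[seq_along(introns)]
    donor <- vapply(introns, function(iv) {
      paste0(gch[iv[1L] + 1L], gch[iv[1L] + 2L])
    }, character(1L))
    acceptor <- vapply(introns, function(iv) {
      paste0(gch[iv[2L] - 1L], gch[iv[2L]])
    }, character(1L))
    canonical <- donor == "GT" & acceptor == "AG"
    idf <- data.frame(genomic_start = as.integer(starts),
                      genomic_end = as.integer(ends), donor = donor,
                      acceptor = acceptor,
                      cdna_insertion_point = as.integer(insertion),
                      phase = as.integer(insertion %% 3L),
                      canonical = canonical, stringsAsFactors = FALSE)
    if (any(!canonical)) {
      warning("gene '", gene_id, "': ", sum(!canonical),
              " intron(s) with noncanonical junctions")
    }
  } else {
    idf <- data.frame(genomic_start = integer(0), genomic_end = integer(0),
                      donor = character(0), acceptor = character(0),
                      cdna_insertion_point = integer(0), phase = integer(0),
                      canonical = logical(0), stringsAsFactors = FALSE)
  }
  structure(list(gene_id = gene_id, introns = idf, exons = exons),
            class = "intron_map")
}

#' @export
print.intron_map <- function(x, ...) {
  cat(sprintf("<intron_map %s: %d intron(s), %d exon(s)>\n", x$gene_id,
              nrow(x$introns), nrow(x$exons)))
  invisible(x)
}

#' Splice exons out of a genomic sequence
#'
#' @param genomic dna [seq_record()] or string.
#' @param map [map_introns()] result.
#' @return the reconstructed cDNA string.
#' @export
splice <- function(genomic, map) {
  g <- residues_of(genomic)
  paste(vapply(seq_len(nrow(map$exons)), function(k) {
    substr(g, map$exons$genomic_start[k] + 1L, map$exons$genomic_end[k])
  }, character(1L)), collapse = "")
}

#' Project intron positions onto a protein alignment
#'
#' Maps each intron insertion point to its codon, then to the mature-protein
#' residue and that residue's alignment column, so intron positions can be
#' compared across genes. Introns falling inside a codon are reported with
#' their phase (1 or 2), never dropped.
#'
#' @param maps list of [map_introns()] results.
#' @param aln protein [alignment()] containing a row per gene.
#' @param cds_offsets named integer vector: 0-based offset of the first
#'   codon's first nucleotide within each cDNA (default 0 for all genes).
#' @return data.frame `gene`, `intron` (ordinal, 1-based), `column`
#'   (0-based alignment column), `phase`, sorted by column.
#' @export
intron_positions_on_alignment <- function(maps, aln, cds_offsets = NULL) {
  rows <- list()
  for (map in maps) {
    gid <- map$gene_id
    if (!gid %in% aln$ids) {
      stop("gene '", gid, "' absent from the alignment")
    }
    off <- if (!is.null(cds_offsets) && gid %in% names(cds_offsets)) {
      as.integer(cds_offsets[[gid]])
    } else 0L
    row <- aln$rows[[gid]]
    cols0 <- which(strsplit(row, "", fixed = TRUE)[[1L]] != "-") - 1L
    if (nrow(map$introns)) {
      for (k in seq_len(nrow(map$introns))) {
        ins <- map$introns$cdna_insertion_point[k] - off
        if (ins < 0L) stop("gene '", gid, "': intron upstream of the CDS")
        resid <- ins %/% 3L
        phase <- ins %% 3L
        if (resid + 1L > length(cols0)) {
          stop("gene '", gid, "': intron beyond the aligned protein")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gid, intron = k, column = cols0[resid + 1L],
          phase = as.integer(phase), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), intron = integer(0),
                      column = integer(0), phase = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$column, out$gene, out$intron), , drop = FALSE]
  rownames(out) <- NULL
  out
}
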