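# The central decision procedure: a pure function from the structural feature
# vector to a cystatin subtype, with a fired-rule trace. The rules codify the
# textbook subtype definitions (stefins: intracellular, no signal peptide, no
# bridges, D-x-L-x-Y-F C-terminus; type 2 cystatins: secreted, bridged, no
# stefin C-terminus) plus the atypical-stefin definition (stefin-like pair
# with the C-terminal region missing, without / with a signal peptide).
# Contradictory feature combinations are left unclassified, never forced.

SUBTYPE_LABELS <- c("classical_stefin", "atypical_stefin_type1",
                    "atypical_stefin_type2", "type2_cystatin", "unclassified")

#' Classify an annotated sequence into a cystatin subtype
#'
#' Decision order:
#' \enumerate{
#'   \item `type2_cystatin`: cystatin-class pair, signal peptide, >= 1
#'     disulfide bridge, D-x-L-x-Y-F absent.
#'   \item `classical_stefin`: stefin-class pair, D-x-L-x-Y-F present
#'     (canonical or substituted), no signal peptide, no bridges.
#'   \item `atypical_stefin_type1`: stefin-class pair, D-x-L-x-Y-F absent,
#'     no signal peptide, no bridges.
#'   \item `atypical_stefin_type2`: as (3) but with a signal peptide.
#'   \item otherwise `unclassified`, with the failing criteria in the trace.
#' }
#' A substituted C-terminal region that has lost its tyrosine still counts as
#' present (the D/L anchors carry it); tyrosine presence is flagged in
#' `notes` because of its role in stabilising the inhibitor-protease complex.
#'
#' @param f [structural_features()] object.
#' @return object of class `subtype_call`: `id`, `label`, `rule_trace`
#'   (character vector of `criterion=outcome`), `notes`, `lineage`.
#' @export
classify <- function(f) {
  stopifnot(inherits(f, "structural_features"))
  need <- c("has_signal_peptide", "disulfide_pairs", "motif_hits")
  for (field in need) {
    if (is.null(f[[field]])) stop("missing feature field '", field, "'")
  }
  hits <- f$motif_hits
  pair <- hits[hits$motif == "hairpin2_pair", ]
  dxl <- hits[hits$motif == "DxLxYF_cterm", ]

  pair_class <- if (pair$status == "absent") "unassigned"
                else classify_pair(pair$matched)$class
  dxl_present <- dxl$status != "absent"
  dxl_has_y <- dxl_present && substr(dxl$matched, 5L, 5L) == "Y"
  has_sp <- isTRUE(f$has_signal_peptide)
  n_bridges <- length(f$disulfide_pairs)

  trace <- c(
    paste0("pair_class=", pair_class),
    paste0("pair_status=", pair$status),
    paste0("DxLxYF=", dxl$status),
    paste0("signal_peptide=", has_sp),
    paste0("disulfide_bridges=", n_bridges)
  )

  label <-
    if (pair_class == "cystatin_class" && has_sp && n_bridges >= 1L &&
        !dxl_present) {
      "type2_cystatin"
    } else if (pair_class == "stefin_class" && dxl_present && !has_sp &&
               n_bridges == 0L) {
      "classical_stefin"
    } else if (pair_class == "stefin_class" && !dxl_present && !has_sp &&
               n_bridges == 0L) {
      "atypical_stefin_type1"
    } else if (pair_class == "stefin_class" && !dxl_present && has_sp &&
               n_bridges == 0L) {
      "atypical_stefin_type2"
    } else {
      "unclassified"
    }

  notes <- character(0)
  if (pair$status == "substituted") {
    notes <- c(notes, paste0("pair_substituted:", pair$matched))
  }
  if (dxl_present && dxl$status == "substituted") {
    notes <- c(notes, paste0("cterm_substituted:", dxl$matched),
               paste0("cterm_tyrosine:", if (dxl_has_y) "present" else "lost"))
  }
  h7 <- hits[hits$motif == "H_minus7", ]
  if (h7$status == "substituted") {
    notes <- c(notes, paste0("H_minus7_replaced:", h7$matched))
  }
  k8 <- hits[hits$motif == "K_minus8", ]
  if (k8$status == "substituted") {
    notes <- c(notes, paste0("K_minus8_replaced:", k8$matched))
  }

  structure(list(id = f$id, label = label, rule_trace = trace,
                 notes = notes, lineage = f$lineage),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("<subtype_call %s: %s>\n", x$id, x$label))
  invisible(x)
}

#' Annotate a set of protein records
#'
#' Convenience wrapper: computes [structural_features()] for every record and
#' returns both the feature objects and a long motif table.
#'
#' @param records list of protein [seq_record()]s.
#' @param windows [motif_windows()].
#' @param overrides optional [read_feature_overrides()] table.
#' @return list with `features` (named list of [structural_features()]) and
#'   `motifs` (long data.frame with an `id` column).
#' @export
annotate_records <- function(records, windows = motif_windows(),
                             overrides = NULL) {
  feats <- lapply(records, structural_features, windows = windows,
                  overrides = overrides)
  names(feats) <- record_ids(records)
  motifs <- do.call(rbind, lapply(feats, function(f) {
    cbind(data.frame(id = f$id, stringsAsFactors = FALSE), f$motif_hits)
  }))
  rownames(motifs) <- NULL
  list(features = feats, motifs = motifs)
}

#' Classify a set of annotated records
#'
#' @param features list of [structural_features()].
#' @return data.frame `id`, `label`, `lineage`, `rule_trace`
#'   (pipe-collapsed), `notes` (pipe-collapsed).
#' @export
classify_records <- function(features) {
  calls <- lapply(features, classify)
  data.frame(
    id = vapply(calls, `[[`, character(1L), "id"),
    label = vapply(calls, `[[`, character(1L), "label"),
    lineage = vapply(calls, function(x) x$lineage %||% NA_character_,
                     character(1L)),
    rule_trace = vapply(calls, function(x) paste(x$rule_trace,
                                                 collapse = "|"),
                        character(1L)),
    notes = vapply(calls, function(x) paste(x$notes, collapse = "|"),
                   character(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Summarise subtype calls into a lineage x character presence matrix
#'
#' Presence is 1 iff the lineage has at least one call of the label family;
#' `atypical_stefin_type1` and `atypical_stefin_type2` collapse into
#' `atypical_stefin`. Multi-domain cystatins are not detected by this
#' pipeline, so that column is always 0.
#'
#' @param calls data.frame from [classify_records()] with a `lineage` column,
#'   or a list of `subtype_call`s.
#' @param lineages optional character vector fixing row order (defaults to
#'   order of first appearance).
#' @return [presence_matrix()].
#' @export
repertoire_summary <- function(calls, lineages = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- data.frame(
      id = vapply(calls, `[[`, character(1L), "id"),
      label = vapply(calls, `[[`, character(1L), "label"),
      lineage = vapply(calls, function(x) x$lineage %||% NA_character_,
                       character(1L)),
      stringsAsFactors = FALSE)
  }
  if (nrow(calls) && anyNA(calls$lineage)) {
    stop("every call must carry a lineage")
  }
  if (is.null(lineages)) lineages <- unique(calls$lineage)
  m <- matrix(0L, nrow = length(lineages), ncol = length(PRESENCE_CHARACTERS),
              dimnames = list(lineages, PRESENCE_CHARACTERS))
  if (nrow(calls)) {
    fam <- c(classical_stefin = "stefin", type2_cystatin = "type2_cystatin",
             atypical_stefin_type1 = "atypical_stefin",
             atypical_stefin_type2 = "atypical_stefin")
    keep <- calls$label %in% names(fam)
    for (k in which(keep)) {
      m[calls$lineage[k], fam[[calls$label[k]]]] <- 1L
    }
  }
  presence_matrix(m)
}
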