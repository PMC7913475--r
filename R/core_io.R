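#' @useDynLib cystakit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom stats setNames as.dist cophenetic
NULL

# Coordinate convention used package-wide: 0-based, half-open [start, end).

PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                      "R","S","T","V","W","Y","X")
DNA_ALPHABET <- c("A","C","G","T","N")

PRESENCE_CHARACTERS <- c("stefin", "type2_cystatin", "atypical_stefin",
                         "multidomain")

#' Create a sequence record
#'
#' A `seq_record` holds one protein or nucleotide sequence together with its
#' identity, free-text description, taxon and optional lineage tag
#' (e.g. `"Porifera"`, `"Myxosporea"`). Residues are validated against the
#' moltype alphabet (20 amino acids + X, or ACGT + N).
#'
#' @param id unique identifier token.
#' @param residues character scalar of residues, no gaps.
#' @param moltype `"protein"` or `"dna"`.
#' @param description free text (FASTA header remainder).
#' @param taxon free-text taxon name.
#' @param lineage optional lineage token, matched case-insensitively against
#'   species-tree tips.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, residues, moltype = c("protein", "dna"),
                       description = "", taxon = "", lineage = NA_character_) {
  moltype <- match.arg(moltype)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    stop("record '", id, "': residues must be nonempty")
  }
  check_alphabet(residues, moltype, id)
  structure(
    list(id = id, description = description, residues = residues,
         moltype = moltype, taxon = taxon, lineage = lineage),
    class = "seq_record"
  )
}

check_alphabet <- function(residues, moltype, id) {
  alphabet <- if (moltype == "dna") DNA_ALPHABET else PROTEIN_ALPHABET
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop("record '", id, "': illegal ", moltype, " character '",
         chars[bad[1L]], "' at position ", bad[1L] - 1L)
  }
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s (%s, %d residues)%s>\n", x$id, x$moltype,
              nchar(x$residues),
              if (!is.na(x$lineage)) paste0(" lineage=", x$lineage) else ""))
  invisible(x)
}

record_ids <- function(records) vapply(records, `[[`, character(1L), "id")

residues_of <- function(x) {
  if (inherits(x, "seq_record")) x$residues else as.character(x)
}

#' Read a plain (ungapped) FASTA file
#'
#' Headers are parsed as `">id description"`. When `moltype` is `NULL` it is
#' inferred from the pooled residue content of the whole file: if at least 90%
#' of characters fall in `ACGTN` the file is read as DNA, otherwise as
#' protein. `*` stop characters are stripped with a warning; gap characters
#' are rejected (use [read_alignment()] for gapped FASTA).
#'
#' @param path FASTA file path.
#' @param moltype `"protein"`, `"dna"`, or `NULL` to infer.
#' @param lineage optional lineage tag applied to all records.
#' @return list of [seq_record()] in file order.
#' @export
read_fasta <- function(path, moltype = NULL, lineage = NA_character_) {
  raw <- read_fasta_raw(path)
  ids <- raw$ids
  dup <- anyDuplicated(ids)
  if (dup) stop("duplicate id '", ids[dup], "' in ", path)
  seqs <- toupper(raw$seqs)
  if (any(grepl("-", seqs, fixed = TRUE))) {
    bad <- ids[grepl("-", seqs, fixed = TRUE)][1L]
    stop("record '", bad, "': gap characters are not allowed in plain FASTA")
  }
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop characters from ", path)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (is.null(moltype)) moltype <- infer_moltype(seqs)
  mapply(function(id, desc, s) seq_record(id, s, moltype, description = desc,
                                          lineage = lineage),
         ids, raw$descs, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Biostrings does the FASTA lexing; header split and validation happen here.
read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("empty FASTA header in ", path)
  list(ids = ids, descs = descs, seqs = as.character(set))
}

infer_moltype <- function(seqs) {
  chars <- unlist(strsplit(toupper(paste(seqs, collapse = "")), "",
                           fixed = TRUE))
  if (mean(chars %in% DNA_ALPHABET) >= 0.9) "dna" else "protein"
}

#' Write sequence records as FASTA
#'
#' Lines are wrapped at 60 columns.
#'
#' @param records list of [seq_record()] (or a gapped named character vector).
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1L))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1L),
                                       "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Construct an alignment from gapped rows
#'
#' @param rows named character vector of equal-length gapped strings
#'   (`-` gaps); names are the sequence ids.
#' @return object of class `cysta_alignment` with elements `ids`, `rows`,
#'   `n_columns`.
#' @export
alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  if (anyDuplicated(names(rows))) {
    stop("duplicate row id '", names(rows)[anyDuplicated(names(rows))], "'")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- names(rows)[which(widths != widths[1L])[1L]]
    stop("ragged alignment: row '", bad, "' has length ",
         nchar(rows[[bad]]), ", expected ", widths[1L])
  }
  structure(list(ids = names(rows), rows = toupper(rows),
                 n_columns = unname(widths[1L])),
            class = "cysta_alignment")
}

#' @export
print.cysta_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d rows x %d columns>\n", length(x$ids),
              x$n_columns))
  invisible(x)
}

#' Read a gapped FASTA alignment
#'
#' @param path gapped FASTA path with at least two rows.
#' @return [alignment()] object; ragged rows raise an error naming the row.
#' @export
read_alignment <- function(path) {
  raw <- read_fasta_raw(path)
  dup <- anyDuplicated(raw$ids)
  if (dup) stop("duplicate id '", raw$ids[dup], "' in ", path)
  alignment(setNames(toupper(raw$seqs), raw$ids))
}

#' Write an alignment as gapped FASTA
#' @param aln [alignment()] object.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$rows)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Remove gaps from an alignment row
#' @param x gapped string.
#' @return ungapped string.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Read a lineage x character presence/absence matrix
#'
#' TSV with the lineage label in the first column and one column per
#' character; cells must be 0 or 1. Character names must come from
#' `stefin`, `type2_cystatin`, `atypical_stefin`, `multidomain`.
#'
#' @param path TSV path (lines starting with `#` are ignored).
#' @return integer matrix of class `presence_matrix` with lineage rownames.
#' @export
read_presence_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("presence matrix needs a lineage column plus >=1 character column")
  lineages <- as.character(df[[1L]])
  if (anyDuplicated(lineages)) {
    stop("duplicate lineage label '", lineages[anyDuplicated(lineages)], "'")
  }
  chars <- colnames(df)[-1L]
  unknown <- setdiff(chars, PRESENCE_CHARACTERS)
  if (length(unknown)) {
    stop("unknown character name(s): ", paste(unknown, collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!vals %in% c("0", "1", 0L, 1L))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(vals)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(vals)) + 1L
    stop("non-binary cell '", vals[i, j], "' at lineage '",
         lineages[i], "', character '", chars[j], "'")
  }
  presence_matrix(matrix(as.integer(vals), nrow = nrow(vals),
                         dimnames = list(lineages, chars)))
}

#' Construct a presence matrix
#' @param m integer 0/1 matrix, lineages as rownames, characters as colnames.
#' @export
presence_matrix <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate lineage labels")
  if (!all(m %in% c(0L, 1L))) stop("presence values must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("presence_matrix", "matrix")
  m
}

#' Write a presence matrix as TSV
#' @param m [presence_matrix()].
#' @param path output path.
#' @param seed optional seed recorded in the commented header.
#' @export
write_presence_matrix <- function(m, path, seed = NULL) {
  df <- data.frame(lineage = rownames(m), unclass(m), check.names = FALSE,
                   row.names = NULL)
  write_tsv_commented(df, path, seed = seed)
}

#' Read a rooted species tree from newick
#'
#' @param path newick file.
#' @return `ape::phylo` tree; tip labels must be unique.
#' @export
read_species_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("cannot parse newick in ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label '",
         tree$tip.label[anyDuplicated(tree$tip.label)], "'")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths in ", path)
  }
  tree
}

#' Map lineage labels to species-tree tips (case-insensitive)
#'
#' @param lineages character vector of lineage tokens.
#' @param tree `phylo` tree.
#' @return integer vector of tip indices, named by lineage.
#' @export
match_lineage_tips <- function(lineages, tree) {
  idx <- match(tolower(lineages), tolower(tree$tip.label))
  if (anyNA(idx)) {
    stop("lineage(s) with no matching tree tip: ",
         paste(lineages[is.na(idx)], collapse = ", "))
  }
  setNames(idx, lineages)
}

#' Path to a packaged fixture
#' @param file file name under `extdata`.
#' @export
cystakit_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cystakit")
  if (!nzchar(path)) stop("no packaged file '", file, "'")
  path
}

# All TSV outputs carry a commented header naming tool version and seed.
write_tsv_commented <- function(df, path, seed = NULL) {
  header <- paste0("# cystakit ", as.character(packageVersion("cystakit")),
                   if (!is.null(seed)) paste0(" seed=", seed) else "")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  )
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
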