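# Orchestrates the full run: (simulate|load) -> annotate -> features ->
# classify -> introns -> profile -> evolve, writing one TSV per stage plus a
# manifest with input/output digests. Reruns with the same config and seed
# are byte-identical (no timestamps are written).

#' Build a validated pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in all outputs and used for every
#'   random stage.
#' @param simulate optional [family_config()]; when given, inputs are
#'   generated rather than read.
#' @param proteins,genomic,cdna,alignment,tree,matrix optional input paths
#'   (protein FASTA, genomic/cDNA FASTA pairs keyed by shared id, gapped
#'   FASTA, newick, presence TSV).
#' @param character character analysed in the evolve stage.
#' @param evalue_cutoff,min_occupancy,gain_penalty,max_gains,windows
#'   stage thresholds (documented at each stage's function).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = NULL, proteins = NULL,
                       genomic = NULL, cdna = NULL, alignment = NULL,
                       tree = NULL, matrix = NULL,
                       character = "type2_cystatin", evalue_cutoff = 1e-5,
                       min_occupancy = 0.5, gain_penalty = 2, max_gains = 3L,
                       windows = motif_windows()) {
  if (is.null(simulate) && is.null(proteins)) {
    stop("config needs either a simulate block or a proteins input")
  }
  stopifnot(evalue_cutoff > 0, min_occupancy > 0, min_occupancy <= 1,
            gain_penalty > 0, max_gains >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, proteins = proteins, genomic = genomic,
                 cdna = cdna, alignment = alignment, tree = tree,
                 matrix = matrix, character = character,
                 evalue_cutoff = evalue_cutoff,
                 min_occupancy = min_occupancy, gain_penalty = gain_penalty,
                 max_gains = as.integer(max_gains), windows = windows),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; a `simulate`
#' block maps onto [family_config()].
#'
#' @param path YAML file.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    # subtype counts live under `counts` (YAML 1.1 reads a bare `n` key as
    # a boolean, so that spelling is tolerated but not documented)
    counts <- sim$counts %||% sim[["n"]] %||% sim[["FALSE"]]
    raw$simulate <- family_config(
      n = unlist(counts), lineage = sim$lineage %||% "Synthetica",
      pair_variants = sim$pair_variants,
      mutation_rate = sim$mutation_rate %||% 0,
      intron_counts = sim$intron_counts,
      seed = sim$seed %||% raw$seed %||% 1L)
  }
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full annotation/classification pipeline
#'
#' @param config [run_config()].
#' @return invisibly, a list with the per-stage results and the manifest
#'   data.frame; all stage TSVs and the manifest are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out <- function(f) file.path(config$out_dir, f)
  inputs <- character(0)
  results <- list()

  # --- acquire inputs ---
  if (!is.null(config$simulate)) {
    fam <- stage("simulate", make_family(config$simulate))
    write_fasta(fam$proteins, out("proteins.faa"))
    write_fasta(fam$genomic, out("genomic.fna"))
    write_fasta(fam$cdna, out("cdna.fna"))
    write_tsv_commented(fam$truth, out("ground_truth.tsv"),
                        seed = config$seed)
    proteins <- fam$proteins
    genomic <- fam$genomic
    cdna <- fam$cdna
    results$family <- fam
  } else {
    proteins <- stage("load", {
      if (!file.exists(config$proteins)) {
        stop("missing input file ", config$proteins)
      }
      read_fasta(config$proteins, moltype = "protein")
    })
    genomic <- if (!is.null(config$genomic)) {
      stage("load", read_fasta(config$genomic, moltype = "dna"))
    }
    cdna <- if (!is.null(config$cdna)) {
      stage("load", read_fasta(config$cdna, moltype = "dna"))
    }
    for (p in c(config$proteins, config$genomic, config$cdna)) {
      inputs <- c(inputs, p)
    }
  }

  # --- annotate + features + classify ---
  ann <- stage("annotate",
               annotate_records(proteins, windows = config$windows))
  write_tsv_commented(ann$motifs, out("motifs.tsv"), seed = config$seed)

  feat_df <- stage("features", data.frame(
    id = vapply(ann$features, `[[`, character(1L), "id"),
    has_signal_peptide = vapply(ann$features, `[[`, logical(1L),
                                "has_signal_peptide"),
    cleavage_pos = vapply(ann$features, function(f) {
      f$cleavage_pos %||% NA_integer_
    }, integer(1L)),
    n_disulfide_bridges = vapply(ann$features, function(f) {
      length(f$disulfide_pairs)
    }, integer(1L)),
    source = vapply(ann$features, `[[`, character(1L), "source"),
    lineage = vapply(ann$features, function(f) f$lineage %||% NA_character_,
                     character(1L)),
    stringsAsFactors = FALSE, row.names = NULL))
  write_tsv_commented(feat_df, out("features.tsv"), seed = config$seed)

  calls <- stage("classify", classify_records(ann$features))
  write_tsv_commented(calls, out("calls.tsv"), seed = config$seed)
  results$calls <- calls

  if (!anyNA(calls$lineage) && nrow(calls)) {
    rep_m <- stage("repertoire", repertoire_summary(calls))
    write_presence_matrix(rep_m, out("repertoire.tsv"), seed = config$seed)
    results$repertoire <- rep_m
  }

  # --- introns ---
  if (!is.null(genomic) && !is.null(cdna)) {
    maps <- stage("introns", {
      cd_ids <- record_ids(cdna)
      lapply(genomic, function(g) {
        k <- match(g$id, cd_ids)
        if (is.na(k)) stop("no cDNA for gene '", g$id, "'")
        map_introns(g, cdna[[k]])
      })
    })
    intron_df <- do.call(rbind, lapply(maps, function(m) {
      if (!nrow(m$introns)) return(NULL)
      cbind(data.frame(gene = m$gene_id, stringsAsFactors = FALSE),
            m$introns)
    }))
    if (is.null(intron_df)) {
      intron_df <- data.frame(gene = character(0))
    }
    write_tsv_commented(intron_df, out("introns.tsv"), seed = config$seed)
    results$intron_maps <- maps
  }

  # --- conservation profile ---
  if (!is.null(config$alignment)) {
    prof <- stage("profile", {
      aln <- read_alignment(config$alignment)
      trimmed <- trim_alignment(aln, min_occupancy = config$min_occupancy)
      column_information(trimmed)
    })
    write_tsv_commented(
      prof[, c("column", "information_content", "consensus",
               "gap_fraction")],
      out("profile.tsv"), seed = config$seed)
    inputs <- c(inputs, config$alignment)
    results$profile <- prof
  }

  # --- gain/loss scenarios ---
  if (!is.null(config$tree) && !is.null(config$matrix)) {
    scen <- stage("evolve", {
      tree <- read_species_tree(config$tree)
      m <- read_presence_matrix(config$matrix)
      states <- tip_states_from_matrix(m, config$character)
      enumerate_scenarios(tree, states, max_gains = config$max_gains,
                          gain_penalty = config$gain_penalty,
                          character = config$character)
    })
    write_tsv_commented(scenario_table(scen), out("scenarios.tsv"),
                        seed = config$seed)
    inputs <- c(inputs, config$tree, config$matrix)
    results$scenarios <- scen
  }

  # --- manifest ---
  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, out("manifest.tsv"))
  manifest <- rbind(
    data.frame(item = "cystakit_version",
               value = as.character(packageVersion("cystakit")),
               stringsAsFactors = FALSE),
    data.frame(item = "seed", value = as.character(config$seed),
               stringsAsFactors = FALSE),
    if (length(inputs)) {
      data.frame(item = paste0("input:", basename(inputs)),
                 value = unname(tools::md5sum(inputs)),
                 stringsAsFactors = FALSE)
    },
    data.frame(item = paste0("output:", basename(outputs)),
               value = unname(tools::md5sum(outputs)),
               stringsAsFactors = FALSE)
  )
  write_tsv_commented(manifest, out("manifest.tsv"), seed = config$seed)
  results$manifest <- manifest
  invisible(results)
}
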