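# Stage orchestration: the query surface that ties UTR construction,
# engines, validation, calibration, consensus and evaluation together, with
# flat-file outputs and a run-metadata echo. The command-line wrapper in
# exec/mircons is a thin shell over these functions.

consensus_columns <- c("mirna_id", "gene_symbol", "transcript_id", "biotype",
                       "utr_source", "site_types", "utr_start", "utr_end",
                       "chrom", "g_start", "g_end", "strand", "engines",
                       "raw_scores", "zs", "ws", "agreement",
                       "agreement_exact", "cws", "validated",
                       "validated_sources", "validated_tier")

# Attach gene/biotype/utr_source metadata and member UTR spans to groups.
annotate_groups <- function(groups, sites, space) {
  m <- match(groups$transcript_id, space$meta$transcript_id)
  groups$gene_symbol <- space$meta$gene_symbol[m]
  groups$biotype <- space$meta$biotype[m]
  groups$utr_source <- space$meta$utr_source[m]
  groups$utr_start <- vapply(groups$members, function(ii) {
    min(sites$seed_start[ii])
  }, numeric(1))
  groups$utr_end <- vapply(groups$members, function(ii) {
    max(sites$seed_end[ii])
  }, numeric(1))
  groups
}

# Label individual sites (gene level) against the unique validated pairs;
# needed to calibrate the per-engine weight curves.
label_sites <- function(sites, space, unique_pairs) {
  m <- match(sites$transcript_id, space$meta$transcript_id)
  gene <- space$meta$gene_symbol[m]
  key <- paste(normalize_mirna_id(sites$mirna_id), normalize_gene(gene),
               sep = "\r")
  vkey <- paste(unique_pairs$mirna_id, unique_pairs$gene_symbol, sep = "\r")
  sites$validated <- key %in% vkey
  sites
}

#' Run the full prediction-to-consensus pipeline
#'
#' Builds the UTR space, runs the engines (plus any imported external
#' prediction tables), standardizes and calibrates scores against the
#' validated pairs, groups co-located predictions, computes the consensus
#' weighted score, and writes all outputs under `out_dir`:
#' `utr/` (FASTA + BED12 + TSV), `sites_<engine>.tsv`, `calibration.tsv`,
#' `unique_pairs.tsv`, `consensus.csv` and `run_metadata.txt` (the only
#' file carrying a timestamp).
#'
#' @param genome_path genome FASTA.
#' @param gtf_path transcript annotation GTF.
#' @param mirna_path mature miRNA FASTA.
#' @param validated_paths named vector of validated-pair TSVs (names are
#'   source databases).
#' @param out_dir output directory.
#' @param config a [default_config()].
#' @param engines built-in engines to run.
#' @param conservation optional bedGraph path / scored `GRanges`.
#' @param external optional named vector of external prediction TSVs
#'   (names become engine labels).
#' @param organism_filter optional miRNA organism prefix filter.
#' @return list with `space`, `mirnas`, `sites`, `curves`, `groups`
#'   (ranked consensus table), `records`, `unique_pairs`, `config`, `paths`.
#' @export
run_pipeline <- function(genome_path, gtf_path, mirna_path, validated_paths,
                         out_dir, config = default_config(),
                         engines = c("seedscan", "dpalign", "duplexfold"),
                         conservation = NULL, external = NULL,
                         organism_filter = NULL) {
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- load_genome(genome_path)
  transcripts <- load_annotation(gtf_path, genome)
  space <- build_utr_space(transcripts, genome, config)
  if (nrow(space$meta) == 0) stop("all transcripts removed by filters")
  write_utr_space(space, file.path(out_dir, "utr"))
  mirnas <- load_mirnas(mirna_path, organism_filter)

  sites <- predict_targets(space, mirnas, config, engines,
                           conservation = conservation)
  if (!is.null(external)) {
    for (eng in names(external)) {
      ext <- import_external_predictions(external[[eng]], eng, space)
      sites <- rbind(sites, ext)
    }
  }
  if (nrow(sites) == 0) stop("no predictions produced; nothing to combine")
  sites <- standardize(sites)

  records <- load_validated(validated_paths)
  unique_pairs <- dedup_pairs(records)
  utils::write.table(unique_pairs, file.path(out_dir, "unique_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- label_sites(sites, space, unique_pairs)
  for (eng in unique(sites$engine)) {
    write_sites(sites[sites$engine == eng, , drop = FALSE],
                file.path(out_dir, paste0("sites_", eng, ".tsv")))
  }
  curves <- calibrate_weights(sites, epsilon = config$epsilon)
  write_calibration(curves, file.path(out_dir, "calibration.tsv"))

  groups <- group_overlapping(sites)
  groups <- annotate_groups(groups, sites, space)
  groups <- score_groups(groups, sites, curves)
  groups <- label_predictions(groups, unique_pairs)
  groups <- rank_predictions(groups)

  n0 <- nrow(groups)
  groups_out <- groups[groups$agreement >= config$min_agreement, ,
                       drop = FALSE]
  if (isTRUE(config$validated_only)) {
    groups_out <- groups_out[groups_out$validated, , drop = FALSE]
  }
  if (nrow(groups_out) < n0) {
    message(n0 - nrow(groups_out), " group(s) removed by consensus filters")
  }
  if (nrow(groups_out) == 0) {
    warning("consensus filters removed every prediction group")
  }
  write_consensus(groups_out, file.path(out_dir, "consensus.csv"))

  meta_lines <- c(
    paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("package_version=",
           as.character(utils::packageVersion("miRcons"))),
    paste0("seed=", config$seed),
    paste0("proxy_length=", config$proxy_length),
    paste0("min_utr_length=", config$min_utr_length),
    paste0("engines=", paste(engines, collapse = ",")),
    paste0("energy_table=", basename(system.file(
      "extdata", "stack_energies.tsv", package = "miRcons"))),
    paste0("n_transcripts=", nrow(space$meta)),
    paste0("n_proxy_utrs=", sum(space$meta$utr_source == "proxy")),
    paste0("n_mirnas=", nrow(mirnas)),
    paste0("n_sites=", nrow(sites)),
    paste0("n_groups=", n0),
    paste0("n_groups_after_filters=", nrow(groups_out)),
    paste0("n_validated_records=", nrow(records)),
    paste0("n_unique_pairs=", nrow(unique_pairs)))
  writeLines(meta_lines, file.path(out_dir, "run_metadata.txt"))

  list(space = space, mirnas = mirnas, sites = sites, curves = curves,
       groups = groups_out, all_groups = groups, records = records,
       unique_pairs = unique_pairs, config = config,
       paths = list(out_dir = out_dir,
                    consensus = file.path(out_dir, "consensus.csv")))
}

#' Write / read the consensus CSV
#'
#' Fixed documented column order; `members` (internal row indices) are not
#' serialized.
#' @param groups ranked consensus groups.
#' @param path CSV path.
#' @export
write_consensus <- function(groups, path) {
  df <- groups
  for (col in setdiff(consensus_columns, names(df))) df[[col]] <- NA
  utils::write.csv(df[, consensus_columns, drop = FALSE], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Query the consensus store by miRNA, gene or transcript id
#'
#' @param consensus a consensus data.frame or the path to `consensus.csv`.
#' @param id a miRNA id, gene symbol or transcript id (case-insensitive for
#'   the first two).
#' @return matching rows (possibly empty, with an informative message).
#' @export
query_consensus <- function(consensus, id) {
  if (is.character(consensus) && length(consensus) == 1) {
    consensus <- read_consensus(consensus)
  }
  hit <- normalize_mirna_id(consensus$mirna_id) == normalize_mirna_id(id) |
    normalize_gene(consensus$gene_symbol) == normalize_gene(id) |
    consensus$transcript_id == id
  res <- consensus[hit, , drop = FALSE]
  if (nrow(res) == 0) {
    message("no predictions found for '", id, "'")
  }
  rownames(res) <- NULL
  res
}

#' Evaluate a pipeline run by ROC
#'
#' @param result list from [run_pipeline()].
#' @param per_site evaluate per site instead of per unique pair.
#' @return list with `table` (pair-level scores), `methods` (per-engine and
#'   consensus `roc_result`s) and `tiers` (tier-stratified consensus ROC).
#' @export
evaluate_pipeline <- function(result, per_site = FALSE) {
  eval_tab <- evaluation_table(result$all_groups, result$sites,
                               per_site = per_site)
  list(table = eval_tab,
       methods = evaluate_methods(eval_tab),
       tiers = evaluate_by_tier(eval_tab, result$records))
}
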