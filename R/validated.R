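# Ingestion of experimentally validated miRNA-gene pairs, deduplication
# across source databases, reliability tiers, and labelling of predictions.

#' Default source-database reliability tiers
#'
#' Manually curated sources are high reliability, partially curated sources
#' medium, and text-mining-derived sources low.
#' @return named character vector source -> tier.
#' @export
default_tier_map <- function() {
  c(oncomirdb = "high", mirecords = "medium",
    tarbase = "low", mirtarbase = "low", other = "low")
}

tier_rank <- c(low = 1L, medium = 2L, high = 3L)

# Canonical id forms used for matching: miRNA ids are lower-cased,
# gene symbols upper-cased.
normalize_mirna_id <- function(x) tolower(trimws(x))
normalize_gene <- function(x) toupper(trimws(x))

#' Load validated miRNA-gene pairs from per-source TSV tables
#'
#' Each table needs columns `mirna_id` and `gene_symbol` (an `evidence`
#' column is carried through when present). Ids are normalized to canonical
#' form (lower-case miRNA ids, upper-case gene symbols); rows whose miRNA id
#' does not look like a miRBase-style id (`xxx-mir-...`/`xxx-let-...`) are
#' skipped with a warning.
#'
#' @param tsv_paths named character vector: names are source-database labels
#'   (e.g. `oncomirdb`), values are file paths.
#' @param tier_map named vector source -> tier; defaults to
#'   [default_tier_map()].
#' @return data.frame with columns `mirna_id`, `gene_symbol`, `source_db`,
#'   `evidence`, `reliability_tier`.
#' @export
load_validated <- function(tsv_paths, tier_map = default_tier_map()) {
  stopifnot(!is.null(names(tsv_paths)), all(nzchar(names(tsv_paths))))
  out <- list()
  for (src in names(tsv_paths)) {
    tab <- utils::read.table(tsv_paths[[src]], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    if (!all(c("mirna_id", "gene_symbol") %in% names(tab))) {
      stop("validated table for ", src,
           " must have mirna_id and gene_symbol columns")
    }
    mid <- normalize_mirna_id(tab$mirna_id)
    ok <- grepl("^[a-z]+-(mir|let)-", mid)
    if (any(!ok)) {
      warning(sum(!ok), " row(s) with unmappable miRNA id skipped in ", src)
    }
    tier <- unname(tier_map[src])
    if (is.na(tier)) tier <- unname(tier_map["other"])
    if (is.na(tier)) tier <- "low"
    out[[src]] <- data.frame(
      mirna_id = mid[ok],
      gene_symbol = normalize_gene(tab$gene_symbol[ok]),
      source_db = src,
      evidence = if ("evidence" %in% names(tab)) tab$evidence[ok]
                 else NA_character_,
      reliability_tier = tier,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deduplicate validated pairs across sources
#'
#' One record per unique (miRNA, gene) pair; `source_db` becomes the
#' comma-joined set of supporting databases and the tier becomes the best
#' (highest-reliability) supporting tier.
#'
#' @param pairs data.frame from [load_validated()].
#' @return data.frame of unique pairs with columns `mirna_id`,
#'   `gene_symbol`, `source_db`, `reliability_tier`, `n_sources`.
#' @export
dedup_pairs <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(data.frame(mirna_id = character(), gene_symbol = character(),
                      source_db = character(),
                      reliability_tier = character(),
                      n_sources = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(pairs$mirna_id, pairs$gene_symbol, sep = "\r")
  idx <- split(seq_len(nrow(pairs)), key)
  rows <- lapply(idx, function(ii) {
    srcs <- sort(unique(pairs$source_db[ii]))
    tiers <- pairs$reliability_tier[ii]
    data.frame(mirna_id = pairs$mirna_id[ii[1]],
               gene_symbol = pairs$gene_symbol[ii[1]],
               source_db = paste(srcs, collapse = ","),
               reliability_tier = names(tier_rank)[max(tier_rank[tiers])],
               n_sources = length(srcs), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$mirna_id, res$gene_symbol), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Label consensus groups against the validated-pair set
#'
#' A group is flagged validated when its (miRNA, gene) pair appears in the
#' unique validated set; matching is at gene level because the validated
#' databases are gene-oriented.
#'
#' @param groups consensus-group data.frame (needs `mirna_id` and
#'   `gene_symbol` columns).
#' @param unique_pairs data.frame from [dedup_pairs()].
#' @return `groups` with added `validated` (logical), `validated_sources`
#'   and `validated_tier` columns.
#' @export
label_predictions <- function(groups, unique_pairs) {
  gkey <- paste(normalize_mirna_id(groups$mirna_id),
                normalize_gene(groups$gene_symbol), sep = "\r")
  vkey <- paste(unique_pairs$mirna_id, unique_pairs$gene_symbol, sep = "\r")
  m <- match(gkey, vkey)
  groups$validated <- !is.na(m)
  groups$validated_sources <- ifelse(is.na(m), "", unique_pairs$source_db[m])
  groups$validated_tier <- ifelse(is.na(m), NA_character_,
                                  unique_pairs$reliability_tier[m])
  groups
}
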