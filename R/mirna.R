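#' Load mature miRNAs from a miRBase-style FASTA
#'
#' Headers are expected to start with the miRNA id (e.g.
#' `hsa-let-7a-5p MIMAT0000062 ...`); an accession, when present, is the
#' second word. Sequences are normalized to RNA (T to U) and the seed
#' (positions 2-8, 1-based, 7 nt) is precomputed. The organism tag is the
#' id prefix before the first dash (hsa, mmu, rno, ebv, kshv, ...).
#'
#' @param fasta_path path to the mature miRNA FASTA.
#' @param organism_filter optional prefix (e.g. `"hsa"`); only matching
#'   records are kept.
#' @return data.frame with columns `mirna_id`, `accession`, `sequence`,
#'   `seed`, `organism`.
#' @export
load_mirnas <- function(fasta_path, organism_filter = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  acc <- ifelse(grepl("\\s", headers),
                sub("^\\S+\\s+(\\S+).*$", "\\1", headers), NA_character_)
  sequence <- as_rna(as.character(seqs), name = ids)
  short <- nchar(sequence) < 15
  if (any(short)) {
    stop("mature miRNA shorter than 15 nt: ",
         paste(ids[short], collapse = ", "))
  }
  df <- data.frame(
    mirna_id = ids, accession = acc, sequence = sequence,
    seed = substr(sequence, 2, 8),
    organism = sub("-.*$", "", ids),
    stringsAsFactors = FALSE)
  if (!is.null(organism_filter)) {
    df <- df[df$organism %in% organism_filter, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
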