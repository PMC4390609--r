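# seedscan: exact seed-match engine (perfect-seed-pairing family).
#
# Finds every exact match of the reverse complement of the miRNA seed
# (positions 2-7, extended to 2-8) in the UTR, classifies the match by the
# canonical hierarchy 8mer > 7mer-m8 > 7mer-A1 > 6mer, and scores it as
# type score + local A/U context + position-in-UTR contribution.

classify_seed_match <- function(has_m8, has_a1) {
  if (has_m8 && has_a1) "8mer"
  else if (has_m8) "7mer-m8"
  else if (has_a1) "7mer-A1"
  else "6mer"
}

#' Scan a UTR for exact seed matches
#'
#' @param mirna one-row data.frame from [load_mirnas()].
#' @param utr_seq UTR sequence (RNA character string).
#' @param transcript_id transcript identifier for the output rows.
#' @param blocks `GRanges` of the UTR's genomic blocks (genomic order).
#' @param config a [default_config()] list.
#' @return TargetSite data.frame (possibly empty).
#' @export
scan_seed_sites <- function(mirna, utr_seq, transcript_id, blocks,
                            config = default_config()) {
  cfg <- config$seedscan
  n <- nchar(utr_seq)
  if (n < 8) return(empty_sites())
  seq7 <- mirna$sequence
  core6 <- substr(seq7, 2, 7)                   # miRNA positions 2-7
  m8 <- substr(seq7, 8, 8)                      # miRNA position 8
  match6 <- rna_revcomp(core6)                  # UTR-side 6mer
  m8_comp <- rna_revcomp(m8)                    # UTR base pairing position 8

  hits <- Biostrings::matchPattern(match6, Biostrings::RNAString(utr_seq))
  if (length(hits) == 0) return(empty_sites())

  utr_chars <- strsplit(utr_seq, "")[[1]]
  rows <- list()
  for (k in seq_along(hits)) {
    s1 <- Biostrings::start(hits)[k]            # 1-based start of 6mer
    has_m8 <- s1 > 1 && utr_chars[s1 - 1] == m8_comp
    has_a1 <- (s1 + 6) <= n && utr_chars[s1 + 6] == "A"
    type <- classify_seed_match(has_m8, has_a1)
    seed_start <- if (has_m8) s1 - 2L else s1 - 1L         # 0-based
    seed_end <- if (has_a1) s1 + 6L else s1 + 5L           # half-open
    # A/U fraction in the flanking context (excluding the site itself)
    fl <- cfg$au_flank %/% 2L
    left <- if (seed_start >= 1) {
      utr_chars[max(1, seed_start - fl + 1):seed_start]
    } else character()
    right_from <- seed_end + 1L
    right_to <- min(n, seed_end + fl)
    right <- if (right_from <= right_to) utr_chars[right_from:right_to]
             else character()
    ctx <- c(left, right)
    au <- if (length(ctx) == 0) 0 else mean(ctx %in% c("A", "U"))
    # central placement reward in [0, 1]
    mid <- (seed_start + seed_end) / 2
    pos <- 1 - abs(mid - n / 2) / (n / 2)
    score <- unname(cfg$type_scores[type]) + cfg$au_weight * au +
      cfg$pos_weight * pos
    if (score < cfg$min_score) next
    g <- lift_seed(blocks, seed_start, seed_end)
    rows[[length(rows) + 1]] <- data.frame(
      engine = "seedscan", mirna_id = mirna$mirna_id,
      transcript_id = transcript_id,
      utr_start = seed_start, utr_end = seed_end,
      seed_start = seed_start, seed_end = seed_end,
      chrom = g$chrom, strand = g$strand,
      g_start = g$g_start, g_end = g$g_end, g_blocks = g$g_blocks,
      site_type = type, raw_score = score,
      energy = NA_real_, conservation = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_sites())
  do.call(rbind, rows)
}
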