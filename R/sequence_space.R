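#' Read a genome FASTA into a named DNAStringSet
#'
#' @param genome_path path to an (uncompressed or gzipped) FASTA file.
#' @return `DNAStringSet` named by the first word of each header.
#' @export
load_genome <- function(genome_path) {
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Load transcript models from a GTF annotation
#'
#' Builds one transcript record per transcript feature, keeping every
#' biotype (coding, non-coding, pseudogene, ...). Exons are stored in
#' genomic order; the boundary between coding sequence and 3'-UTR is
#' derived from CDS and stop_codon features when present.
#'
#' @param gtf_path path to a GTF file with exon (and optionally CDS,
#'   stop_codon) features carrying `transcript_id`/`gene_id` attributes.
#' @param genome a `DNAStringSet` as returned by [load_genome()], or a path
#'   to the genome FASTA. Used to check that every annotated contig exists.
#' @return named list of transcript records, each a list with elements
#'   `transcript_id`, `gene_id`, `gene_symbol`, `biotype`,
#'   `principal_isoform`, `exons` (a `GRanges`, genomic order) and
#'   `cds_end` (0-based genomic boundary between coding region and 3'-UTR
#'   in transcription direction, or `NA` for non-coding transcripts).
#' @export
load_annotation <- function(gtf_path, genome) {
  if (is.character(genome)) genome <- load_genome(genome)
  gtf <- rtracklayer::import(gtf_path, format = "gtf")

  contigs <- unique(as.character(GenomicRanges::seqnames(gtf)))
  missing <- setdiff(contigs, names(genome))
  if (length(missing) > 0) {
    stop("annotation references contig(s) absent from the genome: ",
         paste(missing, collapse = ", "))
  }

  meta <- S4Vectors::mcols(gtf)
  type <- as.character(meta$type)
  tx_ids <- unique(meta$transcript_id[!is.na(meta$transcript_id)])

  exon_idx <- which(type == "exon")
  cds_idx  <- which(type %in% c("CDS", "stop_codon"))

  exon_by_tx <- split(exon_idx, meta$transcript_id[exon_idx])
  cds_by_tx  <- split(cds_idx, meta$transcript_id[cds_idx])

  records <- list()
  for (tx in tx_ids) {
    idx <- exon_by_tx[[tx]]
    if (is.null(idx) || length(idx) == 0) {
      warning("transcript ", tx, " has no exons; skipped")
      next
    }
    exons <- GenomicRanges::sort(gtf[idx])
    S4Vectors::mcols(exons) <- NULL
    strand <- as.character(GenomicRanges::strand(exons))[1]
    row1 <- meta[idx[1], ]
    cds_end <- NA_integer_
    cidx <- cds_by_tx[[tx]]
    if (!is.null(cidx) && length(cidx) > 0) {
      cds <- gtf[cidx]
      cds_end <- if (strand == "-") {
        min(GenomicRanges::start(cds)) - 1L  # 0-based boundary
      } else {
        max(GenomicRanges::end(cds))         # 1-based end == 0-based exclusive
      }
    }
    principal <- NA
    if ("principal_isoform" %in% colnames(meta)) {
      principal <- isTRUE(as.logical(row1$principal_isoform))
    } else if ("tag" %in% colnames(meta)) {
      principal <- isTRUE(grepl("principal", as.character(row1$tag)))
    }
    records[[tx]] <- list(
      transcript_id = tx,
      gene_id = as.character(row1$gene_id),
      gene_symbol = if ("gene_name" %in% colnames(meta) &&
                        !is.na(row1$gene_name)) as.character(row1$gene_name)
                    else as.character(row1$gene_id),
      biotype = if ("transcript_biotype" %in% colnames(meta) &&
                    !is.na(row1$transcript_biotype))
                  as.character(row1$transcript_biotype)
                else if ("gene_biotype" %in% colnames(meta) &&
                         !is.na(row1$gene_biotype))
                  as.character(row1$gene_biotype)
                else "unknown",
      principal_isoform = principal,
      exons = exons,
      cds_end = cds_end
    )
  }
  records
}

# Spliced sequence of genomic blocks, in transcription order, as RNA.
spliced_sequence <- function(blocks, chrom_seq, strand) {
  if (length(blocks) == 0) return("")
  parts <- as.character(Biostrings::extractAt(
    chrom_seq, IRanges::ranges(blocks)))
  if (strand == "-") {
    parts <- rev(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(parts))))
  }
  as_rna(paste(parts, collapse = ""))
}

#' Extract the 3'-UTR of one transcript
#'
#' If the transcript has an annotated 3'-UTR (exonic sequence downstream of
#' the translation stop) of at least `min_utr_length` nt, that spliced,
#' strand-corrected sequence is returned (`utr_source = "annotated"`).
#' Otherwise the `proxy_length` genomic bases immediately downstream of the
#' last exon end, in transcription direction, stand in for the UTR
#' (`utr_source = "proxy"`). The proxy is unspliced genomic sequence; it is
#' truncated (with a warning) where it would run off the contig.
#'
#' @param tx a transcript record from [load_annotation()].
#' @param genome a `DNAStringSet`.
#' @param proxy_length nt of downstream proxy sequence (default 130).
#' @param min_utr_length minimum annotated UTR length kept as-is (default 50).
#' @return list with `transcript_id`, `sequence` (RNA), `blocks` (`GRanges`
#'   in genomic order), `utr_source` and `length`.
#' @export
extract_3utr <- function(tx, genome, proxy_length = 130L,
                         min_utr_length = 50L) {
  chrom <- as.character(GenomicRanges::seqnames(tx$exons))[1]
  if (!chrom %in% names(genome)) {
    stop("contig ", chrom, " absent from genome")
  }
  chrom_seq <- genome[[chrom]]
  clen <- length(chrom_seq)
  strand <- as.character(GenomicRanges::strand(tx$exons))[1]

  # annotated UTR: exonic sequence 3' of the coding boundary
  if (!is.na(tx$cds_end)) {
    utr_region <- if (strand == "-") {
      GenomicRanges::GRanges(chrom, IRanges::IRanges(1, max(1, tx$cds_end)),
                             strand = strand)
    } else {
      GenomicRanges::GRanges(chrom, IRanges::IRanges(tx$cds_end + 1L, clen),
                             strand = strand)
    }
    blocks <- suppressWarnings(
      GenomicRanges::intersect(tx$exons, utr_region, ignore.strand = TRUE))
    GenomicRanges::strand(blocks) <- strand
    if (sum(GenomicRanges::width(blocks)) >= min_utr_length) {
      seq <- spliced_sequence(blocks, chrom_seq, strand)
      return(list(transcript_id = tx$transcript_id, sequence = seq,
                  blocks = blocks, utr_source = "annotated",
                  length = nchar(seq)))
    }
  }

  # proxy: fixed-length genomic window downstream of the last exon
  if (strand == "-") {
    first_start <- min(GenomicRanges::start(tx$exons))  # 1-based
    start1 <- first_start - proxy_length
    end1 <- first_start - 1L
  } else {
    last_end <- max(GenomicRanges::end(tx$exons))
    start1 <- last_end + 1L
    end1 <- last_end + proxy_length
  }
  if (start1 < 1L || end1 > clen) {
    warning("proxy UTR for ", tx$transcript_id,
            " truncated at contig boundary")
    start1 <- max(1L, start1)
    end1 <- min(clen, end1)
  }
  if (end1 < start1) stop("empty proxy UTR for ", tx$transcript_id)
  blocks <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                                   strand = strand)
  seq <- spliced_sequence(blocks, chrom_seq, strand)
  list(transcript_id = tx$transcript_id, sequence = seq, blocks = blocks,
       utr_source = "proxy", length = nchar(seq))
}

#' Build the full 3'-UTR sequence space
#'
#' Applies [extract_3utr()] to every transcript and assembles the result
#' into a `utr_space` object: a metadata table, the RNA sequences, and the
#' genomic block structure needed to lift local UTR coordinates back to the
#' genome.
#'
#' @param transcripts list from [load_annotation()].
#' @param genome a `DNAStringSet`.
#' @param config a [default_config()] list (uses `proxy_length`,
#'   `min_utr_length`, `biotypes`, `principal_only`, `include_proxy_utrs`).
#' @return object of class `utr_space` with elements `meta` (data.frame),
#'   `sequences` (named character, RNA) and `blocks` (named `GRangesList`).
#' @export
build_utr_space <- function(transcripts, genome, config = default_config()) {
  recs <- lapply(transcripts, extract_3utr, genome = genome,
                 proxy_length = config$proxy_length,
                 min_utr_length = config$min_utr_length)
  meta <- do.call(rbind, lapply(seq_along(recs), function(i) {
    tx <- transcripts[[i]]; u <- recs[[i]]
    data.frame(
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      gene_symbol = tx$gene_symbol, biotype = tx$biotype,
      principal_isoform = tx$principal_isoform,
      utr_source = u$utr_source, length = u$length,
      chrom = as.character(GenomicRanges::seqnames(u$blocks))[1],
      strand = as.character(GenomicRanges::strand(u$blocks))[1],
      stringsAsFactors = FALSE)
  }))
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(config$biotypes)) keep <- keep & meta$biotype %in% config$biotypes
  if (isTRUE(config$principal_only)) keep <- keep & meta$principal_isoform %in% TRUE
  if (!isTRUE(config$include_proxy_utrs)) keep <- keep & meta$utr_source == "annotated"
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " transcript(s) removed by filters")
  meta <- meta[keep, , drop = FALSE]
  recs <- recs[keep]
  rownames(meta) <- NULL
  space <- list(
    meta = meta,
    sequences = stats::setNames(vapply(recs, `[[`, "", "sequence"),
                                meta$transcript_id),
    blocks = stats::setNames(
      GenomicRanges::GRangesList(lapply(recs, `[[`, "blocks")),
      meta$transcript_id)
  )
  class(space) <- "utr_space"
  space
}

#' @export
print.utr_space <- function(x, ...) {
  cat("utr_space:", nrow(x$meta), "transcripts (",
      sum(x$meta$utr_source == "annotated"), "annotated,",
      sum(x$meta$utr_source == "proxy"), "proxy UTRs )\n")
  invisible(x)
}

#' Statistical mode of annotated 3'-UTR lengths
#'
#' Most frequent length among annotated (non-proxy) UTRs; ties are broken
#' by the smallest length.
#'
#' @param space a `utr_space`, or an integer vector of annotated lengths.
#' @return the modal length in nt.
#' @export
mode_utr_length <- function(space) {
  lengths <- if (inherits(space, "utr_space")) {
    space$meta$length[space$meta$utr_source == "annotated"]
  } else as.integer(space)
  if (length(lengths) == 0) stop("no annotated UTRs")
  tab <- table(lengths)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

#' Map local UTR coordinates to genomic blocks
#'
#' Lifts a 0-based half-open interval on the spliced UTR sequence to its
#' genomic blocks, respecting strand and splice junctions.
#'
#' @param blocks `GRanges` of UTR exonic blocks in genomic order.
#' @param local_start,local_end 0-based half-open positions on the UTR.
#' @return `GRanges` of genomic blocks (genomic order).
#' @export
utr_to_genomic <- function(blocks, local_start, local_end) {
  strand <- as.character(GenomicRanges::strand(blocks))[1]
  w <- GenomicRanges::width(blocks)
  ord <- if (strand == "-") rev(seq_along(blocks)) else seq_along(blocks)
  offs <- cumsum(c(0L, w[ord]))  # transcription-order offsets
  total <- offs[length(offs)]
  stopifnot(local_start >= 0, local_end > local_start, local_end <= total)
  out <- list()
  for (k in seq_along(ord)) {
    b0 <- offs[k]; b1 <- offs[k + 1]
    s <- max(local_start, b0); e <- min(local_end, b1)
    if (s >= e) next
    blk <- blocks[ord[k]]
    if (strand == "-") {
      gstart <- GenomicRanges::end(blk) - (e - b0) + 1L
      gend <- GenomicRanges::end(blk) - (s - b0)
    } else {
      gstart <- GenomicRanges::start(blk) + (s - b0)
      gend <- GenomicRanges::start(blk) + (e - b0) - 1L
    }
    out[[length(out) + 1]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(blk),
      IRanges::IRanges(gstart, gend), strand = strand)
  }
  GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Map genomic blocks back to local UTR coordinates
#'
#' Inverse of [utr_to_genomic()]: returns the 0-based half-open local
#' interval covered by `gblocks` on the spliced UTR.
#'
#' @param blocks UTR exonic blocks (`GRanges`, genomic order).
#' @param gblocks genomic blocks to map back.
#' @return c(local_start, local_end), 0-based half-open.
#' @export
genomic_to_utr <- function(blocks, gblocks) {
  strand <- as.character(GenomicRanges::strand(blocks))[1]
  w <- GenomicRanges::width(blocks)
  ord <- if (strand == "-") rev(seq_along(blocks)) else seq_along(blocks)
  offs <- cumsum(c(0L, w[ord]))
  locals <- c()
  for (i in seq_along(gblocks)) {
    g <- gblocks[i]
    for (k in seq_along(ord)) {
      blk <- blocks[ord[k]]
      if (GenomicRanges::start(g) >= GenomicRanges::start(blk) &&
          GenomicRanges::end(g) <= GenomicRanges::end(blk)) {
        if (strand == "-") {
          s <- offs[k] + GenomicRanges::end(blk) - GenomicRanges::end(g)
          e <- offs[k] + GenomicRanges::end(blk) - GenomicRanges::start(g) + 1L
        } else {
          s <- offs[k] + GenomicRanges::start(g) - GenomicRanges::start(blk)
          e <- offs[k] + GenomicRanges::end(g) - GenomicRanges::start(blk) + 1L
        }
        locals <- c(locals, s, e)
      }
    }
  }
  if (length(locals) == 0) stop("genomic blocks do not fall inside the UTR")
  c(min(locals), max(locals))
}

#' Write a UTR space to FASTA + BED12 + TSV
#'
#' @param space a `utr_space`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_utr_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "utrs.fa")
  bed <- file.path(dir, "utrs.bed")
  tsv <- file.path(dir, "utr_metadata.tsv")
  seqs <- Biostrings::RNAStringSet(space$sequences)
  Biostrings::writeXStringSet(seqs, fa)
  bed_gr <- rtracklayer::asBED(space$blocks)
  rtracklayer::export(bed_gr, bed, format = "bed")
  utils::write.table(space$meta, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, bed = bed, tsv = tsv))
}

#' Read a UTR space back from FASTA + BED12 + TSV
#'
#' @param dir directory written by [write_utr_space()].
#' @return a `utr_space`.
#' @export
read_utr_space <- function(dir) {
  seqs <- Biostrings::readRNAStringSet(file.path(dir, "utrs.fa"))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.table(file.path(dir, "utr_metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  bed <- rtracklayer::import(file.path(dir, "utrs.bed"), format = "bed")
  blk <- rtracklayer::blocks(bed)
  names(blk) <- bed$name
  # restore strand (blocks() keeps it, but be explicit) and order as meta
  blk <- blk[meta$transcript_id]
  space <- list(meta = meta,
                sequences = stats::setNames(as.character(seqs)[meta$transcript_id],
                                            meta$transcript_id),
                blocks = blk)
  class(space) <- "utr_space"
  space
}
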