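# Shared infrastructure for the prediction engines: the TargetSite table
# schema, genomic lifting of seed intervals, overlap reduction, optional
# conservation annotation, and the external-prediction importer.

site_columns <- c("engine", "mirna_id", "transcript_id",
                  "utr_start", "utr_end", "seed_start", "seed_end",
                  "chrom", "strand", "g_start", "g_end", "g_blocks",
                  "site_type", "raw_score", "energy", "conservation")

empty_sites <- function() {
  df <- data.frame(engine = character(), mirna_id = character(),
                   transcript_id = character(),
                   utr_start = integer(), utr_end = integer(),
                   seed_start = integer(), seed_end = integer(),
                   chrom = character(), strand = character(),
                   g_start = integer(), g_end = integer(),
                   g_blocks = character(), site_type = character(),
                   raw_score = numeric(), energy = numeric(),
                   conservation = numeric(), stringsAsFactors = FALSE)
  df
}

# Plain (non-S4) view of a UTR's genomic blocks, precomputed once per
# transcript so coordinate lifting in engine hot loops stays cheap.
# starts/ends are 1-based inclusive, in transcription order.
as_block_info <- function(blocks) {
  if (!inherits(blocks, "GRanges")) return(blocks)   # already converted
  strand <- as.character(GenomicRanges::strand(blocks))[1]
  starts <- GenomicRanges::start(blocks)
  ends <- GenomicRanges::end(blocks)
  ord <- if (strand == "-") rev(seq_along(starts)) else seq_along(starts)
  list(chrom = as.character(GenomicRanges::seqnames(blocks))[1],
       strand = strand, starts = starts[ord], ends = ends[ord],
       offs = cumsum(c(0L, (ends - starts + 1L)[ord])))
}

# Lift a local 0-based half-open seed interval to genomic block notation.
# Returns list(chrom, strand, g_start, g_end, g_blocks) with 0-based
# half-open genomic coordinates ("start-end" joined by commas).
lift_seed <- function(blocks, seed_start, seed_end) {
  bi <- as_block_info(blocks)
  nb <- length(bi$starts)
  gs <- integer(); ge <- integer()
  for (k in seq_len(nb)) {
    b0 <- bi$offs[k]; b1 <- bi$offs[k + 1]
    s <- max(seed_start, b0); e <- min(seed_end, b1)
    if (s >= e) next
    if (bi$strand == "-") {
      gstart <- bi$ends[k] - (e - b0) + 1L
      gend <- bi$ends[k] - (s - b0)
    } else {
      gstart <- bi$starts[k] + (s - b0)
      gend <- bi$starts[k] + (e - b0) - 1L
    }
    gs <- c(gs, gstart); ge <- c(ge, gend)
  }
  o <- order(gs)
  s0 <- gs[o] - 1L; e0 <- ge[o]
  list(chrom = bi$chrom, strand = bi$strand,
       g_start = min(s0), g_end = max(e0),
       g_blocks = paste(paste0(s0, "-", e0), collapse = ","))
}

#' Reduce overlapping same-engine sites to the best one per cluster
#'
#' For one engine, overlapping sites (local UTR intervals, same miRNA and
#' transcript) are collapsed to the single best-scoring site, so each
#' binding position is reported once.
#'
#' @param sites a TargetSite data.frame from one engine.
#' @return filtered data.frame.
#' @export
reduce_overlaps <- function(sites) {
  if (nrow(sites) <= 1) return(sites)
  keep <- logical(nrow(sites))
  for (key in unique(paste(sites$mirna_id, sites$transcript_id))) {
    idx <- which(paste(sites$mirna_id, sites$transcript_id) == key)
    ir <- IRanges::IRanges(sites$utr_start[idx] + 1L, sites$utr_end[idx])
    cl <- S4Vectors::subjectHits(
      IRanges::findOverlaps(ir, IRanges::reduce(ir)))
    for (c in unique(cl)) {
      sub <- idx[cl == c]
      keep[sub[which.max(sites$raw_score[sub])]] <- TRUE
    }
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate sites with mean conservation over the seed interval
#'
#' @param sites TargetSite data.frame.
#' @param track `GRanges` with a numeric `score` column (e.g. imported from
#'   a bedGraph), or a path to a bedGraph file. Bases not covered by the
#'   track count as 0.
#' @return `sites` with the `conservation` column filled.
#' @export
annotate_conservation <- function(sites, track) {
  if (is.character(track)) {
    track <- rtracklayer::import(track, format = "bedGraph")
  }
  if (nrow(sites) == 0) return(sites)
  cons <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    parts <- strsplit(sites$g_blocks[i], ",")[[1]]
    se <- do.call(rbind, lapply(strsplit(parts, "-"), as.integer))
    gr <- GenomicRanges::GRanges(sites$chrom[i],
                                 IRanges::IRanges(se[, 1] + 1L, se[, 2]))
    total <- sum(GenomicRanges::width(gr))
    hits <- GenomicRanges::findOverlaps(gr, track, ignore.strand = TRUE)
    acc <- 0
    if (length(hits) > 0) {
      pi_ <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                       track[S4Vectors::subjectHits(hits)],
                                       ignore.strand = TRUE)
      acc <- sum(GenomicRanges::width(pi_) *
                   track$score[S4Vectors::subjectHits(hits)])
    }
    cons[i] <- acc / total
  }
  sites$conservation <- cons
  sites
}

#' Run the built-in engines over the UTR space
#'
#' @param space a `utr_space`.
#' @param mirnas data.frame from [load_mirnas()].
#' @param config a [default_config()] list.
#' @param engines subset of `c("seedscan", "dpalign", "duplexfold")`.
#' @param model an `energy_model` (loaded from the packaged table when NULL).
#' @param conservation optional bedGraph path or scored `GRanges`; when
#'   supplied, seedscan sites below the conservation threshold are dropped.
#' @return TargetSite data.frame over all engines (overlap-reduced per
#'   engine).
#' @export
predict_targets <- function(space, mirnas, config = default_config(),
                            engines = c("seedscan", "dpalign", "duplexfold"),
                            model = NULL, conservation = NULL) {
  if (is.null(model) && "duplexfold" %in% engines) {
    model <- load_energy_model(config = config)
  }
  block_info <- lapply(space$blocks, as_block_info)
  out <- list()
  for (eng in engines) {
    per_eng <- list()
    for (t in seq_len(nrow(space$meta))) {
      tx <- space$meta$transcript_id[t]
      utr_seq <- space$sequences[[tx]]
      blocks <- block_info[[tx]]
      for (m in seq_len(nrow(mirnas))) {
        sites <- switch(eng,
          seedscan = scan_seed_sites(mirnas[m, ], utr_seq, tx, blocks, config),
          dpalign = align_complementarity(mirnas[m, ], utr_seq, tx, blocks,
                                          config),
          duplexfold = hybridization_energy(mirnas[m, ], utr_seq, tx, blocks,
                                            model, config),
          stop("unknown engine: ", eng))
        if (nrow(sites) > 0) per_eng[[length(per_eng) + 1]] <- sites
      }
    }
    if (length(per_eng) > 0) {
      eng_df <- reduce_overlaps(do.call(rbind, per_eng))
      out[[eng]] <- eng_df
    }
  }
  sites <- if (length(out) > 0) do.call(rbind, out) else empty_sites()
  rownames(sites) <- NULL
  if (!is.null(conservation) && nrow(sites) > 0) {
    sites <- annotate_conservation(sites, conservation)
    thr <- config$seedscan$conservation_threshold
    drop <- sites$engine == "seedscan" & sites$conservation < thr
    if (any(drop)) message(sum(drop), " seedscan site(s) below conservation ",
                           "threshold removed")
    sites <- sites[!drop, , drop = FALSE]
    rownames(sites) <- NULL
  }
  sites
}

#' Import externally computed predictions as TargetSites
#'
#' Reads a TSV with columns `mirna_id`, `transcript_id`, `start`, `end`,
#' `score`. The coordinate convention is taken from a `#coords=` comment on
#' the first line (`0-based-half-open` or `1-based-inclusive`) or from the
#' `coords` argument; 1-based-inclusive input is converted to the internal
#' 0-based half-open convention. Rows for transcripts absent from the UTR
#' space are skipped (a warning reports the count); malformed rows are an
#' error naming the line.
#'
#' @param tsv_path input table path.
#' @param engine_name label under which the sites enter the consensus.
#' @param space a `utr_space` used to lift coordinates.
#' @param coords default coordinate convention if no header comment.
#' @return TargetSite data.frame.
#' @export
import_external_predictions <- function(tsv_path, engine_name, space,
                                        coords = "0-based-half-open") {
  first <- readLines(tsv_path, n = 1)
  if (grepl("^#\\s*coords=", first)) {
    coords <- sub("^#\\s*coords=\\s*", "", first)
  }
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("mirna_id", "transcript_id", "start", "end", "score")
  if (!all(need %in% names(tab))) {
    stop("external prediction table must have columns: ",
         paste(need, collapse = ", "))
  }
  bad <- which(is.na(tab$start) | is.na(tab$end) | is.na(tab$score) |
                 !is.finite(tab$score))
  if (length(bad) > 0) stop("malformed row at line ", bad[1] + 1)
  if (coords == "1-based-inclusive") {
    tab$start <- tab$start - 1L
  } else if (coords != "0-based-half-open") {
    stop("unknown coordinate convention: ", coords)
  }
  if (any(tab$end <= tab$start)) {
    stop("malformed row at line ",
         which(tab$end <= tab$start)[1] + 1, ": empty interval")
  }
  known <- tab$transcript_id %in% space$meta$transcript_id
  if (any(!known)) {
    warning(sum(!known), " row(s) with unknown transcript_id skipped")
    tab <- tab[known, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    blocks <- space$blocks[[tab$transcript_id[i]]]
    ulen <- nchar(space$sequences[[tab$transcript_id[i]]])
    s <- max(0L, as.integer(tab$start[i]))
    e <- min(ulen, as.integer(tab$end[i]))
    g <- lift_seed(blocks, s, e)
    data.frame(engine = engine_name, mirna_id = tab$mirna_id[i],
               transcript_id = tab$transcript_id[i],
               utr_start = s, utr_end = e, seed_start = s, seed_end = e,
               chrom = g$chrom, strand = g$strand,
               g_start = g$g_start, g_end = g$g_end, g_blocks = g$g_blocks,
               site_type = "non-canonical", raw_score = tab$score[i],
               energy = NA_real_, conservation = NA_real_,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) return(empty_sites())
  do.call(rbind, rows)
}

#' Write / read TargetSite tables
#'
#' Engine output is a TSV with the documented column order.
#' @param sites TargetSite data.frame.
#' @param path output TSV path.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, site_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
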