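# dpalign: complementarity alignment engine (dynamic-programming family).
#
# Local alignment (affine gaps, Gotoh) of the reversed miRNA against the
# UTR, scoring complementarity rather than identity: Watson-Crick pairs
# score `match`, G-U pairs score `wobble`, everything else `mismatch`.
# Pair scores at miRNA seed positions 2-8 are multiplied by
# `seed_multiplier`. A gap of length L costs `gap_open + L * gap_extend`.

# Pair score lookup table for (mirna base, utr base).
dp_pair_score <- function(params) {
  bases <- c("A", "C", "G", "U")
  sm <- matrix(params$mismatch, 4, 4, dimnames = list(bases, bases))
  sm["A", "U"] <- sm["U", "A"] <- params$match
  sm["G", "C"] <- sm["C", "G"] <- params$match
  sm["G", "U"] <- sm["U", "G"] <- params$wobble
  sm
}

# Full Gotoh matrices for one miRNA/UTR pair. Rows follow the reversed
# miRNA (row i = miRNA position M - i + 1), columns follow the UTR.
dpalign_matrices <- function(mirna_seq, utr_seq, params) {
  if (params$match <= 0) stop("dpalign match score must be positive")
  m <- strsplit(mirna_seq, "")[[1]]
  u <- strsplit(utr_seq, "")[[1]]
  M <- length(m); N <- length(u)
  mrev <- rev(m)
  mirna_pos <- M - seq_len(M) + 1L
  seed_row <- mirna_pos >= 2 & mirna_pos <= 8
  sm <- dp_pair_score(params)
  go <- params$gap_open; ge <- params$gap_extend
  H <- matrix(0, M + 1, N + 1)
  E <- matrix(-Inf, M + 1, N + 1)
  F_ <- matrix(-Inf, M + 1, N + 1)
  PH <- matrix(0L, M + 1, N + 1)   # 0 fresh, 1 diag, 2 from E, 3 from F
  PE <- matrix(0L, M + 1, N + 1)   # 1 opened from H, 0 extended
  PF <- matrix(0L, M + 1, N + 1)
  for (i in seq_len(M)) {
    srow <- sm[mrev[i], ]
    mult <- if (seed_row[i]) params$seed_multiplier else 1
    for (j in seq_len(N)) {
      e_open <- H[i + 1, j] - go - ge
      e_ext <- E[i + 1, j] - ge
      if (e_open >= e_ext) { E[i + 1, j + 1] <- e_open; PE[i + 1, j + 1] <- 1L }
      else E[i + 1, j + 1] <- e_ext
      f_open <- H[i, j + 1] - go - ge
      f_ext <- F_[i, j + 1] - ge
      if (f_open >= f_ext) { F_[i + 1, j + 1] <- f_open; PF[i + 1, j + 1] <- 1L }
      else F_[i + 1, j + 1] <- f_ext
      diag <- H[i, j] + srow[u[j]] * mult
      best <- 0; code <- 0L
      if (diag > best) { best <- diag; code <- 1L }
      if (E[i + 1, j + 1] > best) { best <- E[i + 1, j + 1]; code <- 2L }
      if (F_[i + 1, j + 1] > best) { best <- F_[i + 1, j + 1]; code <- 3L }
      H[i + 1, j + 1] <- best
      PH[i + 1, j + 1] <- code
    }
  }
  list(H = H, E = E, F = F_, PH = PH, PE = PE, PF = PF,
       seed_row = seed_row, M = M, N = N)
}

#' Optimal local complementarity alignment score
#'
#' @param mirna_seq miRNA sequence, 5' to 3' (RNA).
#' @param utr_seq UTR sequence (RNA).
#' @param params the `dpalign` element of a [default_config()].
#' @return the optimal local alignment score (0 when nothing aligns).
#' @export
dpalign_score <- function(mirna_seq, utr_seq,
                          params = default_config()$dpalign) {
  max(dpalign_matrices(mirna_seq, utr_seq, params)$H)
}

# Traceback from cell (i, j) (1-based in the padded matrices) in state H.
# Returns UTR interval, aligned seed columns and path length.
dpalign_traceback <- function(dp, i, j) {
  cols <- integer(); seed_cols <- integer()
  state <- "H"
  while (i > 1 && j > 1) {
    if (state == "H") {
      code <- dp$PH[i, j]
      if (code == 0L) break
      if (code == 1L) {
        cols <- c(cols, j - 1L)
        if (dp$seed_row[i - 1]) seed_cols <- c(seed_cols, j - 1L)
        if (dp$H[i - 1, j - 1] == 0 && dp$PH[i - 1, j - 1] == 0L) {
          i <- i - 1L; j <- j - 1L; break
        }
        i <- i - 1L; j <- j - 1L
      } else if (code == 2L) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      opened <- dp$PE[i, j] == 1L
      j <- j - 1L
      if (opened) state <- "H"
    } else {
      opened <- dp$PF[i, j] == 1L
      i <- i - 1L
      if (opened) state <- "H"
    }
  }
  if (length(cols) == 0) return(NULL)
  utr_start <- min(cols) - 1L            # 0-based half-open
  utr_end <- max(cols)
  if (length(seed_cols) > 0) {
    seed_start <- min(seed_cols) - 1L; seed_end <- max(seed_cols)
  } else {
    seed_start <- max(utr_start, utr_end - 8L); seed_end <- utr_end
  }
  list(utr_start = utr_start, utr_end = utr_end,
       seed_start = seed_start, seed_end = seed_end)
}

#' Complementarity-alignment target sites for one miRNA/UTR pair
#'
#' @param mirna one-row data.frame from [load_mirnas()].
#' @param utr_seq UTR sequence (RNA character string).
#' @param transcript_id transcript identifier.
#' @param blocks `GRanges` of UTR genomic blocks.
#' @param config a [default_config()] list.
#' @return TargetSite data.frame with sites scoring at least the engine's
#'   `score_threshold`, best site per overlap cluster.
#' @export
align_complementarity <- function(mirna, utr_seq, transcript_id, blocks,
                                  config = default_config()) {
  params <- config$dpalign
  dp <- dpalign_matrices(mirna$sequence, utr_seq, params)
  hits <- which(dp$H >= params$score_threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_sites())
  ord <- order(dp$H[hits], decreasing = TRUE)
  hits <- hits[ord, , drop = FALSE]
  tk_s <- integer(); tk_e <- integer()
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1]; j <- hits[k, 2]
    tb <- dpalign_traceback(dp, i, j)
    if (is.null(tb)) next
    if (any(tb$utr_start < tk_e & tb$utr_end > tk_s)) next
    tk_s <- c(tk_s, tb$utr_start); tk_e <- c(tk_e, tb$utr_end)
    g <- lift_seed(blocks, tb$seed_start, tb$seed_end)
    rows[[length(rows) + 1]] <- data.frame(
      engine = "dpalign", mirna_id = mirna$mirna_id,
      transcript_id = transcript_id,
      utr_start = tb$utr_start, utr_end = tb$utr_end,
      seed_start = tb$seed_start, seed_end = tb$seed_end,
      chrom = g$chrom, strand = g$strand,
      g_start = g$g_start, g_end = g$g_end, g_blocks = g$g_blocks,
      site_type = "non-canonical", raw_score = dp$H[i, j],
      energy = NA_real_, conservation = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_sites())
  do.call(rbind, rows)
}
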