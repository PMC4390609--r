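# duplexfold: intermolecular duplex free-energy engine (hybridization
# family). Computes the minimum-free-energy duplex between the miRNA and
# the UTR by dynamic programming over nearest-neighbour stacks with affine
# bulge/internal-loop costs. Intramolecular pairs are never formed: the two
# strands only pair with each other, antiparallel and without crossing.

# Dynamic programme over one strand pair. `x_seq` plays the miRNA role
# (reversed internally so row i pairs x position length-i+1), `y_seq` the
# target. H[i+1, j+1] is the best (lowest) energy of a duplex whose last
# (3'-most on y) base pair is (rev(x)[i], y[j]), initiation included.
duplex_dp <- function(x_seq, y_seq, model) {
  x <- rev(strsplit(x_seq, "")[[1]])
  y <- strsplit(y_seq, "")[[1]]
  M <- length(x); N <- length(y)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  P <- matrix(NA_integer_, M, N)
  for (i in seq_len(M)) {
    P[i, ] <- match(paste0(y, x[i]), pairs)
  }
  H <- matrix(Inf, M + 1, N + 1)
  CODE <- matrix(NA_integer_, M + 1, N + 1)  # di*1000 + dj; 0 = duplex start
  D <- model$max_loop + 1L
  for (i in seq_len(M)) {
    pv <- !is.na(P[i, ])
    if (!any(pv)) next
    best <- ifelse(pv, model$initiation, Inf)
    code <- ifelse(pv, 0L, NA_integer_)
    # stacked continuation from the immediately previous pair
    if (i >= 2) {
      sE <- rep(Inf, N)
      jj <- which(pv)
      jj <- jj[jj >= 2]
      lab_prev <- P[i - 1, jj - 1]
      okp <- !is.na(lab_prev)
      sE[jj[okp]] <- model$stack[cbind(lab_prev[okp], P[i, jj[okp]])]
      w <- H[i, 1:N]                       # padded (i-1, j-1) predecessors
      cand <- w + sE
      upd <- !is.na(cand) & cand < best
      best[upd] <- cand[upd]
      code[upd] <- 1001L
    }
    # loop/bulge continuations (vectorized over the UTR axis)
    for (di in seq_len(min(D, i))) {
      Hrow <- H[i + 1L - di, ]
      for (dj in seq_len(D)) {
        if (di == 1L && dj == 1L) next
        cost <- loop_cost(di + dj - 2L, model)
        w <- c(rep(Inf, dj - 1L), Hrow)[1:N]   # w[j] = H[i+1-di, j+1-dj]
        cand <- w + cost
        upd <- pv & cand < best
        if (any(upd)) {
          best[upd] <- cand[upd]
          code[upd] <- di * 1000L + dj
        }
      }
    }
    H[i + 1, 2:(N + 1)] <- best
    CODE[i + 1, 2:(N + 1)] <- code
  }
  list(H = H, CODE = CODE, M = M, N = N)
}

#' Minimum free energy of the intermolecular duplex of two strands
#'
#' @param x_seq,y_seq RNA sequences, 5' to 3'.
#' @param model an `energy_model` from [load_energy_model()].
#' @return MFE in kcal/mol; 0 when no structure is stabilizing.
#' @export
duplex_mfe <- function(x_seq, y_seq, model) {
  if (nchar(x_seq) == 0 || nchar(y_seq) == 0) return(0)
  dp <- duplex_dp(x_seq, y_seq, model)
  min(0, suppressWarnings(min(dp$H)))
}

# Walk the CODE matrix back from endpoint (i, j) (unpadded indices).
# Returns all paired (row, col) along the duplex.
duplex_traceback <- function(dp, i, j) {
  rows <- integer(); cols <- integer()
  repeat {
    rows <- c(rows, i); cols <- c(cols, j)
    code <- dp$CODE[i + 1, j + 1]
    if (is.na(code) || code == 0L) break
    di <- code %/% 1000L; dj <- code %% 1000L
    i <- i - di; j <- j - dj
  }
  list(rows = rows, cols = cols)
}

#' Duplex-energy target sites for one miRNA/UTR pair
#'
#' Sites are duplexes with free energy below the engine threshold
#' (default 0 kcal/mol); overlapping duplexes are reduced to the most
#' stable one. `raw_score` is the negated energy so that larger is better.
#'
#' @param mirna one-row data.frame from [load_mirnas()].
#' @param utr_seq UTR sequence (RNA character string).
#' @param transcript_id transcript identifier.
#' @param blocks `GRanges` of UTR genomic blocks.
#' @param model an `energy_model`.
#' @param config a [default_config()] list.
#' @return TargetSite data.frame.
#' @export
hybridization_energy <- function(mirna, utr_seq, transcript_id, blocks,
                                 model, config = default_config()) {
  if (nchar(utr_seq) < 6) return(empty_sites())
  thr <- config$duplexfold$energy_threshold
  dp <- duplex_dp(mirna$sequence, utr_seq, model)
  # candidate endpoints: best row per UTR column (one duplex ends per base)
  col_best <- apply(dp$H, 2, which.min)
  col_e <- dp$H[cbind(col_best, seq_along(col_best))]
  keep <- which(is.finite(col_e) & col_e < thr)
  if (length(keep) == 0) return(empty_sites())
  hits <- cbind(row = col_best[keep], col = keep)
  ord <- order(dp$H[hits])
  hits <- hits[ord, , drop = FALSE]
  M <- nchar(mirna$sequence)
  tk_s <- integer(); tk_e <- integer()
  rows_out <- list()
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1] - 1L; j <- hits[k, 2] - 1L
    tb <- duplex_traceback(dp, i, j)
    utr_start <- min(tb$cols) - 1L; utr_end <- max(tb$cols)
    if (any(utr_start < tk_e & utr_end > tk_s)) next
    tk_s <- c(tk_s, utr_start); tk_e <- c(tk_e, utr_end)
    # rows pairing miRNA positions 2-8 (row i pairs position M - i + 1)
    pos <- M - tb$rows + 1L
    seed_cols <- tb$cols[pos >= 2 & pos <= 8]
    if (length(seed_cols) > 0) {
      seed_start <- min(seed_cols) - 1L; seed_end <- max(seed_cols)
    } else {
      seed_start <- max(utr_start, utr_end - 8L); seed_end <- utr_end
    }
    energy <- dp$H[i + 1, j + 1]
    g <- lift_seed(blocks, seed_start, seed_end)
    rows_out[[length(rows_out) + 1]] <- data.frame(
      engine = "duplexfold", mirna_id = mirna$mirna_id,
      transcript_id = transcript_id,
      utr_start = utr_start, utr_end = utr_end,
      seed_start = seed_start, seed_end = seed_end,
      chrom = g$chrom, strand = g$strand,
      g_start = g$g_start, g_end = g$g_end, g_blocks = g$g_blocks,
      site_type = "non-canonical", raw_score = -energy,
      energy = energy, conservation = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows_out) == 0) return(empty_sites())
  do.call(rbind, rows_out)
}

#' Accessibility-adjusted duplex energy
#'
#' Approximates the cost of opening the unbound target site as the
#' self-complementarity energy of the site region against its local
#' flanking sequence: ddG = duplex energy - min(0, E_self). The adjustment
#' is never negative, so the adjusted energy is never more favourable than
#' the raw duplex energy.
#'
#' @param site one TargetSite row (from [hybridization_energy()]).
#' @param utr_seq the UTR sequence the site lies on.
#' @param model an `energy_model`.
#' @param flank nt of flanking sequence on each side considered as the
#'   competing intramolecular partner (default 20).
#' @return adjusted energy in kcal/mol.
#' @export
accessibility_adjusted_energy <- function(site, utr_seq, model, flank = 20L) {
  n <- nchar(utr_seq)
  s <- site$utr_start; e <- site$utr_end   # 0-based half-open
  region <- substr(utr_seq, s + 1L, e)
  up <- if (s > 0) substr(utr_seq, max(1L, s - flank + 1L), s) else ""
  down <- if (e < n) substr(utr_seq, e + 1L, min(n, e + flank)) else ""
  e_self <- min(0,
                duplex_mfe(region, up, model),
                duplex_mfe(region, down, model))
  site$energy - e_self
}
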