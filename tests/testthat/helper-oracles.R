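# Independent oracles and small constructors used across the test files.
# The oracles deliberately use different formulations (exhaustive
# enumeration, pair counting, an external aligner) from the implementation
# they check.

mirna_row <- function(id, seq) {
  data.frame(mirna_id = id, accession = NA, sequence = seq,
             seed = substr(seq, 2, 8), organism = sub("-.*$", "", id),
             stringsAsFactors = FALSE)
}

single_block <- function(len, chrom = "ctg", start = 1001L, strand = "+") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start, start + len - 1L),
                         strand = strand)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# --- alignment oracles ------------------------------------------------------

# Complementarity substitution matrix in DNA letters for pairwiseAlignment.
complement_matrix <- function(params) {
  b <- c("A", "C", "G", "T")
  sm <- matrix(params$mismatch, 4, 4, dimnames = list(b, b))
  sm["A", "T"] <- sm["T", "A"] <- params$match
  sm["G", "C"] <- sm["C", "G"] <- params$match
  sm["G", "T"] <- sm["T", "G"] <- params$wobble
  sm
}

# Independent local-alignment score via Biostrings (no seed multiplier).
# Biostrings charges gapOpening + L*gapExtension for a gap of length L,
# the same affine model the package uses.
oracle_align_score <- function(mirna_seq, utr_seq, params) {
  mrev <- paste(rev(strsplit(mirna_seq, "")[[1]]), collapse = "")
  p <- chartr("U", "T", mrev)
  s <- chartr("U", "T", utr_seq)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(p), Biostrings::DNAString(s),
    substitutionMatrix = complement_matrix(params),
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend,
    type = "local", scoreOnly = TRUE)
  max(0, sc)
}

# Exhaustive enumeration of all gapped local alignments (all increasing
# chains of aligned pairs; interior gaps cost open + len * extend per run).
# Supports the seed multiplier. Only feasible for tiny instances.
oracle_align_exhaustive <- function(mirna_seq, utr_seq, params) {
  m <- rev(strsplit(mirna_seq, "")[[1]])
  u <- strsplit(utr_seq, "")[[1]]
  M <- length(m); N <- length(u)
  pos <- M - seq_len(M) + 1L
  mult <- ifelse(pos >= 2 & pos <= 8, params$seed_multiplier, 1)
  sm <- complement_matrix(params)
  md <- chartr("U", "T", m); ud <- chartr("U", "T", u)
  gap <- function(l) if (l > 0) params$gap_open + l * params$gap_extend else 0
  best <- 0
  rec <- function(i0, j0, acc) {
    if (i0 >= M || j0 >= N) return(invisible())
    for (i in (i0 + 1):M) {
      for (j in (j0 + 1):N) {
        sc <- acc + sm[md[i], ud[j]] * mult[i] -
          gap(i - i0 - 1) - gap(j - j0 - 1)
        if (sc > best) best <<- sc
        rec(i, j, sc)
      }
    }
  }
  # chains starting at every first pair (no leading gap cost: local)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      sc <- sm[md[i], ud[j]] * mult[i]
      if (sc > best) best <- sc
      rec(i, j, sc)
    }
  }
  best
}

# --- duplex structure enumeration oracle ------------------------------------

# Minimum energy over every legal intermolecular structure (all increasing
# chains of complementary pairs, stacks when contiguous, affine loop costs
# otherwise). Mirrors the model definition, not the DP.
oracle_duplex_mfe <- function(x_seq, y_seq, model) {
  x <- rev(strsplit(x_seq, "")[[1]])
  y <- strsplit(y_seq, "")[[1]]
  M <- length(x); N <- length(y)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  lab <- function(i, j) match(paste0(y[j], x[i]), pairs)
  best <- Inf
  rec <- function(i0, j0, acc) {
    if (i0 >= M || j0 >= N) return(invisible())
    for (i in (i0 + 1):M) {
      for (j in (j0 + 1):N) {
        l <- lab(i, j)
        if (is.na(l)) next
        link <- if (i == i0 + 1 && j == j0 + 1) {
          model$stack[lab(i0, j0), l]
        } else {
          loop_u <- (i - i0 - 1) + (j - j0 - 1)
          if ((i - i0 - 1) > model$max_loop || (j - j0 - 1) > model$max_loop)
            next
          model$loop_open + model$loop_extend * loop_u
        }
        e <- acc + link
        if (e < best) best <<- e
        rec(i, j, e)
      }
    }
  }
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      if (is.na(lab(i, j))) next
      e <- model$initiation
      if (e < best) best <- e
      rec(i, j, e)
    }
  }
  min(0, best)
}

# --- seed-site regex oracle --------------------------------------------------

oracle_seed_sites <- function(mirna_seq, utr_seq) {
  core6 <- rna_revcomp(substr(mirna_seq, 2, 7))
  m8c <- rna_revcomp(substr(mirna_seq, 8, 8))
  hits <- gregexpr(paste0("(?=", core6, ")"), utr_seq, perl = TRUE)[[1]]
  if (hits[1] == -1) return(data.frame(start = integer(), type = character()))
  u <- strsplit(utr_seq, "")[[1]]
  n <- length(u)
  out <- lapply(as.integer(hits), function(s1) {
    m8 <- s1 > 1 && u[s1 - 1] == m8c
    a1 <- (s1 + 6) <= n && u[s1 + 6] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    data.frame(start = s1, type = type, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# --- AUC pair-counting oracle ------------------------------------------------

oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# --- shared fixture runs (cached across test files) -------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed, ...) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("mircons_fx_", seed))
    .fixture_cache[[key]] <- generate_fixture(fixture_spec(seed = seed, ...),
                                              dir)
  }
  .fixture_cache[[key]]
}

cached_pipeline <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture(seed)
    out <- file.path(tempdir(), paste0("mircons_run_", seed))
    .fixture_cache[[key]] <- run_pipeline(
      fx$paths$genome, fx$paths$gtf, fx$paths$mirnas, fx$paths$validated,
      out, default_config(seed = seed))
  }
  .fixture_cache[[key]]
}
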