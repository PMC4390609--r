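# Seeded synthetic-fixture generator. Produces a toy genome, a GTF with
# coding/non-coding/short-UTR transcripts on both strands, a mature-miRNA
# FASTA, four tiered validated-pair tables with controlled label noise, and
# a ground-truth table of every planted site -- everything the pipeline
# consumes, with no downloads.

#' Specification of a synthetic fixture
#'
#' @param seed mandatory random seed.
#' @param n_transcripts total transcripts (genes plus extra isoforms).
#' @param n_mirnas number of mature miRNAs (all `hsa-`).
#' @param p_absent fraction of transcripts with no annotated 3'-UTR
#'   (half non-coding, half coding to the exon end).
#' @param p_short fraction with an annotated UTR shorter than 50 nt.
#' @param utr_len_range range of ordinary annotated UTR lengths (nt).
#' @param n_true_pairs number of true miRNA-gene target pairs (each gets a
#'   planted strong site: full complement of miRNA positions 2-22 plus an A
#'   opposite position 1, i.e. an 8mer seed site).
#' @param decoy_rate probability that a non-true (miRNA, gene) combination
#'   gets a planted weak 6mer-only site.
#' @param tier_noise named fractions of corrupted rows per tier.
#' @param oncomirdb_coverage,mirecords_coverage fraction of true pairs
#'   listed by the high- and medium-tier sources.
#' @param extra_isoforms how many genes carry a second isoform.
#' @param n_spliced how many genes have a splice junction inside the UTR.
#' @param proxy_length downstream proxy window (nt).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_transcripts = 14L, n_mirnas = 6L,
                         p_absent = 0.25, p_short = 0.15,
                         utr_len_range = c(150L, 280L),
                         n_true_pairs = 10L, decoy_rate = 0.15,
                         tier_noise = c(high = 0, medium = 0.1, low = 0.3),
                         oncomirdb_coverage = 0.6, mirecords_coverage = 0.8,
                         extra_isoforms = 2L, n_spliced = 2L,
                         proxy_length = 130L) {
  if (missing(seed)) stop("fixture seed is mandatory")
  probs <- c(p_absent, p_short, decoy_rate, tier_noise,
             oncomirdb_coverage, mirecords_coverage)
  stopifnot(all(probs >= 0 & probs <= 1))
  spec <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
               n_mirnas = as.integer(n_mirnas), p_absent = p_absent,
               p_short = p_short, utr_len_range = as.integer(utr_len_range),
               n_true_pairs = as.integer(n_true_pairs),
               decoy_rate = decoy_rate, tier_noise = tier_noise,
               oncomirdb_coverage = oncomirdb_coverage,
               mirecords_coverage = mirecords_coverage,
               extra_isoforms = as.integer(extra_isoforms),
               n_spliced = as.integer(n_spliced),
               proxy_length = as.integer(proxy_length))
  class(spec) <- "fixture_spec"
  spec
}

random_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Plus-strand local layout of one gene (0-based half-open local coords).
# class: "plain", "spliced", "short", "absent_coding", "noncoding".
gene_layout <- function(class, L3, proxy_length) {
  pad5 <- 100L; utr5 <- 30L; cds1 <- 120L; intron <- 70L; cds2 <- 90L
  if (class == "spliced") {
    utr_a <- 40L
    exon1 <- c(pad5, pad5 + utr5 + cds1 + 3L + utr_a)      # [100, 293)
    intron_end <- exon1[2] + intron
    exon2 <- c(intron_end, intron_end + L3 - utr_a)
    cds <- list(c(pad5 + utr5, pad5 + utr5 + cds1))
    stop_c <- c(cds[[1]][2], cds[[1]][2] + 3L)
    utr_blocks <- list(c(stop_c[2], exon1[2]), exon2)
  } else if (class == "noncoding") {
    exon1 <- c(pad5, pad5 + 150L)
    intron_end <- exon1[2] + intron
    exon2 <- c(intron_end, intron_end + 150L)
    cds <- NULL; stop_c <- NULL; utr_blocks <- NULL
  } else {
    # plain / short / absent_coding: UTR (possibly empty) inside exon2
    exon1 <- c(pad5, pad5 + utr5 + cds1)                    # [100, 250)
    intron_end <- exon1[2] + intron
    exon2 <- c(intron_end, intron_end + cds2 + 3L + L3)
    cds <- list(c(pad5 + utr5, exon1[2]), c(intron_end, intron_end + cds2))
    stop_c <- c(intron_end + cds2, intron_end + cds2 + 3L)
    utr_blocks <- if (L3 > 0) list(c(stop_c[2], exon2[2])) else NULL
  }
  last_end <- exon2[2]
  list(exons = list(exon1, exon2), cds = cds, stop_codon = stop_c,
       utr_blocks = utr_blocks,
       proxy = c(last_end, last_end + proxy_length),
       contig_len = last_end + proxy_length + 40L)
}

# Map a UTR-local 0-based offset to a local (plus-strand) genomic position
# within the region where sites are planted.
plant_map <- function(layout, class, u) {
  if (class %in% c("short", "absent_coding", "noncoding")) {
    return(layout$proxy[1] + u)      # planted in the downstream proxy window
  }
  if (class == "spliced") {
    b1 <- layout$utr_blocks[[1]]; w1 <- b1[2] - b1[1]
    if (u < w1) return(b1[1] + u)
    return(layout$utr_blocks[[2]][1] + (u - w1))
  }
  layout$utr_blocks[[1]][1] + u
}

# Usable planting span (UTR-local, 0-based) for one gene.
plant_span <- function(layout, class, proxy_length) {
  if (class %in% c("short", "absent_coding", "noncoding")) {
    c(0L, proxy_length)
  } else if (class == "spliced") {
    w1 <- layout$utr_blocks[[1]][2] - layout$utr_blocks[[1]][1]
    w2 <- layout$utr_blocks[[2]][2] - layout$utr_blocks[[2]][1]
    c(w1, w1 + w2)                   # keep planted sites inside block 2
  } else {
    c(0L, layout$utr_blocks[[1]][2] - layout$utr_blocks[[1]][1])
  }
}

gtf_attrs <- function(...) {
  kv <- list(...)
  paste(vapply(names(kv), function(k) sprintf('%s "%s";', k, kv[[k]]), ""),
        collapse = " ")
}

#' Generate a complete synthetic fixture
#'
#' Writes `genome.fa`, `annotation.gtf`, `mirnas.fa`, four
#' `validated_<source>.tsv` tables, `truth_sites.tsv`, `truth_pairs.tsv`
#' and `fixture_metadata.txt` into `outdir`. All randomness comes from the
#' spec seed; the same spec produces byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param outdir writable output directory.
#' @return list with `paths` (named), `truth_sites`, `truth_pairs`, `spec`.
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  n_tx <- spec$n_transcripts
  n_extra <- spec$extra_isoforms
  n_genes <- n_tx - n_extra
  n_absent <- round(spec$p_absent * n_tx)
  n_short <- round(spec$p_short * n_tx)
  n_plain <- n_genes - n_absent - n_short
  if (n_plain < max(1L, spec$n_spliced + n_extra)) {
    stop("infeasible fixture spec: not enough plain annotated genes")
  }

  # miRNAs with distinct seeds; the 5'-terminal base cycles U/G/A so that
  # perfect target sites differ in how the base opposite position 1 pairs
  # (match / wobble / mismatch), as real miRNA populations do
  first_base <- rep(c("U", "G", "A"), length.out = spec$n_mirnas)
  repeat {
    mir_seqs <- vapply(seq_len(spec$n_mirnas), function(i) {
      paste(c(first_base[i],
              sample(c("A", "C", "G", "U"), 21, replace = TRUE)),
            collapse = "")
    }, "")
    if (!anyDuplicated(substr(mir_seqs, 2, 8))) break
  }
  mir_ids <- sprintf("hsa-miR-9%02d-5p", seq_len(spec$n_mirnas))
  mirnas <- data.frame(mirna_id = mir_ids, sequence = mir_seqs,
                       stringsAsFactors = FALSE)

  # gene classes: plain first (isoform hosts, then spliced), then short,
  # then absent (alternating coding-to-end / non-coding)
  classes <- c(rep("plain", n_plain), rep("short", n_short),
               rep(c("absent_coding", "noncoding"), length.out = n_absent))
  if (spec$n_spliced > 0) {
    classes[(n_extra + 1):(n_extra + spec$n_spliced)] <- "spliced"
  }
  strands <- rep(c("+", "-"), length.out = n_genes)

  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    class <- classes[g]
    L3 <- switch(class,
                 plain = sample(spec$utr_len_range[1]:spec$utr_len_range[2], 1),
                 spliced = sample(max(120L, spec$utr_len_range[1]):spec$utr_len_range[2], 1),
                 short = sample(20:49, 1),
                 0L)
    layout <- gene_layout(class, L3, spec$proxy_length)
    genes[[g]] <- list(
      gene_id = sprintf("G%03d", g), gene_name = sprintf("GENE%03d", g),
      contig = sprintf("ctg%03d", g), strand = strands[g],
      class = class, L3 = L3, layout = layout,
      biotype = switch(class, noncoding = "lincRNA", "protein_coding"),
      seq = random_dna(layout$contig_len),
      used = IRanges::IRanges())
  }

  # choose true pairs, spreading them over genes so planted sites fit even
  # in 130 nt proxy windows (at most ceiling(n_true/n_genes) per gene)
  if (spec$n_true_pairs > 2L * n_genes) {
    stop("infeasible fixture spec: too many true pairs per gene")
  }
  true_g <- rep(sample(n_genes), length.out = spec$n_true_pairs)
  true_m <- integer(spec$n_true_pairs)
  for (k in seq_len(spec$n_true_pairs)) {
    used_m <- true_m[true_g == true_g[k] & seq_along(true_m) < k]
    true_m[k] <- sample(setdiff(seq_len(spec$n_mirnas), used_m), 1)
  }
  # keep both 5'-U and non-5'-U miRNAs among the targeting ones, so perfect
  # sites are not all identical in how position 1 pairs with the 8mer A
  is_u <- first_base == "U"
  if (spec$n_true_pairs >= 2 && spec$n_mirnas >= 2 &&
      length(unique(is_u[true_m])) < 2) {
    k <- spec$n_true_pairs
    alt <- setdiff(which(is_u != is_u[true_m[k]]),
                   true_m[true_g == true_g[k]])
    if (length(alt) > 0) true_m[k] <- alt[1]
  }
  combos <- expand.grid(m = seq_len(spec$n_mirnas), g = seq_len(n_genes))
  is_true <- paste(combos$m, combos$g) %in% paste(true_m, true_g)

  truth_sites <- list(); truth_pairs <- list()

  # deterministic per-gene cursor: sites are packed left to right with a
  # 3 nt spacer, so planting never collides for any seed
  cursors <- vapply(genes, function(gn) {
    plant_span(gn$layout, gn$class, spec$proxy_length)[1] + 12L
  }, integer(1))
  plant <- function(g, site_chars, kind, mirna_id, site_type) {
    gene <- genes[[g]]
    span <- plant_span(gene$layout, gene$class, spec$proxy_length)
    len <- length(site_chars)
    u <- cursors[g]
    if (u + len > span[2] - 4L) {
      stop("infeasible fixture spec: planted site does not fit the UTR ",
           "region of ", gene$gene_id)
    }
    s_loc <- plant_map(gene$layout, gene$class, u)
    genes[[g]]$seq[(s_loc + 1):(s_loc + len)] <<-
      chartr("U", "T", site_chars)
    cursors[g] <<- u + len + 3L
    u
  }

  for (k in seq_len(nrow(combos))) {
    g <- combos$g[k]; m <- combos$m[k]
    gene <- genes[[g]]
    if (is_true[k]) {
      site <- paste0(rna_revcomp(substr(mir_seqs[m], 2, 22)), "A")
      u <- plant(g, strsplit(site, "")[[1]], "strong", mir_ids[m], "8mer")
      kind <- "strong"; type <- "8mer"
    } else if (stats::runif(1) < spec$decoy_rate) {
      site <- rna_revcomp(substr(mir_seqs[m], 2, 7))
      u <- plant(g, strsplit(site, "")[[1]], "decoy", mir_ids[m], "6mer")
      kind <- "decoy"; type <- "6mer"
    } else next
    iso_offsets <- c(a = 0L)
    if (gene$class == "plain" && g <= n_extra) iso_offsets <- c(a = 0L, b = 9L)
    for (iso in names(iso_offsets)) {
      tx_id <- if (iso == "a") sprintf("T%03da", g) else sprintf("T%03db", g)
      truth_sites[[length(truth_sites) + 1]] <- data.frame(
        mirna_id = mir_ids[m], transcript_id = tx_id,
        gene_symbol = gene$gene_name,
        utr_offset = u + iso_offsets[[iso]],
        site_type = type, kind = kind, stringsAsFactors = FALSE)
    }
    if (kind == "strong") {
      truth_pairs[[length(truth_pairs) + 1]] <- data.frame(
        mirna_id = mir_ids[m], gene_symbol = gene$gene_name,
        stringsAsFactors = FALSE)
    }
  }
  truth_sites <- do.call(rbind, truth_sites)
  truth_pairs <- do.call(rbind, truth_pairs)

  # assemble contigs (mirror minus-strand genes) and the GTF
  fa <- character(); gtf <- character()
  mirror <- function(iv, L) c(L - iv[2], L - iv[1])
  for (g in seq_len(n_genes)) {
    gene <- genes[[g]]
    L <- gene$layout$contig_len
    seq_chars <- gene$seq
    tx_list <- list(list(suffix = "a", shift = 0L))
    if (gene$class == "plain" && g <= n_extra) {
      tx_list[[2]] <- list(suffix = "b", shift = 9L)
    }
    if (gene$strand == "-") {
      seq_chars <- rev(chartr("ACGT", "TGCA", seq_chars))
    }
    fa <- c(fa, paste0(">", gene$contig), paste(seq_chars, collapse = ""))
    conv <- function(iv) {         # local 0-based -> genomic 1-based incl.
      if (gene$strand == "-") iv <- mirror(iv, L)
      c(iv[1] + 1L, iv[2])
    }
    for (tx in tx_list) {
      tx_id <- sprintf("T%03d%s", g, tx$suffix)
      attrs <- gtf_attrs(gene_id = gene$gene_id, transcript_id = tx_id,
                         gene_name = gene$gene_name,
                         gene_biotype = gene$biotype,
                         transcript_biotype = gene$biotype,
                         principal_isoform = if (tx$suffix == "a") "TRUE"
                                             else "FALSE")
      feat <- function(type, iv, frame = ".") {
        ge <- conv(iv)
        sprintf("%s\tfixtures\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                gene$contig, type, ge[1], ge[2], gene$strand, frame, attrs)
      }
      tx_span <- c(gene$layout$exons[[1]][1], gene$layout$exons[[2]][2])
      rows <- c(feat("transcript", tx_span),
                vapply(gene$layout$exons, function(e) feat("exon", e), ""))
      if (!is.null(gene$layout$cds)) {
        cds <- gene$layout$cds; stop_c <- gene$layout$stop_codon
        if (tx$shift > 0L) {        # isoform b: translation stops earlier
          cds[[length(cds)]][2] <- cds[[length(cds)]][2] - tx$shift
          stop_c <- stop_c - tx$shift
        }
        rows <- c(rows,
                  vapply(cds, function(e) feat("CDS", e, "0"), ""),
                  feat("stop_codon", stop_c, "0"))
      }
      gtf <- c(gtf, rows)
    }
  }

  # validated tables with tier-dependent coverage and corruption
  corrupt <- function(tab, frac) {
    n_bad <- round(frac * nrow(tab))
    if (n_bad == 0) return(tab)
    bad <- sample(nrow(tab), n_bad)
    all_genes <- vapply(genes, `[[`, "", "gene_name")
    for (i in bad) {
      true_g <- truth_pairs$gene_symbol[truth_pairs$mirna_id == tab$mirna_id[i]]
      pool <- setdiff(all_genes, true_g)
      tab$gene_symbol[i] <- sample(pool, 1)
    }
    tab
  }
  take <- function(frac) {
    truth_pairs[sample(nrow(truth_pairs), round(frac * nrow(truth_pairs))), ,
                drop = FALSE]
  }
  validated <- list(
    oncomirdb = corrupt(take(spec$oncomirdb_coverage),
                        spec$tier_noise[["high"]]),
    mirecords = corrupt(take(spec$mirecords_coverage),
                        spec$tier_noise[["medium"]]),
    tarbase = corrupt(take(1), spec$tier_noise[["low"]]),
    mirtarbase = corrupt(take(1), spec$tier_noise[["low"]])
  )

  paths <- list(genome = file.path(outdir, "genome.fa"),
                gtf = file.path(outdir, "annotation.gtf"),
                mirnas = file.path(outdir, "mirnas.fa"),
                truth_sites = file.path(outdir, "truth_sites.tsv"),
                truth_pairs = file.path(outdir, "truth_pairs.tsv"),
                metadata = file.path(outdir, "fixture_metadata.txt"))
  writeLines(fa, paths$genome)
  writeLines(gtf, paths$gtf)
  writeLines(as.vector(rbind(paste0(">", mir_ids,
                                    sprintf(" MIMAT%07d", seq_along(mir_ids))),
                             mir_seqs)), paths$mirnas)
  vpaths <- c()
  for (src in names(validated)) {
    p <- file.path(outdir, paste0("validated_", src, ".tsv"))
    tab <- validated[[src]]
    tab$evidence <- "reporter_assay"
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    vpaths[src] <- p
  }
  paths$validated <- vpaths
  utils::write.table(truth_sites, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_pairs, paths$truth_pairs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("seed=", spec$seed),
               paste0("n_transcripts=", n_tx),
               paste0("n_genes=", n_genes),
               paste0("n_mirnas=", spec$n_mirnas),
               paste0("n_true_pairs=", spec$n_true_pairs)),
             paths$metadata)
  list(paths = paths, truth_sites = truth_sites, truth_pairs = truth_pairs,
       spec = spec)
}

#' Generate a labelled per-engine score benchmark
#'
#' Each of `n` pairs gets a latent quality q ~ N(0,1); engine i scores
#' a_i * q + noise, and the validated label is Bernoulli(sigmoid(b * q)).
#' Drives the calibration-recovery and consensus-vs-individual properties.
#'
#' @param n number of pairs.
#' @param a named vector of engine signal loadings.
#' @param noise_sd noise standard deviation (scalar or per engine).
#' @param b label steepness.
#' @param seed random seed (mandatory).
#' @return data.frame with `pair_id`, `q`, `label` and one `score_<engine>`
#'   column per engine; parameters attached as attributes.
#' @export
generate_score_benchmark <- function(n = 4000,
                                     a = c(seedscan = 1.0, dpalign = 0.8,
                                           duplexfold = 0.6),
                                     noise_sd = 1, b = 2, seed) {
  if (missing(seed)) stop("benchmark seed is mandatory")
  set.seed(seed)
  q <- stats::rnorm(n)
  label <- stats::rbinom(n, 1, stats::plogis(b * q)) == 1
  df <- data.frame(pair_id = sprintf("p%05d", seq_len(n)), q = q,
                   label = label, stringsAsFactors = FALSE)
  noise_sd <- rep(noise_sd, length.out = length(a))
  for (i in seq_along(a)) {
    df[[paste0("score_", names(a)[i])]] <- a[i] * q +
      stats::rnorm(n, sd = noise_sd[i])
  }
  attr(df, "params") <- list(a = a, noise_sd = noise_sd, b = b, seed = seed)
  df
}
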