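# UTR sequence-space construction: annotation loading, annotated-vs-proxy
# extraction rules, strand handling, coordinate round-trips, mode length.

gtf_line <- function(chrom, type, start, end, strand, tx, gene,
                     biotype = "protein_coding", name = gene) {
  sprintf(paste0('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                 'transcript_id "%s"; gene_name "%s"; gene_biotype "%s"; ',
                 'transcript_biotype "%s";'),
          chrom, type, start, end, strand, gene, tx, name, biotype, biotype)
}

write_toy_inputs <- function(dir) {
  set.seed(42)
  contig <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  fa <- file.path(dir, "g.fa")
  writeLines(c(">c1 toy contig", contig), fa)
  gtf <- file.path(dir, "a.gtf")
  lines <- c(
    # plus-strand coding transcript with an 87 nt spliced-free annotated UTR
    gtf_line("c1", "exon", 101, 160, "+", "tx_plus", "gA"),
    gtf_line("c1", "exon", 201, 300, "+", "tx_plus", "gA"),
    gtf_line("c1", "CDS", 121, 160, "+", "tx_plus", "gA"),
    gtf_line("c1", "CDS", 201, 210, "+", "tx_plus", "gA"),
    gtf_line("c1", "stop_codon", 211, 213, "+", "tx_plus", "gA"),
    # minus-strand non-coding transcript (always proxy)
    gtf_line("c1", "exon", 201, 260, "-", "tx_minus", "gB",
             biotype = "processed_pseudogene"),
    gtf_line("c1", "exon", 301, 360, "-", "tx_minus", "gB",
             biotype = "processed_pseudogene"))
  writeLines(lines, gtf)
  list(fa = fa, gtf = gtf, contig = contig)
}

test_that("annotation loading keeps all biotypes and genomic exon order", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  tx <- load_annotation(toy$gtf, toy$fa)
  expect_length(tx, 2)
  expect_setequal(vapply(tx, `[[`, "", "biotype"),
                  c("protein_coding", "processed_pseudogene"))
  minus <- tx$tx_minus
  expect_equal(as.character(GenomicRanges::strand(minus$exons)),
               c("-", "-"))
  expect_equal(GenomicRanges::start(minus$exons), c(201, 301))  # genomic order
  expect_true(is.na(minus$cds_end))
})

test_that("annotation referencing a missing contig is a hard error", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  bad <- file.path(dir, "bad.gtf")
  writeLines(gtf_line("cMISSING", "exon", 1, 50, "+", "t1", "g1"), bad)
  expect_error(load_annotation(bad, toy$fa), "cMISSING")
})

test_that("transcripts without exons are skipped with a warning", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  gtf <- file.path(dir, "noexon.gtf")
  writeLines(c(gtf_line("c1", "exon", 101, 200, "+", "t_ok", "g1"),
               gtf_line("c1", "transcript", 101, 200, "+", "t_bare", "g1")),
             gtf)
  expect_warning(tx <- load_annotation(gtf, toy$fa), "t_bare")
  expect_named(tx, "t_ok")
})

test_that("annotated 3'-UTR of sufficient length is returned as such", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  genome <- load_genome(toy$fa)
  tx <- load_annotation(toy$gtf, genome)
  utr <- extract_3utr(tx$tx_plus, genome)
  expect_equal(utr$utr_source, "annotated")
  expect_equal(utr$length, 87)   # exon2 positions 214..300
  expect_equal(utr$sequence,
               as_rna(substr(toy$contig, 214, 300)))
})

test_that("missing or short annotated UTRs fall back to a 130 nt proxy", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  genome <- load_genome(toy$fa)
  # no annotated UTR at all (non-coding)
  tx <- load_annotation(toy$gtf, genome)
  utr <- extract_3utr(tx$tx_minus, genome)
  expect_equal(utr$utr_source, "proxy")
  expect_equal(utr$length, 130)
  # annotated UTR of 49 nt -> proxy replaces it
  gtf49 <- file.path(dir, "short.gtf")
  writeLines(c(gtf_line("c1", "exon", 101, 262, "+", "t49", "g1"),
               gtf_line("c1", "CDS", 101, 210, "+", "t49", "g1"),
               gtf_line("c1", "stop_codon", 211, 213, "+", "t49", "g1")),
             gtf49)
  tx49 <- load_annotation(gtf49, genome)
  u49 <- extract_3utr(tx49$t49, genome)
  expect_equal(u49$utr_source, "proxy")
  expect_equal(u49$length, 130)
  expect_equal(u49$sequence, as_rna(substr(toy$contig, 263, 392)))
  # annotated UTR of exactly 50 nt is kept
  gtf50 <- file.path(dir, "len50.gtf")
  writeLines(c(gtf_line("c1", "exon", 101, 263, "+", "t50", "g1"),
               gtf_line("c1", "CDS", 101, 210, "+", "t50", "g1"),
               gtf_line("c1", "stop_codon", 211, 213, "+", "t50", "g1")),
             gtf50)
  u50 <- extract_3utr(load_annotation(gtf50, genome)$t50, genome)
  expect_equal(u50$utr_source, "annotated")
  expect_equal(u50$length, 50)
})

test_that("minus-strand proxy is the reverse complement of the 130 bases
           genomically upstream of the leftmost exon start", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  genome <- load_genome(toy$fa)
  tx <- load_annotation(toy$gtf, genome)
  utr <- extract_3utr(tx$tx_minus, genome)
  upstream <- substr(toy$contig, 201 - 130, 200)
  expect_equal(utr$sequence, rna_revcomp(as_rna(upstream)))
})

test_that("proxy windows are truncated at contig boundaries with a warning", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  genome <- load_genome(toy$fa)
  gtf <- file.path(dir, "edge.gtf")
  writeLines(gtf_line("c1", "exon", 200, 350, "+", "t_edge", "g1",
                      biotype = "lincRNA"), gtf)
  tx <- load_annotation(gtf, genome)
  expect_warning(u <- extract_3utr(tx$t_edge, genome), "truncated")
  expect_equal(u$length, 50)   # only 50 bases remain downstream of 350
})

test_that("plus and minus copies of one gene give strand-correct proxy UTRs", {
  dir <- withr::local_tempdir()
  toy <- write_toy_inputs(dir)
  genome <- load_genome(toy$fa)
  gtf <- file.path(dir, "pm.gtf")
  writeLines(c(gtf_line("c1", "exon", 151, 230, "+", "t_p", "g1",
                        biotype = "lincRNA"),
               gtf_line("c1", "exon", 151, 230, "-", "t_m", "g1",
                        biotype = "lincRNA")), gtf)
  tx <- load_annotation(gtf, genome)
  up <- extract_3utr(tx$t_p, genome)   # proxy downstream: [231, 360]
  um <- extract_3utr(tx$t_m, genome)   # proxy upstream, revcomp: rc([21, 150])
  expect_equal(up$sequence, as_rna(substr(toy$contig, 231, 360)))
  expect_equal(um$sequence, rna_revcomp(as_rna(substr(toy$contig, 21, 150))))
})

test_that("mode of annotated UTR lengths uses smallest-value tie-break", {
  expect_equal(mode_utr_length(c(5L, 5L, 7L)), 5L)
  # brute-force frequency count confirms the tie-break
  lens <- c(3L, 3L, 4L, 4L)
  tab <- sapply(unique(lens), function(l) sum(lens == l))
  expect_equal(mode_utr_length(lens), min(unique(lens)[tab == max(tab)]))
  expect_equal(mode_utr_length(142L), 142L)
  expect_error(mode_utr_length(integer()), "no annotated UTRs")
})

test_that("UTR space round-trips bit-exactly through FASTA + BED12 + TSV", {
  fx <- cached_fixture(11)
  genome <- load_genome(fx$paths$genome)
  space <- build_utr_space(load_annotation(fx$paths$gtf, genome), genome)
  dir <- withr::local_tempdir()
  write_utr_space(space, dir)
  back <- read_utr_space(dir)
  expect_identical(unname(back$sequences), unname(space$sequences))
  expect_equal(back$meta$length, space$meta$length)
  for (tx in space$meta$transcript_id) {
    expect_equal(GenomicRanges::start(back$blocks[[tx]]),
                 GenomicRanges::start(space$blocks[[tx]]))
    expect_equal(GenomicRanges::end(back$blocks[[tx]]),
                 GenomicRanges::end(space$blocks[[tx]]))
    expect_equal(as.character(GenomicRanges::strand(back$blocks[[tx]])),
                 as.character(GenomicRanges::strand(space$blocks[[tx]])))
  }
})

test_that("local<->genomic coordinate mapping is an exact round-trip", {
  # spliced minus-strand UTR: two blocks
  blocks <- GenomicRanges::GRanges("c1",
                                   IRanges::IRanges(c(101, 301), c(150, 340)),
                                   strand = "-")
  total <- 50 + 40
  set.seed(3)
  for (k in 1:25) {
    s <- sample(0:(total - 2), 1)
    e <- sample((s + 1):total, 1)
    g <- utr_to_genomic(blocks, s, e)
    back <- genomic_to_utr(blocks, g)
    expect_equal(back[1], s)
    expect_equal(back[2], e)
  }
  # junction-spanning interval maps to two genomic blocks
  g <- utr_to_genomic(blocks, 38, 44)
  expect_length(g, 2)
  expect_equal(sum(GenomicRanges::width(g)), 6)
})
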