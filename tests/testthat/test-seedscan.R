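# Seed-match engine: canonical site-type hierarchy, A/U context and
# positional scoring, agreement with a regex oracle, planted-site
# sensitivity.

let7 <- function() mirna_row("hsa-let-7a-5p", "UGAGGUAGUAGGUUGUAUAGUU")

utr_with <- function(core, pre = 40, post = 40, seed = 1) {
  set.seed(seed)
  paste0(random_rna(pre), core, random_rna(post))
}

test_that("site types follow the canonical hierarchy", {
  # revcomp(GAGGUAG) = CUACCUC; trailing A gives the 8mer
  utr8 <- utr_with("CUACCUCA")
  s8 <- scan_seed_sites(let7(), utr8, "t1", single_block(nchar(utr8)))
  expect_equal(s8$site_type, "8mer")
  expect_equal(s8$seed_end - s8$seed_start, 8)
  utr7 <- utr_with("CUACCUCU")
  s7 <- scan_seed_sites(let7(), utr7, "t1", single_block(nchar(utr7)))
  expect_equal(s7$site_type, "7mer-m8")
  # no 6mer complement at all -> empty
  empty <- scan_seed_sites(let7(), paste(rep("A", 60), collapse = ""),
                           "t1", single_block(60))
  expect_equal(nrow(empty), 0)
})

test_that("A/U context raises the score relative to G/C context", {
  site <- "CUACCUCA"
  utr_au <- paste0(strrep("A", 30), site, strrep("U", 30))
  utr_gc <- paste0(strrep("G", 30), site, strrep("G", 30))
  s_au <- scan_seed_sites(let7(), utr_au, "t1", single_block(68))
  s_gc <- scan_seed_sites(let7(), utr_gc, "t1", single_block(68))
  expect_equal(s_au$site_type, s_gc$site_type)
  # identical placement, A/U fraction 1.0 vs 0.0
  expect_equal(s_au$raw_score - s_gc$raw_score,
               default_config()$seedscan$au_weight)
})

test_that("detection and typing agree with the regex oracle", {
  set.seed(101)
  for (k in 1:40) {
    mir <- mirna_row("hsa-miR-x", random_rna(22))
    utr <- random_rna(300)
    got <- scan_seed_sites(mir, utr, "t1", single_block(300))
    want <- oracle_seed_sites(mir$sequence, utr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      # the 6mer core starts at oracle position; compare type per core
      ord <- order(got$utr_start)
      expect_equal(got$site_type[ord], want$type[order(want$start)])
    }
  }
})

test_that("every planted exact seed match in the fixture is found", {
  fx <- cached_fixture(11)
  genome <- load_genome(fx$paths$genome)
  space <- build_utr_space(load_annotation(fx$paths$gtf, genome), genome)
  mir <- load_mirnas(fx$paths$mirnas)
  sites <- predict_targets(space, mir, engines = "seedscan")
  strong <- fx$truth_sites[fx$truth_sites$kind == "strong", ]
  for (r in seq_len(nrow(strong))) {
    hit <- sites$mirna_id == strong$mirna_id[r] &
      sites$transcript_id == strong$transcript_id[r] &
      sites$site_type == "8mer"
    expect_true(any(hit),
                label = paste("planted site found for",
                              strong$mirna_id[r], strong$transcript_id[r]))
  }
})

test_that("conservation annotation filters seedscan sites when supplied", {
  utr <- utr_with("CUACCUCA")
  blocks <- single_block(nchar(utr), chrom = "c9", start = 501)
  s <- scan_seed_sites(let7(), utr, "t1", blocks)
  # track covering the whole contig at score 0.9 vs 0.1
  hi <- GenomicRanges::GRanges("c9", IRanges::IRanges(1, 2000), score = 0.9)
  lo <- GenomicRanges::GRanges("c9", IRanges::IRanges(1, 2000), score = 0.1)
  expect_equal(annotate_conservation(s, hi)$conservation, 0.9)
  expect_equal(annotate_conservation(s, lo)$conservation, 0.1)
})
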