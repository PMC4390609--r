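---
title: "Consensus miRNA target prediction: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus miRNA target prediction: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcons)
```

## The problem

Animal microRNAs repress mRNAs mainly through sites in 3'-UTRs that pair
with the miRNA *seed* (nucleotides 2-8 from the miRNA 5' end). Individual
prediction tools disagree notoriously, both because they model different
aspects of recognition (seed match class, duplex thermodynamics, site
accessibility, conservation) and because they run on different transcript
sets. miRcons addresses both problems at desk scale: every engine runs on
the *same* isoform-level 3'-UTR sequence space, and their heterogeneous
scores are fused into one calibrated consensus.

## The 3'-UTR sequence space

All transcript isoforms of all biotypes are kept, because any isoform can
carry a private 3'-UTR. For a coding transcript, the annotated 3'-UTR is
the spliced, strand-corrected exonic sequence downstream of the translation
stop. Two failure modes are handled by a *proxy rule*: when a transcript
has no annotated UTR (non-coding transcripts, pseudogenes, coding models
that stop at the exon end), or its annotated UTR is shorter than
`min_utr_length` (default 50 nt), the `proxy_length` (default 130 nt) of
unspliced genomic sequence immediately downstream of the last exon end, in
transcription direction, stands in for it. 130 nt is the rounded average of
the modal annotated-UTR lengths observed in human, mouse and rat
(142/131/122 nt); both constants are configuration, not code. Proxy
windows that would run off a contig are truncated with a warning. A short
annotated UTR is *replaced* by the proxy (not extended to 130 nt), and the
proxy always starts at the last exon end rather than at the stop codon;
both choices keep the rule independent of CDS annotation quality.

Internally, interval arithmetic uses `GRanges` (1-based, closed), the
native Bioconductor container; every external surface -- BED output, the
local and genomic columns of site tables, the coordinate convention of
imported prediction tables -- is 0-based half-open. `utr_to_genomic()` /
`genomic_to_utr()` map spliced UTR-local coordinates to genomic blocks and
back; the mapping is exactly invertible and property-tested on both strands.

## The three engines

The engines implement the three mechanism families used by the established
tools, not the tools themselves; their scores are this package's own.

**seedscan** (exact seed pairing). Every exact match of the reverse
complement of miRNA positions 2-7 is classified by the canonical hierarchy:
8mer (match 2-8 plus an A opposite position 1), 7mer-m8, 7mer-A1, 6mer.
`raw_score = type_score + au_weight * AU + pos_weight * central`, where
`AU` is the A/U fraction of the 30 nt flanking the site (A/U-rich context
favours functional sites) and `central` in [0, 1] rewards placement around
the middle of the UTR. Defaults: type scores 4/3/2/1, `au_weight` 1,
`pos_weight` 0.5. When a per-base conservation bedGraph is supplied, the
mean conservation over the seed is attached and sites below
`conservation_threshold` (0.5) are dropped; without a track the filter is
disabled and the field is `NA` -- conservation is consumed, never computed.

**dpalign** (complementarity alignment). Local affine-gap alignment
(Gotoh) of the reversed miRNA against the UTR, scoring complementarity:
Watson-Crick pairs +5, G-U wobble +1, mismatch -3; a gap of length L costs
`gap_open + L * gap_extend` (8 + 2L). Pair scores at miRNA positions 2-8
are doubled (`seed_multiplier = 2`), reflecting the dominant contribution
of seed pairing. Sites are kept at alignment score >= 140 -- the
conventional stringent cutoff for this score family (a fully paired 22-mer
scores 145 with the seed bonus). The implementation is verified against an
independent aligner on random instances and against exhaustive enumeration
of all gapped alignments on tiny instances.

**duplexfold** (hybridization energy). The minimum-free-energy
intermolecular duplex between miRNA and UTR, computed by dynamic
programming over nearest-neighbour stacks with affine bulge/internal-loop
costs and a duplex initiation penalty; intramolecular pairs are never
formed. Watson-Crick stack energies are the standard published
nearest-neighbour values; G-U wobble stacks are simplified to uniform
-1.2 kcal/mol (-0.5 for wobble-on-wobble), and loops cost
`3.0 + 0.5/nt` kcal/mol rather than full tabulated loop tables -- a
deliberate desk-scale simplification of duplex thermodynamics (the DP is
verified against exhaustive structure enumeration under the same model).
Sites are kept at energy < 0 kcal/mol, the permissive convention of this
family, and `raw_score = -energy`. A Pita-style accessibility adjustment is
available: `accessibility_adjusted_energy()` returns the duplex energy
minus the self-complementarity energy of the site region against its local
flanks -- an opening-cost approximation that can only make a site *less*
favourable.

Per engine, overlapping sites for one miRNA-transcript pair are reduced to
the best-scoring site per overlap cluster, so one binding position is one
event. Externally computed prediction tables (TSV with a declared
coordinate convention) can be imported as additional engines.

## Standardization, calibration, consensus

Raw scores are incomparable across engines. Two transformations make them
commensurable:

* **Z-standardization.** Within each engine, scores are oriented so larger
  is better and standardized over the engine's whole prediction set, using
  the population (n) standard deviation for exact reproducibility.
* **Precision-above-score weights.** Against the unique validated pairs,
  each observed score s gets `W(s) = P(validated | score >= s)` -- the
  precision of the engine's complementary cumulative score distribution.
  The raw curve is not monotone on finite data, so it is made
  non-decreasing by pool-adjacent-violators isotonic regression, weighted
  by the number of predictions above each knot; a probability
  interpretation requires monotonicity. W is evaluated *at each
  prediction's own score* (not one constant per engine) and floored at
  `epsilon = 1e-6` so the consensus denominator never vanishes.

Predictions from different engines that hit the same genomic position --
seed intervals overlapping by at least 1 bp, for the same miRNA and
transcript, merged transitively -- form one consensus group. Exact
coincidence (same site type and identical coordinates from two or more
engines) is additionally flagged `agreement_exact`. Each group is scored

$$\mathrm{CWS} = \frac{\sum_i Z_i W_i}{\sum_i W_i},$$

a convex combination of the members' standardized scores weighted by each
engine's calibrated reliability at that score. Groups are ranked by
descending CWS, with deterministic tie-breaks (agreement, then
identifiers and position). Predictions whose (miRNA, gene) pair appears in
the validated set are flagged; matching is at gene-symbol level because the
validated databases are gene-oriented, so all isoforms of a validated gene
are flagged.

## Validated pairs and evaluation

Validated-pair tables are ingested per source database with a reliability
tier: manually curated sources are `high` (OncomirDB-like), partially
curated `medium` (miRecords-like), text-mining-derived `low`
(TarBase/miRTarBase-like). Pairs are deduplicated on (miRNA, gene); the
merged record keeps the set of supporting sources and the best tier, and
the merge is monotone (adding a source never lowers a tier).

ROC evaluation treats every predicted pair not in the validated set as a
*presumed negative* -- a known bias shared with the evaluation design this
package follows, and the reason absolute AUCs here should be read
comparatively, not as error rates. The evaluation universe is the set of
predicted pairs (per unique pair, each method's best score; engines that
missed a pair contribute their observed floor), with a per-site mode
available. AUC uses the trapezoid rule, which equals the concordance
(rank) statistic with ties counted 1/2. Tier-stratified ROC takes, per
tier, the pairs supported by that tier's sources as positives -- a pair
backed by several tiers is a positive in each -- mirroring per-database
evaluation datasets.

## The synthetic study conditions

`generate_fixture()` builds everything the pipeline consumes from one
seed: a toy genome (one contig per gene, <= 4 kb), a GTF with coding,
non-coding, short-UTR, spliced-UTR and second-isoform transcripts on both
strands (default 14 transcripts: 25% UTR-absent, 15% short, two spliced,
two extra isoforms), six 22-nt miRNAs whose 5'-terminal base cycles U/G/A
(real miRNA 5' ends vary, with a U bias; without this, every perfect site
would carry an identical alignment score), ten true miRNA-gene pairs each
with a planted strong site (full complement of miRNA positions 2-22 plus
an A opposite position 1, i.e. a guaranteed 8mer), weak 6mer decoys for
15% of non-true combinations, and four validated tables with tiered
coverage and corruption: the high tier lists 60% of true pairs noiselessly,
the medium tier 80% with 10% corrupted rows, the low tiers all true pairs
with 30% of rows pointing at wrong genes. Planted sites are packed
deterministically left-to-right inside the (annotated or proxy) UTR
region, so generation is reproducible byte-for-byte and never collides.

What the fixture does *not* emulate: realistic base composition,
UTR-length distributions, multiple sites with cooperative spacing,
conservation tracks, and the scale of genome-wide runs. Passing tests
therefore demonstrate correctness of the machinery and the direction of
the qualitative effects (consensus >= individual engines; clean tiers
score higher than corrupted ones), not genome-scale accuracy.

`generate_score_benchmark()` drives the statistical properties directly:
each of n pairs has latent quality q ~ N(0,1), engine i reports
`a_i q + noise` (defaults a = 1.0/0.8/0.6, unit noise), and the validated
label is Bernoulli(sigmoid(2q)). On 4,000 pairs the calibrated consensus
reliably outperforms the best single engine; on 10,000 pairs the fitted
W curve recovers the generative precision-above-score curve within 0.05
at every decile (checked against an independent 400,000-draw Monte-Carlo
oracle).

## Numerical choices and degenerate inputs

* Population (n) standard deviation in standardization; engines with fewer
  than two predictions or zero score variance are an error naming the
  engine, not a silent skip.
* Weight lookup is a right-continuous step function over the observed
  score knots; out-of-range scores clamp to the end knots.
* PAVA is the weighted pool-adjacent-violators algorithm; it preserves the
  weighted mean and is idempotent.
* Duplex DP candidate endpoints are the per-UTR-column minima; overlap
  reduction is greedy from the most stable site. The loop cap
  (`max_loop = 8` unpaired nt per strand) bounds the DP and is part of the
  energy model's definition.
* Ranking ties break on agreement, then miRNA id, transcript id and
  genomic start, so equal-CWS output orders are stable.
* All randomness flows from a single integer seed; rerunning a pipeline
  with the same seed reproduces every CSV byte-for-byte (the run-metadata
  file carries the only timestamp).

## Problem sizes

The packaged tests and the acceptance script run the full pipeline on the
default 14-transcript/6-miRNA fixture (about 15 s), the 4,000-pair
consensus benchmark, the 10,000-pair calibration recovery, 200 random
alignment-oracle instances (<= 10 x 12 nt), 100 duplex-enumeration
instances (<= 8 nt) and 40 tiny exhaustive-alignment instances. These sizes
were chosen so the whole suite completes in about a minute while every
oracle comparison remains exhaustive or independent.

## Known limitations

* The engines are mechanism-family implementations, not re-implementations
  of the published binaries; their raw scores are not comparable to
  miRanda/TargetScan/RNAhybrid/Pita output (imported tables enter the
  consensus on their own calibrated scale instead).
* Presumed negatives bias calibration and ROC downward for engines that
  find genuinely novel sites.
* The wobble stack energies and affine loop costs are simplified; absolute
  duplex energies are approximate even though the DP is exact for the
  model.
* Calibration is pooled over the whole run; per-organism calibration is a
  matter of running the pipeline per organism.
* Conservation input is optional and external; no alignment-based
  conservation is computed.
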