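#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside ACGUT (and N) is an
#' error; the offending record name is reported when given.
#'
#' @param x character vector of sequences.
#' @param name optional record names used in error messages.
#' @return character vector over ACGUN.
#' @export
as_rna <- function(x, name = NULL) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    lab <- if (is.null(name)) which(bad)[1] else name[bad][1]
    stop("sequence contains non-ACGUT characters: ", lab)
  }
  x
}

#' Reverse complement of an RNA string
#' @param x character vector of RNA sequences.
#' @return reverse-complemented character vector.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", toupper(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Is an RNA base pair Watson-Crick?
#' @keywords internal
is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

#' Is an RNA base pair a G-U wobble?
#' @keywords internal
is_wobble_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults. Engine
#' keep-thresholds follow the conventions of the corresponding published
#' tool families: the alignment engine keeps sites scoring at least 140
#' (an alignment score, not a physical energy) and the duplex engine keeps
#' sites with free energy below 0 kcal/mol.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `mircons_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    proxy_length      = 130L,  # nt, downstream proxy for absent/short UTRs
    min_utr_length    = 50L,   # nt, annotated UTRs shorter than this use the proxy
    # seedscan (seed-match) engine
    seedscan = list(
      type_scores = c("8mer" = 4, "7mer-m8" = 3, "7mer-A1" = 2, "6mer" = 1),
      au_flank    = 30L,   # nt of flanking context for the A/U fraction
      au_weight   = 1,
      pos_weight  = 0.5,   # reward for central placement in long UTRs
      min_score   = 0,
      conservation_threshold = 0.5  # applied only when a track is supplied
    ),
    # dpalign (complementarity alignment) engine
    dpalign = list(
      match = 5, mismatch = -3, wobble = 1,
      gap_open = 8, gap_extend = 2,   # penalties, subtracted
      seed_multiplier = 2,            # multiplier on miRNA positions 2-8
      score_threshold = 140
    ),
    # duplexfold (duplex free-energy) engine
    duplexfold = list(
      energy_threshold = 0,    # keep sites with energy < 0 kcal/mol
      max_loop = 8L,           # max unpaired stretch per strand inside a duplex
      loop_open = 3.0,         # kcal/mol, affine loop/bulge opening
      loop_extend = 0.5,       # kcal/mol per additional unpaired base
      initiation = 4.09        # kcal/mol duplex initiation
    ),
    epsilon = 1e-6,            # calibration weight floor
    min_agreement = 1L,
    validated_only = FALSE,
    include_proxy_utrs = TRUE,
    biotypes = NULL,           # optional allow-list
    principal_only = FALSE,
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(cfg$dpalign$match > 0)
  class(cfg) <- "mircons_config"
  cfg
}
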