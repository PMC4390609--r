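# Consensus layer: per-engine Z-standardization, precision-above-score
# weight calibration (isotonic), overlap grouping across engines, and the
# consensus weighted score
#
#   CWS = sum_i(Z_i * W_i) / sum_i(W_i)
#
# over the member predictions of one group, where Z_i is the engine's
# standardized score and W_i the calibrated probability that a prediction
# scoring at least as high is not a false positive.

#' Default score orientation per engine
#'
#' Declares, per engine, whether larger raw scores are better (`"larger"`)
#' or lower values (energies) are better (`"lower"`). The built-in engines
#' all store larger-is-better raw scores (duplexfold negates its energy).
#' @return named character vector.
#' @export
default_orientation <- function() {
  c(seedscan = "larger", dpalign = "larger", duplexfold = "larger")
}

#' Z-standardize raw scores within each engine
#'
#' Orients every engine's scores so that larger is better, then centres and
#' scales them over the engine's whole prediction set using the population
#' (n) standard deviation.
#'
#' @param sites TargetSite data.frame (all engines together).
#' @param orientation_map named vector engine -> `"larger"`/`"lower"`;
#'   engines not named are assumed larger-is-better.
#' @return `sites` with an added `z` column.
#' @export
standardize <- function(sites, orientation_map = default_orientation()) {
  sites$z <- NA_real_
  for (eng in unique(sites$engine)) {
    idx <- sites$engine == eng
    s <- sites$raw_score[idx]
    if (sum(idx) < 2) stop("engine ", eng, " has fewer than 2 predictions")
    orient <- unname(orientation_map[eng])
    if (is.na(orient)) orient <- "larger"
    if (orient == "lower") s <- -s
    mu <- mean(s)
    sd_pop <- sqrt(mean((s - mu)^2))
    if (sd_pop == 0) stop("zero score variance for engine ", eng)
    sites$z[idx] <- (s - mu) / sd_pop
  }
  sites
}

#' Weighted pool-adjacent-violators (non-decreasing isotonic fit)
#'
#' @param y values to fit.
#' @param w non-negative weights.
#' @return non-decreasing fit minimizing the weighted squared error.
#' @export
pava_nondecreasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric())
  vals <- y; wts <- w; sizes <- rep(1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    vals[k] <- y[i]; wts[k] <- w[i]; sizes[k] <- 1L
    while (k > 1L && vals[k - 1L] > vals[k]) {
      tot <- wts[k - 1L] + wts[k]
      vals[k - 1L] <- (vals[k - 1L] * wts[k - 1L] + vals[k] * wts[k]) / tot
      wts[k - 1L] <- tot
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      k <- k - 1L
    }
  }
  rep(vals[seq_len(k)], sizes[seq_len(k)])
}

#' Calibrate per-engine precision-above-score weight curves
#'
#' For each engine, every observed (oriented) raw score s gets the raw
#' weight W(s) = #validated predictions scoring >= s divided by
#' #predictions scoring >= s -- the precision of the engine above that
#' score, estimated from the complementary cumulative score distribution
#' against the validated set. The raw curve is made non-decreasing in s by
#' pool-adjacent-violators isotonic regression weighted by the number of
#' predictions above each knot, and floored at `epsilon`.
#'
#' @param sites TargetSite data.frame with a logical `validated` column.
#' @param orientation_map as in [standardize()].
#' @param epsilon weight floor (default 1e-6).
#' @return named list of `calibration_curve` objects (one per engine), each
#'   a data.frame with ascending `score` knots (oriented scale) and `W`.
#' @export
calibrate_weights <- function(sites, orientation_map = default_orientation(),
                              epsilon = 1e-6) {
  stopifnot("validated" %in% names(sites))
  curves <- list()
  for (eng in unique(sites$engine)) {
    idx <- sites$engine == eng
    if (sum(idx) == 0) { warning("engine ", eng, " has no predictions"); next }
    orient <- unname(orientation_map[eng])
    if (is.na(orient)) orient <- "larger"
    s <- sites$raw_score[idx]
    if (orient == "lower") s <- -s
    v <- as.logical(sites$validated[idx])
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; v <- v[ord]
    last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
    knots <- s[last]                         # descending unique scores
    n_above <- seq_along(s)[last]            # predictions scoring >= knot
    v_above <- cumsum(v)[last]
    W_raw <- v_above / n_above
    # ascending score order for the isotonic fit
    kn_asc <- rev(knots)
    W_asc <- rev(W_raw)
    wt_asc <- rev(n_above)
    W_fit <- pava_nondecreasing(W_asc, wt_asc)
    W_fit <- pmin(1, pmax(epsilon, W_fit))
    curve <- data.frame(score = unname(kn_asc), W = unname(W_fit))
    class(curve) <- c("calibration_curve", "data.frame")
    attr(curve, "engine") <- eng
    attr(curve, "orientation") <- orient
    curves[[eng]] <- curve
  }
  curves
}

#' Look up calibrated weights at raw scores
#'
#' Step-function lookup: the weight of the right-most knot at or below the
#' (oriented) score; scores below the first knot take the first knot's
#' weight.
#'
#' @param curve a `calibration_curve`.
#' @param raw_score engine-native raw scores.
#' @return numeric weights in `[epsilon, 1]`.
#' @export
lookup_weight <- function(curve, raw_score) {
  s <- raw_score
  if (attr(curve, "orientation") == "lower") s <- -s
  i <- findInterval(s, curve$score)
  i[i < 1] <- 1L
  curve$W[i]
}

#' Serialize / read calibration curves as TSV
#' @param curves named list from [calibrate_weights()].
#' @param path output TSV (columns engine, score, W).
#' @export
write_calibration <- function(curves, path) {
  tab <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(engine = attr(cv, "engine"),
               orientation = attr(cv, "orientation"),
               score = cv$score, W = cv$W, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  curves <- list()
  for (eng in unique(tab$engine)) {
    sub <- tab[tab$engine == eng, , drop = FALSE]
    curve <- data.frame(score = sub$score, W = sub$W)
    class(curve) <- c("calibration_curve", "data.frame")
    attr(curve, "engine") <- eng
    attr(curve, "orientation") <- sub$orientation[1]
    curves[[eng]] <- curve
  }
  curves
}

#' Group co-located predictions across engines
#'
#' Predictions for the same (miRNA, transcript) whose genomic seed
#' intervals overlap by at least 1 bp are merged into one group (transitive
#' closure). Within a group each engine contributes its single best-scoring
#' member. `agreement` counts distinct engines; `agreement_exact` is TRUE
#' when at least two engines coincide in both site type and exact seed
#' coordinates.
#'
#' @param sites TargetSite data.frame with a `z` column (see
#'   [standardize()]).
#' @return data.frame with one row per group and a `members` list-column of
#'   member row indices into `sites`.
#' @export
group_overlapping <- function(sites) {
  if (nrow(sites) == 0) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  key <- paste(sites$mirna_id, sites$transcript_id, sep = "\r")
  for (kk in unique(key)) {
    idx <- which(key == kk)
    ir <- IRanges::IRanges(sites$g_start[idx] + 1L, sites$g_end[idx])
    red <- IRanges::reduce(ir)
    cl <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (c in unique(cl)) {
      member_idx <- idx[cl == c]
      # best member per engine
      by_eng <- split(member_idx, sites$engine[member_idx])
      member_idx <- vapply(by_eng, function(ii) {
        ii[which.max(sites$raw_score[ii])]
      }, integer(1))
      engs <- sites$engine[member_idx]
      exact <- FALSE
      if (length(member_idx) >= 2) {
        sig <- paste(sites$site_type[member_idx], sites$seed_start[member_idx],
                     sites$seed_end[member_idx])
        exact <- anyDuplicated(sig) > 0
      }
      out[[length(out) + 1]] <- data.frame(
        mirna_id = sites$mirna_id[member_idx[1]],
        transcript_id = sites$transcript_id[member_idx[1]],
        chrom = sites$chrom[member_idx[1]],
        strand = sites$strand[member_idx[1]],
        g_start = min(sites$g_start[member_idx]),
        g_end = max(sites$g_end[member_idx]),
        agreement = length(unique(engs)),
        agreement_exact = exact,
        members = I(list(unname(member_idx))),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consensus weighted score of one group
#'
#' @param z member standardized scores.
#' @param W member calibrated weights.
#' @return CWS = sum(z * W) / sum(W).
#' @export
compute_cws <- function(z, W) {
  stopifnot(length(z) == length(W), length(z) >= 1, all(W > 0))
  sum(z * W) / sum(W)
}

#' Attach weights and CWS to consensus groups
#'
#' @param groups data.frame from [group_overlapping()].
#' @param sites the standardized TargetSite table the groups index into.
#' @param curves calibration curves from [calibrate_weights()].
#' @return `groups` with `cws` plus per-group member summaries
#'   (`engines`, `site_types`, `zs`, `ws`, `raw_scores` as packed strings).
#' @export
score_groups <- function(groups, sites, curves) {
  n <- nrow(groups)
  cws <- numeric(n)
  engines <- character(n); types <- character(n)
  zs <- character(n); ws <- character(n); raws <- character(n)
  for (g in seq_len(n)) {
    ii <- groups$members[[g]]
    z <- sites$z[ii]
    W <- vapply(seq_along(ii), function(k) {
      eng <- sites$engine[ii[k]]
      if (!eng %in% names(curves)) return(1e-6)
      lookup_weight(curves[[eng]], sites$raw_score[ii[k]])
    }, numeric(1))
    cws[g] <- compute_cws(z, W)
    engines[g] <- paste(sites$engine[ii], collapse = ";")
    types[g] <- paste(sites$site_type[ii], collapse = ";")
    zs[g] <- paste(signif(z, 8), collapse = ";")
    ws[g] <- paste(signif(W, 8), collapse = ";")
    raws[g] <- paste(signif(sites$raw_score[ii], 8), collapse = ";")
  }
  groups$cws <- cws
  groups$engines <- engines
  groups$site_types <- types
  groups$zs <- zs
  groups$ws <- ws
  groups$raw_scores <- raws
  groups
}

#' Rank consensus groups
#'
#' Descending CWS; ties broken by agreement (descending), then miRNA id,
#' transcript id and genomic start for determinism.
#'
#' @param groups scored group data.frame.
#' @return reordered data.frame.
#' @export
rank_predictions <- function(groups) {
  if (nrow(groups) == 0) return(groups)
  ord <- order(-groups$cws, -groups$agreement, groups$mirna_id,
               groups$transcript_id, groups$g_start)
  res <- groups[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
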