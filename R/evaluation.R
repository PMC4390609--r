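# ROC/AUC evaluation of individual engines and the consensus against
# validated pairs, with stratification by reliability tier.

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (descending). The curve starts at
#' (0,0) and ends at (1,1); tied scores move diagonally, so the trapezoid
#' AUC equals the rank-statistic (concordance) formulation with ties
#' counted 1/2.
#'
#' @param scores numeric prediction scores (larger = more positive).
#' @param labels logical or 0/1 vector; needs at least one of each class.
#' @param label method label carried in the result.
#' @return object of class `roc_result`: list with `label`, `points`
#'   (data.frame fpr, tpr) and `auc`.
#' @export
roc_curve <- function(scores, labels, label = "method") {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) stop("ROC needs both classes; got ", P,
                             " positives and ", N, " negatives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # advance one unique score at a time
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(label = label,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC [", x$label, "]: AUC =", format(x$auc, digits = 4), "over",
      nrow(x$points) - 1, "thresholds\n")
  invisible(x)
}

#' Pair-level evaluation table
#'
#' Collapses scored consensus groups to one row per (miRNA, gene) pair:
#' each engine's best z among the pair's groups (engines that predicted
#' nothing for a pair contribute their floor, the engine's minimum z over
#' the whole run), the best CWS, and the validated label.
#'
#' @param groups labelled, scored groups (see [score_groups()],
#'   [label_predictions()]).
#' @param sites standardized TargetSite table the groups index into.
#' @param per_site if TRUE, evaluate per site (group) instead of per pair.
#' @return data.frame with `mirna_id`, `gene_symbol`, one `z_<engine>`
#'   column per engine, `cws`, `validated`, `validated_tier`.
#' @export
evaluation_table <- function(groups, sites, per_site = FALSE) {
  engines <- sort(unique(sites$engine))
  floors <- vapply(engines, function(e) min(sites$z[sites$engine == e]),
                   numeric(1))
  key <- if (per_site) seq_len(nrow(groups))
         else paste(groups$mirna_id, groups$gene_symbol, sep = "\r")
  idx_by_pair <- split(seq_len(nrow(groups)), key)
  rows <- lapply(idx_by_pair, function(gi) {
    member_rows <- unlist(groups$members[gi])
    z <- stats::setNames(floors, engines)
    for (e in engines) {
      mi <- member_rows[sites$engine[member_rows] == e]
      if (length(mi) > 0) z[e] <- max(sites$z[mi])
    }
    out <- data.frame(mirna_id = groups$mirna_id[gi[1]],
                      gene_symbol = groups$gene_symbol[gi[1]],
                      stringsAsFactors = FALSE)
    for (e in engines) out[[paste0("z_", e)]] <- unname(z[e])
    out$cws <- max(groups$cws[gi])
    out$validated <- any(groups$validated[gi])
    tiers <- groups$validated_tier[gi]
    out$validated_tier <- if (all(is.na(tiers))) NA_character_
                          else names(which.max(tier_rank[stats::na.omit(tiers)]))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' ROC evaluation of each engine and the consensus
#'
#' All methods are evaluated on the identical prediction universe (the
#' unique predicted pairs); labels are the validated flags, with
#' non-validated predictions treated as presumed negatives.
#'
#' @param eval_tab data.frame from [evaluation_table()].
#' @return named list of `roc_result` (one per engine plus `"cws"`).
#' @export
evaluate_methods <- function(eval_tab) {
  zcols <- grep("^z_", names(eval_tab), value = TRUE)
  res <- list()
  for (col in zcols) {
    lab <- sub("^z_", "", col)
    res[[lab]] <- roc_curve(eval_tab[[col]], eval_tab$validated, label = lab)
  }
  res[["cws"]] <- roc_curve(eval_tab$cws, eval_tab$validated, label = "cws")
  res
}

#' Tier-stratified ROC of the consensus
#'
#' Recomputes the consensus ROC three times, each time taking as positives
#' the pairs supported by sources of one reliability tier (high / medium /
#' low); all other predictions count as negatives. A pair backed by several
#' tiers is a positive in each of them. Tiers without positives are skipped
#' with a warning.
#'
#' @param eval_tab data.frame from [evaluation_table()].
#' @param validated_records data.frame from [load_validated()] (one row per
#'   source record, with `reliability_tier`).
#' @param score_col which score to stratify (default `"cws"`).
#' @return named list of `roc_result` per tier.
#' @export
evaluate_by_tier <- function(eval_tab, validated_records, score_col = "cws") {
  ekey <- paste(normalize_mirna_id(eval_tab$mirna_id),
                normalize_gene(eval_tab$gene_symbol), sep = "\r")
  res <- list()
  for (tier in c("high", "medium", "low")) {
    rec <- validated_records[validated_records$reliability_tier == tier, ,
                             drop = FALSE]
    tkey <- unique(paste(rec$mirna_id, rec$gene_symbol, sep = "\r"))
    pos <- ekey %in% tkey
    if (sum(pos) == 0) {
      warning("tier ", tier, " has no positives among predictions; skipped")
      next
    }
    if (all(pos)) {
      warning("tier ", tier, " has no negatives among predictions; skipped")
      next
    }
    res[[tier]] <- roc_curve(eval_tab[[score_col]], pos,
                             label = paste0("cws_", tier))
  }
  res
}

#' AUC table of a list of ROC results
#' @param rocs named list of `roc_result`.
#' @return data.frame with `method` and `auc`.
#' @export
auc_table <- function(rocs) {
  data.frame(method = vapply(rocs, `[[`, "", "label"),
             auc = vapply(rocs, `[[`, numeric(1), "auc"),
             row.names = NULL, stringsAsFactors = FALSE)
}
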