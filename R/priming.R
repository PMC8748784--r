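#' Univariate regressions of a module score on candidate features
#'
#' For each feature column, ordinary least squares of the module score on
#' that feature alone: slope, two-sided t-test p-value on the slope, and
#' Benjamini-Hochberg adjustment across features. Zero-variance features
#' are excluded with a flag rather than fit.
#'
#' @param score Per-cell module score vector.
#' @param features Cell x feature numeric matrix (same cells, >= 10).
#' @param kind Feature kind recorded in the output (`"motif"` or `"tf"`).
#' @return data.frame: `feature`, `kind`, `coef`, `p`, `adj_p`, `flagged`.
#' @export
regress_features <- function(score, features, kind = "motif") {
  n <- length(score)
  if (nrow(features) != n) stopf("score and features disagree on cell count")
  if (n < 10L) stopf("need >= 10 cells for regression")
  xm <- colMeans(features)
  xc <- sweep(features, 2, xm)
  yc <- score - mean(score)
  sxx <- colSums(xc^2)
  flagged <- sxx <= 0
  slope <- se <- pv <- rep(NA_real_, ncol(features))
  ok <- !flagged
  slope[ok] <- colSums(xc[, ok, drop = FALSE] * yc) / sxx[ok]
  # residual variance per feature, df = n - 2
  syy <- sum(yc^2)
  rss <- syy - slope[ok]^2 * sxx[ok]
  rss <- pmax(rss, 0)
  se[ok] <- sqrt(rss / (n - 2) / sxx[ok])
  tstat <- slope[ok] / se[ok]
  pv[ok] <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pv[ok][se[ok] == 0] <- 0           # exact linear dependence
  data.frame(feature = colnames(features), kind = kind, coef = slope,
             p = pv, adj_p = p.adjust(pv, method = "BH"), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Clip regression coefficients to the positively-associated set
#'
#' Coefficients that are negative or whose adjusted p-value exceeds `alpha`
#' are set to 0; the rest pass through. Idempotent.
#'
#' @param raw A [regress_features()] result.
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @return The input with a `coef_clipped` column added.
#' @export
clip_and_filter <- function(raw, alpha = 0.05) {
  cc <- raw$coef
  cc[is.na(cc) | raw$coef < 0 | is.na(raw$adj_p) | raw$adj_p > alpha] <- 0
  raw$coef_clipped <- cc
  raw
}

#' Identify co-enriched motif/TF priming pairs per tissue
#'
#' Runs the clipped regressions of each tissue's module score against motif
#' deviations and TF gene activities, then flags a curated (motif, TF) pair
#' for a tissue when both members' clipped coefficients are positive.
#'
#' @param module_scores Cell x tissue score matrix.
#' @param motif_activity Cell x motif deviation matrix.
#' @param tf_activity Cell x TF gene-activity matrix.
#' @param pairing data.frame with columns `motif_id`, `tf_id` (many-to-many
#'   allowed).
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @param cells Optional per-tissue named list of cell indices to regress
#'   on (e.g. the cells of each tissue's establishment timepoint); default
#'   all cells.
#' @return Object of class `priming_result`: list with `coefficients`
#'   (per tissue regression tables) and `pairs` (data.frame `tissue`,
#'   `motif_id`, `tf_id`, `motif_coef`, `tf_coef`, `flagged`).
#' @export
pair_motif_tf <- function(module_scores, motif_activity, tf_activity,
                          pairing, alpha = 0.05, cells = NULL) {
  tissues <- colnames(module_scores)
  coefs <- list()
  pair_rows <- list()
  for (tissue in tissues) {
    idx <- if (is.null(cells)) seq_len(nrow(module_scores)) else cells[[tissue]]
    rm_ <- clip_and_filter(
      regress_features(module_scores[idx, tissue], motif_activity[idx, , drop = FALSE],
                       kind = "motif"), alpha)
    rt_ <- clip_and_filter(
      regress_features(module_scores[idx, tissue], tf_activity[idx, , drop = FALSE],
                       kind = "tf"), alpha)
    coefs[[tissue]] <- rbind(rm_, rt_)
    if (nrow(pairing) == 0L) next
    mi <- match(pairing$motif_id, rm_$feature)
    ti <- match(pairing$tf_id, rt_$feature)
    missing <- is.na(mi) | is.na(ti)
    if (any(missing))
      warnf("%d pairing rows reference features absent from the results; skipped",
            sum(missing))
    keep <- which(!missing)
    if (!length(keep)) next
    mc <- rm_$coef_clipped[mi[keep]]
    tc <- rt_$coef_clipped[ti[keep]]
    pair_rows[[tissue]] <- data.frame(
      tissue = tissue, motif_id = pairing$motif_id[keep],
      tf_id = pairing$tf_id[keep], motif_coef = mc, tf_coef = tc,
      flagged = mc > 0 & tc > 0, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(tissue = character(), motif_id = character(),
               tf_id = character(), motif_coef = numeric(),
               tf_coef = numeric(), flagged = logical())
  rownames(pairs) <- NULL
  structure(list(coefficients = coefs, pairs = pairs, alpha = alpha),
            class = "priming_result")
}

#' @export
print.priming_result <- function(x, ...) {
  cat(sprintf("<priming_result> %d tissues, %d flagged pairs (alpha %.3g)\n",
              length(x$coefficients), sum(x$pairs$flagged), x$alpha))
  invisible(x)
}
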