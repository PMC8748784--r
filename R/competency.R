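#' Adjusted Fisher-Pearson standardized skewness (G1)
#'
#' `g1 = m3 / m2^{3/2}` on the biased central moments, corrected to
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)`. Returns `NA` with attribute
#' `flag = "constant"` for constant input.
#'
#' @param x Numeric vector, length >= 3.
#' @return Scalar skewness.
#' @export
skewness_g1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stopf("skewness needs >= 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(structure(NA_real_, flag = "constant"))
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Configuration for diffuse/skewed competency calls
#'
#' At non-earliest timepoints a tissue score distribution is called
#' `skewed` iff its skewness exceeds `skew_cutoff` (strictly). At the
#' earliest timepoint the skewness bar is lowered to `earliest_skew_cutoff`
#' but a maximum-score filter `earliest_max_score` is added, guarding
#' against low-magnitude score distributions.
#'
#' @param skew_cutoff Skewness cutoff at non-earliest timepoints (default 1).
#' @param earliest_skew_cutoff Lowered cutoff at the earliest timepoint
#'   (default 0.4).
#' @param earliest_max_score Max-score filter at the earliest timepoint
#'   (default 15).
#' @param earliest_timepoint Label of the earliest timepoint; if `NULL`, the
#'   first timepoint seen by [competency_report()] is used.
#' @return An object of class `competency_config`.
#' @export
competency_config <- function(skew_cutoff = 1, earliest_skew_cutoff = 0.4,
                              earliest_max_score = 15,
                              earliest_timepoint = NULL) {
  if (!all(is.finite(c(skew_cutoff, earliest_skew_cutoff, earliest_max_score))))
    stopf("cutoffs must be finite")
  if (earliest_skew_cutoff > skew_cutoff)
    stopf("earliest_skew_cutoff must not exceed skew_cutoff")
  structure(list(skew_cutoff = skew_cutoff,
                 earliest_skew_cutoff = earliest_skew_cutoff,
                 earliest_max_score = earliest_max_score,
                 earliest_timepoint = earliest_timepoint),
            class = "competency_config")
}

#' Classify one score distribution as diffuse or skewed
#'
#' @param scores Per-cell module scores at one timepoint.
#' @param timepoint Timepoint label of the scores.
#' @param cfg A [competency_config()].
#' @return `"skewed"` or `"diffuse"`, with attributes `skewness` and
#'   `max_score` (and `flag` when skewness is undefined).
#' @export
classify_competency <- function(scores, timepoint, cfg = competency_config()) {
  sk <- skewness_g1(scores[is.finite(scores)])
  mx <- max(scores[is.finite(scores)])
  if (is.na(sk))
    return(structure("diffuse", skewness = NA_real_, max_score = mx,
                     flag = "undefined skewness"))
  earliest <- !is.null(cfg$earliest_timepoint) &&
    identical(timepoint, cfg$earliest_timepoint)
  status <- if (earliest) {
    if (sk > cfg$earliest_skew_cutoff && mx > cfg$earliest_max_score)
      "skewed" else "diffuse"
  } else {
    if (sk > cfg$skew_cutoff) "skewed" else "diffuse"
  }
  structure(status, skewness = unclass(sk), max_score = mx)
}

#' Competency report over all tissues and timepoints
#'
#' @param score_list Named per-timepoint list of `module_scores` (from
#'   [score_all()]); annotation columns are tissues.
#' @param cfg A [competency_config()]; a `NULL` `earliest_timepoint`
#'   defaults to the first element of `score_list`.
#' @return data.frame of class `competency_report`: one row per
#'   (tissue, timepoint) with `skewness`, `max_score`, `status`.
#' @export
competency_report <- function(score_list, cfg = competency_config()) {
  if (is.null(cfg$earliest_timepoint))
    cfg$earliest_timepoint <- names(score_list)[1]
  rows <- list()
  for (tp in names(score_list)) {
    sc <- score_list[[tp]]$scores
    for (tissue in colnames(sc)) {
      st <- classify_competency(sc[, tissue], tp, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tissue, timepoint = tp,
        skewness = attr(st, "skewness"), max_score = attr(st, "max_score"),
        status = as.character(st), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "timepoints") <- names(score_list)
  class(out) <- c("competency_report", "data.frame")
  out
}

#' Establishment timepoint per tissue
#'
#' The earliest timepoint at which a tissue's score distribution is called
#' skewed; a later diffuse call does not veto an earlier skewed one.
#'
#' @param report A [competency_report()].
#' @return data.frame with `tissue`, `establishment` (timepoint label or
#'   `NA` for "not established") and `established` flag.
#' @export
establishment_table <- function(report) {
  tps <- attr(report, "timepoints")
  if (is.null(tps)) tps <- unique(report$timepoint)
  out <- lapply(split(report, report$tissue), function(df) {
    sk <- df$timepoint[df$status == "skewed"]
    est <- if (length(sk)) tps[min(match(sk, tps))] else NA_character_
    data.frame(tissue = df$tissue[1], establishment = est,
               established = length(sk) > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$tissue, unique(report$tissue))), , drop = FALSE]
}

#' Write a competency report to TSV
#' @param report A [competency_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_competency_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
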