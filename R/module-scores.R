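#' Expected per-cell counts for a peak set under the depth model
#'
#' Under the null that accessibility in a peak set is proportional to a
#' cell's sequencing depth, the expected count for cell i is
#' `E_i = T_i * (t_set / T)` with `T_i` the cell's total count, `t_set` the
#' set's total count over all cells, and `T` the grand total. The
#' expectations conserve the set's observed total: `sum_i E_i = t_set`.
#'
#' @param atlas A [cell_atlas()].
#' @param set Integer vector of peak indices.
#' @return Numeric vector of per-cell expectations.
#' @export
expected_counts <- function(atlas, set) {
  if (length(set) == 0L) stopf("peak set is empty")
  Ti <- Matrix::colSums(atlas$counts)
  Tg <- sum(Ti)
  if (Tg <= 0) stopf("matrix has zero total count")
  t_set <- sum(Matrix::colSums(atlas$counts[set, , drop = FALSE]))
  if (t_set <= 0) stopf("annotation has zero total count")
  Ti * (t_set / Tg)
}

#' Raw chromVAR-style deviation
#'
#' `Y = (X - E) / E`: the relative excess of observed over expected
#' accessibility. `Y >= -1`, with 0 iff `X = E`.
#'
#' @param observed Per-cell observed counts in the set.
#' @param expected Per-cell expectations (positive).
#' @return Numeric vector of raw deviations.
#' @export
raw_deviation <- function(observed, expected) {
  if (any(expected <= 0)) stopf("expected counts must be positive")
  (observed - expected) / expected
}

#' Sample covariate-matched background peak sets
#'
#' For each member of `set`, candidate background peaks are its
#' `k_candidates` nearest neighbours in the standardized (GC fraction, mean
#' accessibility) plane; each background set draws one candidate per member,
#' with replacement, giving `n_background` sets of the same cardinality as
#' `set`.
#'
#' @param peak_meta data.frame with columns `gc` and `mean_access` for every
#'   peak.
#' @param set Integer peak indices.
#' @param n_background Number of background sets (>= 2).
#' @param seed Integer seed (sampling is reproducible).
#' @param k_candidates Neighbourhood size per member.
#' @return Integer matrix, `n_background` rows x `length(set)` columns.
#' @export
sample_background_sets <- function(peak_meta, set, n_background, seed = 0L,
                                   k_candidates = 100L) {
  if (n_background < 2L) stopf("n_background must be >= 2")
  n_peaks <- nrow(peak_meta)
  if (n_peaks < length(set)) stopf("fewer candidate peaks than set size")
  if (anyNA(peak_meta$gc) || anyNA(peak_meta$mean_access))
    stopf("peak_meta must provide gc and mean_access for all peaks")
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  cov2 <- cbind(std(peak_meta$gc), std(peak_meta$mean_access))
  k <- min(k_candidates, n_peaks)
  # nearest candidates per set member in the standardized covariate plane
  cand <- vapply(set, function(j) {
    d2 <- (cov2[, 1] - cov2[j, 1])^2 + (cov2[, 2] - cov2[j, 2])^2
    order(d2)[seq_len(k)]
  }, integer(k))
  with_seed(seed, {
    m <- matrix(0L, n_background, length(set))
    for (b in seq_len(n_background))
      m[b, ] <- cand[cbind(sample.int(k, length(set), replace = TRUE),
                           seq_along(set))]
    m
  })
}

# per-cell raw deviations for many sets at once: rows of `sets_mat` are
# peak-index vectors; returns length(sets) x n_cells matrix of Y
multi_set_deviation <- function(counts, sets_mat, Ti, Tg) {
  n_sets <- nrow(sets_mat)
  ind <- Matrix::sparseMatrix(
    i = rep(seq_len(n_sets), ncol(sets_mat)),
    j = as.vector(sets_mat), x = 1,
    dims = c(n_sets, nrow(counts)))
  X <- as.matrix(ind %*% counts)                       # set totals per cell
  t_set <- rowSums(X)
  E <- (t_set / Tg) %o% Ti
  (X - E) / E
}

#' Bias-corrected deviation z-score for one peak set
#'
#' The foreground raw deviation is standardized against the raw deviations
#' of `n_background` covariate-matched background sets:
#' `z_i = (Y_i - mean_b Y_i^b) / sd_b(Y_i^b)`. Cells whose background
#' deviations are degenerate (zero spread) get `NA` and are flagged in the
#' `"undefined"` attribute rather than silently zeroed.
#'
#' @inheritParams sample_background_sets
#' @param atlas A [cell_atlas()].
#' @return Numeric per-cell z-score vector with attributes `raw` (foreground
#'   Y), `expected` (E) and `undefined` (logical flags).
#' @export
deviation_zscore <- function(atlas, set, n_background = 50L, seed = 0L,
                             k_candidates = 100L) {
  E <- expected_counts(atlas, set)
  Ti <- Matrix::colSums(atlas$counts)
  Tg <- sum(Ti)
  X <- Matrix::colSums(atlas$counts[set, , drop = FALSE])
  Y <- raw_deviation(X, E)
  bg <- sample_background_sets(atlas$peak_meta, set, n_background, seed,
                               k_candidates)
  Yb <- multi_set_deviation(atlas$counts, bg, Ti, Tg)
  mu <- colMeans(Yb)
  sdev <- apply(Yb, 2, sd)
  undef <- !(sdev > 0)
  if (all(undef)) stopf("background deviations degenerate for every cell")
  z <- rep(NA_real_, length(Y))
  z[!undef] <- (Y[!undef] - mu[!undef]) / sdev[!undef]
  names(z) <- colnames(atlas$counts)
  structure(z, raw = Y, expected = E, undefined = undef)
}

#' Score every annotation at every timepoint (retrograde application)
#'
#' Applies a late-stage peak-set collection to each timepoint's matrix,
#' producing one bias-corrected deviation z-score per (cell, annotation).
#' Input atlases are never mutated.
#'
#' @param atlases Named list of [cell_atlas()] objects (one per timepoint),
#'   all on the same peak universe.
#' @param peak_sets A [peak_set_collection()].
#' @param n_background,seed,k_candidates Passed to [deviation_zscore()].
#' @return Named list (per timepoint) of `module_scores` objects: list with
#'   `scores`, `raw_deviations`, `expectations` (cell x annotation
#'   matrices), `n_background`, `seed`.
#' @export
score_all <- function(atlases, peak_sets, n_background = 50L, seed = 0L,
                      k_candidates = 100L) {
  stopifnot(inherits(peak_sets, "peak_set_collection"))
  lapply(atlases, function(atlas) {
    n_peaks <- nrow(atlas$counts)
    bad <- vapply(peak_sets$sets, function(s) any(s < 1L | s > n_peaks),
                  logical(1))
    if (any(bad))
      stopf("annotation(s) %s reference peaks outside this timepoint's space",
            paste(names(peak_sets$sets)[bad], collapse = ", "))
    cols <- lapply(names(peak_sets$sets), function(nm)
      deviation_zscore(atlas, peak_sets$sets[[nm]], n_background, seed,
                       k_candidates))
    scores <- do.call(cbind, lapply(cols, as.vector))
    raw <- do.call(cbind, lapply(cols, attr, "raw"))
    expd <- do.call(cbind, lapply(cols, attr, "expected"))
    dn <- list(colnames(atlas$counts), names(peak_sets$sets))
    dimnames(scores) <- dimnames(raw) <- dimnames(expd) <- dn
    structure(list(scores = scores, raw_deviations = raw,
                   expectations = expd, n_background = n_background,
                   seed = seed, timepoint = atlas$timepoint),
              class = "module_scores")
  })
}

#' Cluster-enriched peak detection by likelihood-ratio test
#'
#' For each (cluster, peak), compares a logistic model of binarized
#' accessibility on {in-cluster indicator + log fragments-in-peaks} against
#' the depth-only null, with the LR statistic referred to chi-square(1).
#' P-values are Benjamini-Hochberg adjusted across peaks within each
#' cluster; a peak is selected for a cluster when its adjusted p-value is
#' below `alpha` and the in-cluster effect is positive. Degenerate fits are
#' flagged and excluded from selection.
#'
#' @param atlas A [cell_atlas()] whose `cell_meta$cluster` is populated.
#' @param alpha Adjusted p-value cutoff (default 0.001).
#' @param min_cells Minimum cells per cluster.
#' @return List with `table` (cluster, peak, log-fold difference of
#'   accessible fraction, lr statistic, p, adj_p, flag) and `selected`
#'   (named list of peak indices per cluster).
#' @export
enriched_peaks <- function(atlas, alpha = 0.001, min_cells = 3L) {
  cl <- atlas$cell_meta$cluster
  if (is.null(cl) || anyNA(cl)) stopf("cluster labels required")
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L) stopf("need >= 2 clusters")
  if (any(table(cl) < min_cells)) stopf("every cluster needs >= %d cells", min_cells)
  y_all <- methods::as(atlas$counts > 0, "CsparseMatrix")
  logfrag <- log(pmax(atlas$cell_meta$fragments, 1))
  n_peaks <- nrow(atlas$counts)

  # null fits (depth only) are cluster-independent: one per peak
  null_dev <- numeric(n_peaks)
  xnull <- cbind(1, logfrag)
  ymat <- as.matrix(y_all)
  for (j in seq_len(n_peaks)) {
    fit <- suppressWarnings(stats::glm.fit(xnull, ymat[j, ],
                                           family = stats::binomial()))
    null_dev[j] <- fit$deviance
  }
  rows <- vector("list", length(clusters))
  selected <- setNames(vector("list", length(clusters)), clusters)
  for (ci in seq_along(clusters)) {
    inc <- as.numeric(cl == clusters[ci])
    xfull <- cbind(1, inc, logfrag)
    lfd <- coef <- lr <- pv <- numeric(n_peaks)
    flag <- logical(n_peaks)
    for (j in seq_len(n_peaks)) {
      yj <- ymat[j, ]
      fit <- suppressWarnings(
        tryCatch(stats::glm.fit(xfull, yj, family = stats::binomial()),
                 error = function(e) NULL))
      # NA coefficients from pivoting on collinear covariates (e.g. constant
      # depth) are benign; only a missing in-cluster effect is degenerate
      if (is.null(fit) || !fit$converged || is.na(fit$coefficients[2])) {
        flag[j] <- TRUE
        lr[j] <- NA_real_; pv[j] <- NA_real_; coef[j] <- NA_real_
      } else {
        coef[j] <- fit$coefficients[2]
        lr[j] <- max(0, null_dev[j] - fit$deviance)
        pv[j] <- pchisq(lr[j], df = 1, lower.tail = FALSE)
      }
      p_in <- mean(yj[inc == 1]); p_out <- mean(yj[inc == 0])
      lfd[j] <- log((p_in + 1e-9) / (p_out + 1e-9))
    }
    adj <- p.adjust(pv, method = "BH")
    rows[[ci]] <- data.frame(cluster = clusters[ci], peak = seq_len(n_peaks),
                             log_fold = lfd, effect = coef, lr = lr, p = pv,
                             adj_p = adj, flagged = flag,
                             stringsAsFactors = FALSE)
    sel <- which(!flag & !is.na(adj) & adj < alpha & coef > 0)
    selected[[ci]] <- sel
  }
  list(table = do.call(rbind, rows), selected = selected)
}
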