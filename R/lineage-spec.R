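#' Specify a planted developmental lineage for atlas simulation
#'
#' A `lineage_spec` fixes everything the synthetic-atlas generator needs: the
#' terminal tissues, a rooted binary lineage tree over them, the timepoint at
#' which each tissue's specific peaks first gain accessibility
#' (its establishment timepoint), and the sampling model parameters.
#'
#' Counts are drawn as `Poisson(depth_i * p_j * f_jk)` where `depth_i` is a
#' lognormal per-cell depth, `p_j` a per-peak base accessibility probability,
#' and `f_jk` is `effect_size` for a tissue-specific peak in a cell of that
#' lineage at or after the tissue's establishment timepoint, `family_effect`
#' for cells of sibling tissues in the same lineage family (shared-progenitor
#' accessibility), and 1 otherwise.
#'
#' @param tissues Character vector of terminal tissue labels (>= 2).
#' @param timepoints Ordered character vector of timepoint labels (>= 2).
#' @param establishment_time Named integer vector, tissue -> timepoint index
#'   at which that tissue's peaks become accessible. Default cycles over the
#'   earlier timepoints (indices `1..max(1, T-2)`), so establishment precedes
#'   the terminal stages as in a real time course.
#' @param cells_per_timepoint Cells simulated at each timepoint.
#' @param peaks_per_tissue Number of tissue-specific peaks per tissue.
#' @param background_peaks Number of non-specific peaks.
#' @param effect_size Fold-increase (>= 1) of accessibility probability for
#'   in-lineage cells at/after establishment. 1 gives a null atlas.
#' @param family_effect Fold-increase for same-family (sibling) lineage
#'   cells; default `(1 + effect_size) / 2`.
#' @param n_families Number of lineage families (subtrees) the tissues are
#'   grouped into; default `min(5, floor(n_tissues / 2))`.
#' @param depth_lognormal `c(meanlog, sdlog)` of the per-cell depth.
#' @param n_decoy_pairs Number of decoy motif/TF pairs simulated alongside
#'   the planted priming pairs (one planted pair per tissue).
#' @param priming_effect Additive shift of a planted priming motif's
#'   deviation in in-lineage cells (post-establishment), in noise-SD units.
#' @param tf_transfer Slope linking a planted TF's gene activity to its
#'   paired motif deviation.
#' @param gc_confounded If TRUE, tissue-specific peaks get GC shifted +0.15,
#'   stress-testing background matching.
#' @param binarize If TRUE, counts are binarized to presence/absence.
#' @param seed Integer seed; all outputs are bit-identical for equal seeds.
#'
#' @return An object of class `lineage_spec`.
#' @export
lineage_spec <- function(tissues = paste0("tissue", 1:10),
                         timepoints = paste0("t", 1:5),
                         establishment_time = NULL,
                         cells_per_timepoint = 2000,
                         peaks_per_tissue = 50,
                         background_peaks = 1000,
                         effect_size = 3,
                         family_effect = NULL,
                         n_families = NULL,
                         depth_lognormal = c(log(5000), 0.5),
                         n_decoy_pairs = 200,
                         priming_effect = 2,
                         tf_transfer = 0.8,
                         gc_confounded = FALSE,
                         binarize = FALSE,
                         seed = 1L) {
  n_tissue <- length(tissues)
  n_tp <- length(timepoints)
  if (n_tissue < 2L) stopf("need at least 2 tissues, got %d", n_tissue)
  if (anyDuplicated(tissues)) stopf("tissue labels must be unique")
  if (n_tp < 2L) stopf("need at least 2 timepoints, got %d", n_tp)
  if (!is_count(cells_per_timepoint)) stopf("cells_per_timepoint must be a positive integer")
  if (!is_count(peaks_per_tissue)) stopf("peaks_per_tissue must be a positive integer")
  if (!is_count(background_peaks)) stopf("background_peaks must be a positive integer")
  if (!is.numeric(effect_size) || effect_size < 1)
    stopf("effect_size must be >= 1 (got %s)", format(effect_size))
  if (is.null(family_effect)) family_effect <- (1 + effect_size) / 2
  if (family_effect < 1 || family_effect > effect_size)
    stopf("family_effect must lie in [1, effect_size]")
  if (is.null(n_families)) n_families <- min(5L, max(1L, n_tissue %/% 2L))
  if (n_families > n_tissue) stopf("n_families exceeds tissue count")
  if (is.null(establishment_time)) {
    establishment_time <- setNames(
      rep_len(seq_len(max(1L, n_tp - 2L)), n_tissue), tissues)
  }
  if (!all(tissues %in% names(establishment_time)))
    stopf("establishment_time must name every tissue")
  establishment_time <- establishment_time[tissues]
  if (any(establishment_time < 1L | establishment_time > n_tp))
    stopf("establishment_time values must be timepoint indices in 1..%d", n_tp)
  if (length(depth_lognormal) != 2L || depth_lognormal[2] < 0)
    stopf("depth_lognormal must be c(meanlog, sdlog) with sdlog >= 0")

  fam <- split(tissues, sort(rep_len(seq_len(n_families), n_tissue)))
  families <- setNames(rep(seq_along(fam), lengths(fam)), unlist(fam))[tissues]
  tree <- ape::read.tree(text = paste0(balanced_newick(
    vapply(fam, function(f) balanced_newick(f), character(1))), ";"))

  structure(list(
    tissues = tissues, timepoints = timepoints, tree = tree,
    establishment_time = establishment_time, families = families,
    cells_per_timepoint = as.integer(cells_per_timepoint),
    peaks_per_tissue = as.integer(peaks_per_tissue),
    background_peaks = as.integer(background_peaks),
    effect_size = effect_size, family_effect = family_effect,
    depth_lognormal = as.numeric(depth_lognormal),
    n_decoy_pairs = as.integer(n_decoy_pairs),
    priming_effect = priming_effect, tf_transfer = tf_transfer,
    gc_confounded = isTRUE(gc_confounded), binarize = isTRUE(binarize),
    seed = as.integer(seed)
  ), class = "lineage_spec")
}

# newick for a balanced rooted binary tree over labels (no branch lengths)
balanced_newick <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(labels)
  k <- ceiling(n / 2)
  paste0("(", balanced_newick(labels[seq_len(k)]), ",",
         balanced_newick(labels[(k + 1):n]), ")")
}

#' @export
print.lineage_spec <- function(x, ...) {
  cat(sprintf(
    "<lineage_spec> %d tissues x %d timepoints, %d cells/timepoint\n",
    length(x$tissues), length(x$timepoints), x$cells_per_timepoint))
  cat(sprintf("  peaks: %d specific/tissue + %d background; effect %.2g (family %.2g)\n",
              x$peaks_per_tissue, x$background_peaks, x$effect_size, x$family_effect))
  cat(sprintf("  establishment: %s\n",
              paste(x$tissues, "@", x$timepoints[x$establishment_time], collapse = ", ")))
  invisible(x)
}
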