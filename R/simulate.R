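#' Simulate a multi-timepoint chromatin accessibility atlas with planted truth
#'
#' Generates, for each timepoint of the design, a peak-by-cell fragment count
#' matrix plus the annotations every downstream stage consumes: tissue peak
#' sets (module annotations), per-cell motif deviation and TF gene-activity
#' matrices with planted priming pairs, and the ground truth (lineage tree,
#' establishment timepoints, families, priming pairs, cell fate assignments).
#'
#' Each cell carries a terminal fate drawn balanced over tissues; a cell is
#' "in the lineage" of its fate tissue. Counts follow the sampling model
#' documented in [lineage_spec()]. Planted priming motifs are standard
#' Gaussian deviations shifted by `priming_effect` in in-lineage cells after
#' establishment; planted TF activities are `tf_transfer` times the paired
#' motif plus unit noise; decoy motifs and TFs are pure noise.
#'
#' @param spec A [lineage_spec()].
#' @return An object of class `synthetic_atlas`: list with `atlases` (named
#'   list of [cell_atlas()] per timepoint), `module_sets` (a
#'   `peak_set_collection` of tissue-specific peak indices), `motif_activity`
#'   and `tf_activity` (per-timepoint cell x feature matrices), `pairing`
#'   (curated motif/TF pairing table including decoys) and `truth`
#'   (`synthetic_truth`).
#' @export
simulate_atlas <- function(spec) {
  if (!inherits(spec, "lineage_spec")) stopf("spec must be a lineage_spec")
  with_seed(spec$seed, simulate_atlas_impl(spec))
}

simulate_atlas_impl <- function(spec) {
  n_tissue <- length(spec$tissues)
  n_tp <- length(spec$timepoints)
  ppt <- spec$peaks_per_tissue
  n_peaks <- n_tissue * ppt + spec$background_peaks
  n_cells <- spec$cells_per_timepoint

  # peak universe: tissue-specific blocks first, background after
  peak_id <- sprintf("peak_%05d", seq_len(n_peaks))
  chrom <- paste0("chr", 1L + (seq_len(n_peaks) - 1L) %% 4L)
  start <- 1000L * (seq_len(n_peaks) - 1L)
  peaks <- data.frame(chrom = chrom, start = start, end = start + 500L,
                      id = peak_id, stringsAsFactors = FALSE)
  module_sets <- setNames(lapply(seq_len(n_tissue), function(i)
    ((i - 1L) * ppt + 1L):(i * ppt)), spec$tissues)

  gc <- rbeta(n_peaks, 5, 5)
  if (spec$gc_confounded) {
    idx <- seq_len(n_tissue * ppt)
    gc[idx] <- pmin(0.99, gc[idx] + 0.15)
  }

  w <- rgamma(n_peaks, shape = 2, rate = 2)
  p_base <- w / sum(w)

  # planted priming features
  motif_ids <- c(paste0("motif_", spec$tissues),
                 sprintf("decoy_motif_%03d", seq_len(spec$n_decoy_pairs)))
  tf_ids <- c(paste0("tf_", spec$tissues),
              sprintf("decoy_tf_%03d", seq_len(spec$n_decoy_pairs)))
  pairing <- data.frame(motif_id = motif_ids, tf_id = tf_ids,
                        stringsAsFactors = FALSE)
  priming_pairs <- data.frame(motif_id = paste0("motif_", spec$tissues),
                              tf_id = paste0("tf_", spec$tissues),
                              tissue = spec$tissues, stringsAsFactors = FALSE)

  atlases <- vector("list", n_tp)
  motif_act <- vector("list", n_tp)
  tf_act <- vector("list", n_tp)
  assign_list <- vector("list", n_tp)

  for (t in seq_len(n_tp)) {
    tp <- spec$timepoints[t]
    barcodes <- sprintf("%s_cell%04d", tp, seq_len(n_cells))
    fate <- sample(rep_len(spec$tissues, n_cells))
    depth <- rlnorm(n_cells, spec$depth_lognormal[1], spec$depth_lognormal[2])

    fold <- matrix(1, n_peaks, n_cells)
    for (i in seq_len(n_tissue)) {
      if (spec$establishment_time[i] > t) next
      rows <- module_sets[[i]]
      own <- fate == spec$tissues[i]
      sib <- !own & spec$families[fate] == spec$families[i]
      if (any(own)) fold[rows, own] <- spec$effect_size
      if (any(sib)) fold[rows, sib] <- spec$family_effect
    }
    lambda <- (p_base * fold) * rep(depth, each = n_peaks)
    counts <- matrix(rpois(length(lambda), lambda), n_peaks, n_cells)
    if (spec$binarize) counts <- (counts > 0L) + 0L
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"), "dMatrix")
    dimnames(counts) <- list(peak_id, barcodes)

    frip <- rbeta(n_cells, 13, 7)
    atlases[[t]] <- cell_atlas(
      counts = counts, peaks = peaks, timepoint = tp,
      cell_meta = data.frame(barcode = barcodes,
                             fragments = Matrix::colSums(counts),
                             frip = frip, cluster = fate,
                             stringsAsFactors = FALSE),
      peak_meta = data.frame(id = peak_id, gc = gc,
                             mean_access = Matrix::rowMeans(counts),
                             stringsAsFactors = FALSE))

    mm <- matrix(rnorm(n_cells * length(motif_ids)), n_cells,
                 dimnames = list(barcodes, motif_ids))
    tt <- matrix(rnorm(n_cells * length(tf_ids)), n_cells,
                 dimnames = list(barcodes, tf_ids))
    for (i in seq_len(n_tissue)) {
      active <- fate == spec$tissues[i] & spec$establishment_time[i] <= t
      mm[active, i] <- mm[active, i] + spec$priming_effect
      tt[, i] <- spec$tf_transfer * mm[, i] + tt[, i]
    }
    motif_act[[t]] <- mm
    tf_act[[t]] <- tt
    assign_list[[t]] <- data.frame(timepoint = tp, barcode = barcodes,
                                   tissue = fate, stringsAsFactors = FALSE)
  }
  names(atlases) <- names(motif_act) <- names(tf_act) <- spec$timepoints

  truth <- structure(list(
    spec = spec,
    establishment = spec$establishment_time,
    families = spec$families,
    priming_pairs = priming_pairs,
    cell_assignments = do.call(rbind, assign_list)
  ), class = "synthetic_truth")

  structure(list(atlases = atlases,
                 module_sets = peak_set_collection(module_sets, kind = "module"),
                 motif_activity = motif_act, tf_activity = tf_act,
                 pairing = pairing, truth = truth),
            class = "synthetic_atlas")
}

#' Tabulate the planted ground truth
#'
#' One row per tissue with its establishment timepoint and family, followed
#' by one row per planted priming pair.
#'
#' @param truth A `synthetic_truth` (from [simulate_atlas()]).
#' @return A data.frame with columns `record` ("establishment" or
#'   "priming_pair"), `tissue`, `timepoint`, `family`, `motif_id`, `tf_id`.
#' @export
truth_report <- function(truth) {
  if (!inherits(truth, "synthetic_truth")) stopf("truth must be a synthetic_truth")
  spec <- truth$spec
  est <- data.frame(
    record = "establishment", tissue = spec$tissues,
    timepoint = spec$timepoints[truth$establishment],
    family = unname(truth$families[spec$tissues]),
    motif_id = NA_character_, tf_id = NA_character_,
    stringsAsFactors = FALSE)
  pp <- truth$priming_pairs
  if (nrow(pp) == 0L) return(est)
  pair <- data.frame(
    record = "priming_pair", tissue = pp$tissue,
    timepoint = NA_character_, family = NA_integer_,
    motif_id = pp$motif_id, tf_id = pp$tf_id, stringsAsFactors = FALSE)
  rbind(est, pair)
}

#' Write / read a truth report as TSV
#' @param truth A `synthetic_truth`.
#' @param path Output TSV path.
#' @return `path`, invisibly; `read_truth_report()` returns the data.frame.
#' @export
write_truth_report <- function(truth, path) {
  write.table(truth_report(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_report
#' @export
read_truth_report <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(timepoint = "character"))
}
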