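#' Container for one timepoint's peak-by-cell accessibility matrix
#'
#' Thin validated container holding a sparse non-negative count matrix with
#' its peak intervals (0-based half-open, BED convention), cell barcodes and
#' per-cell / per-peak metadata.
#'
#' @param counts Sparse (dgCMatrix) or dense non-negative matrix, peaks x cells.
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `id`.
#' @param timepoint Timepoint label.
#' @param cell_meta data.frame with columns `barcode`, `fragments`
#'   (fragments in peaks), `frip` (fraction of reads in peaks), and
#'   optionally `cluster`.
#' @param peak_meta data.frame with columns `id`, `gc`, `mean_access`.
#' @return An object of class `cell_atlas`.
#' @export
cell_atlas <- function(counts, peaks, timepoint, cell_meta, peak_meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (nrow(counts) != nrow(peaks))
    stopf("counts has %d rows but %d peaks given", nrow(counts), nrow(peaks))
  if (ncol(counts) != nrow(cell_meta))
    stopf("counts has %d columns but %d cell metadata rows", ncol(counts),
          nrow(cell_meta))
  if (ncol(counts) == 0L) stopf("no cells")
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  if (any(peaks$start >= peaks$end))
    stopf("peak intervals must satisfy start < end")
  if (any(cell_meta$frip < 0 | cell_meta$frip > 1))
    stopf("frip must lie in [0, 1]")
  if (is.null(peak_meta))
    peak_meta <- data.frame(id = peaks$id, gc = NA_real_,
                            mean_access = Matrix::rowMeans(counts),
                            stringsAsFactors = FALSE)
  structure(list(counts = counts, peaks = peaks, timepoint = timepoint,
                 cell_meta = cell_meta, peak_meta = peak_meta),
            class = "cell_atlas")
}

#' @export
print.cell_atlas <- function(x, ...) {
  cat(sprintf("<cell_atlas> %s: %d peaks x %d cells (%.1f%% nonzero)\n",
              x$timepoint, nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' Named collection of peak sets (modules or motif annotations)
#'
#' @param sets Named list of integer peak-index vectors.
#' @param kind `"module"` or `"motif"`.
#' @param n_peaks Optional peak-universe size for range validation.
#' @return An object of class `peak_set_collection`.
#' @export
peak_set_collection <- function(sets, kind = c("module", "motif"),
                                n_peaks = NULL) {
  kind <- match.arg(kind)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stopf("peak sets must be named")
  if (any(lengths(sets) == 0L)) stopf("peak sets must be non-empty")
  sets <- lapply(sets, as.integer)
  if (!is.null(n_peaks) && any(unlist(sets) < 1L | unlist(sets) > n_peaks))
    stopf("peak indices out of range 1..%d", n_peaks)
  structure(list(sets = sets, kind = kind), class = "peak_set_collection")
}

#' Write / read a timepoint atlas as a 10x-style triplet
#'
#' `write_atlas()` writes `matrix.mtx` (MatrixMarket coordinate, 1-based on
#' disk), `peaks.bed` (BED3+, 0-based half-open), `barcodes.tsv`, and the two
#' metadata sidecars `cell_meta.tsv` / `peak_meta.tsv` into `dir`.
#' `read_atlas()` reads them back and validates mutual consistency.
#'
#' @param atlas A [cell_atlas()].
#' @param dir Directory for the triplet.
#' @param timepoint Timepoint label for the loaded atlas.
#' @return `write_atlas()` returns `dir` invisibly; `read_atlas()` a
#'   `cell_atlas`.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(atlas$counts, file.path(dir, "matrix.mtx"))
  write.table(atlas$peaks[, c("chrom", "start", "end", "id")],
              file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(atlas$cell_meta$barcode, file.path(dir, "barcodes.tsv"))
  write.table(atlas$cell_meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(atlas$peak_meta, file.path(dir, "peak_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir, timepoint = basename(dir)) {
  mtx <- file.path(dir, "matrix.mtx")
  bed <- file.path(dir, "peaks.bed")
  bc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, bed, bc)) if (!file.exists(f)) stopf("missing file: %s", f)
  counts <- tryCatch(Matrix::readMM(mtx),
                     error = function(e) stopf("malformed MatrixMarket file %s: %s",
                                               mtx, conditionMessage(e)))
  peaks <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(peaks) < 3L) stopf("%s is not BED3+", bed)
  names(peaks)[1:3] <- c("chrom", "start", "end")
  peaks$id <- if (ncol(peaks) >= 4L) peaks[[4]] else
    sprintf("peak_%05d", seq_len(nrow(peaks)))
  peaks <- peaks[, c("chrom", "start", "end", "id")]
  if (any(peaks$start >= peaks$end))
    stopf("%s contains an interval with start >= end", bed)
  barcodes <- readLines(bc)
  if (ncol(counts) == 0L) stopf("no cells in %s", mtx)
  if (length(barcodes) != ncol(counts))
    stopf("%s has %d barcodes but matrix has %d columns", bc,
          length(barcodes), ncol(counts))
  if (nrow(peaks) != nrow(counts))
    stopf("%s has %d peaks but matrix has %d rows", bed, nrow(peaks),
          nrow(counts))
  dimnames(counts) <- list(peaks$id, barcodes)
  cm_path <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(cm_path))
    read.table(cm_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else data.frame(barcode = barcodes, fragments = Matrix::colSums(counts),
                  frip = NA_real_, stringsAsFactors = FALSE)
  pm_path <- file.path(dir, "peak_meta.tsv")
  peak_meta <- if (file.exists(pm_path))
    read.table(pm_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else NULL
  cell_atlas(counts, peaks, timepoint, cell_meta, peak_meta)
}

#' Write a whole simulated atlas to disk
#'
#' One triplet directory per timepoint plus the pairing table, truth report
#' and motif/TF activity matrices as TSV.
#'
#' @param sim A `synthetic_atlas` from [simulate_atlas()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_atlas <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(sim$atlases))
    write_atlas(sim$atlases[[tp]], file.path(dir, tp))
  write_peak_sets(sim$module_sets, file.path(dir, "module_sets.tsv"),
                  peak_ids = sim$atlases[[1]]$peaks$id)
  write.table(sim$pairing, file.path(dir, "pairing.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_truth_report(sim$truth, file.path(dir, "truth.tsv"))
  for (tp in names(sim$motif_activity)) {
    write.table(sim$motif_activity[[tp]],
                file.path(dir, paste0(tp, "_motif_activity.tsv")),
                sep = "\t", quote = FALSE)
    write.table(sim$tf_activity[[tp]],
                file.path(dir, paste0(tp, "_tf_activity.tsv")),
                sep = "\t", quote = FALSE)
  }
  invisible(dir)
}

#' Write / read peak-set annotations as two-column TSV (set id, peak id)
#' @param sets A [peak_set_collection()].
#' @param path TSV path.
#' @param peak_ids Character vector mapping peak indices to ids.
#' @param kind Annotation kind for the loaded collection.
#' @return `path` invisibly; `read_peak_sets()` a `peak_set_collection`.
#' @export
write_peak_sets <- function(sets, path, peak_ids) {
  df <- data.frame(
    set = rep(names(sets$sets), lengths(sets$sets)),
    peak = peak_ids[unlist(sets$sets)], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_sets
#' @export
read_peak_sets <- function(path, peak_ids, kind = "module") {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  idx <- match(df$peak, peak_ids)
  if (anyNA(idx)) stopf("%s references unknown peak ids", path)
  peak_set_collection(split(idx, df$set), kind = kind,
                      n_peaks = length(peak_ids))
}

#' Filter cells on quality thresholds
#'
#' Retains exactly the cells with fraction-of-reads-in-peaks strictly above
#' `frip_min` and fragments-in-peaks inside the inclusive range `frag_range`.
#' Retained columns are selected, never altered.
#'
#' @param atlas A [cell_atlas()].
#' @param frip_min FRIP threshold (strict `>`), as a fraction.
#' @param frag_range `c(lo, hi)` inclusive fragments-in-peaks window.
#' @return The filtered `cell_atlas`; attribute `"qc"` records cells removed
#'   by each rule.
#' @export
qc_filter_cells <- function(atlas, frip_min, frag_range) {
  if (!is.finite(frip_min)) stopf("frip_min must be finite")
  if (length(frag_range) != 2L || frag_range[1] >= frag_range[2])
    stopf("frag_range must be c(lo, hi) with lo < hi")
  frip <- atlas$cell_meta$frip
  frag <- atlas$cell_meta$fragments
  keep_frip <- frip > frip_min
  keep_frag <- frag >= frag_range[1] & frag <= frag_range[2]
  keep <- keep_frip & keep_frag
  if (!any(keep))
    stopf(paste0("all %d cells removed by QC (frip range %.3f-%.3f, ",
                 "fragment range %d-%d observed)"),
          length(keep), min(frip), max(frip), min(frag), max(frag))
  out <- atlas
  out$counts <- atlas$counts[, keep, drop = FALSE]
  out$cell_meta <- atlas$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  attr(out, "qc") <- list(n_input = length(keep), n_kept = sum(keep),
                          removed_frip = sum(!keep_frip),
                          removed_frag = sum(!keep_frag))
  out
}

#' Per-timepoint QC threshold presets
#'
#' Returns the stage-resolved thresholds used for the zebrafish cranial
#' neural crest snATAC atlas: FRIP > 0.50 at most stages (0.30 at 60 dpf,
#' 0.45 at 210 dpf) and fragments-in-peaks in 5000-30000 at 5 dpf,
#' 1000-11000 at 14 dpf, 1000-20000 otherwise.
#'
#' @param preset Preset name; currently `"zebrafish_cncc"`.
#' @return data.frame with columns `stage`, `frip_min`, `frag_lo`, `frag_hi`.
#' @export
qc_presets <- function(preset = "zebrafish_cncc") {
  if (preset != "zebrafish_cncc") stopf("unknown preset '%s'", preset)
  data.frame(
    stage = c("1.5dpf", "2dpf", "3dpf", "5dpf", "14dpf", "60dpf", "210dpf"),
    frip_min = c(0.50, 0.50, 0.50, 0.50, 0.50, 0.30, 0.45),
    frag_lo = c(1000, 1000, 1000, 5000, 1000, 1000, 1000),
    frag_hi = c(20000, 20000, 20000, 30000, 11000, 20000, 20000),
    stringsAsFactors = FALSE)
}

#' Merge peak files into a union peak profile
#'
#' Reads each BED3+ file, pools the intervals per chromosome, and merges
#' overlapping or bookended (half-open touching) intervals into the minimal
#' disjoint set covering the union.
#'
#' @param bed_files Character vector of BED3+ paths, or a list of
#'   data.frames with columns `chrom`, `start`, `end`.
#' @return data.frame (`chrom`, `start`, `end`) of disjoint intervals,
#'   0-based half-open, sorted by chromosome then start.
#' @export
merge_peak_files <- function(bed_files) {
  dfs <- lapply(bed_files, function(f) {
    if (is.character(f)) {
      df <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
      if (ncol(df) < 3L) stopf("%s is not BED3+", f)
      df <- df[, 1:3]
    } else df <- as.data.frame(f)[, 1:3]
    names(df) <- c("chrom", "start", "end")
    df
  })
  styles <- vapply(dfs, function(d) any(grepl("^chr", d$chrom)), logical(1))
  if (length(unique(styles[vapply(dfs, nrow, 1L) > 0])) > 1L)
    warnf("inconsistent chromosome naming across inputs ('chr' prefix mixed); names treated as distinct")
  all <- do.call(rbind, dfs)
  if (any(all$start >= all$end)) stopf("interval with start >= end")
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  gr <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
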