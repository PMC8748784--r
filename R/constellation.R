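#' Tissue score dendrogram at one timepoint
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of the tissues' per-cell score vectors.
#'
#' @param scores Cell x tissue score matrix, or a `module_scores` object.
#' @param timepoint Timepoint label (taken from the `module_scores` if
#'   present).
#' @param method Linkage passed to [stats::hclust()].
#' @return Object of class `tissue_dendrogram`: list with `timepoint`,
#'   `hclust`, `phylo` (ape tree) and `labels`.
#' @export
build_dendrogram <- function(scores, timepoint = NULL, method = "average") {
  if (inherits(scores, "module_scores")) {
    if (is.null(timepoint)) timepoint <- scores$timepoint
    scores <- scores$scores
  }
  if (ncol(scores) < 2L) stopf("need >= 2 tissues to build a dendrogram")
  hc <- hclust(dist(t(scores)), method = method)
  structure(list(timepoint = timepoint, hclust = hc,
                 phylo = ape::as.phylo(hc), labels = colnames(scores),
                 method = method),
            class = "tissue_dendrogram")
}

#' @export
print.tissue_dendrogram <- function(x, ...) {
  cat(sprintf("<tissue_dendrogram> %s: %d tissues (%s linkage)\n",
              x$timepoint %||% "?", length(x$labels), x$method))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a dendrogram as Newick
#' @param dend A `tissue_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(dend$phylo, file = path)
  invisible(path)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "tissue_dendrogram")) return(tree$phylo)
  if (inherits(tree, "phylo")) return(tree)
  if (inherits(tree, "hclust")) return(ape::as.phylo(tree))
  stopf("cannot interpret object of class '%s' as a tree", class(tree)[1])
}

# non-trivial unrooted bipartitions of a tree, canonicalized as the side
# not containing the alphabetically first leaf; returned as key strings
tree_splits <- function(tree) {
  phy <- as_phylo_tree(tree)
  labs <- phy$tip.label
  n <- length(labs)
  ref <- min(labs)
  po <- ape::reorder.phylo(phy, "postorder")
  desc <- vector("list", max(po$edge))
  for (tip in seq_len(n)) desc[[tip]] <- labs[tip]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  internal <- setdiff(seq_along(desc), seq_len(n))
  keys <- character(0)
  for (nd in internal) {
    s <- desc[[nd]]
    side <- if (ref %in% s) setdiff(labs, s) else s
    if (length(side) >= 2L && length(side) <= n - 2L)
      keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two tissue dendrograms
#'
#' Count of non-trivial bipartitions induced by internal edges that are
#' present in exactly one of the two trees (topology only; merge heights
#' ignored). Both trees must carry identical leaf sets.
#'
#' @param t1,t2 `tissue_dendrogram`, `phylo` or `hclust` objects.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  p1 <- as_phylo_tree(t1); p2 <- as_phylo_tree(t2)
  if (!setequal(p1$tip.label, p2$tip.label))
    stopf("leaf sets differ: {%s} vs {%s}",
          paste(sort(p1$tip.label), collapse = ","),
          paste(sort(p2$tip.label), collapse = ","))
  s1 <- tree_splits(p1); s2 <- tree_splits(p2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Combined (tissue, timepoint) constellation distance
#'
#' For nodes `(A, t1)` and `(B, t2)`:
#' `D = D_tissue + a * D_timepoint`, where
#' `D_tissue = (d_(A,B),t1 + d_(A,B),t2) / 2` averages the Euclidean
#' distances between the two tissues' per-cell score vectors at each
#' timepoint, and `D_timepoint` is the Robinson-Foulds distance between the
#' two timepoints' tissue score dendrograms (0 when `t1 == t2`). The weight
#' `a` (default 12) puts the timepoint term on the scale of the tissue term.
#'
#' @param score_list Named per-timepoint list of `module_scores` or plain
#'   cell x tissue matrices; every tissue must be scored at every timepoint.
#' @param dendrograms Optional named list of [build_dendrogram()] results;
#'   built from `score_list` when `NULL`.
#' @param a Non-negative timepoint weight.
#' @param normalize If TRUE, per-timepoint tissue distances are divided by
#'   `sqrt(n_cells)` (root-mean-square scale), making timepoints with
#'   different cell counts comparable.
#' @param linkage Linkage for internally built dendrograms.
#' @return Object of class `constellation_dist`: list with `nodes`
#'   (data.frame tissue/timepoint), `D`, `D_tissue`, `D_timepoint`
#'   (symmetric matrices) and `a`.
#' @export
build_distance <- function(score_list, dendrograms = NULL, a = 12,
                           normalize = FALSE, linkage = "average") {
  if (a < 0) stopf("a must be >= 0")
  tps <- names(score_list)
  mats <- lapply(score_list, function(s)
    if (inherits(s, "module_scores")) s$scores else as.matrix(s))
  tissues <- colnames(mats[[1]])
  for (tp in tps)
    if (!identical(colnames(mats[[tp]]), tissues))
      stopf("timepoint %s is missing score columns", tp)
  if (is.null(dendrograms))
    dendrograms <- lapply(tps, function(tp)
      build_dendrogram(mats[[tp]], tp, method = linkage))
  names(dendrograms) <- tps

  dtis <- lapply(mats, function(m) {
    d <- as.matrix(dist(t(m)))
    if (normalize) d <- d / sqrt(nrow(m))
    d
  })
  n_tp <- length(tps)
  rf <- matrix(0, n_tp, n_tp, dimnames = list(tps, tps))
  if (n_tp > 1L)
    for (i in seq_len(n_tp - 1L)) for (j in (i + 1L):n_tp)
      rf[i, j] <- rf[j, i] <- rf_distance(dendrograms[[i]], dendrograms[[j]])

  nodes <- expand.grid(tissue = tissues, timepoint = tps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  node_id <- paste(nodes$tissue, nodes$timepoint, sep = "@")
  n <- nrow(nodes)
  Dt <- Dp <- matrix(0, n, n, dimnames = list(node_id, node_id))
  ti <- match(nodes$tissue, tissues)
  pi <- match(nodes$timepoint, tps)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    Dt[i, j] <- (dtis[[pi[i]]][ti[i], ti[j]] + dtis[[pi[j]]][ti[i], ti[j]]) / 2
    Dp[i, j] <- rf[pi[i], pi[j]]
  }
  structure(list(nodes = cbind(nodes, node = node_id), D = Dt + a * Dp,
                 D_tissue = Dt, D_timepoint = Dp, a = a,
                 dendrograms = dendrograms),
            class = "constellation_dist")
}

#' Embed constellation nodes in two dimensions
#'
#' Places the (tissue, timepoint) nodes in the plane by classical
#' multidimensional scaling of the precomputed combined distance matrix;
#' the embedding is deterministic (the `seed` argument is accepted for
#' interface stability and recorded).
#'
#' @param cd A [build_distance()] result.
#' @param seed Recorded seed.
#' @param statuses Optional [competency_report()] to attach per-node status.
#' @return data.frame of class `constellation_map`: `node`, `tissue`,
#'   `timepoint`, `x`, `y`, `status`.
#' @export
embed_constellation <- function(cd, seed = 0L, statuses = NULL) {
  D <- cd$D
  if (any(!is.finite(D))) stopf("distance matrix contains non-finite values")
  if (any(abs(D - t(D)) > 1e-8)) stopf("distance matrix must be symmetric")
  n <- nrow(D)
  xy <- if (n == 1L) matrix(0, 1, 2) else {
    co <- cmdscale(D, k = min(2L, n - 1L))
    if (ncol(co) < 2L) cbind(co, 0) else co
  }
  out <- data.frame(node = cd$nodes$node, tissue = cd$nodes$tissue,
                    timepoint = cd$nodes$timepoint, x = xy[, 1], y = xy[, 2],
                    status = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(statuses)) {
    key <- paste(statuses$tissue, statuses$timepoint, sep = "@")
    out$status <- statuses$status[match(out$node, key)]
  }
  attr(out, "seed") <- seed
  class(out) <- c("constellation_map", "data.frame")
  out
}

#' Group constellation nodes by hierarchical cut of the combined distance
#'
#' @param cd A [build_distance()] result.
#' @param k Number of groups.
#' @param nodes Optional character vector of node ids to restrict the
#'   grouping to (e.g. competency-established nodes only).
#' @param linkage Linkage method.
#' @return Named integer vector of group labels.
#' @export
group_nodes <- function(cd, k, nodes = NULL, linkage = "average") {
  D <- cd$D
  if (!is.null(nodes)) {
    miss <- setdiff(nodes, rownames(D))
    if (length(miss)) stopf("unknown nodes: %s", paste(miss, collapse = ", "))
    D <- D[nodes, nodes, drop = FALSE]
  }
  if (k > nrow(D)) stopf("k = %d exceeds node count %d", k, nrow(D))
  if (nrow(D) == 1L) return(setNames(1L, rownames(D)))
  cutree(hclust(as.dist(D), method = linkage), k = k)
}

#' Write constellation outputs as TSV
#' @param cd A `constellation_dist`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_constellation <- function(cd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("D", "D_tissue", "D_timepoint"))
    write.table(cd[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE)
  for (tp in names(cd$dendrograms))
    write_dendrogram_newick(cd$dendrograms[[tp]],
                            file.path(dir, paste0("dendrogram_", tp, ".nwk")))
  invisible(dir)
}
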