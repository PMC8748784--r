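#' TF-IDF weighting of an accessibility matrix
#'
#' `log(1 + TF * IDF * scale)` with term frequency `TF = count / cell
#' total`, inverse document frequency `IDF = n_cells / n_cells containing
#' the peak`, and `scale = 1e4`. Computed per timepoint (the IDF uses only
#' that timepoint's cells). Peaks present in no cell have undefined IDF and
#' are dropped with a warning.
#'
#' @param atlas A [cell_atlas()] or a peak x cell sparse matrix.
#' @param scale Scale factor inside the log (default 1e4).
#' @param binarize If TRUE, counts are binarized before weighting, making
#'   the result invariant to per-cell depth rescaling.
#' @return Cell x peak sparse weighted matrix (note the transpose: cells as
#'   rows, ready for [lsi()]); attribute `kept_peaks` gives the retained
#'   peak indices.
#' @export
tfidf <- function(atlas, scale = 1e4, binarize = FALSE) {
  m <- if (inherits(atlas, "cell_atlas")) atlas$counts else
    methods::as(atlas, "CsparseMatrix")
  if (binarize) m <- methods::as(m > 0, "dMatrix") * 1
  cell_tot <- Matrix::colSums(m)
  if (any(cell_tot == 0)) stopf("matrix contains empty cells")
  occ <- Matrix::rowSums(m > 0)
  kept <- which(occ > 0)
  if (length(kept) < nrow(m)) {
    warnf("dropping %d peak(s) present in no cell (undefined IDF)",
          nrow(m) - length(kept))
    m <- m[kept, , drop = FALSE]
    occ <- occ[kept]
  }
  n_cells <- ncol(m)
  tf <- m %*% Matrix::Diagonal(x = 1 / cell_tot)          # peak x cell TF
  w <- Matrix::Diagonal(x = n_cells / occ) %*% tf         # IDF * TF
  w@x <- log1p(w@x * scale)
  out <- Matrix::t(w)                                     # cell x peak
  dimnames(out) <- list(colnames(m), rownames(m))
  structure(out, kept_peaks = kept)
}

#' Truncated SVD factorization for latent semantic indexing
#'
#' Factorizes the cell x peak weighted matrix `M = U S Vt` keeping the top
#' `rank` components. Downstream analyses use `component_range` (default
#' 2..rank: the first component, dominated by depth, is dropped).
#'
#' @param weighted Cell x peak matrix (from [tfidf()]).
#' @param rank Number of components (default 30; reduced with a warning if
#'   it exceeds `min(dim)`).
#' @param component_range Components used downstream.
#' @return Object of class `lsi_factorization`: `U` (cell x rank), `S`
#'   (descending singular values), `Vt` (rank x peak), `rank`,
#'   `component_range`.
#' @export
lsi <- function(weighted, rank = 30L, component_range = NULL) {
  x <- as.matrix(weighted)
  maxr <- min(dim(x))
  if (rank > maxr) {
    warnf("rank %d exceeds min(dim) = %d; reduced", rank, maxr)
    rank <- maxr
  }
  sv <- svd(x, nu = rank, nv = rank)
  if (is.null(component_range)) component_range <- c(min(2L, rank), rank)
  structure(list(U = sv$u, S = sv$d[seq_len(rank)], Vt = t(sv$v),
                 rank = rank, component_range = as.integer(component_range),
                 cells = rownames(x)),
            class = "lsi_factorization")
}

#' Project an earlier timepoint into a later timepoint's LSI basis
#'
#' Solves `M_{t-1} = U^p S_t Vt_t` for the projected left factor in the
#' least-squares sense: `U^p = M_{t-1} V_t S_t^{-1}`. Projecting the matrix
#' that produced the factorization returns its own `U`.
#'
#' @param weighted_prev Cell x peak weighted matrix at timepoint t-1, on
#'   the same peak space as the factorized matrix.
#' @param fact An [lsi()] factorization at timepoint t.
#' @return Projected cell x rank left factor.
#' @export
project_lsi <- function(weighted_prev, fact) {
  if (ncol(weighted_prev) != ncol(fact$Vt))
    stopf("peak spaces differ: %d vs %d", ncol(weighted_prev), ncol(fact$Vt))
  zero <- which(fact$S <= 0)
  if (length(zero))
    stopf("zero singular value at component %d", zero[1])
  up <- as.matrix(weighted_prev %*% t(fact$Vt))
  sweep(up, 2, fact$S, "/")
}

# rows scaled to unit length (zero rows untouched)
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# k nearest rows of `ref` for each row of `query` (Euclidean); returns
# list(idx = query x k indices into ref, dist = matching distances)
knn_rows <- function(query, ref, k) {
  k <- min(k, nrow(ref))
  qn <- rowSums(query^2)
  rn <- rowSums(ref^2)
  idx <- matrix(0L, nrow(query), k)
  dd <- matrix(0, nrow(query), k)
  block <- max(1L, floor(2e7 / nrow(ref)))
  for (s in seq(1L, nrow(query), by = block)) {
    e <- min(s + block - 1L, nrow(query))
    d2 <- outer(qn[s:e], rn, "+") - 2 * tcrossprod(query[s:e, , drop = FALSE], ref)
    d2[d2 < 0] <- 0
    for (r in seq_len(e - s + 1L)) {
      o <- order(d2[r, ])[seq_len(k)]
      idx[s + r - 1L, ] <- o
      dd[s + r - 1L, ] <- sqrt(d2[r, o])
    }
  }
  list(idx = idx, dist = dd)
}

#' Cross-timepoint link edges in combined projected LSI space
#'
#' Concatenates the timepoint-t left factor and the projected t-1 factor
#' (restricted to the downstream component range), scales every row to unit
#' length, and links each cell of t to its `k_link` nearest t-1 cells by
#' Euclidean distance in that space.
#'
#' @param fact_t An [lsi()] factorization at timepoint t.
#' @param u_prev Projected left factor of timepoint t-1 (from
#'   [project_lsi()] with `fact_t`).
#' @param k_link Number of cross links per cell of t.
#' @return data.frame `from` (cell index at t), `to` (cell index at t-1),
#'   `dist`, `weight` (`1 / (1 + dist)`).
#' @export
link_timepoints <- function(fact_t, u_prev, k_link = 10L) {
  cr <- fact_t$component_range
  comps <- cr[1]:cr[2]
  ut <- fact_t$U[, comps, drop = FALSE]
  up <- u_prev[, comps, drop = FALSE]
  if (k_link > nrow(up)) {
    warnf("k_link %d exceeds %d cells at t-1; clipped", k_link, nrow(up))
    k_link <- nrow(up)
  }
  comb <- l2_normalize_rows(rbind(ut, up))
  ut_n <- comb[seq_len(nrow(ut)), , drop = FALSE]
  up_n <- comb[nrow(ut) + seq_len(nrow(up)), , drop = FALSE]
  nn <- knn_rows(ut_n, up_n, k_link)
  data.frame(from = rep(seq_len(nrow(ut)), each = ncol(nn$idx)),
             to = as.vector(t(nn$idx)), dist = as.vector(t(nn$dist)),
             weight = 1 / (1 + as.vector(t(nn$dist))))
}

#' Build the temporal cell graph across all timepoints
#'
#' Intra-timepoint k-nearest-neighbour edges in each timepoint's own LSI
#' space (component range 2..rank) plus cross-timepoint edges from
#' [link_timepoints()] for every adjacent pair, collected into an igraph
#' object.
#'
#' @param atlases Named per-timepoint list of [cell_atlas()] objects on a
#'   shared peak space.
#' @param rank LSI rank (default 30).
#' @param k_intra Intra-timepoint neighbours (default 20).
#' @param k_link Cross-timepoint links per cell (default 10).
#' @param binarize Passed to [tfidf()].
#' @return Object of class `temporal_graph`: list with `graph` (igraph),
#'   `nodes` (data.frame timepoint/barcode), `edges` (data.frame with
#'   `type` intra/cross), `k_intra`, `k_link`.
#' @export
build_temporal_graph <- function(atlases, rank = 30L, k_intra = 20L,
                                 k_link = 10L, binarize = FALSE) {
  tps <- names(atlases)
  if (length(tps) < 2L)
    warnf("single timepoint: graph will contain intra edges only")
  peaks0 <- atlases[[1]]$peaks$id
  for (a in atlases)
    if (!identical(a$peaks$id, peaks0))
      stopf("atlases must share one union peak space")
  weighted <- lapply(atlases, tfidf, binarize = binarize)
  # peaks dropped in any timepoint are dropped everywhere (shared V basis)
  kept <- Reduce(intersect, lapply(weighted, attr, "kept_peaks"))
  weighted <- lapply(weighted, function(w)
    w[, match(peaks0[kept], colnames(w)), drop = FALSE])
  facts <- lapply(weighted, lsi, rank = rank)

  offsets <- c(0L, cumsum(vapply(atlases, function(a) ncol(a$counts), 1L)))
  nodes <- do.call(rbind, lapply(seq_along(tps), function(i)
    data.frame(timepoint = tps[i], barcode = colnames(atlases[[i]]$counts),
               stringsAsFactors = FALSE)))
  edge_list <- list()
  for (i in seq_along(tps)) {
    f <- facts[[i]]
    comps <- f$component_range[1]:f$component_range[2]
    u <- f$U[, comps, drop = FALSE]
    nn <- knn_rows(u, u, min(k_intra + 1L, nrow(u)))
    # drop the self column
    from <- rep(seq_len(nrow(u)), each = ncol(nn$idx))
    to <- as.vector(t(nn$idx)); d <- as.vector(t(nn$dist))
    keep <- from != to
    ord <- stats::ave(seq_along(from[keep]), from[keep],
                      FUN = seq_along) <= k_intra
    from <- from[keep][ord]; to <- to[keep][ord]; d <- d[keep][ord]
    edge_list[[length(edge_list) + 1L]] <- data.frame(
      source = offsets[i] + from, target = offsets[i] + to,
      weight = 1 / (1 + d), type = "intra", stringsAsFactors = FALSE)
  }
  if (length(tps) > 1L) for (i in 2:length(tps)) {
    up <- project_lsi(weighted[[i - 1]], facts[[i]])
    links <- link_timepoints(facts[[i]], up, k_link)
    edge_list[[length(edge_list) + 1L]] <- data.frame(
      source = offsets[i] + links$from, target = offsets[i - 1] + links$to,
      weight = links$weight, type = "cross", stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edge_list)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nodes)),
                          timepoint = nodes$timepoint,
                          barcode = nodes$barcode))
  structure(list(graph = g, nodes = nodes, edges = edges,
                 k_intra = k_intra, k_link = k_link, rank = rank),
            class = "temporal_graph")
}

#' Export / import a temporal graph
#'
#' Writes the edge list as CSV (`source`, `target`, `weight`, `type`), the
#' node table as TSV, and the graph as GraphML for external force-directed
#' layout. The CSV/TSV pair round-trips exactly via
#' [read_temporal_graph()].
#'
#' @param tg A [build_temporal_graph()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_temporal_graph <- function(tg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(tg$edges, file.path(dir, "edges.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(tg$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(tg$graph, file.path(dir, "graph.graphml"),
                      format = "graphml")
  invisible(dir)
}

#' @rdname write_temporal_graph
#' @export
read_temporal_graph <- function(dir) {
  edges <- read.table(file.path(dir, "edges.csv"), sep = ",", header = TRUE,
                      stringsAsFactors = FALSE)
  nodes <- read.table(file.path(dir, "nodes.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nodes)),
                          timepoint = nodes$timepoint,
                          barcode = nodes$barcode))
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "temporal_graph")
}
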