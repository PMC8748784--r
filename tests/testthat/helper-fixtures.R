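# shared fixtures and small oracles used across test files

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# hand-built atlas from a dense count matrix (equal-weight metadata unless given)
toy_atlas <- function(counts, frip = NULL, fragments = NULL, cluster = NULL,
                      gc = NULL, timepoint = "t1") {
  counts <- as.matrix(counts)
  n_peaks <- nrow(counts); n_cells <- ncol(counts)
  if (is.null(frip)) frip <- rep(0.8, n_cells)
  if (is.null(fragments)) fragments <- colSums(counts)
  if (is.null(gc)) gc <- seq(0.3, 0.7, length.out = n_peaks)
  peaks <- data.frame(chrom = "chr1", start = 1000L * seq_len(n_peaks),
                      end = 1000L * seq_len(n_peaks) + 500L,
                      id = sprintf("p%03d", seq_len(n_peaks)))
  cm <- data.frame(barcode = sprintf("c%03d", seq_len(n_cells)),
                   fragments = fragments, frip = frip)
  if (!is.null(cluster)) cm$cluster <- cluster
  pm <- data.frame(id = peaks$id, gc = gc, mean_access = rowMeans(counts))
  cell_atlas(counts, peaks, timepoint, cm, pm)
}

# small simulated study reused by several files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- lineage_spec(tissues = paste0("ts", 1:6),
                           timepoints = paste0("t", 1:3),
                           cells_per_timepoint = 400, peaks_per_tissue = 25,
                           background_peaks = 250, effect_size = 3,
                           n_families = 3, seed = 42)
      cache <<- list(spec = spec, sim = simulate_atlas(spec))
    }
    cache
  }
})

# study-scale atlas used by the acceptance checks, cached per seed
study_sim <- local({
  cache <- list()
  function(seed) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      spec <- lineage_spec(seed = seed)
      sim <- simulate_atlas(spec)
      scores <- score_all(sim$atlases, sim$module_sets, n_background = 50,
                          seed = seed)
      cache[[key]] <<- list(spec = spec, sim = sim, scores = scores)
    }
    cache[[key]]
  }
})

# brute-force non-trivial bipartitions of an ape tree: delete each edge and
# read the leaf partition off graph connectivity (independent of the
# package's postorder split extraction)
brute_splits <- function(phy) {
  labs <- phy$tip.label
  n <- length(labs)
  ref <- min(labs)
  keys <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    g <- igraph::graph_from_edgelist(
      matrix(as.character(phy$edge[-e, , drop = FALSE]), ncol = 2),
      directed = FALSE)
    comp <- igraph::components(g)$membership
    child <- as.character(phy$edge[e, 2])
    if (!child %in% names(comp)) next       # isolated tip
    side_nodes <- as.integer(names(comp)[comp == comp[[child]]])
    side <- labs[side_nodes[side_nodes <= n]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

brute_rf <- function(p1, p2) {
  s1 <- brute_splits(p1); s2 <- brute_splits(p2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
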