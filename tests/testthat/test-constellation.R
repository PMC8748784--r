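test_that("dendrograms merge nearest tissues first", {
  # pairwise tissue distances {AB: small, AC/BC: large}
  sc <- cbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(10, 0, 0))
  d <- build_dendrogram(sc, "t1")
  expect_s3_class(d, "tissue_dendrogram")
  first_merge <- d$hclust$merge[1, ]
  expect_setequal(d$hclust$labels[-first_merge], c("A", "B"))
  # duplicated vectors merge at height zero
  sc2 <- cbind(A = c(1, 2), B = c(1, 2), C = c(5, 5))
  d2 <- build_dendrogram(sc2, "t1")
  expect_equal(min(d2$hclust$height), 0)
  expect_error(build_dendrogram(sc[, 1, drop = FALSE]), ">= 2 tissues")
})

test_that("average-linkage agglomeration matches a naive oracle", {
  # naive O(n^3) average-linkage on the raw distance matrix, compared via
  # cophenetic distances
  naive_avg_cophenetic <- function(D) {
    n <- nrow(D)
    groups <- as.list(seq_len(n))
    coph <- matrix(0, n, n)
    active <- rep(TRUE, 2 * n - 1)
    dd <- matrix(Inf, 2 * n - 1, 2 * n - 1)
    dd[1:n, 1:n] <- D; diag(dd) <- Inf
    members <- c(as.list(seq_len(n)), vector("list", n - 1))
    nxt <- n + 1
    alive <- seq_len(n)
    while (length(alive) > 1) {
      sub <- dd[alive, alive, drop = FALSE]
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      a <- alive[ij[1]]; b <- alive[ij[2]]
      h <- dd[a, b]
      members[[nxt]] <- c(members[[a]], members[[b]])
      for (x in members[[a]]) for (y in members[[b]]) {
        coph[x, y] <- h; coph[y, x] <- h
      }
      alive <- setdiff(alive, c(a, b))
      for (o in alive) {
        # unweighted average linkage over all member pairs
        dd[nxt, o] <- dd[o, nxt] <-
          mean(D[members[[nxt]], members[[o]], drop = FALSE])
      }
      alive <- c(alive, nxt)
      nxt <- nxt + 1
    }
    coph
  }
  set.seed(12)
  sc <- matrix(rnorm(8 * 6), 8, 6,
               dimnames = list(NULL, paste0("ts", 1:6)))
  D <- as.matrix(dist(t(sc)))
  d <- build_dendrogram(sc, "t1")
  coph_pkg <- as.matrix(stats::cophenetic(d$hclust))
  o <- colnames(sc)
  expect_equal(unname(coph_pkg[o, o]), unname(naive_avg_cophenetic(D)),
               tolerance = 1e-10)
})

test_that("Robinson-Foulds distance counts bipartition differences", {
  t_ab <- ape::read.tree(text = "((A,B),(C,D));")
  t_ac <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t_ab, t_ab), 0)
  expect_equal(rf_distance(t_ab, t_ac), 2)
  expect_error(rf_distance(t_ab, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets differ")
})

test_that("RF matches brute-force enumeration over all 6-leaf topologies", {
  skip_if_not_installed("phangorn")
  trees <- phangorn::allTrees(6, tip.label = LETTERS[1:6])
  expect_equal(length(trees), 105)
  splits <- lapply(trees, brute_splits)
  n <- length(trees)
  rf_phangorn <- as.matrix(phangorn::RF.dist(trees))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mine <- rf_distance(trees[[i]], trees[[j]])
    brute <- length(setdiff(splits[[i]], splits[[j]])) +
      length(setdiff(splits[[j]], splits[[i]]))
    if (mine != brute) fail(sprintf("pair (%d, %d): %d vs brute %d",
                                    i, j, mine, brute))
    if (mine != rf_phangorn[i, j])
      fail(sprintf("pair (%d, %d): %d vs phangorn %d",
                   i, j, mine, rf_phangorn[i, j]))
  }
  # bounds for binary trees on 6 leaves: 0 <= RF <= 2(n-3) = 6
  expect_true(all(rf_phangorn >= 0 & rf_phangorn <= 6))
  expect_true(all(diag(rf_phangorn) == 0))
  succeed()
})

test_that("the combined distance reproduces the hand computation", {
  # 3 tissues x 2 timepoints, 4 cells each; hand-set score vectors
  s1 <- cbind(A = c(1, 0, 0, 0), B = c(0, 1, 0, 0), C = c(2, 2, 2, 2))
  s2 <- cbind(A = c(1, 1, 1, 1), B = c(3, 1, 1, 1), C = c(0, 0, 0, 5))
  cd <- build_distance(list(t1 = s1, t2 = s2), a = 12)
  # three leaves admit no non-trivial bipartition: timepoint term is 0
  expect_true(all(cd$D_timepoint == 0))
  d_t <- list(t1 = as.matrix(dist(t(s1))), t2 = as.matrix(dist(t(s2))))
  tis <- c("A", "B", "C"); tps <- c("t1", "t2")
  for (i1 in 1:3) for (p1 in 1:2) for (i2 in 1:3) for (p2 in 1:2) {
    expected <- (d_t[[p1]][i1, i2] + d_t[[p2]][i1, i2]) / 2
    node1 <- paste0(tis[i1], "@", tps[p1])
    node2 <- paste0(tis[i2], "@", tps[p2])
    expect_equal(cd$D[node1, node2], expected, tolerance = 1e-12)
  }
  # spot check one entry fully by hand:
  # d_AB,t1 = sqrt(1+1) = sqrt(2); d_AB,t2 = sqrt(4) = 2
  expect_equal(cd$D["A@t1", "B@t2"], (sqrt(2) + 2) / 2, tolerance = 1e-12)
  expect_equal(cd$D["A@t1", "A@t1"], 0)
})

test_that("the timepoint term adds a x RF when dendrograms disagree", {
  # 4 tissues; topology ((A,B),(C,D)) at t1 vs ((A,C),(B,D)) at t2: RF = 2
  s1 <- cbind(A = c(0, 0), B = c(0.2, 0), C = c(10, 0), D = c(10.2, 0))
  s2 <- cbind(A = c(0, 0), C = c(0.2, 0), B = c(10, 0), D = c(10.2, 0))[, c("A", "B", "C", "D")]
  cd <- build_distance(list(t1 = s1, t2 = s2), a = 12)
  expect_equal(rf_distance(cd$dendrograms[["t1"]], cd$dendrograms[["t2"]]), 2)
  cross <- cd$nodes$timepoint == "t1"
  expect_true(all(cd$D_timepoint[cross, !cross] == 2))
  expect_true(all(cd$D_timepoint[cross, cross] == 0))
  expect_equal(cd$D["A@t1", "A@t2"], 0 + 12 * 2, tolerance = 1e-12)
  expect_equal(cd$D, cd$D_tissue + 12 * cd$D_timepoint, tolerance = 1e-12)
})

test_that("distance invariants: symmetry, diagonal, scaling", {
  sm <- small_sim()
  scores <- score_all(sm$sim$atlases, sm$sim$module_sets, n_background = 15,
                      seed = 2)
  cd <- build_distance(scores, a = 12)
  expect_equal(max(abs(cd$D - t(cd$D))), 0)
  expect_true(all(diag(cd$D) == 0))
  # D_timepoint depends only on the timepoint pair
  for (p1 in c("t1", "t2", "t3")) for (p2 in c("t1", "t2", "t3")) {
    blk <- cd$D_timepoint[cd$nodes$timepoint == p1, cd$nodes$timepoint == p2]
    expect_equal(max(blk) - min(blk), 0)
  }
  # positive rescaling of all scores scales D_tissue, leaves D_timepoint
  scaled <- lapply(scores, function(s) s$scores * 3)
  cd3 <- build_distance(scaled, a = 12)
  expect_equal(cd3$D_tissue, 3 * cd$D_tissue, tolerance = 1e-9)
  expect_equal(cd3$D_timepoint, cd$D_timepoint)
})

test_that("embedding separates planted groups and is deterministic", {
  set.seed(6)
  base1 <- rnorm(20); base2 <- rnorm(20) + 50
  mk <- function() {
    m <- sapply(1:6, function(i)
      (if (i <= 3) base1 else base2) + rnorm(20, sd = 0.5))
    colnames(m) <- paste0("ts", 1:6)
    m
  }
  cd <- build_distance(list(t1 = mk(), t2 = mk()), a = 12)
  m1 <- embed_constellation(cd, seed = 0)
  m2 <- embed_constellation(cd, seed = 0)
  expect_identical(m1$x, m2$x)
  km <- kmeans(cbind(m1$x, m1$y), centers = 2, nstart = 10)
  truth <- as.integer(sub("ts", "", m1$tissue)) <= 3
  expect_gte(ari(km$cluster, truth), 0.9)
})

test_that("embedding handles degenerate inputs per contract", {
  cd1 <- list(nodes = data.frame(tissue = "A", timepoint = "t1",
                                 node = "A@t1"),
              D = matrix(0, 1, 1, dimnames = list("A@t1", "A@t1")))
  class(cd1) <- "constellation_dist"
  m <- embed_constellation(cd1)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$x, m$y), c(0, 0))
  cd_bad <- cd1
  cd_bad$D[1, 1] <- NaN
  expect_error(embed_constellation(cd_bad), "non-finite")
})

test_that("grouping cuts behave at the extremes", {
  sc <- list(t1 = cbind(A = rnorm(10), B = rnorm(10), C = rnorm(10)))
  cd <- build_distance(sc, a = 12)
  g1 <- group_nodes(cd, k = 3)
  expect_equal(length(unique(g1)), 3)
  g2 <- group_nodes(cd, k = 1)
  expect_equal(length(unique(g2)), 1)
  expect_error(group_nodes(cd, k = 10), "exceeds node count")
})

test_that("newick serialization round-trips the topology", {
  sc <- cbind(A = c(0, 0), B = c(1, 0), C = c(5, 0), D = c(9, 9))
  d <- build_dendrogram(sc, "t1")
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(d, path)
  back <- ape::read.tree(path)
  expect_equal(rf_distance(d, back), 0)
})
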