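test_that("expectations follow the depth model and conserve totals", {
  # full annotation: E_i = T_i, raw deviation identically 0
  sm <- small_sim()
  a <- sm$sim$atlases[["t1"]]
  E <- expected_counts(a, seq_len(nrow(a$counts)))
  expect_equal(E, Matrix::colSums(a$counts), tolerance = 1e-12)
  X <- Matrix::colSums(a$counts)
  expect_equal(unname(raw_deviation(X, E)), rep(0, length(E)),
               tolerance = 1e-12)

  # conservation holds for arbitrary sets
  set.seed(4)
  for (i in 1:10) {
    s <- sample(nrow(a$counts), sample(5:50, 1))
    E <- expected_counts(a, s)
    expect_equal(sum(E), sum(a$counts[s, ]), tolerance = 1e-9)
  }
  expect_error(expected_counts(a, integer(0)), "empty")
})

test_that("the two-cell two-peak worked example is exact", {
  a <- toy_atlas(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  E <- expected_counts(a, 1L)
  expect_equal(unname(E), c(1, 1))
  X <- as.numeric(a$counts[1, ])
  expect_equal(unname(raw_deviation(X, E)), c(1, -1))
})

test_that("uniform matrices have zero raw deviation for any set", {
  a <- toy_atlas(matrix(3, 8, 5))
  for (s in list(1L, c(2L, 5L), 1:8)) {
    E <- expected_counts(a, s)
    X <- Matrix::colSums(a$counts[s, , drop = FALSE])
    expect_equal(max(abs(raw_deviation(X, E))), 0)
  }
})

test_that("background sampling is covariate-matched and reproducible", {
  pm <- data.frame(gc = rep(0.5, 40), mean_access = rep(1, 40))
  b1 <- sample_background_sets(pm, set = 1:5, n_background = 2000, seed = 3)
  b2 <- sample_background_sets(pm, set = 1:5, n_background = 2000, seed = 3)
  expect_identical(b1, b2)
  expect_equal(dim(b1), c(2000L, 5L))
  # identical covariates: inclusion frequencies uniform over all 40 peaks
  freq <- tabulate(b1, nbins = 40)
  expect_gt(suppressWarnings(chisq.test(freq)$p.value), 0.001)

  # matched: with two covariate blobs, backgrounds stay within the blob
  pm2 <- data.frame(gc = c(rep(0.2, 30), rep(0.8, 30)),
                    mean_access = c(rep(0.5, 30), rep(2, 30)))
  b3 <- sample_background_sets(pm2, set = 1:4, n_background = 50, seed = 1,
                               k_candidates = 20)
  expect_true(all(b3 <= 30))

  # minimal case and the full-set case
  b4 <- sample_background_sets(pm, set = 1:40, n_background = 2, seed = 1)
  expect_equal(dim(b4), c(2L, 40L))
  expect_true(all(b4 >= 1 & b4 <= 40))
  expect_error(sample_background_sets(pm, 1:5, n_background = 1), ">= 2")
  expect_error(sample_background_sets(pm[1:3, ], 1:5, 10), "fewer candidate")
})

test_that("z-scores flag degenerate backgrounds instead of zeroing them", {
  a <- toy_atlas(matrix(2, 10, 6))  # uniform: every deviation is 0
  expect_error(deviation_zscore(a, 1:3, n_background = 10),
               "degenerate")
})

test_that("null z-scores are calibrated near mean 0, variance 1", {
  spec <- lineage_spec(tissues = c("a", "b"), timepoints = c("t1", "t2"),
                       cells_per_timepoint = 500, peaks_per_tissue = 5,
                       background_peaks = 290, effect_size = 1, seed = 3)
  sim <- simulate_atlas(spec)
  a <- sim$atlases[["t1"]]
  set.seed(11)
  zs <- sapply(1:20, function(i)
    deviation_zscore(a, sample(300, 30), n_background = 50, seed = i))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.2)
  expect_gt(var(as.vector(zs), na.rm = TRUE), 0.7)
  expect_lt(var(as.vector(zs), na.rm = TRUE), 1.3)
})

test_that("planted lineage cells outscore others on their own module", {
  sm <- small_sim()
  tp <- "t3"   # every tissue established by the last timepoint
  z <- deviation_zscore(sm$sim$atlases[[tp]], sm$sim$module_sets$sets[["ts1"]],
                        n_background = 25, seed = 2)
  ca <- sm$sim$truth$cell_assignments
  fate <- ca$tissue[ca$timepoint == tp]
  w <- wilcox.test(z[fate == "ts1"], z[fate != "ts1"],
                   alternative = "greater")
  expect_lt(w$p.value, 1e-10)
})

test_that("score_all applies late peak sets retrogradely without mutation", {
  sm <- small_sim()
  before <- as.matrix(sm$sim$atlases[["t1"]]$counts)
  scores <- score_all(sm$sim$atlases, sm$sim$module_sets, n_background = 15,
                      seed = 5)
  expect_equal(names(scores), c("t1", "t2", "t3"))
  for (tp in names(scores))
    expect_equal(dim(scores[[tp]]$scores), c(400L, 6L))
  expect_identical(as.matrix(sm$sim$atlases[["t1"]]$counts), before)

  # composition identity: one set at one timepoint
  single <- peak_set_collection(list(ts1 = sm$sim$module_sets$sets[["ts1"]]))
  one <- score_all(sm$sim$atlases["t2"], single, n_background = 15, seed = 5)
  direct <- deviation_zscore(sm$sim$atlases[["t2"]],
                             sm$sim$module_sets$sets[["ts1"]],
                             n_background = 15, seed = 5)
  expect_equal(unname(one[["t2"]]$scores[, 1]), unname(as.vector(direct)))

  # annotations outside the peak space are refused
  bad <- peak_set_collection(list(oops = c(1L, 10000L)))
  expect_error(score_all(sm$sim$atlases, bad), "outside")
})

test_that("cluster-enriched peaks are detected and flat peaks are not", {
  set.seed(8)
  n_per <- 200
  cl <- rep(c("A", "B"), each = n_per)
  # peak 1: 90% accessible in A, 5% in B; peak 2 flat at 50%; peaks 3-12 flat
  probs <- rbind(c(0.9, 0.05), matrix(0.5, 11, 2))
  counts <- t(sapply(seq_len(nrow(probs)), function(j)
    rbinom(2 * n_per, 1, probs[j, (cl == "B") + 1])))
  a <- toy_atlas(counts, fragments = rep(5000, 2 * n_per), cluster = cl)
  res <- enriched_peaks(a, alpha = 0.001)
  expect_true(1 %in% res$selected[["A"]])
  expect_false(1 %in% res$selected[["B"]])
  expect_false(2 %in% res$selected[["A"]])
  expect_false(2 %in% res$selected[["B"]])
  # alpha = 0 empties the selection
  res0 <- enriched_peaks(a, alpha = 0)
  expect_equal(sum(lengths(res0$selected)), 0)
  expect_true(all(res$table$adj_p >= 0 & res$table$adj_p <= 1, na.rm = TRUE))
})

test_that("LR-test peak ranking agrees with an exact Fisher screen", {
  set.seed(15)
  n_per <- 150
  cl <- rep(c("A", "B"), each = n_per)
  p_a <- seq(0.9, 0.3, length.out = 20)
  counts <- t(sapply(p_a, function(p)
    rbinom(2 * n_per, 1, ifelse(cl == "A", p, 0.3))))
  a <- toy_atlas(counts, fragments = rep(4000, 2 * n_per), cluster = cl)
  res <- enriched_peaks(a, alpha = 0.001)
  tab <- res$table[res$table$cluster == "A", ]
  fisher_p <- vapply(seq_len(nrow(counts)), function(j) {
    m <- table(factor(counts[j, ] > 0, c(FALSE, TRUE)), cl)
    fisher.test(m)$p.value
  }, numeric(1))
  top_lr <- order(tab$p)[1:5]
  top_fisher <- order(fisher_p)[1:5]
  expect_gte(length(intersect(top_lr, top_fisher)), 4)
})
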