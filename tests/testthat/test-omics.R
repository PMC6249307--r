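# TMT normalization, replicate averaging, log-ratio transform, correlation,
# clustering with optimal leaf ordering, t statistics, IF quantification,
# network filtering.

make_tmt <- function(values, conditions = NULL) {
  n <- ncol(values)
  runs <- rep(c("E1", "E2"), length.out = n)
  if (is.null(conditions)) conditions <- paste0("c", seq_len(n))
  samples <- tibble::tibble(
    sample_id = colnames(values),
    condition = conditions,
    dose = seq_len(n),
    run = rep("E1", n),
    tumor_id = colnames(values),
    is_normalization_channel = c(TRUE, rep(FALSE, n - 1)),
    crude_median = rep(1, n)
  )
  new_omics_matrix(values, samples, type = "tmt")
}

test_that("TMT normalization divides by crude medians then ratios to the run reference", {
  v <- matrix(c(10, 20, 30, 40, 60, 20), nrow = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  om <- make_tmt(v)
  om$samples$crude_median <- c(1, 2, 1)
  norm <- tmt_normalize(om)
  # brute-force two-step oracle
  expected <- sweep(v, 2, c(1, 2, 1), "/")
  expected <- expected / expected[, 1]
  expect_equal(norm$values, expected)
  # all-identical samples give all ratios 1
  same <- make_tmt(matrix(5, 3, 2, dimnames = list(paste0("p", 1:3),
                                                   c("a", "b"))))
  expect_true(all(tmt_normalize(same)$values == 1))
  # crude median 2 halves values before ratioing
  expect_equal(norm$values[, 2], (v[, 2] / 2) / v[, 1])
})

test_that("a zero normalization-channel value flags the feature missing", {
  v <- matrix(c(0, 5, 10, 5), 2, 2,
              dimnames = list(c("p1", "p2"), c("ref", "s")))
  om <- make_tmt(v)
  norm <- tmt_normalize(om)
  expect_true(all(is.na(norm$values["p1", ])))
  expect_equal(attr(norm, "n_flagged"), 1)
})

test_that("geometric replicate averaging collapses tumors correctly", {
  v <- matrix(c(2, 4, 8, 4, 5, 9), nrow = 2,
              dimnames = list(c("p1", "p2"), c("a1", "a2", "b")))
  samples <- tibble::tibble(
    sample_id = c("a1", "a2", "b"), condition = c("x", "x", "y"),
    dose = c(0, 0, 1), run = c("E1", "E2", "E1"),
    tumor_id = c("A", "A", "B"),
    is_normalization_channel = c(TRUE, TRUE, FALSE),
    crude_median = 1
  )
  om <- new_omics_matrix(v, samples, type = "tmt")
  avg <- geometric_mean_replicates(om)
  expect_equal(dim(avg$values), c(2, 2))
  expect_equal(avg$values["p1", "A"], sqrt(2 * 8))  # (2, 8) -> 4
  expect_equal(avg$values["p2", "A"], sqrt(4 * 4))  # identical replicates
  expect_equal(avg$values[, "B"], c(p1 = 5, p2 = 9))  # singleton unchanged
  om$values["p1", "a2"] <- 0
  expect_error(geometric_mean_replicates(om), regexp = "geometric")
})

test_that("log-ratio transform follows the pseudocount convention", {
  v <- matrix(c(0, 0.999, 5, 0, 0, 5), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("ref", "s")))
  samples <- tibble::tibble(sample_id = c("ref", "s"),
                            condition = c("ctrl", "t"), tumor_id = c("ref", "s"))
  om <- new_omics_matrix(v, samples, type = "fpkm")
  tx <- log_ratio_transform(om, reference_sample = "ref", pseudocount = 0.001)
  expect_true(all(tx$values[, "ref"] == 0))
  expect_equal(tx$values["g1", "s"], 0)  # 0 vs 0 under the pseudocount
  expect_equal(tx$values["g2", "s"], log2(0.001 / 1), tolerance = 1e-9)
  # v = 0.999 against reference 0: log2(1000) ~ 9.966
  om2 <- new_omics_matrix(
    matrix(c(0, 0.999), 1, 2, dimnames = list("g", c("ref", "s"))),
    tibble::tibble(sample_id = c("ref", "s"), tumor_id = c("ref", "s")),
    type = "fpkm")
  tx2 <- log_ratio_transform(om2, "ref")
  expect_equal(tx2$values["g", "s"], log2(1000), tolerance = 1e-4)
  expect_equal(tx2$values["g", "s"], 9.966, tolerance = 1e-3)
  expect_error(log_ratio_transform(om, "missing"),
               class = "msipk_invalid_argument")
  expect_equal(attr(tx, "log_base"), 2)
})

test_that("feature correlation matrix matches a brute-force pairwise oracle", {
  set.seed(11)
  v <- matrix(rlnorm(10 * 5), 10, 5,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
  samples <- tibble::tibble(sample_id = colnames(v), tumor_id = colnames(v))
  om <- new_omics_matrix(v, samples, type = "fpkm")
  cm <- feature_correlation_matrix(om)
  expect_equal(unname(diag(cm$r)), rep(1, 10))
  expect_equal(cm$r, t(cm$r))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(cm$r[i, j], cor(v[i, ], v[j, ]), tolerance = 1e-12)
  }
  # constant features are excluded with a warning
  v2 <- rbind(v, const = rep(2, 5))
  om2 <- new_omics_matrix(v2, samples, type = "fpkm")
  expect_warning(cm2 <- feature_correlation_matrix(om2), "constant")
  expect_false("const" %in% rownames(cm2$r))
})

test_that("planted anti-correlated transcript blocks show the expected sign structure", {
  om <- generate_omics(n_phospho = 30, n_transcript = 80,
                       phospho_module_size = 10,
                       transcript_block_sizes = c(20, 20), noise_cv = 0.05,
                       seed = 9L)
  tx <- log_ratio_transform(om$transcripts, om$truth$reference_sample)
  cm <- feature_correlation_matrix(tx)
  down <- rownames(cm$r) %in% om$truth$transcript_blocks$down
  up <- rownames(cm$r) %in% om$truth$transcript_blocks$up
  within_down <- cm$r[down, down]
  between <- cm$r[down, up]
  expect_gt(mean(within_down[upper.tri(within_down)]), 0)
  expect_lt(mean(between), 0)
})

test_that("phospho and transcript blocks combine over shared samples", {
  om <- generate_omics(n_phospho = 20, n_transcript = 30,
                       phospho_module_size = 5,
                       transcript_block_sizes = c(5, 5), seed = 13L)
  norm <- tmt_normalize(om$phospho)
  avg <- geometric_mean_replicates(norm)
  plog <- avg; plog$values <- log2(avg$values)
  tx <- log_ratio_transform(om$transcripts, om$truth$reference_sample)
  cm <- feature_correlation_matrix(plog, tx)
  expect_setequal(unique(cm$classes), c("phospho", "transcript"))
  expect_equal(length(cm$samples), ncol(avg$values))
  expect_equal(nrow(cm$r), sum(table(cm$classes)))
})

test_that("hierarchical clustering reproduces an exhaustive agglomeration oracle", {
  set.seed(5)
  X <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(paste0("f", 1:7), NULL))
  D <- as.matrix(dist(X))
  for (linkage in c("average", "mcquitty")) {
    dend <- hierarchical_cluster(X, linkage = linkage)
    expect_equal(sort(dend$merge_heights),
                 agglomerate_oracle(D, linkage), tolerance = 1e-10)
    expect_true(all(diff(dend$merge_heights) >= -1e-12))
    expect_setequal(dend$leaf_order, 1:7)
  }
  # two features: a single merge at their distance
  two <- X[1:2, ]
  d2 <- hierarchical_cluster(two)
  expect_equal(d2$merge_heights, as.numeric(dist(two)))
})

test_that("optimal leaf ordering never worsens adjacent-leaf similarity", {
  set.seed(21)
  X <- matrix(rnorm(20 * 6), 20, 6)
  D <- as.matrix(dist(X))
  path_cost <- function(ord) sum(D[cbind(ord[-length(ord)], ord[-1])])
  native <- hierarchical_cluster(X, order = "none")
  ordered <- hierarchical_cluster(X, order = "optimal")
  expect_lte(path_cost(ordered$leaf_order), path_cost(native$leaf_order) + 1e-10)
  # ordering is a permutation consistent with the same merge tree
  expect_setequal(ordered$leaf_order, seq_len(20))
  expect_equal(ordered$merge_heights, native$merge_heights)
})

test_that("planted 3-module correlation structure is recovered by cutting the tree", {
  set.seed(31)
  n_per <- 12
  base <- matrix(rnorm(3 * 8), 3, 8)
  X <- do.call(rbind, lapply(1:3, function(m) {
    base[rep(m, n_per), ] + matrix(rnorm(n_per * 8, sd = 0.3), n_per, 8)
  })) + 20  # shifted positive; a constant shift leaves Pearson r unchanged
  rownames(X) <- sprintf("f%02d", seq_len(nrow(X)))
  colnames(X) <- paste0("s", 1:8)
  cm <- feature_correlation_matrix(
    new_omics_matrix(X, tibble::tibble(sample_id = paste0("s", 1:8),
                                       tumor_id = paste0("s", 1:8)),
                     type = "fpkm"))
  dend <- hierarchical_cluster(cm, linkage = "average")
  modules <- cut_modules(dend, 3)
  truth <- rep(1:3, each = n_per)
  expect_gte(ari(modules, truth), 0.95)
})

test_that("clustering rejects NaN distances naming the features", {
  X <- matrix(c(1, 2, NA, 4, 5, NA), 3, 2,
              dimnames = list(c("ok1", "bad", "ok2"), NULL))
  expect_error(hierarchical_cluster(X), regexp = "bad",
               class = "msipk_invalid_argument")
})

test_that("dendrograms export as Newick trees", {
  X <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(letters[1:5], NULL))
  dend <- hierarchical_cluster(X)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, tmp)
  phy <- ape::read.tree(tmp)
  expect_setequal(phy$tip.label, letters[1:5])
})

test_that("two-tailed t p-values reproduce the printed study statistics", {
  expect_lt(abs(t_pvalue(1.183, 2) - 0.358), 0.001)
  expect_lt(abs(t_pvalue(4.213, 4) - 0.0136), 0.0005)
  expect_lt(abs(t_pvalue(8.562, 4) - 0.001), 0.0005)
  expect_lt(abs(t_pvalue(13.069, 4) - 0.0002), 0.0001)
  expect_lt(abs(t_pvalue(0.162, 2) - 0.8859), 0.001)
  expect_equal(t_pvalue(0, 17), 1)
  expect_error(t_pvalue(1, 0))
})

test_that("t p-values agree with closed forms and decrease in |t|", {
  ts <- c(0.3, 0.9, 1.7, 3.2)
  expect_equal(t_pvalue(ts, 1), 1 - (2 / pi) * atan(abs(ts)), tolerance = 1e-12)
  expect_equal(t_pvalue(ts, 2), 1 - ts / sqrt(ts^2 + 2), tolerance = 1e-12)
  x <- ts / sqrt(ts^2 + 4)
  expect_equal(t_pvalue(ts, 4), 1 - x * (3 - x^2) / 2, tolerance = 1e-12)
  expect_true(all(diff(t_pvalue(seq(0, 5, 0.5), 3)) < 0))
})

test_that("pooled t-test matches the textbook formula and the df convention", {
  a <- c(5.1, 6.2, 4.8)
  b <- c(3.9, 4.4, 3.1)
  res <- unpaired_t_test(a, b)
  expect_equal(res$df, 4)  # n = 3 vs 3, as in the flank comparisons
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against the standard library implementation
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- unpaired_t_test(c(2, 2.5), c(2, 2.5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # zero variance with unequal means: degenerate infinite-t path
  degen <- unpaired_t_test(c(2, 2), c(3, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_error(unpaired_t_test(1, c(2, 3)))
})

test_that("IF ROI quantification thresholds the nuclear channel like an Otsu oracle", {
  set.seed(7)
  nuclear <- matrix(rnorm(900, 20, 2), 30, 30)
  nuclear[8:22, 8:22] <- rnorm(225, 120, 5)  # bright high-cellularity block
  marker <- matrix(1, 30, 30)
  marker[8:22, 8:22] <- 9
  res <- if_roi_quantify(nuclear, marker)
  expect_equal(res$mean_intensity, 9, tolerance = 0.2)
  # the selected ROI is (essentially) the bright block
  truth <- matrix(FALSE, 30, 30); truth[8:22, 8:22] <- TRUE
  expect_gt(dice_coefficient(res$roi$pixels, truth), 0.95)
  # a uniform marker returns its value for any ROI
  res2 <- if_roi_quantify(nuclear, matrix(3.5, 30, 30))
  expect_equal(res2$mean_intensity, 3.5)
  # manual mask path
  res3 <- if_roi_quantify(nuclear, marker, mask = truth)
  expect_equal(res3$mean_intensity, 9)
  expect_error(if_roi_quantify(matrix(1, 5, 5), matrix(1, 5, 5)),
               class = "msipk_empty_roi")
})

test_that("dose-response phantom images yield decreasing means detected by the t-test", {
  set.seed(17)
  doses <- c(placebo = 100, low = 55, high = 25)  # marker means per group
  group_means <- lapply(doses, function(mu) {
    vapply(1:3, function(i) {
      nuclear <- matrix(rnorm(400, 10, 1), 20, 20)
      nuclear[5:15, 5:15] <- rnorm(121, 80, 4)
      marker <- matrix(rnorm(400, 5, 1), 20, 20)
      marker[5:15, 5:15] <- rnorm(121, mu, 5)
      if_roi_quantify(nuclear, marker)$mean_intensity
    }, numeric(1))
  })
  means <- vapply(group_means, mean, numeric(1))
  expect_true(all(diff(means) < 0))
  res <- unpaired_t_test(group_means$placebo, group_means$high)
  expect_equal(res$df, 4)
  expect_lt(res$p, 0.05)
})

test_that("network edge filtering applies a strict threshold and channel exclusion", {
  edges <- tibble::tibble(
    node_a = c("A", "B", "C", "D", "E"),
    node_b = c("B", "C", "D", "E", "F"),
    confidence = c(0.91, 0.89, 0.90, 0.95, 0.99),
    channel = c("experimental", "experimental", "database", "textmining",
                "coexpression")
  )
  kept <- filter_network_edges(edges)
  # 0.90 fails the strict > 0.9 rule; the 0.95 edge is text mining
  expect_setequal(kept$node_a, c("A", "E"))
  expect_equal(nrow(filter_network_edges(edges[0, ])), 0)
  # brute-force comparison on a larger fixture
  set.seed(2)
  big <- tibble::tibble(node_a = paste0("n", 1:10), node_b = paste0("m", 1:10),
                        confidence = round(runif(10), 3),
                        channel = sample(c("experimental", "textmining"), 10,
                                         replace = TRUE))
  got <- filter_network_edges(big, threshold = 0.5)
  manual <- big[big$confidence > 0.5 & big$channel != "textmining", ]
  expect_equal(got, manual)
  loops <- tibble::tibble(node_a = "A", node_b = "A", confidence = 0.95,
                          channel = "experimental")
  expect_error(filter_network_edges(loops))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(edges, tmp)
  expect_equal(read_network_tsv(tmp)$confidence, edges$confidence)
})

test_that("planted phospho module decreases monotonically after normalization", {
  om <- generate_omics(n_phospho = 60, n_transcript = 40,
                       phospho_module_size = 15,
                       transcript_block_sizes = c(10, 10), seed = 19L)
  norm <- tmt_normalize(om$phospho)
  avg <- geometric_mean_replicates(norm)
  mod <- avg$values[om$truth$phospho_module, , drop = FALSE]
  cond_means <- tapply(colMeans(mod), avg$samples$dose, mean)
  expect_true(all(diff(cond_means[order(as.numeric(names(cond_means)))]) < 0))
})

test_that("the bundled synthetic interaction table filters to high-confidence edges", {
  path <- system.file("extdata", "synthetic_string_edges.tsv",
                      package = "msipk")
  edges <- read_network_tsv(path)
  expect_equal(nrow(edges), 20)
  kept <- filter_network_edges(edges)
  # strict > 0.9, text-mining evidence excluded
  expect_true(all(kept$confidence > 0.9))
  expect_false(any(kept$channel == "textmining"))
  manual <- edges[edges$confidence > 0.9 & edges$channel != "textmining", ]
  expect_equal(nrow(kept), nrow(manual))
})
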