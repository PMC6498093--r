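test_that("entropy matches the closed-form oracle", {
  expect_equal(entropy_bits(rep("a", 7)), 0)
  expect_equal(entropy_bits(c(rep("a", 5), rep("b", 5))), 1)
  # 10 vs 9, the cohort split
  expect_equal(entropy_bits(make_labels(10, 9)), oracle_entropy(c(10, 9)))
  expect_error(entropy_bits(character(0)), "empty")
})

test_that("information gain matches hand arithmetic", {
  labels <- c("+", "+", "-", "-", "-")
  # one empty side: no information
  expect_equal(information_gain(labels, integer(0), 1:5), 0)
  # perfect separation of 5/5 gains one full bit
  ten <- c(rep("+", 5), rep("-", 5))
  expect_equal(information_gain(ten, 1:5, 6:10), 1)
  # {1,2} | {3,4,5}: parent H(2/5) - 3/5 * H(0/3)
  expected <- oracle_entropy(c(2, 3)) - 0.4 * 0 - 0.6 * 0
  expect_equal(information_gain(labels, 1:2, 3:5), expected)
  # overlapping partition rejected
  expect_error(information_gain(labels, 1:3, 3:5), "partition")
})

test_that("tree root split equals the exhaustive brute-force argmax", {
  # 6 samples, 2 features, no pure single split; unique argmax by construction
  m <- make_matrix(rbind(c(1, 2, 3, 4, 5, 6),
                         c(5, 1, 4, 2, 6, 3)))
  labels <- label_vector(c("a", "a", "a", "g", "g", "g")[c(1, 2, 4, 3, 5, 6)],
                         sprintf("s%02d", 1:6), positive = "a")
  oracle <- oracle_best_split(m, labels)
  tree <- build_tree(m, labels)
  expect_equal(tree$nodes$feature_id[1], oracle$feature)
  expect_equal(tree$nodes$threshold[1], oracle$threshold)
  expect_equal(tree$nodes$ig[1], oracle$ig)
})

test_that("trees handle separable and degenerate inputs", {
  # one feature perfectly separating classes: depth-1 tree, train accuracy 1
  m <- make_matrix(rbind(c(1, 2, 3, 10, 11, 12), c(7, 7, 7, 7, 7, 7)))
  labels <- make_labels(3, 3)
  labels <- label_vector(c(rep("granuloma", 3), rep("adenocarcinoma", 3)),
                         sprintf("s%02d", 1:6))
  tree <- build_tree(m, labels)
  expect_equal(nrow(tree$nodes), 1L)
  expect_equal(predict_tree(tree$root, m), as.character(labels))

  # all samples one class: single leaf, no internal nodes
  pure <- label_vector(rep("granuloma", 4), sprintf("s%02d", 1:4),
                       positive = "adenocarcinoma", negative = "granuloma")
  tree2 <- build_tree(make_matrix(matrix(1:8, 2)), pure)
  expect_equal(nrow(tree2$nodes), 0L)
  expect_true(tree2$root$leaf)
})

test_that("node invariants hold: ig bounded by node entropy, wacc in [0,1]", {
  ds <- planted_dataset(seed = 3, n_features = 25)
  ri <- run_mcfs(ds$expression, ds$labels,
                 mcfs_params(m = 8, s = 10, t = 3, seed = 5),
                 return_trees = TRUE)
  trees <- attr(ri, "trees")
  expect_length(trees, 30)
  for (tr in trees) {
    tm <- tr$tree
    expect_true(tm$wacc >= 0 && tm$wacc <= 1)
    if (nrow(tm$nodes)) {
      # a node's gain can never exceed the entropy of a binary node
      expect_true(all(tm$nodes$ig <= 1 + 1e-12))
      expect_true(all(tm$nodes$ig >= 0))
      expect_true(all(tm$nodes$n_node <= tm$n_tree))
    }
  }
})

test_that("relative importance equals a direct recount over the fitted trees", {
  ds <- planted_dataset(seed = 8, n_features = 20)
  for (exps in list(c(u = 1, v = 1), c(u = 0, v = 0), c(u = 2, v = 0.5))) {
    ri <- run_mcfs(ds$expression, ds$labels,
                   mcfs_params(m = 6, s = 8, t = 2, u = exps["u"],
                               v = exps["v"], seed = 42),
                   return_trees = TRUE)
    recount <- setNames(numeric(nrow(ds$expression)), rownames(ds$expression))
    for (tr in attr(ri, "trees")) {
      tm <- tr$tree
      if (!nrow(tm$nodes)) next
      for (i in seq_len(nrow(tm$nodes)))
        recount[tm$nodes$feature_id[i]] <- recount[tm$nodes$feature_id[i]] +
          tm$wacc^exps["u"] * tm$nodes$ig[i] *
          (tm$nodes$n_node[i] / tm$n_tree)^exps["v"]
    }
    expect_equal(setNames(ri$ri, ri$feature_id), recount)
  }
})

test_that("a feature outside every projection scores exactly zero", {
  ds <- planted_dataset(seed = 4, n_features = 50)
  ri <- run_mcfs(ds$expression, ds$labels,
                 mcfs_params(m = 2, s = 3, t = 1, seed = 1))
  never <- ri$times_sampled == 0
  expect_gt(sum(never), 0)
  expect_true(all(ri$ri[never] == 0))
  expect_true(all(ri$times_used[never] == 0))
  expect_true(all(ri$ri[ri$times_used == 0] == 0))
})

test_that("projection batches are additive: split runs sum to the combined run", {
  ds <- planted_dataset(seed = 6, n_features = 30)
  p <- function(s, offset) run_mcfs(ds$expression, ds$labels,
                                    mcfs_params(m = 10, s = s, t = 2, seed = 99),
                                    projection_offset = offset)
  combined <- p(8, 0)
  batch1 <- p(4, 0)
  batch2 <- p(4, 4)
  expect_equal(batch1$ri + batch2$ri, combined$ri)
  expect_equal(batch1$times_sampled + batch2$times_sampled,
               combined$times_sampled)
})

test_that("mcfs rejects projections as large as the feature space", {
  ds <- planted_dataset(seed = 1, n_features = 10)
  expect_error(run_mcfs(ds$expression, ds$labels,
                        mcfs_params(m = 10, s = 2, t = 1)), "smaller than d")
})

test_that("ranking is decreasing with lexicographic tie-breaks", {
  ri <- data.frame(feature_id = c("b", "a", "c"), ri = c(0, 0, 0),
                   times_sampled = 1L, times_used = 0L)
  class(ri) <- c("ri_table", "data.frame")
  expect_equal(rank_features(ri), c("a", "b", "c"))
  ri$ri <- c(3, 5, 4)
  expect_equal(rank_features(ri), c("a", "c", "b"))
})

test_that("a strong planted marker dominates the ranking and larger effects never rank worse", {
  ranks <- sapply(1:12, function(seed) {
    ds <- planted_dataset(seed = seed, n_features = 120, effect = 300)
    ri <- run_mcfs(ds$expression, ds$labels,
                   mcfs_params(m = 12, s = 40, t = 2, seed = seed))
    which(rank_features(ri) == rownames(ds$expression)[3])
  })
  expect_gte(mean(ranks == 1), 0.9)

  # monotonicity of expected rank in the effect size (paired by seed)
  rank_at_effect <- function(effect, seed) {
    cfg <- synthetic_config(n_features = 80,
                            markers = list(marker_spec(3, "fold_shift", effect)),
                            seed = seed)
    ds <- generate_compartment_dataset(cfg)
    ri <- run_mcfs(ds$expression, ds$labels,
                   mcfs_params(m = 10, s = 30, t = 2, seed = seed))
    which(rank_features(ri) == rownames(ds$expression)[3])
  }
  weak <- mean(sapply(1:8, function(s) rank_at_effect(1.5, s)))
  strong <- mean(sapply(1:8, function(s) rank_at_effect(40, s)))
  expect_lte(strong, weak)
})

test_that("single-tree importance equals wacc x ig x node fraction by hand", {
  # one projection, one tree: RI of each used feature recomputable by hand
  ds <- planted_dataset(seed = 10, n_features = 4)
  params <- mcfs_params(m = 3, s = 1, t = 1, u = 1, v = 1, seed = 2)
  ri <- run_mcfs(ds$expression, ds$labels, params, return_trees = TRUE)
  tm <- attr(ri, "trees")[[1]]$tree
  for (fid in unique(tm$nodes$feature_id)) {
    rows <- tm$nodes[tm$nodes$feature_id == fid, ]
    hand <- sum(tm$wacc * rows$ig * (rows$n_node / tm$n_tree))
    expect_equal(ri$ri[ri$feature_id == fid], hand)
  }
  expect_true(all(ri$ri[!ri$feature_id %in% tm$nodes$feature_id] == 0))
})
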