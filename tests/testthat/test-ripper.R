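test_that("FOIL gain follows the closed form and its boundary contracts", {
  expect_identical(foil_gain(10, 9, 0, 0), -Inf)
  expect_equal(foil_gain(10, 9, 10, 9), 0)
  # perfect purification of the 10/19 cohort
  expect_equal(foil_gain(10, 9, 10, 0), 10 * (0 - log2(10 / 19)))
  # independent recomputation on arbitrary counts
  expect_equal(foil_gain(8, 5, 6, 1),
               6 * (log2(6 / 7) - log2(8 / 13)))
  expect_error(foil_gain(5, 5, 6, 0))
})

test_that("grow_rule finds a separating threshold on 1-D separable data", {
  # positives all above 5, negatives all below
  m <- make_matrix(matrix(c(8, 9, 7.5, 10, 1, 2, 4.5), nrow = 1))
  labels <- make_labels(4, 3)
  rule <- grow_rule(m, labels, "adenocarcinoma")
  expect_length(rule$conditions, 1)
  cond <- rule$conditions[[1]]
  expect_equal(cond$op, ">=")
  expect_gt(cond$threshold, 4.5)
  expect_lte(cond$threshold, 7.5)
  # brute force: no single candidate condition has higher FOIL gain
  best_gain <- foil_gain(4, 3, 4, 0)
  for (v in m[1, ]) for (op in c("<=", ">=")) {
    cov <- if (op == "<=") m[1, ] <= v else m[1, ] >= v
    p <- sum(cov[1:4]); n <- sum(cov[5:7])
    expect_lte(foil_gain(4, 3, p, n), best_gain)
  }
})

test_that("grow_rule degenerate inputs follow the stopping contracts", {
  # grow set already pure for the target: empty-condition rule
  m <- make_matrix(matrix(1:4, nrow = 1))
  pure <- label_vector(rep("adenocarcinoma", 4), sprintf("s%02d", 1:4),
                       negative = "granuloma")
  expect_length(grow_rule(m, pure, "adenocarcinoma")$conditions, 0)

  # constant feature: no condition can improve gain, growth stops
  m2 <- make_matrix(matrix(rep(3, 6), nrow = 1))
  labels2 <- make_labels(3, 3)
  expect_length(grow_rule(m2, labels2, "adenocarcinoma")$conditions, 0)
})

test_that("prune_rule equals exhaustive final-segment evaluation", {
  set.seed(14)
  m <- make_matrix(matrix(runif(24, 0, 10), nrow = 3))
  labels <- make_labels(4, 4)
  rule <- structure(list(conditions = list(
    list(feature_id = "miR-01", op = ">=", threshold = 2),
    list(feature_id = "miR-02", op = "<=", threshold = 8),
    list(feature_id = "miR-03", op = ">=", threshold = 5)),
    class = "adenocarcinoma"), class = "ripper_rule")
  pruned <- prune_rule(rule, m, labels)

  metric <- function(conds) {
    cov <- rep(TRUE, 8)
    for (cc in conds) {
      v <- m[cc$feature_id, ]
      cov <- cov & if (cc$op == "<=") v <= cc$threshold else v >= cc$threshold
    }
    if (!any(cov)) return(-1)
    p <- sum(cov & as.character(labels) == "adenocarcinoma")
    (2 * p - sum(cov)) / sum(cov)
  }
  metrics <- sapply(0:3, function(j) metric(rule$conditions[seq_len(j)]))
  expect_equal(length(pruned$conditions), which.max(metrics) - 1L)
  expect_equal(metric(pruned$conditions), max(metrics))
})

test_that("pruning drops a final condition that only excludes positives", {
  # condition 2 excludes prune-set positives and no negatives -> removed
  m <- make_matrix(rbind(c(10, 10, 1, 1), c(0, 5, 5, 5)))
  labels <- make_labels(2, 2)
  rule <- structure(list(conditions = list(
    list(feature_id = "miR-01", op = ">=", threshold = 10),
    list(feature_id = "miR-02", op = "<=", threshold = 2)),
    class = "adenocarcinoma"), class = "ripper_rule")
  pruned <- prune_rule(rule, m, labels)
  expect_length(pruned$conditions, 1)
  expect_equal(pruned$conditions[[1]]$feature_id, "miR-01")

  # a single-condition rule covering only positives is kept unchanged
  keep <- structure(list(conditions = list(
    list(feature_id = "miR-01", op = ">=", threshold = 10)),
    class = "adenocarcinoma"), class = "ripper_rule")
  expect_equal(prune_rule(keep, m, labels), keep)
})

test_that("single-class input yields an empty ruleset with that default", {
  m <- make_matrix(matrix(1:8, nrow = 2))
  pure <- label_vector(rep("granuloma", 4), sprintf("s%02d", 1:4),
                       positive = "adenocarcinoma", negative = "granuloma")
  rs <- train_ripper(m, pure)
  expect_length(rs$rules, 0)
  expect_equal(rs$default_class, "granuloma")
  expect_equal(unname(predict(rs, m)), rep("granuloma", 4))
})

test_that("a planted presence/absence marker is recovered with zero training error", {
  ds <- planted_dataset(seed = 19, n_features = 12, effect = 300)
  rs <- train_ripper(ds$expression, ds$labels)
  pred <- predict(rs, ds$expression)
  expect_equal(unname(pred), as.character(ds$labels))
  # minority class (granuloma, 9 of 19) carries the explicit rule
  expect_equal(rs$target_class, "granuloma")
  expect_equal(rs$default_class, "adenocarcinoma")
  # the separating rule keys on the marker's absence
  all_feats <- unlist(lapply(rs$rules, function(r)
    vapply(r$conditions, `[[`, character(1), "feature_id")))
  expect_true("syn-miR-0003" %in% all_feats)
})

test_that("1-D separable data is solved with training error zero for any seed", {
  m <- make_matrix(matrix(c(6, 7, 8, 9, 10, 1, 2, 3, 4), nrow = 1))
  labels <- make_labels(5, 4)
  for (seed in 1:10) {
    rs <- train_ripper(m, labels, ripper_params(seed = seed))
    expect_equal(unname(predict(rs, m)), as.character(labels),
                 label = sprintf("seed %d", seed))
  }
})

test_that("the ruleset never underperforms the majority-class baseline on training data", {
  for (seed in 1:6) {
    set.seed(seed * 37)
    n_pos <- sample(3:10, 1)
    n_neg <- sample(3:10, 1)
    m <- make_matrix(matrix(runif(6 * (n_pos + n_neg), 0, 50), nrow = 6))
    labels <- make_labels(n_pos, n_neg)
    rs <- train_ripper(m, labels, ripper_params(seed = seed))
    err <- mean(predict(rs, m) != as.character(labels))
    base <- min(n_pos, n_neg) / (n_pos + n_neg)
    expect_lte(err, base + 1e-12, label = sprintf("seed %d", seed))
  }
})

test_that("prediction is pure and errors on missing features", {
  ds <- planted_dataset(seed = 23, n_features = 10, effect = 200)
  rs <- train_ripper(ds$expression, ds$labels)
  p1 <- predict(rs, ds$expression)
  p2 <- predict(rs, ds$expression)
  expect_identical(p1, p2)
  expect_error(predict(rs, ds$expression[setdiff(rownames(ds$expression), "syn-miR-0003"), ]),
               "missing feature")
  # single named sample vector works
  expect_type(predict(rs, ds$expression[, 1]), "character")
})

test_that("rulesets render like a decision list and round-trip through text", {
  rs <- structure(list(
    rules = list(structure(list(conditions = list(
      list(feature_id = "hsa-miR-23b-3p", op = ">=", threshold = 210.43)),
      class = "granuloma"), class = "ripper_rule")),
    default_class = "adenocarcinoma", target_class = "granuloma",
    params = NULL), class = "ripper_ruleset")
  txt <- format(rs)
  expect_equal(txt, c("granuloma: hsa-miR-23b-3p >= 210.43",
                      "adenocarcinoma: otherwise"))
  back <- parse_ruleset(txt)
  expect_equal(back$rules, rs$rules)
  expect_equal(back$default_class, "adenocarcinoma")

  # a sample above the threshold matches the rule; one below falls through
  sample_hi <- c("hsa-miR-23b-3p" = 250)
  sample_lo <- c("hsa-miR-23b-3p" = 100)
  expect_equal(unname(predict(rs, sample_hi)), "granuloma")
  expect_equal(unname(predict(rs, sample_lo)), "adenocarcinoma")

  # thresholds with many digits survive the round-trip losslessly
  rs$rules[[1]]$conditions[[1]]$threshold <- 1 / 3
  expect_equal(parse_ruleset(format(rs))$rules[[1]]$conditions[[1]]$threshold, 1 / 3)
})
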