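#' Shannon entropy of a class multiset, in bits
#'
#' @param labels vector (character/factor) of class labels; must be non-empty.
#' @return entropy in bits; 0 for a pure set.
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0L) stop("entropy of an empty set is undefined")
  p <- tabulate(factor(as.character(labels)))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

# entropy of binary (pos, neg) count vectors, vectorized
ent_counts <- function(p, n) {
  tot <- p + n
  tot[tot == 0] <- 1
  pp <- p / tot
  pn <- n / tot
  a <- pp * log2(pp)
  a[pp == 0] <- 0
  b <- pn * log2(pn)
  b[pn == 0] <- 0
  -a - b
}

#' Information gain of a binary partition, in bits
#'
#' Parent entropy minus the size-weighted entropies of the two sides. The two
#' index sets must partition `seq_along(labels)` exactly; an empty side is
#' allowed and yields gain 0.
#'
#' @param labels class labels.
#' @param left,right integer index vectors forming the partition.
#' @return information gain in bits (non-negative up to rounding).
#' @export
information_gain <- function(labels, left, right) {
  n <- length(labels)
  idx <- c(left, right)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(n)) || length(idx) != n)
    stop("left/right must partition the label indices exactly")
  h <- entropy_bits(labels)
  hl <- if (length(left)) entropy_bits(labels[left]) else 0
  hr <- if (length(right)) entropy_bits(labels[right]) else 0
  h - length(left) / n * hl - length(right) / n * hr
}

# Best (feature, threshold) split of x (samples x features) for binary y
# (logical, TRUE = positive). Candidate thresholds are midpoints between
# consecutive distinct sorted values; "<= threshold" goes left. Ties are
# broken toward the first feature in column order, then the lowest threshold.
best_split <- function(x, y) {
  n <- length(y)
  m <- ncol(x)
  P <- sum(y)
  parent <- ent_counts(P, n - P)
  # sort every feature column in one radix pass
  ord <- order(rep.int(seq_len(m), rep.int(n, m)), as.vector(x),
               method = "radix")
  vs <- matrix(as.vector(x)[ord], n, m)
  ys <- matrix(y[(ord - 1L) %% n + 1L], n, m)
  cs <- matrix(cumsum(as.vector(ys)), n, m)
  if (m > 1) cs <- cs - matrix(rep(c(0, cs[n, -m]), each = n), n, m)
  # candidate split after sorted position k (1..n-1), only where the value
  # actually changes (midpoint thresholds between distinct values)
  kmat <- matrix(seq_len(n - 1L), n - 1L, m)
  pl <- cs[-n, , drop = FALSE]
  nl <- kmat - pl
  ig <- parent - (kmat / n) * ent_counts(pl, nl) -
    ((n - kmat) / n) * ent_counts(P - pl, (n - P) - nl)
  ig[vs[-n, , drop = FALSE] >= vs[-1, , drop = FALSE]] <- -Inf
  bi <- which.max(ig)  # column-major: lowest threshold, then first feature
  if (!length(bi) || ig[bi] <= 1e-12) return(NULL)
  k0 <- (bi - 1L) %% (n - 1L) + 1L
  feat <- (bi - 1L) %/% (n - 1L) + 1L
  list(feature = feat, threshold = (vs[k0, feat] + vs[k0 + 1L, feat]) / 2,
       ig = ig[bi])
}

#' Grow a binary information-gain decision tree
#'
#' At every node the (feature, threshold) pair maximizing information gain is
#' chosen over candidate thresholds placed midway between consecutive distinct
#' observed values; samples with `value <= threshold` go left. Nodes are split
#' until pure, smaller than `min_split`, or until no split gains information;
#' leaves carry the majority class (ties go to the positive class). If a test
#' set is supplied, the tree's weighted accuracy (mean of per-class accuracies
#' over the classes present in the test set) is computed.
#'
#' @param m expression matrix (features x samples) restricted to the
#'   features under consideration.
#' @param labels a [label_vector()] for the training samples.
#' @param test_m,test_labels optional held-out split for the weighted
#'   accuracy.
#' @param min_split minimum node size eligible for splitting (default 2).
#' @return object of class `"tree_model"`: `root` (nested node list), `nodes`
#'   (data frame of internal nodes: feature_id, threshold, ig, n_node),
#'   `n_tree` (training-set size), and `wacc` (weighted accuracy on the test
#'   split, or `NA` if none given).
#' @export
build_tree <- function(m, labels, test_m = NULL, test_labels = NULL,
                       min_split = 2) {
  if (ncol(m) < 2L) stop("at least 2 training samples are required")
  if (ncol(m) != length(labels)) stop("labels must match the matrix columns")
  x <- t(m)
  pos_name <- positive_class(labels)
  neg_name <- negative_class(labels)
  y <- as.character(labels) == pos_name

  records <- list()
  grow <- function(idx) {
    p <- sum(y[idx])
    q <- length(idx) - p
    majority <- if (p >= q) pos_name else neg_name
    if (p == 0L || q == 0L || length(idx) < min_split)
      return(list(leaf = TRUE, class = majority, n_node = length(idx)))
    sp <- best_split(x[idx, , drop = FALSE], y[idx])
    if (is.null(sp))
      return(list(leaf = TRUE, class = majority, n_node = length(idx)))
    fid <- colnames(x)[sp$feature]
    records[[length(records) + 1L]] <<- data.frame(
      feature_id = fid, threshold = sp$threshold, ig = sp$ig,
      n_node = length(idx), stringsAsFactors = FALSE)
    go_left <- x[idx, sp$feature] <= sp$threshold
    list(leaf = FALSE, feature_id = fid, threshold = sp$threshold,
         ig = sp$ig, n_node = length(idx),
         left = grow(idx[go_left]), right = grow(idx[!go_left]))
  }
  root <- grow(seq_len(nrow(x)))
  nodes <- if (length(records)) do.call(rbind, records) else
    data.frame(feature_id = character(), threshold = numeric(),
               ig = numeric(), n_node = integer(), stringsAsFactors = FALSE)

  wacc <- NA_real_
  if (!is.null(test_m)) {
    pred <- predict_tree(root, test_m)
    wacc <- weighted_accuracy_present(as.character(test_labels), pred,
                                      pos_name, neg_name)
  }
  structure(list(root = root, nodes = nodes, n_tree = nrow(x), wacc = wacc),
            class = "tree_model")
}

#' Predict classes from a decision tree
#'
#' @param root a tree node as produced by [build_tree()] (`$root`).
#' @param m expression matrix (features x samples) containing at least the
#'   features the tree splits on.
#' @return character vector of predicted classes, one per sample.
#' @export
predict_tree <- function(root, m) {
  one <- function(node, values) {
    while (!node$leaf) {
      node <- if (values[[node$feature_id]] <= node$threshold) node$left else node$right
    }
    node$class
  }
  vapply(seq_len(ncol(m)), function(j) one(root, m[, j]), character(1))
}

# mean per-class accuracy over the classes actually present in `truth`
weighted_accuracy_present <- function(truth, pred, pos_name, neg_name) {
  accs <- c()
  for (cl in c(neg_name, pos_name)) {
    actual <- truth == cl
    if (any(actual)) accs <- c(accs, mean(pred[actual] == cl))
  }
  mean(accs)
}

#' Parameters for Monte-Carlo feature selection
#'
#' Defaults follow the conventional regime for high-dimensional, small-cohort
#' expression data: each projection draws `m = ceiling(0.05 * d)` of the `d`
#' features, `t = 5` trees are grown per projection on independent stratified
#' train/test splits, and the number of projections `s` defaults to
#' `ceiling(20 * d / m)` so each feature is expected in at least 20
#' projections. The relative-importance exponents default to `u = 1`
#' (tree-accuracy weight) and `v = 1` (node-size weight).
#'
#' @param m features per projection (`NULL` = `ceiling(0.05 * d)`).
#' @param s number of projections (`NULL` = `ceiling(20 * d / m)`).
#' @param t trees per projection.
#' @param u exponent on the tree's weighted accuracy.
#' @param v exponent on the node sample fraction.
#' @param train_fraction share of samples used to grow each tree.
#' @param min_split minimum node size eligible for splitting.
#' @param seed integer seed for the projection/split substreams.
#' @return an object of class `"mcfs_params"`.
#' @export
mcfs_params <- function(m = NULL, s = NULL, t = 5, u = 1, v = 1,
                        train_fraction = 0.66, min_split = 2, seed = 1L) {
  stopifnot(t >= 1, u >= 0, v >= 0,
            train_fraction > 0, train_fraction < 1)
  if (!is.null(s)) stopifnot(s >= 1)
  if (!is.null(m)) stopifnot(m >= 1)
  structure(list(m = m, s = s, t = as.integer(t), u = u, v = v,
                 train_fraction = train_fraction,
                 min_split = as.integer(min_split), seed = as.integer(seed)),
            class = "mcfs_params")
}

# stratified train/test split on the current RNG stream; each class keeps at
# least one sample on each side whenever it has two or more members
stratified_split <- function(labels, fraction) {
  train <- integer(0)
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    n_c <- length(idx)
    n_train <- if (n_c == 1L) 1L else min(max(1L, round(fraction * n_c)), n_c - 1L)
    train <- c(train, sample(idx, n_train))
  }
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

#' Monte-Carlo feature selection
#'
#' Draws `s` random projections of `m` features, grows `t` decision trees per
#' projection (each on its own stratified train/test split), and scores every
#' feature's relative importance
#' \deqn{RI_g = \sum_{\tau} (wAcc_\tau)^u \sum_{n_g(\tau)}
#'   IG(n_g(\tau)) \left(\frac{\mathrm{no.\ in\ } n_g(\tau)}
#'   {\mathrm{no.\ in\ }\tau}\right)^v}
#' summing, over every node of every tree that splits on feature *g*, the
#' node's information gain weighted by the tree's held-out weighted accuracy
#' (power `u`) and the node's share of the tree's training samples (power
#' `v`).
#'
#' Each projection uses a counter-based seed substream derived from
#' `params$seed` and its projection index, so a run split into batches (via
#' `projection_offset`) reproduces exactly the trees of one combined run.
#'
#' @param m expression matrix (features x samples).
#' @param labels a [label_vector()].
#' @param params an [mcfs_params()] object.
#' @param projection_offset index offset for the projection substreams
#'   (default 0); batch `i` of size `s` should pass offset `(i-1) * s`.
#' @param return_trees if `TRUE`, attach the full list of fitted trees (with
#'   their projections) as attribute `"trees"` for auditing.
#' @return an `ri_table`: data frame with columns `feature_id`, `ri`,
#'   `times_sampled` (projections containing the feature), `times_used`
#'   (node appearances) and `rank`.
#' @export
run_mcfs <- function(m, labels, params = mcfs_params(),
                     projection_offset = 0L, return_trees = FALSE) {
  validate_expression_matrix(m)
  if (ncol(m) != length(labels)) stop("labels must match the matrix columns")
  check_both_classes(labels)
  d <- nrow(m)
  mm <- if (is.null(params$m)) ceiling(0.05 * d) else params$m
  if (mm >= d) stop(sprintf("projection size m = %d must be smaller than d = %d", mm, d))
  s <- if (is.null(params$s)) ceiling(20 * d / mm) else params$s

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  ri <- stats::setNames(numeric(d), rownames(m))
  times_sampled <- stats::setNames(integer(d), rownames(m))
  times_used <- stats::setNames(integer(d), rownames(m))
  trees <- if (return_trees) vector("list", s * params$t) else NULL

  for (i in seq_len(s)) {
    set.seed(substream_seed(params$seed, projection_offset + i))
    proj <- sample.int(d, mm)
    times_sampled[proj] <- times_sampled[proj] + 1L
    sub <- m[proj, , drop = FALSE]
    for (tt in seq_len(params$t)) {
      sp <- stratified_split(labels, params$train_fraction)
      tm <- build_tree(sub[, sp$train, drop = FALSE], labels[sp$train],
                       sub[, sp$test, drop = FALSE], labels[sp$test],
                       min_split = params$min_split)
      if (return_trees) trees[[(i - 1L) * params$t + tt]] <-
          list(projection = rownames(m)[proj], tree = tm)
      nodes <- tm$nodes
      if (!nrow(nodes)) next
      contrib <- tm$wacc^params$u * nodes$ig *
        (nodes$n_node / tm$n_tree)^params$v
      add <- rowsum(contrib, nodes$feature_id)
      ri[rownames(add)] <- ri[rownames(add)] + add[, 1]
      cnt <- table(nodes$feature_id)
      times_used[names(cnt)] <- times_used[names(cnt)] + as.integer(cnt)
    }
  }

  out <- data.frame(feature_id = rownames(m), ri = unname(ri),
                    times_sampled = unname(times_sampled),
                    times_used = unname(times_used),
                    stringsAsFactors = FALSE)
  ord <- order(-out$ri, out$feature_id, method = "radix")
  out$rank <- integer(d)
  out$rank[ord] <- seq_len(d)
  class(out) <- c("ri_table", "data.frame")
  attr(out, "params") <- list(m = mm, s = s, t = params$t, u = params$u,
                              v = params$v,
                              train_fraction = params$train_fraction,
                              seed = params$seed,
                              projection_offset = projection_offset)
  if (return_trees) attr(out, "trees") <- trees
  out
}

#' Rank features by decreasing relative importance
#'
#' Ties are broken lexicographically (C locale) by feature id, so the ranking
#' is fully deterministic.
#'
#' @param ri_table an `ri_table` from [run_mcfs()].
#' @return character vector of feature ids, most important first.
#' @export
rank_features <- function(ri_table) {
  if (!nrow(ri_table)) stop("empty relative-importance table")
  ri_table$feature_id[order(-ri_table$ri, ri_table$feature_id, method = "radix")]
}

#' Write a relative-importance report as TSV
#'
#' @param ri_table an `ri_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ri_table <- function(ri_table, path) {
  ord <- order(ri_table$rank)
  utils::write.table(as.data.frame(ri_table)[ord, c("feature_id", "ri",
                                                    "times_sampled",
                                                    "times_used", "rank")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
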