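# Small fixtures and independent oracles shared across test files.

make_matrix <- function(values, features = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(features)) features <- sprintf("miR-%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, features, samples)
}

make_labels <- function(n_pos, n_neg, ids = NULL) {
  classes <- c(rep("adenocarcinoma", n_pos), rep("granuloma", n_neg))
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(classes))
  label_vector(classes, ids)
}

# closed-form binary entropy in bits, independent of the package
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# exhaustive best (feature, threshold-midpoint) split by information gain
oracle_best_split <- function(m, labels) {
  y <- as.character(labels)
  n <- length(y)
  parent <- oracle_entropy(table(y))
  best <- list(ig = -Inf)
  for (f in rownames(m)) {
    v <- m[f, ]
    vs <- sort(unique(v))
    if (length(vs) < 2) next
    for (thr in (vs[-1] + vs[-length(vs)]) / 2) {
      left <- v <= thr
      ig <- parent -
        mean(left) * oracle_entropy(table(y[left])) -
        mean(!left) * oracle_entropy(table(y[!left]))
      if (ig > best$ig + 1e-12) best <- list(feature = f, threshold = thr, ig = ig)
    }
  }
  best
}

# greedy Ward.D2 agglomeration via the Lance-Williams recurrence, starting
# from Euclidean distances; returns the merge heights in order
oracle_ward_heights <- function(points) {
  n <- nrow(points)
  d2 <- as.matrix(dist(points))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) for (b in seq_len(a - 1)) {
      i <- active[a]; j <- active[b]
      if (d2[i, j] < best[1] - 1e-12) best <- c(d2[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# tiny planted-marker dataset used by several files
planted_dataset <- function(seed = 11, n_features = 60, effect = 200) {
  cfg <- synthetic_config(n_features = n_features,
                          markers = list(marker_spec(3, "on_off_positive", effect)),
                          seed = seed)
  generate_compartment_dataset(cfg)
}
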