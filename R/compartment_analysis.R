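#' Overlaps among top-k feature lists
#'
#' Takes the k-prefix of each compartment's ranked feature list and computes
#' all pairwise intersections plus the intersection of all lists — the
#' numbers a Venn diagram of compartment signatures displays.
#'
#' @param lists named list of ordered feature-id vectors (one per
#'   compartment), each with at least `k` entries.
#' @param k prefix length.
#' @return object of class `"venn_result"`: list with `k`, `sets` (the
#'   k-prefixes), `sizes`, `pairwise` (named list of intersection vectors,
#'   names `"A|B"`), and `common` (intersection of all sets).
#' @export
venn_overlaps <- function(lists, k) {
  if (length(lists) < 1L || is.null(names(lists)))
    stop("lists must be a named list of ranked feature vectors")
  short <- names(lists)[vapply(lists, length, integer(1)) < k]
  if (length(short))
    stop("list(s) shorter than k = ", k, ": ", paste(short, collapse = ", "))
  sets <- lapply(lists, function(x) x[seq_len(k)])
  pairs <- if (length(sets) >= 2) utils::combn(names(sets), 2, simplify = FALSE) else list()
  pairwise <- stats::setNames(
    lapply(pairs, function(p) intersect(sets[[p[1]]], sets[[p[2]]])),
    vapply(pairs, paste, character(1), collapse = "|"))
  structure(list(k = k, sets = sets,
                 sizes = vapply(sets, length, integer(1)),
                 pairwise = pairwise,
                 common = Reduce(intersect, sets)),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("top-%d overlaps across %d lists\n", x$k, length(x$sets)))
  for (nm in names(x$pairwise))
    cat(sprintf("  %-30s %d  %s\n", nm, length(x$pairwise[[nm]]),
                paste(x$pairwise[[nm]], collapse = ", ")))
  cat(sprintf("  %-30s %d  %s\n", "all", length(x$common),
              paste(x$common, collapse = ", ")))
  invisible(x)
}

#' Class mean expression of one feature
#'
#' Arithmetic means on the stored expression scale, per class, plus the
#' negative/positive fold change when defined.
#'
#' @param m expression matrix.
#' @param labels a [label_vector()].
#' @param feature_id the feature to summarize.
#' @return list with `feature_id`, `mean_positive`, `mean_negative`,
#'   `fold_change` (`NA` when undefined) and `fold_defined`.
#' @export
class_means <- function(m, labels, feature_id) {
  if (!feature_id %in% rownames(m)) stop("unknown feature: ", feature_id)
  check_both_classes(labels)
  v <- m[feature_id, ]
  pos <- as.character(labels) == positive_class(labels)
  mp <- mean(v[pos])
  mn <- mean(v[!pos])
  list(feature_id = feature_id, mean_positive = mp, mean_negative = mn,
       fold_change = if (mp > 0) mn / mp else NA_real_,
       fold_defined = mp > 0)
}

#' Fold change from a class-means report
#'
#' Negative-class mean over positive-class mean. When the positive-class mean
#' is zero the ratio is undefined; the report then flags it rather than
#' returning an infinity (mirroring the convention of reporting the two means
#' instead of a ratio).
#'
#' @param report output of [class_means()].
#' @return the ratio, or `NA` with `fold_defined = FALSE` in the report.
#' @export
fold_change <- function(report) {
  if (!isTRUE(report$fold_defined)) return(NA_real_)
  report$mean_negative / report$mean_positive
}

#' Ward.D2 hierarchical clustering of samples
#'
#' Agglomerates samples by the Ward.D2 criterion on Euclidean distances
#' (Lance–Williams updates consistent with squared Euclidean merge costs), as
#' used to order compartment heatmaps, and cuts the tree into `n_clusters`
#' groups. Typically run on the top-k feature submatrix.
#'
#' @param m expression matrix (features x samples); samples are clustered.
#' @param n_clusters number of clusters to cut (default 2).
#' @param scale_rows z-score features before clustering (default `FALSE`:
#'   cluster on the stored expression scale).
#' @return list with `hclust` (the [stats::hclust] object), `merges` (data
#'   frame: step, cluster_a, cluster_b, height, size), and `assignment`
#'   (integer cluster per sample, named).
#' @export
ward_cluster <- function(m, n_clusters = 2, scale_rows = FALSE) {
  validate_expression_matrix(m)
  if (ncol(m) < 2L) stop("at least 2 samples are required")
  if (ncol(m) < n_clusters)
    stop(sprintf("cannot cut %d samples into %d clusters", ncol(m), n_clusters))
  vals <- m
  if (scale_rows) {
    sds <- apply(vals, 1, stats::sd)
    sds[sds == 0] <- 1
    vals <- (vals - rowMeans(vals)) / sds
  }
  hc <- stats::hclust(stats::dist(t(vals), method = "euclidean"),
                      method = "ward.D2")
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    count <- function(j) if (j < 0) 1L else sizes[j]
    sizes[i] <- count(hc$merge[i, 1]) + count(hc$merge[i, 2])
  }
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       cluster_a = hc$merge[, 1], cluster_b = hc$merge[, 2],
                       height = hc$height, size = sizes)
  list(hclust = hc, merges = merges,
       assignment = stats::cutree(hc, k = n_clusters))
}

#' Count miss-clustered samples against the class labels
#'
#' With two clusters and two classes, the cluster-to-class mapping is
#' ambiguous; both mappings are evaluated and the one with fewer
#' misassignments is reported (on a 50/50 tie the count is the same either
#' way). The count is invariant under cluster relabeling.
#'
#' @param assignment integer cluster labels (exactly 2 distinct values),
#'   named by sample id or aligned with `labels`.
#' @param labels a [label_vector()].
#' @return list with `total`, `per_class` (named counts of miss-clustered
#'   samples for the chosen mapping), and `mapping` (cluster -> class).
#' @export
count_missclustered <- function(assignment, labels) {
  clusters <- sort(unique(assignment))
  if (length(clusters) != 2L)
    stop("exactly 2 clusters are required; got ", length(clusters))
  if (length(assignment) != length(labels))
    stop("assignment and labels must align")
  truth <- as.character(labels)
  classes <- c(negative_class(labels), positive_class(labels))
  mappings <- list(stats::setNames(classes, clusters),
                   stats::setNames(rev(classes), clusters))
  miss <- vapply(mappings, function(mp)
    sum(mp[as.character(assignment)] != truth), numeric(1))
  best <- mappings[[which.min(miss)]]
  wrong <- best[as.character(assignment)] != truth
  per_class <- vapply(classes, function(cl) sum(wrong & truth == cl), numeric(1))
  list(total = unname(min(miss)), per_class = per_class, mapping = best)
}
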