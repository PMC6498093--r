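#' Parameters for RIPPER rule induction
#'
#' All constants follow the canonical published algorithm (IREP* growing and
#' pruning, MDL-based stopping, optimization passes) and are config-exposed.
#'
#' @param prune_fraction share of the training data held out for rule pruning
#'   (default 1/3).
#' @param min_coverage minimum number of training instances a rule must cover
#'   (default 2).
#' @param dl_slack description-length stopping slack in bits (default 64):
#'   rule adding stops once the ruleset's total description length exceeds the
#'   best length seen so far by more than this.
#' @param n_optimizations number of optimization passes over the ruleset
#'   (default 2).
#' @param seed integer seed for the grow/prune splits.
#' @return an object of class `"ripper_params"`.
#' @export
ripper_params <- function(prune_fraction = 1 / 3, min_coverage = 2,
                          dl_slack = 64, n_optimizations = 2, seed = 1L) {
  stopifnot(prune_fraction > 0, prune_fraction < 1, min_coverage >= 1,
            dl_slack >= 0, n_optimizations >= 0)
  structure(list(prune_fraction = prune_fraction,
                 min_coverage = as.integer(min_coverage),
                 dl_slack = dl_slack,
                 n_optimizations = as.integer(n_optimizations),
                 seed = as.integer(seed)),
            class = "ripper_params")
}

#' FOIL information gain of a rule refinement
#'
#' The grow-phase criterion: a candidate condition shrinking a rule's
#' coverage from (`p0` positives, `n0` negatives) to (`p`, `n`) scores
#' `p * (log2(p / (p + n)) - log2(p0 / (p0 + n0)))` bits; the gain is `-Inf`
#' when the refined rule covers no positives.
#'
#' @param p0,n0 positives/negatives covered before the refinement.
#' @param p,n positives/negatives covered after (`p <= p0`, `n <= n0`).
#' @return gain in bits (`-Inf` if `p == 0`).
#' @export
foil_gain <- function(p0, n0, p, n) {
  stopifnot(p0 >= 0, n0 >= 0, p >= 0, n >= 0, p <= p0, n <= n0)
  if (p == 0) return(-Inf)
  p * (log2(p / (p + n)) - log2(p0 / (p0 + n0)))
}

new_condition <- function(feature_id, op, threshold) {
  stopifnot(op %in% c("<=", ">="), is.finite(threshold))
  list(feature_id = feature_id, op = op, threshold = threshold)
}

condition_holds <- function(cond, x) {
  if (!cond$feature_id %in% colnames(x))
    stop("sample(s) missing feature referenced by rule: ", cond$feature_id)
  if (cond$op == "<=") x[, cond$feature_id] <= cond$threshold
  else x[, cond$feature_id] >= cond$threshold
}

# x: samples x features; returns logical coverage vector of the conjunction
rule_covers <- function(conditions, x) {
  ok <- rep(TRUE, nrow(x))
  for (cond in conditions) ok <- ok & condition_holds(cond, x)
  ok
}

# All candidate single conditions on the covered subset of one feature, with
# their FOIL gains; thresholds are placed at observed data values.
feature_candidate_gains <- function(v, y, p0, n0) {
  o <- order(v)
  vs <- v[o]
  ys <- y[o]
  n_all <- length(vs)
  cp <- cumsum(ys)
  last <- which(c(vs[-1] > vs[-n_all], TRUE))   # last index of each distinct value
  first <- c(1L, last[-length(last)] + 1L)      # first index of each distinct value
  vals <- vs[last]
  # "<= v": covers sorted positions 1..last(v)
  p_le <- cp[last]
  n_le <- last - p_le
  # ">= v": covers sorted positions first(v)..n
  cp0 <- c(0, cp)
  p_ge <- sum(ys) - cp0[first]
  n_ge <- (n_all - first + 1L) - p_ge
  gain <- function(p, n) ifelse(p == 0, -Inf,
                                p * (log2(p / (p + n)) - log2(p0 / (p0 + n0))))
  data.frame(op = rep(c("<=", ">="), each = length(vals)),
             threshold = c(vals, vals),
             gain = c(gain(p_le, n_le), gain(p_ge, n_ge)),
             stringsAsFactors = FALSE)
}

#' Grow a single rule by FOIL gain
#'
#' Starting from the empty conjunction, greedily adds the condition with the
#' highest FOIL gain (candidate thresholds are the observed feature values in
#' the currently covered grow set, with both `<=` and `>=`), until the rule
#' covers no negative grow-set samples or no condition has positive gain.
#' Ties are broken lexicographically by (feature id, op, threshold). A second
#' condition on the same (feature, op) replaces the first (it can only
#' tighten it).
#'
#' @param m expression matrix (features x samples) of the grow set.
#' @param labels labels of the grow set.
#' @param target_class the class the rule predicts.
#' @return an object of class `"ripper_rule"`: list with `conditions` and
#'   `class`.
#' @export
grow_rule <- function(m, labels, target_class) {
  x <- t(m)
  y <- as.character(labels) == target_class
  if (!any(y)) stop("grow set contains no '", target_class, "' sample")
  feat_order <- sort(colnames(x), method = "radix")
  covered <- rep(TRUE, nrow(x))
  conditions <- list()
  repeat {
    p0 <- sum(y[covered])
    n0 <- sum(covered) - p0
    if (n0 == 0 || p0 == 0) break
    best <- NULL
    best_gain <- 0
    for (fid in feat_order) {
      cand <- feature_candidate_gains(x[covered, fid], y[covered], p0, n0)
      cand <- cand[order(cand$op, cand$threshold, method = "radix"), ]
      jm <- which.max(cand$gain)
      if (length(jm) && cand$gain[jm] > best_gain + 1e-12) {
        best_gain <- cand$gain[jm]
        best <- new_condition(fid, cand$op[jm], cand$threshold[jm])
      }
    }
    if (is.null(best)) break
    dup <- which(vapply(conditions, function(cc)
      cc$feature_id == best$feature_id && cc$op == best$op, logical(1)))
    if (length(dup)) conditions[[dup[1]]] <- best
    else conditions[[length(conditions) + 1L]] <- best
    covered <- covered & condition_holds(best, x)
  }
  structure(list(conditions = conditions, class = target_class),
            class = "ripper_rule")
}

prune_metric <- function(conditions, x, y) {
  cov <- rule_covers(conditions, x)
  tot <- sum(cov)
  if (tot == 0) return(-1)
  p <- sum(y[cov])
  (p - (tot - p)) / tot
}

#' Prune a rule on held-out data
#'
#' Evaluates every final-segment deletion of the rule's conditions (keeping
#' conditions `1..j` for `j = 0, ..., K`) with the pruning metric
#' `(p - n) / (p + n)` on the prune set (−1 when the rule covers nothing) and
#' keeps the prefix with the highest metric; ties favor the shorter rule, so
#' a deletion that does not decrease the metric is always taken. The empty
#' rule is allowed.
#'
#' @param rule a `ripper_rule` from [grow_rule()].
#' @param m expression matrix (features x samples) of the prune set.
#' @param labels labels of the prune set.
#' @return the pruned `ripper_rule`.
#' @export
prune_rule <- function(rule, m, labels) {
  x <- t(m)
  y <- as.character(labels) == rule$class
  K <- length(rule$conditions)
  metrics <- vapply(0:K, function(j)
    prune_metric(rule$conditions[seq_len(j)], x, y), numeric(1))
  keep <- which.max(metrics) - 1L  # which.max takes the first (shortest prefix)
  rule$conditions <- rule$conditions[seq_len(keep)]
  rule
}

# ---- description length (MDL) ------------------------------------------------

log2_safe <- function(z) ifelse(z <= 0, 0, log2(z))

# bits to identify a k-subset of t elements, elements marked with probability p
subset_dl <- function(t, k, p) {
  bits <- 0
  if (k > 0) bits <- bits - k * log2_safe(p)
  if (t - k > 0) bits <- bits - (t - k) * log2_safe(1 - p)
  bits
}

# encoding cost of one rule with k conditions out of n_possible candidates
theory_dl <- function(k, n_possible) {
  if (k == 0) return(0)
  tdl <- log2_safe(k)
  if (k > 1 && tdl > 0) tdl <- tdl + 2 * log2_safe(tdl)
  tdl <- tdl + subset_dl(n_possible, k, k / n_possible)
  0.5 * tdl
}

# cost of encoding the exceptions (false positives among covered, false
# negatives among uncovered) of a ruleset for the target class
data_dl <- function(cover, uncover, fp, fn, exp_fp_rate = 0.5) {
  total_bits <- log2_safe(cover + uncover + 1)
  exp_err <- exp_fp_rate * (fp + fn)
  if (cover > uncover) {
    cover_bits <- if (cover > 0) subset_dl(cover, fp, exp_err / cover) else 0
    uncover_bits <- if (uncover > 0) subset_dl(uncover, fn, fn / uncover) else 0
  } else {
    cover_bits <- if (cover > 0) subset_dl(cover, fp, fp / cover) else 0
    uncover_bits <- if (uncover > 0) subset_dl(uncover, fn, exp_err / uncover) else 0
  }
  total_bits + cover_bits + uncover_bits
}

ruleset_dl <- function(rules, x, y, n_possible) {
  cov <- rep(FALSE, nrow(x))
  theory <- 0
  for (r in rules) {
    cov <- cov | rule_covers(r$conditions, x)
    theory <- theory + theory_dl(length(r$conditions), n_possible)
  }
  fp <- sum(cov & !y)
  fn <- sum(!cov & y)
  theory + data_dl(sum(cov), sum(!cov), fp, fn)
}

count_possible_conditions <- function(x) {
  sum(apply(x, 2, function(v) 2L * length(unique(v))))
}

# ---- the full learner --------------------------------------------------------

grow_prune_once <- function(x, y_lab, remaining, target, params, extend = NULL) {
  lab_r <- y_lab[remaining]
  sp <- stratified_split(lab_r, 1 - params$prune_fraction)
  grow_idx <- remaining[sp$train]
  prune_idx <- remaining[sp$test]
  if (!any(as.character(y_lab[grow_idx]) == target) || length(prune_idx) == 0)
    return(NULL)
  grown <- if (is.null(extend)) {
    grow_rule(t(x[grow_idx, , drop = FALSE]), y_lab[grow_idx], target)
  } else {
    extend_rule(extend, x[grow_idx, , drop = FALSE], y_lab[grow_idx])
  }
  rule <- prune_rule(grown, t(x[prune_idx, , drop = FALSE]), y_lab[prune_idx])
  cov_p <- rule_covers(rule$conditions, x[prune_idx, , drop = FALSE])
  err <- if (!any(cov_p)) 1 else
    mean(as.character(y_lab[prune_idx])[cov_p] != target)
  list(rule = rule, grown = grown, prune_error = err)
}

# revision variant of the optimization pass: keep the existing conditions and
# continue growing from them
extend_rule <- function(rule, x_grow, labels_grow) {
  covered <- rule_covers(rule$conditions, x_grow)
  if (!any(covered))
    return(rule)
  sub <- x_grow[covered, , drop = FALSE]
  grown <- grow_rule(t(sub), labels_grow[covered], rule$class)
  rule$conditions <- c(rule$conditions, grown$conditions)
  # deduplicate (feature, op) pairs, keeping the later (tighter) condition
  if (length(rule$conditions) > 1) {
    keys <- vapply(rule$conditions, function(cc)
      paste(cc$feature_id, cc$op), character(1))
    rule$conditions <- rule$conditions[!duplicated(keys, fromLast = TRUE)]
  }
  rule
}

irep_star <- function(x, y_lab, target, params, n_possible, rules = list(),
                      min_dl = NULL) {
  y <- as.character(y_lab) == target
  covered <- rep(FALSE, nrow(x))
  for (r in rules) covered <- covered | rule_covers(r$conditions, x)
  if (is.null(min_dl)) min_dl <- ruleset_dl(rules, x, y, n_possible)
  admissible <- function(rule, remaining) {
    # must cover new positives, satisfy min_coverage on the full training
    # data, and misclassify under half of what it covers on remaining data
    cov_rem <- rule_covers(rule$conditions, x[remaining, , drop = FALSE])
    if (!any(cov_rem & y[remaining])) return(NULL)
    if (sum(rule_covers(rule$conditions, x)) < params$min_coverage) return(NULL)
    if (mean(!y[remaining][cov_rem]) >= 0.5) return(NULL)
    cov_rem
  }
  repeat {
    remaining <- which(!covered)
    if (!any(y[remaining])) break
    gp <- grow_prune_once(x, y_lab, remaining, target, params)
    if (is.null(gp)) break
    rule <- gp$rule
    cov_rem <- if (gp$prune_error < 0.5) admissible(rule, remaining) else NULL
    if (is.null(cov_rem)) {
      # the prune split carried no usable evidence (tiny cohorts): fall back
      # to the unpruned grown rule, judged on all remaining training data
      rule <- gp$grown
      cov_rem <- admissible(rule, remaining)
      if (is.null(cov_rem)) break
    }
    cand <- c(rules, list(rule))
    dl <- ruleset_dl(cand, x, y, n_possible)
    if (dl > min_dl + params$dl_slack) break
    rules <- cand
    min_dl <- min(min_dl, dl)
    covered[remaining[cov_rem]] <- TRUE
  }
  list(rules = rules, min_dl = min_dl)
}

#' Learn an ordered ruleset with RIPPER
#'
#' Repeated Incremental Pruning to Produce Error Reduction, specialized to
#' binary classes over numeric features. Rules are learned for the minority
#' class (IREP*: stratified grow/prune split, FOIL-gain growing, incremental
#' reduced-error pruning, MDL stopping), revised in `n_optimizations`
#' optimization passes (replacement vs. revision chosen by total description
#' length), and the majority class becomes the default. The result has the
#' shape of a clinical decision list: explicit threshold rules for one class,
#' "otherwise" for the other.
#'
#' With very small cohorts a random prune split can contain none of the
#' samples a consistent grown rule covers, which under strict IREP* would
#' discard the rule and stop. When that happens the learner falls back to
#' the unpruned grown rule, accepting it only if it covers new positives and
#' misclassifies under half of what it covers on the remaining training
#' data; the MDL stopping criterion still applies.
#'
#' @param m expression matrix (features x samples).
#' @param labels a [label_vector()].
#' @param params a [ripper_params()] object.
#' @return object of class `"ripper_ruleset"`: list with `rules` (ordered
#'   `ripper_rule`s, all predicting the target class), `default_class`,
#'   `target_class`, and `params`.
#' @export
train_ripper <- function(m, labels, params = ripper_params()) {
  validate_expression_matrix(m)
  if (ncol(m) != length(labels)) stop("labels must match the matrix columns")
  tab <- table(as.character(labels))
  if (length(tab) == 1L)
    return(structure(list(rules = list(), default_class = names(tab),
                          target_class = NULL, params = params),
                     class = "ripper_ruleset"))
  # minority class first; frequency ties broken lexicographically
  ord <- order(as.integer(tab), names(tab), method = "radix")
  target <- names(tab)[ord[1]]
  default <- names(tab)[ord[2]]

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(params$seed, 17L))

  x <- t(m)
  y <- as.character(labels) == target
  n_possible <- count_possible_conditions(x)

  fit <- irep_star(x, labels, target, params, n_possible)
  rules <- fit$rules

  for (pass in seq_len(params$n_optimizations)) {
    for (r_i in seq_along(rules)) {
      covered_before <- rep(FALSE, nrow(x))
      for (r in rules[seq_len(r_i - 1L)])
        covered_before <- covered_before | rule_covers(r$conditions, x)
      remaining <- which(!covered_before)
      if (!any(y[remaining])) next
      variants <- list(original = rules[[r_i]])
      gp_rep <- grow_prune_once(x, labels, remaining, target, params)
      if (!is.null(gp_rep)) variants$replacement <- gp_rep$rule
      gp_rev <- grow_prune_once(x, labels, remaining, target, params,
                                extend = rules[[r_i]])
      if (!is.null(gp_rev)) variants$revision <- gp_rev$rule
      dls <- vapply(variants, function(v) {
        rs <- rules
        rs[[r_i]] <- v
        ruleset_dl(rs, x, y, n_possible)
      }, numeric(1))
      pick <- names(variants)[which.min(dls)]  # ties keep the original
      rules[[r_i]] <- variants[[pick]]
    }
    # mop-up: cover positives left uncovered after revision
    fit <- irep_star(x, labels, target, params, n_possible, rules = rules)
    rules <- fit$rules
  }

  # drop rules that no longer cover any training positive
  keep <- vapply(rules, function(r) {
    cov <- rule_covers(r$conditions, x)
    sum(cov & y) >= 1
  }, logical(1))
  rules <- rules[keep]

  structure(list(rules = rules, default_class = default,
                 target_class = target, params = params),
            class = "ripper_ruleset")
}

#' Predict classes from a RIPPER ruleset
#'
#' A sample gets the class of the first rule whose conjunction it satisfies,
#' or the default class if no rule fires.
#'
#' @param object a `ripper_ruleset`.
#' @param newdata expression matrix (features x samples) or a single named
#'   numeric vector; must provide every feature referenced by the rules.
#' @param ... unused.
#' @return character vector of predicted classes, one per sample.
#' @export
predict.ripper_ruleset <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    if (is.null(names(newdata))) stop("a sample vector must be named by feature id")
    newdata <- matrix(newdata, ncol = 1, dimnames = list(names(newdata), "sample"))
  }
  x <- t(newdata)
  out <- rep(object$default_class, nrow(x))
  undecided <- rep(TRUE, nrow(x))
  for (r in object$rules) {
    fires <- undecided & rule_covers(r$conditions, x)
    out[fires] <- r$class
    undecided <- undecided & !fires
  }
  out
}

# shortest decimal rendering that still round-trips to the same double
format_threshold <- function(v) {
  s <- trimws(formatC(v, format = "g", digits = 15))
  if (as.numeric(s) != v) s <- trimws(formatC(v, format = "g", digits = 17))
  s
}

#' Render a ruleset as text
#'
#' One line per rule, `"<class>: <feature> <op> <value> [& ...]"`, followed by
#' a `"<default>: otherwise"` line — the decision-list layout of published
#' compartment rule tables. The rendering round-trips through
#' [parse_ruleset()] losslessly.
#'
#' @param x a `ripper_ruleset`.
#' @param ... unused.
#' @return character vector of lines.
#' @export
format.ripper_ruleset <- function(x, ...) {
  lines <- vapply(x$rules, function(r) {
    body <- if (!length(r$conditions)) "true" else
      paste(vapply(r$conditions, function(cc)
        paste(cc$feature_id, cc$op, format_threshold(cc$threshold)),
        character(1)), collapse = " & ")
    paste0(r$class, ": ", body)
  }, character(1))
  c(lines, paste0(x$default_class, ": otherwise"))
}

#' @export
print.ripper_ruleset <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Parse a ruleset rendered by [format.ripper_ruleset()]
#'
#' @param lines character vector of rule lines.
#' @return a `ripper_ruleset` (with `params = NULL`).
#' @export
parse_ruleset <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no rule lines to parse")
  parts <- regmatches(lines, regexec("^(.+?): (.*)$", lines))
  rules <- list()
  default_class <- NULL
  target_class <- NULL
  for (p in parts) {
    if (length(p) != 3L) stop("malformed rule line: ", p[1])
    cls <- p[2]
    body <- p[3]
    if (body == "otherwise") {
      default_class <- cls
      next
    }
    conditions <- list()
    if (body != "true") {
      for (tok in strsplit(body, " & ", fixed = TRUE)[[1]]) {
        mm <- regmatches(tok, regexec("^(.+) (<=|>=) ([-0-9.eE+]+)$", tok))[[1]]
        if (length(mm) != 4L) stop("malformed condition: ", tok)
        conditions[[length(conditions) + 1L]] <-
          new_condition(mm[2], mm[3], as.numeric(mm[4]))
      }
    }
    target_class <- cls
    rules[[length(rules) + 1L]] <-
      structure(list(conditions = conditions, class = cls),
                class = "ripper_rule")
  }
  if (is.null(default_class)) stop("ruleset text lacks an 'otherwise' line")
  structure(list(rules = rules, default_class = default_class,
                 target_class = target_class, params = NULL),
            class = "ripper_ruleset")
}
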