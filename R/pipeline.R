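#' Run the full analysis for one compartment
#'
#' Chains the pipeline stages on one compartment of a study: Monte-Carlo
#' feature selection, top-k signature extraction, a full-data RIPPER ruleset,
#' repeated stratified cross-validation of the MCFS–RIPPER classifier, and
#' Ward.D2 clustering of the samples on the top-k submatrix with
#' miss-clustered counts. All stochastic stages derive from `seed`, so the
#' same configuration reproduces byte-identical reports.
#'
#' @param study a `compartment_study`.
#' @param compartment name of the compartment to analyze.
#' @param mcfs an [mcfs_params()].
#' @param ripper a [ripper_params()].
#' @param cv a [cv_config()].
#' @param k_top number of top-ranked features used for rules, CV and
#'   clustering (default 10).
#' @param seed global seed overriding the sub-config seeds (default 1).
#' @param out_dir optional directory; when given, the report bundle is
#'   written as TSV/text files (with the configuration echoed) under
#'   `out_dir/<compartment>/`.
#' @return list with `compartment`, `ri_table`, `top_features`, `ruleset`,
#'   `confusion`, `weighted_accuracy`, `clustering` (assignment +
#'   miss-cluster counts), and `config`.
#' @export
run_compartment <- function(study, compartment, mcfs = mcfs_params(),
                            ripper = ripper_params(), cv = cv_config(),
                            k_top = 10, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(study, "compartment_study"))
  if (!compartment %in% names(study$compartments))
    stop("unknown compartment '", compartment, "'; available: ",
         paste(names(study$compartments), collapse = ", "))
  m <- study$compartments[[compartment]]
  labels <- study$labels
  mcfs$seed <- as.integer(seed)
  ripper$seed <- substream_seed(seed, 2L)
  cv$seed <- substream_seed(seed, 3L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s/%s] %s", compartment, name, conditionMessage(e)),
           call. = FALSE))
  }

  ri <- stage("mcfs", run_mcfs(m, labels, mcfs))
  top <- rank_features(ri)[seq_len(min(k_top, nrow(m)))]
  rs <- stage("ripper", train_ripper(m[top, , drop = FALSE], labels, ripper))
  cm <- stage("cv", repeated_cv(m, labels, cv, mcfs, k_top, ripper))
  cl <- stage("clustering", ward_cluster(m[top, , drop = FALSE]))
  miss <- count_missclustered(cl$assignment, labels)

  config <- list(compartment = compartment, seed = as.integer(seed),
                 k_top = k_top, mcfs = attr(ri, "params"),
                 ripper = unclass(ripper), cv = unclass(cv))
  bundle <- list(compartment = compartment, ri_table = ri,
                 top_features = top, ruleset = rs, confusion = cm,
                 weighted_accuracy = weighted_accuracy(cm),
                 clustering = list(assignment = cl$assignment,
                                   merges = cl$merges, missclustered = miss),
                 config = config)
  if (!is.null(out_dir)) write_compartment_bundle(bundle, out_dir)
  bundle
}

write_compartment_bundle <- function(bundle, out_dir) {
  dir <- file.path(out_dir, bundle$compartment)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ri_table(bundle$ri_table, file.path(dir, "ri_table.tsv"))
  writeLines(bundle$top_features, file.path(dir, "top_features.txt"))
  writeLines(format(bundle$ruleset), file.path(dir, "rules.txt"))
  cm <- bundle$confusion
  utils::write.table(
    data.frame(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
               positive_accuracy = class_accuracy(cm, cm$positive),
               negative_accuracy = class_accuracy(cm, cm$negative),
               weighted_accuracy = weighted_accuracy(cm)),
    file.path(dir, "confusion.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(bundle$clustering$assignment),
               cluster = unname(bundle$clustering$assignment)),
    file.path(dir, "clustering.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(deparse_config(bundle$config), file.path(dir, "config.txt"))
  invisible(dir)
}

deparse_config <- function(cfg, prefix = "") {
  out <- character(0)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.list(v)) out <- c(out, deparse_config(v, paste0(prefix, nm, ".")))
    else out <- c(out, paste0(prefix, nm, " = ",
                              paste(format(v), collapse = ", ")))
  }
  out
}

#' Run the full cross-compartment analysis
#'
#' Analyzes every compartment with [run_compartment()], then compares the
#' compartments: top-k Venn overlaps at each `k` in `venn_k` and a ranking of
#' compartments by cross-validated weighted accuracy.
#'
#' @param study a `compartment_study`.
#' @inheritParams run_compartment
#' @param venn_k prefix lengths for the overlap analysis (default
#'   `c(10, 15, 20)`).
#' @return list with `bundles` (per-compartment reports), `venn` (list of
#'   `venn_result`s keyed by `k`, or `NULL` with fewer than 2 compartments),
#'   and `accuracy_ranking` (data frame sorted by weighted accuracy).
#' @export
run_study <- function(study, mcfs = mcfs_params(), ripper = ripper_params(),
                      cv = cv_config(), k_top = 10, venn_k = c(10, 15, 20),
                      seed = 1L, out_dir = NULL) {
  stopifnot(inherits(study, "compartment_study"))
  bundles <- lapply(names(study$compartments), function(nm)
    run_compartment(study, nm, mcfs, ripper, cv, k_top, seed, out_dir))
  names(bundles) <- names(study$compartments)

  venn <- NULL
  if (length(bundles) >= 2) {
    ranked <- lapply(bundles, function(b) rank_features(b$ri_table))
    venn <- lapply(venn_k, function(k) venn_overlaps(ranked, k))
    names(venn) <- as.character(venn_k)
  }
  ranking <- data.frame(
    compartment = names(bundles),
    weighted_accuracy = vapply(bundles, `[[`, numeric(1), "weighted_accuracy"),
    row.names = NULL)
  ranking <- ranking[order(-ranking$weighted_accuracy), ]

  if (!is.null(out_dir)) {
    utils::write.table(ranking, file.path(out_dir, "accuracy_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(venn)) {
      lines <- unlist(lapply(venn, function(v)
        c(sprintf("k=%d", v$k),
          vapply(names(v$pairwise), function(nm)
            sprintf("  %s\t%d\t%s", nm, length(v$pairwise[[nm]]),
                    paste(v$pairwise[[nm]], collapse = ",")), character(1)))))
      writeLines(lines, file.path(out_dir, "venn_overlaps.txt"))
    }
  }
  list(bundles = bundles, venn = venn, accuracy_ranking = ranking)
}

#' Published reference confusion counts per compartment
#'
#' Pooled 3x10-fold cross-validation confusion counts reported for the
#' GSE71661 three-compartment plasma miRNA cohort (10 lung adenocarcinoma vs
#' 9 granuloma patients; positive class adenocarcinoma). Shipped as a
#' plain-text input for reproducing the published weighted-accuracy
#' arithmetic.
#'
#' @return data frame with columns `compartment`, `tp`, `fn`, `fp`, `tn`.
#' @export
reference_confusion_counts <- function() {
  path <- system.file("extdata", "reference_confusion_counts.tsv",
                      package = "compartmiR", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Published top-10 discriminative miRNA lists per compartment
#'
#' The ranked top-10 miRNA signatures reported for whole plasma, EV and
#' EV-free plasma in the GSE71661 cohort analysis.
#'
#' @return named list of character vectors (rank order preserved).
#' @export
reference_top10_mirnas <- function() {
  path <- system.file("extdata", "reference_top10_mirnas.tsv",
                      package = "compartmiR", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$compartment), function(s)
    s$feature_id[order(s$rank)])
  out[unique(df$compartment)]
}

#' Load the cohort expression tables, if deposited locally
#'
#' Looks for per-compartment expression TSVs (`whole_plasma.tsv`, `EV.tsv`,
#' `EV_free.tsv`) plus `labels.tsv` in `dir`. The package does not bundle
#' the GSE71661 expression matrices; analyses needing them require the user
#' to deposit the tables first.
#'
#' @param dir directory containing the tables.
#' @return a `compartment_study`.
#' @export
load_cohort_study <- function(dir) {
  files <- file.path(dir, c("whole_plasma.tsv", "EV.tsv", "EV_free.tsv"))
  if (!nzchar(dir) || !all(file.exists(files)))
    stop("cohort expression tables not found under '", dir,
         "'; expected whole_plasma.tsv, EV.tsv, EV_free.tsv and labels.tsv")
  lab_df <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  labels <- label_vector(lab_df$class, lab_df$sample_id)
  parts <- lapply(files, function(f)
    list(expression = read_expression_table(f), labels = labels))
  names(parts) <- c("whole_plasma", "EV", "EV_free")
  bind_study(parts)
}
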