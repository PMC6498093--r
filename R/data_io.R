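#' Construct and validate an expression matrix
#'
#' An expression matrix is an ordinary numeric matrix with miRNA features as
#' rows and samples as columns: non-negative values, no missing entries, and
#' unique row and column identifiers. Feature identifiers are case-sensitive
#' verbatim strings (miRBase-style names such as `"hsa-miR-223-3p"`); no alias
#' resolution is attempted.
#'
#' @param values numeric matrix, or an object coercible to one, with features
#'   in rows and samples in columns.
#' @param feature_ids optional character vector of row identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids optional character vector of column identifiers; defaults
#'   to `colnames(values)`.
#' @return a validated numeric matrix with `feature_ids` as rownames and
#'   `sample_ids` as colnames.
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 3,
#'                               dimnames = list(paste0("miR-", 1:3),
#'                                               c("s1", "s2"))))
#' @export
expression_matrix <- function(values, feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_expression_matrix(values)
  values
}

#' Validate expression-matrix invariants
#'
#' Checks that `m` is a numeric matrix with unique feature and sample
#' identifiers, no missing entries and no negative values. Called by every
#' entry point that accepts an expression matrix.
#'
#' @param m matrix to validate.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix (features x samples)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry feature ids (rownames) and sample ids (colnames)")
  dup_f <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_f))
    stop("duplicated feature id(s): ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(m))
    stop("expression matrix contains missing values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  invisible(m)
}

#' Construct a binary sample label vector
#'
#' Labels are stored as a factor named by sample id, with the positive class
#' recorded as an attribute. In the intended application the positive class is
#' lung adenocarcinoma and the negative class granuloma, but any two class
#' names may be used.
#'
#' @param classes character or factor of class labels, one per sample.
#' @param sample_ids sample identifiers; defaults to `names(classes)`.
#' @param positive name of the positive class (default `"adenocarcinoma"`).
#' @param negative name of the negative class; defaults to the other observed
#'   class.
#' @return a named factor of class `"label_vector"` with attributes `positive`
#'   and `negative`.
#' @export
label_vector <- function(classes, sample_ids = names(classes),
                         positive = "adenocarcinoma", negative = NULL) {
  classes <- as.character(classes)
  if (is.null(sample_ids))
    stop("sample ids are required (pass them or name the class vector)")
  if (length(sample_ids) != length(classes))
    stop("sample_ids and classes must have equal length")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s) in labels")
  obs <- unique(classes)
  if (length(obs) > 2)
    stop("label vector must be binary; observed classes: ",
         paste(obs, collapse = ", "))
  if (is.null(negative)) {
    negative <- setdiff(obs, positive)
    if (length(negative) == 0) negative <- "negative"
    negative <- negative[1]
  }
  if (!all(classes %in% c(positive, negative)))
    stop("classes outside {", positive, ", ", negative, "}: ",
         paste(setdiff(obs, c(positive, negative)), collapse = ", "))
  out <- factor(classes, levels = c(negative, positive))
  names(out) <- sample_ids
  attr(out, "positive") <- positive
  attr(out, "negative") <- negative
  class(out) <- c("label_vector", "factor")
  out
}

#' @export
`[.label_vector` <- function(x, ...) {
  out <- NextMethod()
  attr(out, "positive") <- attr(x, "positive")
  attr(out, "negative") <- attr(x, "negative")
  class(out) <- class(x)
  out
}

positive_class <- function(labels) {
  p <- attr(labels, "positive")
  if (is.null(p)) stop("labels carry no positive-class attribute; build them with label_vector()")
  p
}

negative_class <- function(labels) {
  n <- attr(labels, "negative")
  if (is.null(n)) stop("labels carry no negative-class attribute; build them with label_vector()")
  n
}

check_both_classes <- function(labels) {
  tab <- table(as.character(labels))
  if (length(tab) < 2)
    stop("both classes must be present; observed only: ",
         paste(names(tab), collapse = ", "))
  invisible(tab)
}

#' Read an expression table from disk
#'
#' Supports a plain TSV dialect (first column = feature ids, header row =
#' sample ids, numeric body) and the GEO series-matrix textual dialect, in
#' which metadata lines are prefixed with `!` and the expression block sits
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"geo_series_matrix"`.
#' @return a validated expression matrix (features x samples).
#' @export
read_expression_table <- function(path, dialect = c("tsv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin)
      stop("malformed series matrix: table delimiters not found in ", path)
    lines <- lines[(begin + 1L):(end - 1L)]
    lines <- gsub("\"", "", lines, fixed = TRUE)
  } else {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nc <- length(sample_ids)
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = nc,
                 dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != nc + 1L)
      stop(sprintf("row %d ('%s') has %d value(s); expected %d",
                   i, row[1], length(row) - 1L, nc))
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("malformed numeric cell at feature '%s', sample '%s': '%s'",
                   row[1], sample_ids[j], row[j + 1L]))
    }
    vals[i, ] <- v
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression table as TSV
#'
#' Writes the dialect [read_expression_table()] reads: a `feature_id` header
#' column followed by one column per sample.
#'
#' @param m expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(feature_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Total-read (counts-per-scale) normalization
#'
#' Rescales every sample column so that its sum equals `scale`, the standard
#' library-size normalization for small-RNA sequencing counts. Values loaded
#' from already-normalized deposits should not be normalized again;
#' normalization is an explicit opt-in step.
#'
#' @param m expression matrix (features x samples).
#' @param scale target column sum (default `1e6`, i.e. reads-per-million).
#' @return expression matrix with every column summing to `scale`.
#' @export
normalize_total_reads <- function(m, scale = 1e6) {
  validate_expression_matrix(m)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  totals <- colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[totals <= 0]
    stop("sample column(s) with non-positive total: ", paste(bad, collapse = ", "))
  }
  sweep(m, 2, totals / scale, "/")
}

#' Bind per-compartment datasets into one study
#'
#' A compartment study couples one expression matrix per blood compartment
#' (for example whole plasma, EV, EV-free plasma) with a single shared label
#' vector. All compartments must profile the same samples.
#'
#' @param parts named list; each element is a list with components
#'   `expression` (matrix) and `labels` (a [label_vector()]).
#' @return object of class `"compartment_study"`: a list with `compartments`
#'   (named list of matrices) and `labels`.
#' @export
bind_study <- function(parts) {
  if (!is.list(parts) || length(parts) < 1L)
    stop("parts must be a non-empty named list of compartments")
  if (is.null(names(parts)) || any(!nzchar(names(parts))))
    stop("every compartment must be named")
  ref_labels <- parts[[1]]$labels
  ref_ids <- names(ref_labels)
  mats <- vector("list", length(parts))
  names(mats) <- names(parts)
  for (nm in names(parts)) {
    part <- parts[[nm]]
    m <- part$expression
    validate_expression_matrix(m)
    lb <- part$labels
    if (!setequal(colnames(m), ref_ids) || length(colnames(m)) != length(ref_ids)) {
      missing <- setdiff(ref_ids, colnames(m))
      extra <- setdiff(colnames(m), ref_ids)
      stop(sprintf("compartment '%s' sample mismatch%s%s", nm,
                   if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
                   if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""))
    }
    if (!identical(as.character(lb[ref_ids]), as.character(ref_labels)))
      stop(sprintf("compartment '%s' labels disagree with the shared label vector", nm))
    mats[[nm]] <- m[, ref_ids, drop = FALSE]
  }
  structure(list(compartments = mats, labels = ref_labels),
            class = "compartment_study")
}

#' @export
print.compartment_study <- function(x, ...) {
  tab <- table(as.character(x$labels))
  cat(sprintf("compartment_study: %d compartment(s), %d samples (%s)\n",
              length(x$compartments), length(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  for (nm in names(x$compartments))
    cat(sprintf("  %-14s %5d features\n", nm, nrow(x$compartments[[nm]])))
  invisible(x)
}

#' Write a compartment study to disk
#'
#' Writes one expression TSV per compartment, a `labels.tsv` file, and a
#' plain-text `manifest.txt` mapping compartments to files, so a study can be
#' reloaded with [read_study()].
#'
#' @param study a `compartment_study`.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "compartment_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels_path <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(sample_id = names(study$labels),
               class = as.character(study$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(sprintf("labels\tlabels.tsv\tpositive=%s", positive_class(study$labels)))
  for (nm in names(study$compartments)) {
    f <- paste0(nm, ".tsv")
    write_expression_table(study$compartments[[nm]], file.path(dir, f))
    manifest <- c(manifest, sprintf("compartment\t%s\t%s", nm, f))
  }
  manifest_path <- file.path(dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a compartment study written by [write_study()]
#'
#' @param manifest_path path to `manifest.txt`.
#' @return a `compartment_study`.
#' @export
read_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  rows <- strsplit(readLines(manifest_path), "\t", fixed = TRUE)
  lab_row <- Filter(function(r) r[1] == "labels", rows)
  if (length(lab_row) != 1L) stop("manifest must contain exactly one labels entry")
  lab_df <- utils::read.table(file.path(dir, lab_row[[1]][2]), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  positive <- sub("^positive=", "", lab_row[[1]][3])
  labels <- label_vector(lab_df$class, lab_df$sample_id, positive = positive)
  parts <- list()
  for (r in rows) {
    if (r[1] != "compartment") next
    parts[[r[2]]] <- list(expression = read_expression_table(file.path(dir, r[3])),
                          labels = labels)
  }
  bind_study(parts)
}
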