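#' Specify a planted marker feature
#'
#' Markers give selected features a known class-conditional structure so
#' selection and rule learning can be validated against ground truth. Three
#' modes mirror the patterns seen in circulating-miRNA cohorts:
#'
#' * `on_off_positive`: expressed in the positive class (zero-truncated
#'   draws with mean `effect`, so every "on" sample detects the marker),
#'   exactly zero in every negative-class sample — the presence/absence
#'   pattern behind rules of the form `feature <= 0`.
#' * `on_off_negative`: the mirror image.
#' * `fold_shift`: expressed in both classes, with the negative-class mean
#'   equal to `effect` times the positive-class mean (so `effect` is the
#'   negative/positive fold change).
#'
#' @param feature_index 1-based index of the feature carrying the effect.
#' @param mode one of `"on_off_positive"`, `"on_off_negative"`, `"fold_shift"`.
#' @param effect positive real: baseline mean of the "on" class for the on/off
#'   modes; negative/positive fold ratio for `fold_shift`.
#' @param compartments compartment labels the effect applies to, or `NULL`
#'   (default) for all compartments.
#' @return an object of class `"marker_spec"`.
#' @export
marker_spec <- function(feature_index,
                        mode = c("on_off_positive", "on_off_negative", "fold_shift"),
                        effect, compartments = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(feature_index) == 1L, feature_index >= 1,
            is.numeric(effect), length(effect) == 1L, effect > 0)
  if (!is.null(compartments) && length(compartments) == 0L)
    stop("compartments must be NULL (all) or a non-empty character vector")
  structure(list(feature_index = as.integer(feature_index), mode = mode,
                 effect = effect, compartments = compartments),
            class = "marker_spec")
}

#' Configure the synthetic compartment generator
#'
#' Defaults reproduce the cohort geometry of a three-compartment plasma miRNA
#' study: 10 positive (adenocarcinoma) and 9 negative (granuloma) samples and
#' 1,509 miRNA features, with heavy zero-inflation and library-size variation.
#'
#' The count model is negative binomial: feature baselines are drawn
#' log-normally around `noise_mean` (small-RNA expression is strongly skewed),
#' per-sample library factors are gamma with mean 1 and coefficient of
#' variation `library_size_cv`, and each count has mean
#' `baseline * library_factor` with dispersion (NB size) `noise_dispersion`.
#' Independent Bernoulli masking with probability `sparsity` then zeroes
#' entries, except marker features in their "on" class. A `log_normal` model
#' is offered for simulating directly on a normalized continuous scale.
#'
#' @param n_positive,n_negative class sizes (defaults 10 and 9).
#' @param n_features number of miRNA features (default 1509).
#' @param sparsity per-entry zero-masking probability (default 0.6).
#' @param noise_model `"negative_binomial"` (default) or `"log_normal"`.
#' @param noise_mean median feature baseline (NB mean / log-normal scale).
#' @param noise_dispersion NB size parameter (smaller = more overdispersed),
#'   or the log-normal `sdlog` when `noise_model = "log_normal"`.
#' @param baseline_sdlog sdlog of the across-feature baseline distribution.
#' @param markers list of [marker_spec()] objects.
#' @param library_size_cv coefficient of variation of per-sample totals
#'   (default 0.3).
#' @param compartment compartment label this configuration generates
#'   (default `"whole_plasma"`).
#' @param seed integer seed; every stochastic choice derives from it.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_positive = 10, n_negative = 9, n_features = 1509,
                             sparsity = 0.6,
                             noise_model = c("negative_binomial", "log_normal"),
                             noise_mean = 50, noise_dispersion = 0.5,
                             baseline_sdlog = 1,
                             markers = list(), library_size_cv = 0.3,
                             compartment = "whole_plasma", seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (inherits(markers, "marker_spec")) markers <- list(markers)
  if (n_positive + n_negative < 4)
    stop("at least 4 samples are required (n_positive + n_negative >= 4)")
  if (n_features < length(markers))
    stop("n_features must be at least the number of markers")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (library_size_cv < 0) stop("library_size_cv must be non-negative")
  for (mk in markers) {
    if (!inherits(mk, "marker_spec")) stop("markers must be marker_spec objects")
    if (mk$feature_index > n_features)
      stop(sprintf("marker feature_index %d out of range (n_features = %d)",
                   mk$feature_index, n_features))
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 n_features = as.integer(n_features),
                 sparsity = sparsity, noise_model = noise_model,
                 noise_mean = noise_mean, noise_dispersion = noise_dispersion,
                 baseline_sdlog = baseline_sdlog,
                 markers = markers, library_size_cv = library_size_cv,
                 compartment = compartment, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic substream seeds: one global seed drives labels, baselines,
# library sizes, masks and counts through fixed offsets, so each component is
# reproducible independently of the others. Kept below 2^31.
substream_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + stream * 7919L
}

synthetic_labels <- function(cfg) {
  n <- cfg$n_positive + cfg$n_negative
  ids <- sprintf("S%02d", seq_len(n))
  label_vector(c(rep("adenocarcinoma", cfg$n_positive),
                 rep("granuloma", cfg$n_negative)),
               sample_ids = ids)
}

marker_applies <- function(mk, compartment) {
  is.null(mk$compartments) || compartment %in% mk$compartments
}

draw_expression <- function(n, mean, cfg, lib) {
  # library factors scale means multiplicatively; E[value] = mean
  if (cfg$noise_model == "negative_binomial") {
    stats::rnbinom(n, mu = mean * lib, size = cfg$noise_dispersion)
  } else {
    sdl <- cfg$noise_dispersion
    stats::rlnorm(n, meanlog = log(mean * lib) - sdl^2 / 2, sdlog = sdl)
  }
}

# zero-truncated variant for presence/absence markers: an "on"-class sample
# expresses (detects) the marker by definition, so raw zeros are redrawn
draw_expression_nonzero <- function(n, mean, cfg, lib) {
  v <- draw_expression(n, mean, cfg, lib)
  for (guard in 1:100) {
    z <- v == 0
    if (!any(z)) break
    v[z] <- draw_expression(sum(z), mean, cfg, lib[z])
  }
  v[v == 0] <- 1  # pathological means only; keeps the presence contract
  v
}

#' Generate one synthetic compartment dataset
#'
#' Produces a features x samples expression matrix and matching labels, fully
#' reproducible from `cfg$seed`. Without markers the generator is exchangeable
#' across class labels: values are drawn independently of class, so no feature
#' separates the classes better than chance. Marker features carry the
#' class-conditional structure configured in their [marker_spec()];
#' on/off markers are exactly zero in the "off" class.
#'
#' @param cfg a [synthetic_config()].
#' @return list with components `expression` (matrix) and `labels`.
#' @export
generate_compartment_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  labels <- synthetic_labels(cfg)
  n <- length(labels)
  d <- cfg$n_features
  pos <- as.character(labels) == positive_class(labels)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  set.seed(substream_seed(cfg$seed, 1L))
  baselines <- stats::rlnorm(d, meanlog = log(cfg$noise_mean),
                             sdlog = cfg$baseline_sdlog)

  set.seed(substream_seed(cfg$seed, 2L))
  lib <- if (cfg$library_size_cv > 0) {
    shape <- 1 / cfg$library_size_cv^2
    stats::rgamma(n, shape = shape, scale = 1 / shape)
  } else rep(1, n)

  set.seed(substream_seed(cfg$seed, 3L))
  mask <- matrix(stats::runif(d * n) < cfg$sparsity, nrow = d)

  set.seed(substream_seed(cfg$seed, 4L))
  vals <- matrix(0, nrow = d, ncol = n)
  for (i in seq_len(d))
    vals[i, ] <- draw_expression(n, baselines[i], cfg, lib)

  for (mk in cfg$markers) {
    if (!marker_applies(mk, cfg$compartment)) next
    g <- mk$feature_index
    on <- switch(mk$mode,
                 on_off_positive = pos,
                 on_off_negative = !pos,
                 fold_shift = rep(TRUE, n))
    if (mk$mode == "fold_shift") {
      mu <- ifelse(pos, baselines[g], baselines[g] * mk$effect)
      vals[g, ] <- draw_expression(n, mu, cfg, lib)
    } else {
      vals[g, ] <- 0
      vals[g, on] <- draw_expression_nonzero(sum(on), mk$effect, cfg, lib[on])
      mask[g, on] <- FALSE  # "on"-class marker entries are never zero-masked
    }
  }
  vals[mask] <- 0

  dimnames(vals) <- list(sprintf("syn-miR-%04d", seq_len(d)), names(labels))
  list(expression = expression_matrix(vals), labels = labels)
}

#' Generate a multi-compartment synthetic study
#'
#' All compartment configurations must share the cohort sizes; the label
#' vector is shared across compartments. Each compartment draws from its own
#' seed substream (offset by compartment position from `seed`), so
#' compartments differ while the study as a whole is reproducible from one
#' seed.
#'
#' @param cfgs named list of [synthetic_config()] objects, one per
#'   compartment; names become compartment labels and override each config's
#'   `compartment` field.
#' @param seed optional global seed overriding the per-config seeds.
#' @return a `compartment_study`.
#' @export
generate_study <- function(cfgs, seed = NULL) {
  if (is.null(names(cfgs)) || any(!nzchar(names(cfgs))))
    stop("cfgs must be a named list (compartment labels)")
  np <- unique(vapply(cfgs, `[[`, integer(1), "n_positive"))
  nn <- unique(vapply(cfgs, `[[`, integer(1), "n_negative"))
  if (length(np) != 1L || length(nn) != 1L)
    stop("all compartment configs must share cohort sizes")
  parts <- list()
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    cfg$compartment <- names(cfgs)[i]
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    cfg$seed <- substream_seed(cfg$seed, 100L + i)
    parts[[names(cfgs)[i]]] <- generate_compartment_dataset(cfg)
  }
  bind_study(parts)
}

#' Write a synthetic configuration as YAML
#'
#' Serializes a [synthetic_config()] (including its marker list and seed) as
#' a structured text file that [read_synthetic_config()] restores.
#'
#' @param cfg a [synthetic_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read/write config files")
  plain <- unclass(cfg)
  plain$markers <- lapply(plain$markers, unclass)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a synthetic configuration written by [write_synthetic_config()]
#'
#' @param path path to the YAML file.
#' @return a validated [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read/write config files")
  plain <- yaml::read_yaml(path)
  if (is.null(plain$seed)) stop("config file lacks a seed field")
  markers <- lapply(plain$markers, function(mk)
    marker_spec(mk$feature_index, mk$mode, mk$effect, unlist(mk$compartments)))
  synthetic_config(n_positive = plain$n_positive,
                   n_negative = plain$n_negative,
                   n_features = plain$n_features,
                   sparsity = plain$sparsity,
                   noise_model = plain$noise_model,
                   noise_mean = plain$noise_mean,
                   noise_dispersion = plain$noise_dispersion,
                   baseline_sdlog = plain$baseline_sdlog,
                   markers = markers,
                   library_size_cv = plain$library_size_cv,
                   compartment = plain$compartment,
                   seed = plain$seed)
}
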