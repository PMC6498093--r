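test_that("generation is bit-identical for the same config and seed", {
  cfg <- synthetic_config(n_features = 50, seed = 123,
                          markers = list(marker_spec(7, "fold_shift", 3)))
  a <- generate_compartment_dataset(cfg)
  b <- generate_compartment_dataset(cfg)
  expect_identical(a, b)
})

test_that("cohort geometry and invariants match the configuration", {
  cfg <- synthetic_config(n_features = 40, seed = 5)
  ds <- generate_compartment_dataset(cfg)
  expect_equal(dim(ds$expression), c(40L, 19L))
  tab <- table(as.character(ds$labels))
  expect_equal(as.integer(tab[c("adenocarcinoma", "granuloma")]), c(10L, 9L))
  expect_true(all(ds$expression >= 0))
  expect_false(anyNA(ds$expression))
})

test_that("marker index out of range is a config error", {
  expect_error(synthetic_config(n_features = 10,
                                markers = list(marker_spec(11, "fold_shift", 2))),
               "out of range")
})

test_that("on/off markers are exactly zero in the off class and expressed on", {
  for (mode in c("on_off_positive", "on_off_negative")) {
    cfg <- synthetic_config(n_features = 30, seed = 9,
                            markers = list(marker_spec(4, mode, 80)))
    ds <- generate_compartment_dataset(cfg)
    pos <- as.character(ds$labels) == "adenocarcinoma"
    on <- if (mode == "on_off_positive") pos else !pos
    expect_true(all(ds$expression[4, !on] == 0))
    expect_true(all(ds$expression[4, on] > 0))
  }
})

test_that("marker class-conditional means match the configured effect", {
  # large cohort so the empirical mean estimates the configured parameters
  cfg <- synthetic_config(n_positive = 100, n_negative = 100, n_features = 5,
                          markers = list(marker_spec(2, "on_off_positive", 100)),
                          seed = 31)
  ds <- generate_compartment_dataset(cfg)
  pos <- as.character(ds$labels) == "adenocarcinoma"
  v <- ds$expression[2, pos]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 100), 3 * se + 8)  # zero-truncation lifts the mean slightly
  expect_true(all(ds$expression[2, !pos] == 0))

  # fold_shift: negative/positive mean ratio near the configured fold
  cfg2 <- synthetic_config(n_positive = 300, n_negative = 300, n_features = 5,
                           sparsity = 0, library_size_cv = 0,
                           noise_mean = 200, noise_dispersion = 20,
                           markers = list(marker_spec(1, "fold_shift", 2)),
                           seed = 13)
  ds2 <- generate_compartment_dataset(cfg2)
  cm <- class_means(ds2$expression, ds2$labels, rownames(ds2$expression)[1])
  expect_equal(fold_change(cm), 2, tolerance = 0.15)
})

test_that("per-sample totals track the configured library-size CV at large n", {
  # low-noise continuous model so count/masking noise does not add variance
  # on top of the library factors the CV parameter controls
  cfg <- synthetic_config(n_positive = 150, n_negative = 150, n_features = 500,
                          sparsity = 0, noise_model = "log_normal",
                          noise_dispersion = 0.1, library_size_cv = 0.4,
                          seed = 21)
  ds <- generate_compartment_dataset(cfg)
  totals <- colSums(ds$expression)
  expect_equal(sd(totals) / mean(totals), 0.4, tolerance = 0.1)
})

test_that("without markers no feature separates the classes beyond permutation noise", {
  cfg <- synthetic_config(n_features = 300, seed = 77)
  ds <- generate_compartment_dataset(cfg)
  y <- as.character(ds$labels) == "adenocarcinoma"
  sep_stat <- function(lab) {
    dm <- abs(rowMeans(ds$expression[, lab, drop = FALSE]) -
                rowMeans(ds$expression[, !lab, drop = FALSE]))
    sds <- apply(ds$expression, 1, sd)
    max(dm / pmax(sds, 1e-9))
  }
  obs <- sep_stat(y)
  set.seed(99)
  perm <- replicate(30, sep_stat(sample(y)))
  # observed label split should look like any permuted split
  expect_lte(obs, max(perm))
})

test_that("generate_study shares labels and plants compartment-specific markers", {
  mk <- function(i) list(marker_spec(i, "on_off_positive", 150))
  cfgs <- list(
    whole_plasma = synthetic_config(n_features = 40, markers = mk(1)),
    EV = synthetic_config(n_features = 40, markers = mk(2)),
    EV_free = synthetic_config(n_features = 40, markers = mk(3)))
  study <- generate_study(cfgs, seed = 4)
  expect_named(study$compartments, c("whole_plasma", "EV", "EV_free"))
  # compartments differ despite one global seed
  expect_false(identical(study$compartments$whole_plasma, study$compartments$EV))
  # marker restricted to a compartment only appears there
  cfgs2 <- list(
    a = synthetic_config(n_features = 20,
                         markers = list(marker_spec(5, "on_off_positive", 150,
                                                    compartments = "a"))),
    b = synthetic_config(n_features = 20,
                         markers = list(marker_spec(5, "on_off_positive", 150,
                                                    compartments = "a"))))
  st2 <- generate_study(cfgs2, seed = 8)
  neg <- as.character(st2$labels) == "granuloma"
  expect_true(all(st2$compartments$a[5, neg] == 0))
  expect_gt(sum(st2$compartments$b[5, neg] > 0), 0)
})

test_that("mismatched cohort sizes across compartment configs are rejected", {
  cfgs <- list(a = synthetic_config(n_positive = 10, n_features = 10),
               b = synthetic_config(n_positive = 8, n_features = 10))
  expect_error(generate_study(cfgs, seed = 1), "cohort sizes")
})

test_that("synthetic configs round-trip through their YAML text form", {
  cfg <- synthetic_config(n_features = 25, sparsity = 0.5,
                          markers = list(marker_spec(3, "fold_shift", 1.8,
                                                     compartments = "EV")),
                          seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back, cfg)
  expect_identical(generate_compartment_dataset(back),
                   generate_compartment_dataset(cfg))
})
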