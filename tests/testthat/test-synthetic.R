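test_that("generation is deterministic and validates its spec", {
  spec <- canonical_fixture_spec(seed = 5)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$gene_sets, b$gene_sets)

  expect_error(synthetic_spec(planted = list(pair_reversal(1L, 999L, 2))),
               class = "relexp_argument_error")
  expect_error(synthetic_spec(planted = list(pair_reversal(1L, 2L, 2),
                                             triple_cycle(2L, 3L, 4L))),
               "share", class = "relexp_argument_error")
  expect_error(synthetic_spec(noise_sd = 0), class = "relexp_argument_error")
  expect_error(pair_reversal(1L, 2L, gap = -1), class = "relexp_argument_error")
})

test_that("generated datasets satisfy the container invariants", {
  gen <- generate_synthetic(canonical_fixture_spec(seed = 6))
  ds <- gen$dataset
  expect_equal(dim(ds$values), c(100L, 40L))
  expect_equal(anyDuplicated(gene_ids(ds)), 0L)
  expect_equal(anyDuplicated(sample_ids(ds)), 0L)
  expect_equal(as.integer(table(sample_classes(ds))), c(20L, 20L))
  expect_false(anyNA(ds$values))
  expect_equal(length(gen$gene_sets), 10L)   # planted + 9 decoys
  # decoys avoid planted genes
  planted_genes <- sprintf("g%03d", 1:10)
  for (s in gen$gene_sets$sets[-1]) {
    expect_length(intersect(s$genes, planted_genes), 0L)
  }
})

test_that("a wide pair reversal yields delta 1 on the planted pair across seeds", {
  hits <- vapply(1:10, function(seed) {
    ds <- generate_synthetic(synthetic_spec(
      n_genes = 20, n_samples_per_class = 10,
      planted = list(pair_reversal(1L, 2L, gap = 6)), seed = seed))$dataset
    pair_score(ds, "g001", "g002")$delta
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("a dataset without planted signals behaves as a null", {
  ds <- generate_synthetic(synthetic_spec(n_genes = 30,
                                          n_samples_per_class = 10,
                                          seed = 7))$dataset
  res <- cross_validate(ds, "tsp", list(filter_n = 10L), k = 5L,
                        repeats = 5L, seed = 23L)
  expect_lt(abs(res$mean_mcc), 0.45)
})

test_that("shrinking the planted gap cannot increase recovered delta on average", {
  delta_at <- function(gap) {
    mean(vapply(1:20, function(seed) {
      ds <- generate_synthetic(synthetic_spec(
        n_genes = 10, n_samples_per_class = 8,
        planted = list(pair_reversal(1L, 2L, gap = gap)),
        seed = 200 + seed))$dataset
      pair_score(ds, "g001", "g002")$delta
    }, numeric(1)))
  }
  expect_lte(delta_at(0.5), delta_at(1.0) + 1e-9)
  expect_lte(delta_at(1.0), delta_at(2.0) + 1e-9)
})

test_that("the fixture suite round-trips and its planted signals are recoverable", {
  dir <- withr::local_tempdir()
  spec <- canonical_fixture_spec(seed = 9)
  manifest <- write_fixture_suite(dir, spec)
  gen <- generate_synthetic(spec)

  csv <- read_expression_csv(file.path(dir, "expression.csv"))
  expect_identical(csv$values, gen$dataset$values)

  soft <- read_soft(file.path(dir, "dataset.soft"))
  expect_identical(soft$dataset$values, gen$dataset$values)
  labelled <- assign_classes_by_cohort(soft$dataset, soft$cohorts,
                                       "normal", "cancer")
  expect_equal(sample_classes(labelled), sample_classes(gen$dataset))

  gmt <- read_gmt(file.path(dir, "networks.gmt"))
  expect_equal(gmt, gen$gene_sets)

  # end-to-end: the planted pair is recovered from the CSV + SOFT cohorts
  csv_labelled <- assign_classes_by_cohort(csv, soft$cohorts, "normal", "cancer")
  model <- train_tsp(csv_labelled)
  expect_equal(model$delta, 1)
  planted_pair <- manifest$planted[[1]]$genes
  expect_equal(pair_score(csv_labelled, planted_pair[1], planted_pair[2])$delta, 1)
})

test_that("lognormal output preserves the rank structure", {
  base_spec <- synthetic_spec(n_genes = 15, n_samples_per_class = 6,
                              planted = list(pair_reversal(1L, 2L, gap = 8)),
                              seed = 77)
  log_spec <- synthetic_spec(n_genes = 15, n_samples_per_class = 6,
                             planted = list(pair_reversal(1L, 2L, gap = 8)),
                             seed = 77, noise_model = "lognormal")
  a <- generate_synthetic(base_spec)$dataset
  b <- generate_synthetic(log_spec)$dataset
  expect_identical(b$values, 2^a$values)
  expect_equal(train_tsp(b)$delta, train_tsp(a)$delta)
})
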