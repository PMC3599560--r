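test_that("order_probability counts per-sample orderings with ties as 0.5", {
  ds <- make_dataset(rbind(gi = c(1, 2, 3), gj = c(2, 3, 4)),
                     classes = c(1L, 1L, 1L))
  # needs a class-2 sample to be a valid two-class dataset? no: order
  # probability is per class and only needs that class to be non-empty
  expect_equal(order_probability(ds, 1L, "gi", "gj"), 1.0)

  ds2 <- make_dataset(rbind(gi = c(5, 1, 3), gj = c(2, 4, 3)),
                      classes = c(1L, 1L, 1L))
  expect_equal(order_probability(ds2, 1L, "gi", "gj"), 0.5)

  ds3 <- make_dataset(rbind(gi = c(2, 2), gj = c(2, 2)),
                      classes = c(1L, 1L))
  expect_equal(order_probability(ds3, 1L, "gi", "gj"), 0.5)
  expect_error(order_probability(ds3, 2L, "gi", "gj"),
               class = "relexp_precondition_error")
  expect_error(order_probability(ds3, 1L, "gi", "gi"),
               class = "relexp_argument_error")
})

test_that("pair delta spans its extremes and the cyclic construction gives 1/3", {
  perfect <- make_dataset(rbind(gi = c(1, 1, 3, 3), gj = c(2, 2, 2, 2)),
                          classes = c(1L, 1L, 2L, 2L))
  ps <- pair_score(perfect, "gi", "gj")
  expect_equal(ps$delta, 1)
  expect_equal(ps$p1, 1)
  expect_equal(ps$p2, 0)

  # class 1 uniform over the 3 cyclic orders, class 2 over the 3
  # anti-cyclic: every pair has delta exactly 1/3
  cyc <- cyclic_triple_dataset()
  expect_equal(pair_score(cyc, "g1", "g2")$delta, 1 / 3)
  expect_equal(pair_score(cyc, "g1", "g3")$delta, 1 / 3)
  expect_equal(pair_score(cyc, "g2", "g3")$delta, 1 / 3)

  same <- make_dataset(rbind(gi = c(1, 2, 1, 2), gj = c(3, 0, 3, 0)),
                       classes = c(1L, 1L, 2L, 2L))
  expect_equal(pair_score(same, "gi", "gj")$delta, 0)
})

test_that("train_tsp recovers a planted reversal and handles degenerate input", {
  spec <- synthetic_spec(n_genes = 40, n_samples_per_class = 10,
                         planted = list(pair_reversal(5L, 6L, gap = 8)),
                         seed = 21)
  gen <- generate_synthetic(spec)
  model <- train_tsp(gen$dataset)
  expect_equal(model$delta, 1)
  # any delta-1 pair must involve the reversing gene
  expect_true("g005" %in% c(model$gene_i, model$gene_j))
  expect_equal(pair_score(gen$dataset, "g005", "g006")$delta, 1)

  const <- make_dataset(matrix(5, 4, 4), classes = c(1L, 1L, 2L, 2L))
  m0 <- train_tsp(const)
  expect_equal(m0$delta, 0)
  expect_equal(c(m0$gene_i, m0$gene_j), c("g1", "g2"))

  expect_error(train_tsp(make_dataset(matrix(1:4 * 1.0, 1, 4),
                                      classes = c(1L, 1L, 2L, 2L))),
               class = "relexp_precondition_error")
})

test_that("train_tsp equals the brute-force oracle on random instances", {
  for (seed in 1:25) {
    dims <- withr::with_seed(seed, c(sample(5:15, 1), sample(c(6, 8, 10), 1)))
    ds <- random_dataset(dims[1], dims[2], seed = 500 + seed)
    model <- train_tsp(ds)
    oracle <- oracle_tsp(ds)
    expect_equal(c(model$gene_i, model$gene_j),
                 c(oracle$gene_i, oracle$gene_j))
    expect_equal(model$delta, oracle$delta)
  }
})

test_that("delta is invariant under monotone transforms; label swap flips orientation", {
  ds <- random_dataset(8, 10, seed = 31)
  model <- train_tsp(ds)
  mono <- ds
  mono$values <- apply(ds$values, 2, function(x) 2^x + 1)
  rownames(mono$values) <- gene_ids(ds)
  model2 <- train_tsp(mono)
  expect_equal(model2$delta, model$delta)
  expect_equal(c(model2$gene_i, model2$gene_j), c(model$gene_i, model$gene_j))

  swapped <- ds
  swapped$classes <- ifelse(ds$classes == 1L, 2L, 1L)
  names(swapped$classes) <- names(ds$classes)
  model3 <- train_tsp(swapped)
  expect_equal(model3$delta, model$delta)
  expect_equal(pair_score(swapped, model$gene_i, model$gene_j)$delta, model$delta)
})

test_that("classification follows orientation and the documented tie rules", {
  model <- structure(list(gene_i = "a", gene_j = "b", p1 = 1, p2 = 0,
                          delta = 1, gamma = 1, orientation = 1L,
                          class_priors = c(n1 = 5L, n2 = 5L)),
                     class = c("tsp_model", "relexp_model"))
  expect_equal(classify(model, c(a = 1, b = 2)), 1L)
  expect_equal(classify(model, c(a = 2, b = 1)), 2L)
  expect_equal(classify(model, c(a = 2, b = 2)), 1L)   # tie, equal priors
  model$class_priors <- c(n1 = 3L, n2 = 5L)
  expect_equal(classify(model, c(a = 2, b = 2)), 2L)   # tie, larger class
  expect_error(classify(model, c(a = 1)), class = "relexp_lookup_error")
})
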