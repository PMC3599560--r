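test_that("ordering distributions count permutations and split ties", {
  ds <- make_dataset(rbind(a = c(1, 1, 1), b = c(2, 2, 2), c = c(3, 3, 3)),
                     classes = c(1L, 1L, 1L))
  d <- ordering_distribution(ds, 1L, c("a", "b", "c"))
  expect_equal(unname(d["a<b<c"]), 1)
  expect_equal(sum(d), 1)

  tied <- make_dataset(rbind(a = 1, b = 1, c = 2), classes = 1L)
  dt <- ordering_distribution(tied, 1L, c("a", "b", "c"))
  expect_equal(unname(dt["a<b<c"]), 0.5)
  expect_equal(unname(dt["b<a<c"]), 0.5)

  three <- make_dataset(rbind(a = c(1, 3, 2), b = c(2, 1, 3), c = c(3, 2, 1)),
                        classes = c(1L, 1L, 1L))
  d3 <- ordering_distribution(three, 1L, c("a", "b", "c"))
  expect_equal(sort(unname(d3), decreasing = TRUE)[1:3], rep(1 / 3, 3))
  expect_equal(sum(d3 > 0), 3L)

  expect_error(ordering_distribution(ds, 1L, c("a", "a", "b")),
               class = "relexp_argument_error")
})

test_that("the triple score is the total-variation distance", {
  expect_equal(tst_score(c(1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(tst_score(c(1, 1, 1, 0, 0, 0) / 3, c(0, 0, 0, 1, 1, 1) / 3), 1)
  expect_equal(tst_score(c(1, 0, 0, 0, 0, 0), c(0.5, 0.5, 0, 0, 0, 0)), 0.5)

  # metric properties on random distributions
  withr::with_seed(5, {
    for (i in 1:10) {
      p <- prop.table(runif(6)); q <- prop.table(runif(6)); r <- prop.table(runif(6))
      expect_gte(tst_score(p, q), 0)
      expect_lte(tst_score(p, q), 1)
      expect_equal(tst_score(p, q), tst_score(q, p))
      expect_lte(tst_score(p, r), tst_score(p, q) + tst_score(q, r) + 1e-12)
      expect_equal(tst_score(p, p), 0)
    }
  })
})

test_that("the cyclic construction scores 1 for the triple but 1/3 for every pair", {
  ds <- cyclic_triple_dataset(n_extra_genes = 3)
  model <- train_tst(ds)
  expect_equal(model$triple, c("g1", "g2", "g3"))
  expect_equal(model$score, 1)
  best_pair <- train_tsp(ds)
  expect_equal(best_pair$delta, 1 / 3)
})

test_that("exhaustive search matches the brute-force oracle", {
  for (seed in 1:10) {
    dims <- withr::with_seed(seed, c(sample(4:8, 1), sample(c(6, 8), 1)))
    ds <- random_dataset(dims[1], dims[2], seed = 700 + seed)
    model <- train_tst(ds)
    oracle <- oracle_tst(ds)
    expect_equal(model$triple, oracle$triple)
    expect_equal(model$score, oracle$score)
  }
})

test_that("identically distributed classes give score 0 and the first triple", {
  v <- rbind(a = c(1, 2, 3, 1, 2, 3), b = c(2, 3, 4, 2, 3, 4),
             c = c(3, 4, 5, 3, 4, 5), d = c(0, 1, 2, 0, 1, 2))
  ds <- make_dataset(v, classes = c(1L, 1L, 1L, 2L, 2L, 2L))
  model <- train_tst(ds)
  expect_equal(model$score, 0)
  expect_equal(model$triple, c("a", "b", "c"))
})

test_that("a pair's delta never exceeds the TV of a triple containing it", {
  for (seed in 1:6) {
    ds <- random_dataset(5, 10, seed = 40 + seed)
    genes <- gene_ids(ds)
    triples <- combn(genes, 3, simplify = FALSE)
    for (tri in triples) {
      tv <- tst_score(ordering_distribution(ds, 1L, tri),
                      ordering_distribution(ds, 2L, tri))
      for (pair in combn(tri, 2, simplify = FALSE)) {
        expect_lte(pair_score(ds, pair[1], pair[2])$delta, tv + 1e-12)
      }
    }
  }
})

test_that("classification uses the sample's permutation with documented fallbacks", {
  ds <- cyclic_triple_dataset()
  model <- train_tst(ds)
  pred <- predict(model, ds)
  expect_equal(unname(pred), unname(sample_classes(ds)))

  # unseen permutation (both probabilities 0) -> majority class
  model2 <- model
  model2$class_priors <- c(n1 = 5L, n2 = 3L)
  zero_perm <- names(which(model$dist1 + model$dist2 == 0))
  expect_length(zero_perm, 0L)   # cyclic construction covers all 6
  m <- structure(list(triple = c("a", "b", "c"),
                      dist1 = c(1, 0, 0, 0, 0, 0),
                      dist2 = c(0, 1, 0, 0, 0, 0),
                      score = 1, class_priors = c(n1 = 5L, n2 = 3L)),
                 class = c("tst_model", "relexp_model"))
  expect_equal(classify(m, c(a = 1, b = 2, c = 3)), 1L)  # perm 1: a<b<c
  expect_equal(classify(m, c(a = 1, b = 3, c = 2)), 2L)  # perm 2: a<c<b
  expect_equal(classify(m, c(a = 3, b = 2, c = 1)), 1L)  # unseen -> majority
  # tied sample values resolve by gene order before lookup
  expect_equal(classify(m, c(a = 1, b = 1, c = 2)), 1L)  # -> a<b<c
  expect_error(classify(m, c(a = 1, b = 2)), class = "relexp_lookup_error")
})
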