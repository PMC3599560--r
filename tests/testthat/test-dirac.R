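test_that("rank templates record majority pairwise orderings", {
  # all class samples ordered g1 > g2 > g3
  ds <- make_dataset(rbind(g1 = c(9, 8, 7), g2 = c(5, 6, 4), g3 = c(1, 2, 3)),
                     classes = c(1L, 1L, 1L))
  t1 <- rank_template(ds, 1L, c("g1", "g2", "g3"))
  expect_equal(t1$bits, c(1L, 1L, 1L))

  # pair split 2 up / 2 down -> fraction exactly 0.5 -> bit 0
  split <- make_dataset(rbind(g1 = c(2, 2, 0, 0), g2 = c(1, 1, 1, 1)),
                        classes = rep(1L, 4))
  expect_equal(rank_template(split, 1L, c("g1", "g2"))$bits, 0L)

  # single-sample class: template is that sample's orderings
  one <- make_dataset(rbind(g1 = c(1, 9), g2 = c(2, 5), g3 = c(3, 1)),
                      classes = c(1L, 2L))
  expect_equal(rank_template(one, 2L, c("g1", "g2", "g3"))$bits, c(1L, 1L, 1L))
  expect_equal(rank_template(one, 1L, c("g1", "g2", "g3"))$bits, c(0L, 0L, 0L))

  expect_error(rank_template(ds, 1L, c("g1", "absent")),
               class = "relexp_precondition_error")
})

test_that("matching score is the agreeing-pair fraction; sample ties match nothing", {
  template <- structure(list(genes = c("g1", "g2", "g3"),
                             pairs = rbind(c("g1", "g2"), c("g1", "g3"),
                                           c("g2", "g3")),
                             bits = c(1L, 1L, 1L)),
                        class = "rank_template")
  expect_equal(rank_matching_score(c(g1 = 3, g2 = 2, g3 = 1), template), 1)
  expect_equal(rank_matching_score(c(g1 = 1, g2 = 2, g3 = 3), template), 0)
  expect_equal(rank_matching_score(c(g1 = 3, g2 = 1, g3 = 2), template), 2 / 3)
  expect_equal(rank_matching_score(c(g1 = 2, g2 = 2, g3 = 1), template), 2 / 3)
  expect_error(rank_matching_score(c(g1 = 1), template),
               class = "relexp_lookup_error")
})

test_that("conservation index: 1 for identical orderings, 0.5 for opposite pair", {
  ds <- make_dataset(rbind(g1 = c(9, 8, 7), g2 = c(5, 6, 4), g3 = c(1, 2, 3)),
                     classes = c(1L, 1L, 1L))
  expect_equal(rank_conservation_index(ds, 1L, c("g1", "g2", "g3")), 1)

  # two samples with exactly opposite orderings
  opp <- make_dataset(rbind(g1 = c(3, 1), g2 = c(2, 2), g3 = c(1, 3)),
                      classes = c(1L, 1L))
  expect_equal(rank_conservation_index(opp, 1L, c("g1", "g2", "g3")), 0.5)
})

test_that("conservation exceeds the expected score under label-free shuffling", {
  spec <- synthetic_spec(n_genes = 20, n_samples_per_class = 10,
                         planted = list(network_rerank("NET", 1:5)),
                         seed = 12)
  ds <- generate_synthetic(spec)$dataset
  genes <- sprintf("g%03d", 1:5)
  observed <- rank_conservation_index(ds, 1L, genes)
  # null: permute each sample's network values independently
  nulls <- withr::with_seed(99, vapply(1:100, function(i) {
    shuffled <- ds
    for (s in sample_ids(ds)) {
      shuffled$values[genes, s] <- sample(shuffled$values[genes, s])
    }
    rank_conservation_index(shuffled, 1L, genes)
  }, numeric(1)))
  expect_gt(observed, mean(nulls))
  expect_gt(observed, 0.99)
})

test_that("network classification rate: planted reversal 1, null near 1/2", {
  spec <- synthetic_spec(n_genes = 30, n_samples_per_class = 10,
                         planted = list(network_rerank("NET", 1:5)),
                         seed = 13)
  ds <- generate_synthetic(spec)$dataset
  expect_equal(network_classification_rate(ds, sprintf("g%03d", 1:5)), 1)

  null_ds <- random_dataset(10, 20, seed = 14)
  rate <- network_classification_rate(null_ds, gene_ids(null_ds)[1:4])
  expect_lt(abs(rate - 0.5), 0.35)   # apparent rate is optimistic but near chance

  # minimal nontrivial network: a single perfectly reversing pair
  pair_ds <- make_dataset(rbind(g1 = c(2, 2, 0, 0), g2 = c(1, 1, 1, 1)),
                          classes = c(1L, 1L, 2L, 2L))
  expect_equal(network_classification_rate(pair_ds, c("g1", "g2")), 1)
})

test_that("a 2-gene network reduces to the TSP reversal decision", {
  for (seed in 1:5) {
    ds <- generate_synthetic(synthetic_spec(
      n_genes = 2, n_samples_per_class = 6,
      planted = list(pair_reversal(1L, 2L, gap = 6)), seed = 60 + seed))$dataset
    genes <- gene_ids(ds)
    t1 <- rank_template(ds, 1L, genes)
    t2 <- rank_template(ds, 2L, genes)
    expect_true(t1$bits != t2$bits)   # a genuine reversal network
    tsp <- train_tsp(ds)
    for (s in sample_ids(ds)) {
      x <- ds$values[, s]
      vote <- relexp:::dirac_network_vote(x, t1, t2, relexp:::class_priors(ds))
      expect_equal(vote, classify(tsp, x))
    }
  }
})

test_that("training selects the planted network first and classifies with it", {
  spec <- synthetic_spec(n_genes = 60, n_samples_per_class = 10,
                         planted = list(network_rerank("PLANTED", 1:5)),
                         n_decoy_networks = 9, seed = 15)
  gen <- generate_synthetic(spec)
  expect_equal(length(gen$gene_sets), 10L)
  model <- train_dirac(gen$dataset, gen$gene_sets, list(min_size = 3L, m = 1L))
  expect_equal(model$networks[[1]]$name, "PLANTED")
  expect_equal(model$networks[[1]]$rate, 1)
  expect_equal(model$network_ranking$network[1], "PLANTED")
  pred <- predict(model, gen$dataset)
  expect_equal(unname(pred), unname(sample_classes(gen$dataset)))

  # m larger than the number of eligible networks keeps all, with a note
  expect_message(big <- train_dirac(gen$dataset, gen$gene_sets,
                                    list(min_size = 3L, m = 99L)),
                 "eligible")
  expect_equal(big$m, 10L)

  expect_error(train_dirac(gen$dataset, gen$gene_sets,
                           list(min_size = 50L, m = 1L)),
               "min_size", class = "relexp_precondition_error")
})

test_that("templates and scores are invariant under monotone per-sample transforms", {
  spec <- synthetic_spec(n_genes = 20, n_samples_per_class = 8,
                         planted = list(network_rerank("NET", 1:4)),
                         seed = 16)
  ds <- generate_synthetic(spec)$dataset
  genes <- sprintf("g%03d", 1:4)
  t_orig <- rank_template(ds, 1L, genes)
  mono <- ds
  mono$values <- apply(ds$values, 2, function(x) 3 * x^3 + 7)
  rownames(mono$values) <- gene_ids(ds)
  expect_equal(rank_template(mono, 1L, genes), t_orig)
  expect_equal(network_classification_rate(mono, genes),
               network_classification_rate(ds, genes))
})

test_that("multi-network majority vote and tie fallbacks", {
  tmpl <- function(bits) {
    structure(list(genes = c("a", "b"), pairs = rbind(c("a", "b")),
                   bits = bits), class = "rank_template")
  }
  net <- function(t1, t2) list(name = "n", genes = c("a", "b"),
                               template1 = tmpl(t1), template2 = tmpl(t2),
                               rate = 1)
  model <- structure(list(networks = list(net(1L, 0L), net(1L, 0L), net(0L, 1L)),
                          m = 3L, min_size = 2L,
                          class_priors = c(n1 = 4L, n2 = 6L)),
                     class = c("dirac_model", "relexp_model"))
  # sample a > b: votes (1, 1, 2) -> class 1
  expect_equal(classify(model, c(a = 2, b = 1)), 1L)
  # all networks tie (a == b): majority training class
  expect_equal(classify(model, c(a = 1, b = 1)), 2L)
})
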