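# k-TSP: an odd-sized set of gene-disjoint top-scoring pairs combined
# by majority vote. The set size k is chosen by internal stratified
# cross-validation on the training data, refitting the gene filter and
# the pair ranking inside every inner fold so the selected k is not
# optimistically biased.

#' Rank all gene pairs by TSP score
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @return data.frame with columns `gene_i`, `gene_j`, `delta`, `gamma`,
#'   sorted by (`delta` desc, `gamma` desc, lexicographic pair position).
#' @export
rank_all_pairs <- function(dataset) {
  require_two_classes(dataset)
  if (n_genes(dataset) < 2L) abort_precondition("need at least 2 genes")
  tab <- pair_score_tables(dataset)
  ord <- order_pairs(tab)
  genes <- gene_ids(dataset)
  data.frame(gene_i = genes[tab$i[ord]], gene_j = genes[tab$j[ord]],
             delta = tab$delta[ord], gamma = tab$gamma[ord],
             stringsAsFactors = FALSE)
}

#' Greedily select gene-disjoint pairs
#'
#' Scans a ranked pair list top-down, accepting a pair only if neither
#' of its genes has been used already, until `k_max` pairs are accepted
#' or the list is exhausted ("k or less").
#'
#' @param ranked_pairs data.frame as returned by [rank_all_pairs()].
#' @param k_max maximum number of pairs.
#' @return the accepted rows of `ranked_pairs`.
#' @export
select_disjoint_pairs <- function(ranked_pairs, k_max) {
  if (!is_count(k_max) || k_max < 1L) abort_argument("k_max must be >= 1")
  used <- character(0L)
  keep <- integer(0L)
  for (r in seq_len(nrow(ranked_pairs))) {
    gi <- ranked_pairs$gene_i[r]
    gj <- ranked_pairs$gene_j[r]
    if (!(gi %in% used) && !(gj %in% used)) {
      keep <- c(keep, r)
      used <- c(used, gi, gj)
      if (length(keep) == k_max) break
    }
  }
  ranked_pairs[keep, , drop = FALSE]
}

# Build one tsp_model per selected pair (probabilities re-read from the
# training data so each pair votes with its own orientation).
pair_models_from_rows <- function(dataset, rows) {
  priors <- class_priors(dataset)
  lapply(seq_len(nrow(rows)), function(r) {
    ps <- pair_score(dataset, rows$gene_i[r], rows$gene_j[r])
    structure(list(gene_i = ps$gene_i, gene_j = ps$gene_j,
                   p1 = ps$p1, p2 = ps$p2, delta = ps$delta,
                   gamma = ps$gamma,
                   orientation = if (ps$p1 >= ps$p2) 1L else 2L,
                   class_priors = priors, filter_n = 0L),
              class = c("tsp_model", "relexp_model"))
  })
}

largest_odd_leq <- function(x) if (x %% 2L == 0L) x - 1L else x

#' Choose the number of pairs by internal cross-validation
#'
#' For each odd candidate k in 1, 3, ..., `k_max`, estimates the pooled
#' Matthews correlation of a majority vote over the top k disjoint pairs
#' by stratified inner cross-validation (gene filter and pair ranking
#' refit on each inner training fold). Returns the k with the highest
#' MCC; ties go to the smallest k. If a class has fewer samples than
#' `inner_folds`, the fold count is lowered to the minimum class size
#' with a message.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param k_max maximum (odd) number of pairs, >= 1.
#' @param inner_folds number of inner CV folds.
#' @param seed integer seed controlling the inner fold assignment.
#' @param filter_n Mann-Whitney filter size applied inside each inner
#'   fold (0 = no filtering).
#' @return the selected odd k.
#' @export
choose_k <- function(dataset, k_max, inner_folds = 5L, seed = 1L, filter_n = 0L) {
  require_two_classes(dataset)
  if (!is_count(k_max) || k_max < 1L) abort_argument("k_max must be >= 1")
  k_max <- largest_odd_leq(as.integer(k_max))
  if (k_max == 1L) return(1L)
  candidates <- seq(1L, k_max, by = 2L)
  folds <- stratified_folds(dataset, inner_folds, seed)
  confusion <- lapply(candidates, function(k) c(tp = 0, fp = 0, tn = 0, fn = 0))
  names(confusion) <- as.character(candidates)
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(labeled_sample_ids(dataset), test_ids)
    train_ds <- subset_samples(dataset, train_ids)
    train_ds <- apply_gene_filter(train_ds, filter_n)
    rows <- select_disjoint_pairs(rank_all_pairs(train_ds), k_max)
    models <- pair_models_from_rows(train_ds, rows)
    truth <- dataset$classes[test_ids]
    votes <- vapply(models, function(m) {
      vapply(test_ids, function(s) classify(m, dataset$values[, s]), integer(1L))
    }, integer(length(test_ids)))
    votes <- matrix(votes, nrow = length(test_ids))
    for (k in candidates) {
      kk <- largest_odd_leq(min(k, length(models)))
      if (kk < 1L) next
      pred <- apply(votes[, seq_len(kk), drop = FALSE], 1L, function(v) {
        if (sum(v == 1L) > kk / 2) 1L else 2L
      })
      confusion[[as.character(k)]] <-
        confusion[[as.character(k)]] + unlist(confusion_counts(truth, pred))
    }
  }
  mccs <- vapply(confusion, function(cc) {
    mcc(confusion_matrix(cc[["tp"]], cc[["fp"]], cc[["tn"]], cc[["fn"]]))
  }, numeric(1L))
  candidates[which.max(mccs)]   # which.max takes the first (smallest k) on ties
}

#' Train a k-TSP classifier
#'
#' Selects k by [choose_k()] (unless `k` is supplied explicitly), then
#' fits the top k gene-disjoint pairs on the full training data. When
#' fewer disjoint pairs are available than requested, the largest odd
#' number available is used, so the vote can never tie.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param params list: `filter_n` (default 0), `k_max` (default 10),
#'   `inner_folds` (default 5), `seed` (default 1), and optionally `k`
#'   (odd) to skip the internal selection.
#' @return an object of class `ktsp_model` with elements `pairs` (list
#'   of `tsp_model`) and `k`.
#' @export
train_ktsp <- function(dataset, params = list()) {
  require_two_classes(dataset)
  filter_n <- params[["filter_n"]] %||% 0L
  k_max <- params[["k_max"]] %||% 10L
  inner_folds <- params[["inner_folds"]] %||% 5L
  seed <- params[["seed"]] %||% 1L
  k <- params[["k"]]
  if (is.null(k)) {
    k <- choose_k(dataset, k_max, inner_folds, seed, filter_n)
  }
  if (k %% 2L == 0L) abort_argument("k must be odd")
  ds <- apply_gene_filter(dataset, filter_n)
  if (n_genes(ds) < 2L) abort_precondition("k-TSP needs at least 2 genes")
  rows <- select_disjoint_pairs(rank_all_pairs(ds), k)
  n_avail <- largest_odd_leq(nrow(rows))
  if (n_avail < k) {
    message(sprintf("only %d disjoint pairs available; using k = %d",
                    nrow(rows), n_avail))
    k <- n_avail
  }
  models <- pair_models_from_rows(ds, rows[seq_len(k), , drop = FALSE])
  structure(list(pairs = models, k = k, k_max = k_max,
                 filter_n = filter_n,
                 class_priors = class_priors(dataset)),
            class = c("ktsp_model", "relexp_model"))
}

#' @export
print.ktsp_model <- function(x, ...) {
  cat(sprintf("k-TSP classifier: k = %d pairs\n", x$k))
  for (m in x$pairs) {
    cat(sprintf("  (%s, %s)  delta = %.4f\n", m$gene_i, m$gene_j, m$delta))
  }
  invisible(x)
}

#' @rdname classify
#' @export
classify.ktsp_model <- function(model, sample_vector) {
  votes <- vapply(model$pairs, classify, integer(1L),
                  sample_vector = sample_vector)
  if (sum(votes == 1L) > length(votes) / 2) 1L else 2L
}
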