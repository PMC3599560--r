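# Top-Scoring Pair (TSP). For each ordered gene pair (i, j) the score
# is Delta = |P(Xi < Xj | class 1) - P(Xi < Xj | class 2)|, estimated by
# the empirical per-sample frequency with ties contributing 0.5. The
# classifier is the pair maximising Delta; it predicts by checking which
# way the pair is ordered in a new sample.

#' Empirical ordering probability within one class
#'
#' Fraction of the class's samples in which `gene_i` is expressed below
#' `gene_j`; a sample with exactly equal values contributes 0.5.
#'
#' @param dataset an `expression_dataset`.
#' @param class_label 1 or 2.
#' @param gene_i,gene_j distinct gene identifiers.
#' @return a probability in \[0, 1\].
#' @export
order_probability <- function(dataset, class_label, gene_i, gene_j) {
  check_pair_genes(dataset, gene_i, gene_j)
  v <- class_values(dataset, class_label)
  if (ncol(v) == 0L) abort_precondition(sprintf("class %d has no samples", class_label))
  vi <- v[gene_i, ]
  vj <- v[gene_j, ]
  mean((vi < vj) + 0.5 * (vi == vj))
}

check_pair_genes <- function(dataset, gene_i, gene_j) {
  if (identical(gene_i, gene_j)) abort_argument("gene_i and gene_j must differ")
  unknown <- setdiff(c(gene_i, gene_j), gene_ids(dataset))
  if (length(unknown)) abort_lookup(sprintf("unknown gene id: %s", unknown[1L]))
  invisible(NULL)
}

#' Score one gene pair
#'
#' `delta` is the TSP score `|p1 - p2|` with
#' `p_c = P(X_i < X_j | class c)`. `gamma` is the secondary tie-break
#' score: the absolute between-class gap in the mean within-sample rank
#' difference of the two genes. Pairs are reported with `gene_i` before
#' `gene_j` in dataset gene order.
#'
#' @inheritParams order_probability
#' @return a list with `gene_i`, `gene_j`, `p1`, `p2`, `delta`, `gamma`.
#' @export
pair_score <- function(dataset, gene_i, gene_j) {
  check_pair_genes(dataset, gene_i, gene_j)
  require_two_classes(dataset)
  idx <- match(c(gene_i, gene_j), gene_ids(dataset))
  if (idx[1L] > idx[2L]) {   # canonical order: dataset gene order
    tmp <- gene_i; gene_i <- gene_j; gene_j <- tmp
  }
  p1 <- order_probability(dataset, 1L, gene_i, gene_j)
  p2 <- order_probability(dataset, 2L, gene_i, gene_j)
  r1 <- sample_rank_matrix(class_values(dataset, 1L))
  r2 <- sample_rank_matrix(class_values(dataset, 2L))
  d1 <- mean(r1[gene_i, ] - r1[gene_j, ])
  d2 <- mean(r2[gene_i, ] - r2[gene_j, ])
  list(gene_i = gene_i, gene_j = gene_j, p1 = p1, p2 = p2,
       delta = abs(p1 - p2), gamma = abs(d1 - d2))
}

# All-pairs score matrices in one pass. Returns upper-triangle vectors
# indexed by (i, j) with i < j in dataset gene order, plus the P(Xi<Xj)
# matrices needed to orient winning pairs.
pair_score_tables <- function(dataset) {
  require_two_classes(dataset)
  g <- n_genes(dataset)
  accumulate <- function(v) {
    p <- matrix(0, g, g)
    for (s in seq_len(ncol(v))) {
      x <- v[, s]
      p <- p + outer(x, x, "<") + 0.5 * outer(x, x, "==")
    }
    p / ncol(v)
  }
  v1 <- class_values(dataset, 1L)
  v2 <- class_values(dataset, 2L)
  p1 <- accumulate(v1)
  p2 <- accumulate(v2)
  d1 <- rowMeans(sample_rank_matrix(v1))
  d2 <- rowMeans(sample_rank_matrix(v2))
  diff <- (d1 - d2)
  gamma <- abs(outer(diff, diff, "-"))
  ut <- which(upper.tri(p1), arr.ind = TRUE)  # i < j, column-major order
  list(i = ut[, 1L], j = ut[, 2L],
       delta = abs(p1 - p2)[ut], gamma = gamma[ut],
       p1 = p1, p2 = p2)
}

# shared ordering: delta desc, gamma desc, then lexicographic (i, j).
# Scores are ratios of small counts; rounding to 9 decimals removes
# floating-point jitter between algebraically equal values so ties
# cascade deterministically.
round_score <- function(x) round(x, 9L)

order_pairs <- function(tab) {
  order(-round_score(tab$delta), -round_score(tab$gamma), tab$i, tab$j)
}

build_tsp_model <- function(dataset, tab, pick, filter_n) {
  i <- tab$i[pick]; j <- tab$j[pick]
  genes <- gene_ids(dataset)
  p1 <- tab$p1[i, j]; p2 <- tab$p2[i, j]
  structure(list(
    gene_i = genes[i], gene_j = genes[j],
    p1 = p1, p2 = p2,
    delta = abs(p1 - p2), gamma = tab$gamma[pick],
    # class predicted when the new sample shows value_i < value_j
    orientation = if (p1 >= p2) 1L else 2L,
    class_priors = class_priors(dataset),
    filter_n = filter_n
  ), class = c("tsp_model", "relexp_model"))
}

#' Train a Top-Scoring Pair classifier
#'
#' Exhaustively scores every unordered gene pair in the (optionally
#' pre-filtered) dataset and returns the pair with maximal `delta`;
#' ties are broken by larger `gamma`, then by lexicographic pair
#' position in dataset gene order, so training is fully deterministic.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param params list of parameters; `filter_n` (default 0 = no
#'   filtering) keeps only the top-n Mann-Whitney genes before the pair
#'   search.
#' @return an object of class `tsp_model`.
#' @export
train_tsp <- function(dataset, params = list()) {
  require_two_classes(dataset)
  filter_n <- params[["filter_n"]] %||% 0L
  ds <- apply_gene_filter(dataset, filter_n)
  if (n_genes(ds) < 2L) abort_precondition("TSP needs at least 2 genes")
  tab <- pair_score_tables(ds)
  pick <- order_pairs(tab)[1L]
  build_tsp_model(ds, tab, pick, filter_n)
}

#' @export
print.tsp_model <- function(x, ...) {
  cat(sprintf("TSP classifier: (%s, %s)  delta = %.4f  [p1 = %.3f, p2 = %.3f]\n",
              x$gene_i, x$gene_j, x$delta, x$p1, x$p2))
  invisible(x)
}

#' Classify a sample with a trained model
#'
#' Generic over the four classifier families. `sample_vector` is a named
#' numeric vector of expression values containing at least the genes the
#' model uses.
#'
#' @param model a trained classifier.
#' @param sample_vector named numeric expression vector.
#' @return predicted class label, 1 or 2.
#' @export
classify <- function(model, sample_vector) UseMethod("classify")

get_sample_values <- function(sample_vector, genes) {
  missing <- setdiff(genes, names(sample_vector))
  if (length(missing)) {
    abort_lookup(sprintf("sample is missing gene: %s", missing[1L]))
  }
  sample_vector[genes]
}

#' @rdname classify
#' @export
classify.tsp_model <- function(model, sample_vector) {
  v <- get_sample_values(sample_vector, c(model$gene_i, model$gene_j))
  if (v[1L] < v[2L]) return(model$orientation)
  if (v[1L] > v[2L]) return(if (model$orientation == 1L) 2L else 1L)
  majority_class(model$class_priors)
}

#' Predict classes for dataset samples
#'
#' @param object a trained classifier.
#' @param dataset an `expression_dataset`.
#' @param sample_ids samples to predict (default: all).
#' @param ... unused.
#' @return named integer vector of predicted labels.
#' @export
predict.relexp_model <- function(object, dataset,
                                 sample_ids = colnames(dataset$values), ...) {
  out <- vapply(sample_ids, function(s) {
    classify(object, dataset$values[, s])
  }, integer(1L))
  names(out) <- sample_ids
  out
}
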