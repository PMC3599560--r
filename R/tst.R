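# Top-Scoring Triplet (TST). A triple of genes induces, within every
# sample, one of the 6 possible orderings of the three expression
# values. Each class thus has an empirical distribution over the 6
# permutations; the TST score is the total-variation distance between
# the two class distributions, which reduces to the TSP |p1 - p2| for a
# pair and lies in [0, 1]. Training is exhaustive over all C(G, 3)
# triples, which is why the Mann-Whitney pre-filter matters here.

# The 6 permutations, rows listing gene positions from lowest to
# highest value: row (a, b, c) means value[a] < value[b] < value[c].
TRIPLE_PERMS <- rbind(
  c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
)
perm_labels <- function(triple) {
  apply(TRIPLE_PERMS, 1L, function(p) paste(triple[p], collapse = "<"))
}

# map from the comparison code 1*(va>vb) + 2*(va>vc) + 4*(vb>vc) to a
# permutation row; codes 2 and 5 are impossible without ties
PERM_CODE <- c(1L, 3L, NA, 4L, 2L, NA, 5L, 6L)

# per-sample weights over the 6 permutations for a set of triples.
# `v` is the sample's expression vector (by gene index), `tri` an
# n x 3 index matrix. A permutation is compatible with the sample iff
# sorting the triple by it is non-decreasing; samples with ties split
# their unit mass equally over the compatible permutations.
triple_perm_weights <- function(v, tri) {
  ok <- matrix(FALSE, nrow(tri), 6L)
  for (p in seq_len(6L)) {
    a <- v[tri[, TRIPLE_PERMS[p, 1L]]]
    b <- v[tri[, TRIPLE_PERMS[p, 2L]]]
    c_ <- v[tri[, TRIPLE_PERMS[p, 3L]]]
    ok[, p] <- (a <= b) & (b <= c_)
  }
  ok / rowSums(ok)
}

#' Empirical ordering distribution of a gene triple
#'
#' Each sample of the class contributes its observed ordering of the
#' three expression values; within-sample ties split the contribution
#' equally over the compatible orderings. The 6 frequencies are
#' reported in a fixed order and sum to 1.
#'
#' @param dataset an `expression_dataset`.
#' @param class_label 1 or 2.
#' @param triple character vector of three distinct gene identifiers.
#' @return named numeric 6-vector of frequencies (names like
#'   `"gA<gB<gC"`, lowest expression first).
#' @export
ordering_distribution <- function(dataset, class_label, triple) {
  if (length(triple) != 3L || anyDuplicated(triple)) {
    abort_argument("triple must name three distinct genes")
  }
  unknown <- setdiff(triple, gene_ids(dataset))
  if (length(unknown)) abort_lookup(sprintf("unknown gene id: %s", unknown[1L]))
  v <- class_values(dataset, class_label)
  if (ncol(v) == 0L) abort_precondition(sprintf("class %d has no samples", class_label))
  idx <- matrix(match(triple, gene_ids(dataset)), 1L, 3L)
  freq <- numeric(6L)
  for (s in seq_len(ncol(v))) {
    freq <- freq + triple_perm_weights(v[, s], idx)[1L, ]
  }
  freq <- freq / ncol(v)
  names(freq) <- perm_labels(triple)
  freq
}

#' Total-variation distance between two ordering distributions
#'
#' `0.5 * sum(|p1 - p2|)` over the 6 permutations: 0 for identical
#' distributions, 1 for disjoint supports.
#'
#' @param dist1,dist2 numeric 6-vectors of frequencies.
#' @return a real in \[0, 1\].
#' @export
tst_score <- function(dist1, dist2) {
  if (length(dist1) != 6L || length(dist2) != 6L) {
    abort_argument("ordering distributions have 6 components")
  }
  0.5 * sum(abs(dist1 - dist2))
}

#' Train a Top-Scoring Triplet classifier
#'
#' Exhaustively maximises the total-variation score over all gene
#' triples of the (optionally pre-filtered) dataset; score ties are
#' broken by lexicographic triple position in dataset gene order.
#' The cubic search cost is the reason `filter_n` is normally kept at
#' or below a few hundred genes.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param params list; `filter_n` (default 0 = no filtering).
#' @return an object of class `tst_model` with the winning `triple`,
#'   both class ordering distributions and the `score`.
#' @export
train_tst <- function(dataset, params = list()) {
  require_two_classes(dataset)
  filter_n <- params[["filter_n"]] %||% 0L
  ds <- apply_gene_filter(dataset, filter_n)
  g <- n_genes(ds)
  if (g < 3L) abort_precondition("TST needs at least 3 genes")
  tri <- t(utils::combn(g, 3L))           # lexicographic triple order
  class_freq <- function(v) {
    freq <- matrix(0, nrow(tri), 6L)
    for (s in seq_len(ncol(v))) {
      x <- v[, s]
      if (anyDuplicated(x) == 0L) {
        # fast path, no ties: one permutation per triple
        a <- x[tri[, 1L]]; b <- x[tri[, 2L]]; c_ <- x[tri[, 3L]]
        code <- 1L + (a > b) + 2L * (a > c_) + 4L * (b > c_)
        freq[cbind(seq_len(nrow(tri)), PERM_CODE[code])] <-
          freq[cbind(seq_len(nrow(tri)), PERM_CODE[code])] + 1
      } else {
        freq <- freq + triple_perm_weights(x, tri)
      }
    }
    freq / ncol(v)
  }
  f1 <- class_freq(class_values(ds, 1L))
  f2 <- class_freq(class_values(ds, 2L))
  scores <- 0.5 * rowSums(abs(f1 - f2))
  pick <- which.max(round_score(scores))  # first maximum = lexicographic tie-break
  triple <- gene_ids(ds)[tri[pick, ]]
  d1 <- f1[pick, ]; d2 <- f2[pick, ]
  names(d1) <- names(d2) <- perm_labels(triple)
  structure(list(triple = triple, dist1 = d1, dist2 = d2,
                 score = scores[pick],
                 class_priors = class_priors(ds), filter_n = filter_n),
            class = c("tst_model", "relexp_model"))
}

#' @export
print.tst_model <- function(x, ...) {
  cat(sprintf("TST classifier: (%s)  score = %.4f\n",
              paste(x$triple, collapse = ", "), x$score))
  invisible(x)
}

#' @rdname classify
#' @export
classify.tst_model <- function(model, sample_vector) {
  v <- get_sample_values(sample_vector, model$triple)
  # average-rank ordering with ties broken by gene order -> a strict
  # permutation, looked up in both class distributions
  ord <- order(v, seq_len(3L))
  p <- which(apply(TRIPLE_PERMS, 1L, function(row) all(row == ord)))
  p1 <- model$dist1[[p]]
  p2 <- model$dist2[[p]]
  if (p1 > p2) return(1L)
  if (p2 > p1) return(2L)
  majority_class(model$class_priors)
}
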