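# Rank-based differential-expression pre-filter. TSP, k-TSP and TST
# search cost grows polynomially in the number of genes, so they are
# typically run on the top-n genes ranked by a two-sample Mann-Whitney
# (Wilcoxon rank-sum) separation statistic. The score used is the
# centred |U - n1*n2/2| count, not a p-value: only the gene ranking
# matters for top-n selection.

# U statistic (ties counted 0.5) for every gene at once, plus the
# centred separation score. Computed on the labelled samples only.
rank_sum_statistics <- function(dataset) {
  require_two_classes(dataset)
  v1 <- class_values(dataset, 1L)
  v2 <- class_values(dataset, 2L)
  n1 <- ncol(v1)
  n2 <- ncol(v2)
  combined <- cbind(v1, v2)
  # per-gene ranks across samples; U = sum of class-1 ranks - n1(n1+1)/2
  u <- apply(combined, 1L, function(x) {
    sum(rank(x, ties.method = "average")[seq_len(n1)])
  }) - n1 * (n1 + 1) / 2
  data.frame(gene_id = gene_ids(dataset),
             u = u,
             statistic = abs(u - n1 * n2 / 2),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney separation score for one gene
#'
#' Computes `U`, the number of (class-1 sample, class-2 sample) pairs in
#' which the class-1 value is larger (tied pairs count 0.5), and the
#' separation score `|U - n1*n2/2|`. The score is 0 when the two class
#' distributions are rank-identical and reaches `n1*n2/2` for complete
#' separation in either direction; it is invariant under monotone
#' transforms of the gene's values.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param gene_id a gene identifier.
#' @return a list with `gene_id`, `u` and `statistic`.
#' @export
rank_sum_score <- function(dataset, gene_id) {
  if (!gene_id %in% gene_ids(dataset)) {
    abort_lookup(sprintf("unknown gene id: %s", gene_id))
  }
  stats <- rank_sum_statistics(subset_genes(dataset, gene_id))
  list(gene_id = gene_id, u = stats$u[1L], statistic = stats$statistic[1L])
}

#' Keep the most differential genes
#'
#' Restricts the dataset to the `n` genes with the largest Mann-Whitney
#' separation score, computed on the labelled samples of `dataset` only
#' (inside cross-validation this is the training fold, so selection is
#' refit per fold and never sees held-out samples). Score ties are
#' broken in favour of the gene appearing earlier in the dataset; the
#' returned dataset keeps the original gene order.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param n number of genes to keep (1..`n_genes(dataset)`).
#' @return the restricted `expression_dataset`.
#' @export
select_top_genes <- function(dataset, n) {
  if (!is_count(n) || n < 1L || n > n_genes(dataset)) {
    abort_argument(sprintf("n must be between 1 and %d", n_genes(dataset)))
  }
  stats <- rank_sum_statistics(dataset)
  picked <- order(-stats$statistic, seq_len(n_genes(dataset)))[seq_len(n)]
  subset_genes(dataset, gene_ids(dataset)[sort(picked)])
}

# filter_n = 0 disables filtering (used by the learner wrappers)
apply_gene_filter <- function(dataset, filter_n) {
  if (is.null(filter_n) || filter_n == 0L) return(dataset)
  select_top_genes(dataset, min(filter_n, n_genes(dataset)))
}
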