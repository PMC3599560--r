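# Independent brute-force oracles and tiny fixture builders. The
# oracles deliberately share no code with the package internals: they
# recompute everything with naive per-sample loops.

# a dataset from an explicit matrix, classes split in half by default
make_dataset <- function(values, classes = NULL) {
  g <- nrow(values); m <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(g))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(m))
  if (is.null(classes)) classes <- rep(c(1L, 2L), each = m / 2)
  expression_dataset(values, classes = classes)
}

random_dataset <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    n1 <- max(2L, floor(n_samples / 2))
    n2 <- n_samples - n1
    values <- matrix(rnorm(n_genes * n_samples, mean = rep(runif(n_genes, 4, 10), n_samples)),
                     n_genes, n_samples)
    make_dataset(values, classes = rep(c(1L, 2L), c(n1, n2)))
  })
}

# dataset whose class-1 samples realize each of the 3 cyclic value
# orderings of (g1, g2, g3) exactly once and class-2 the 3 anti-cyclic
# ones: the canonical TSP-vs-TST separation instance, by enumeration
cyclic_triple_dataset <- function(n_extra_genes = 0L) {
  # columns = samples; rows g1, g2, g3 with values 1 < 2 < 3
  # class 1 orderings: 1<2<3, 2<3<1, 3<1<2 ; class 2: 1<3<2, 3<2<1, 2<1<3
  v <- cbind(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1),   # cyclic
             c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))   # anti-cyclic
  if (n_extra_genes > 0L) {
    v <- rbind(v, matrix(rep(seq_len(n_extra_genes) + 10, 6), n_extra_genes, 6, byrow = FALSE))
  }
  make_dataset(v, classes = rep(c(1L, 2L), each = 3))
}

# naive TSP oracle: loop over all pairs and samples
oracle_tsp <- function(dataset) {
  v <- dataset$values
  cls <- dataset$classes
  genes <- rownames(v)
  best <- NULL
  prob_less <- function(i, j, c) {
    cols <- which(!is.na(cls) & cls == c)
    total <- 0
    for (s in cols) {
      if (v[i, s] < v[j, s]) total <- total + 1
      else if (v[i, s] == v[j, s]) total <- total + 0.5
    }
    total / length(cols)
  }
  ranks <- vapply(seq_len(ncol(v)), function(s) rank(v[, s]),
                  numeric(nrow(v)))
  rank_diff_gap <- function(i, j) {
    gap <- c(0, 0)
    for (c in 1:2) {
      cols <- which(!is.na(cls) & cls == c)
      gap[c] <- mean(ranks[i, cols] - ranks[j, cols])
    }
    abs(gap[1] - gap[2])
  }
  for (i in seq_len(nrow(v) - 1L)) {
    for (j in (i + 1L):nrow(v)) {
      delta <- abs(prob_less(i, j, 1) - prob_less(i, j, 2))
      gamma <- rank_diff_gap(i, j)
      if (is.null(best) || delta > best$delta + 1e-12 ||
          (abs(delta - best$delta) <= 1e-12 && gamma > best$gamma + 1e-12)) {
        best <- list(gene_i = genes[i], gene_j = genes[j],
                     delta = delta, gamma = gamma)
      }
    }
  }
  best
}

# naive TST oracle: per-sample sort, per-triple count over 6 orderings
oracle_tst <- function(dataset) {
  v <- dataset$values
  cls <- dataset$classes
  genes <- rownames(v)
  g <- nrow(v)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  dist_for <- function(triple, c) {
    cols <- which(!is.na(cls) & cls == c)
    freq <- numeric(6)
    for (s in cols) {
      x <- v[triple, s]
      compat <- vapply(perms, function(p) !is.unsorted(x[p]), logical(1))
      freq <- freq + compat / sum(compat)
    }
    freq / length(cols)
  }
  best <- NULL
  for (i in seq_len(g - 2L)) {
    for (j in (i + 1L):(g - 1L)) {
      for (k in (j + 1L):g) {
        score <- 0.5 * sum(abs(dist_for(c(i, j, k), 1) - dist_for(c(i, j, k), 2)))
        if (is.null(best) || score > best$score + 1e-12) {
          best <- list(triple = genes[c(i, j, k)], score = score)
        }
      }
    }
  }
  best
}
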