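#' Construct a two-class expression dataset
#'
#' The central container used throughout the package: a real-valued
#' genes-by-samples matrix with unique gene and sample identifiers and an
#' optional two-class labelling of the samples. Class labels are the
#' integers 1 and 2; class 1 is treated as the "positive" class in
#' confusion-matrix bookkeeping. Samples left unlabelled (`NA`) are
#' ignored by every training and cross-validation routine.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers; defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `colnames(values)`.
#' @param classes optional labelling: either a named vector (names are
#'   sample ids, values 1, 2 or `NA`) or an unnamed vector of length
#'   `ncol(values)` in column order.
#' @return an object of class `expression_dataset` with elements
#'   `values` (matrix with dimnames) and `classes` (named integer vector,
#'   `NA` = unassigned).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, classes = c(1, 1, 2, 2))
#' n_genes(ds)
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values),
                               classes = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_argument("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort_argument("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    abort_argument(sprintf(
      "matrix is %d x %d but %d gene ids and %d sample ids were given",
      nrow(values), ncol(values), length(gene_ids), length(sample_ids)))
  }
  if (anyDuplicated(gene_ids)) {
    abort_argument(sprintf("duplicate gene id: %s",
                           gene_ids[duplicated(gene_ids)][1L]))
  }
  if (anyDuplicated(sample_ids)) {
    abort_argument(sprintf("duplicate sample id: %s",
                           sample_ids[duplicated(sample_ids)][1L]))
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort_argument("dataset must contain at least one gene and one sample")
  }
  if (anyNA(values)) abort_argument("expression values must not be missing")
  dimnames(values) <- list(gene_ids, sample_ids)

  cls <- rep(NA_integer_, length(sample_ids))
  names(cls) <- sample_ids
  if (!is.null(classes)) {
    if (!is.null(names(classes))) {
      unknown <- setdiff(names(classes), sample_ids)
      if (length(unknown)) {
        abort_lookup(sprintf("unknown sample id in classes: %s", unknown[1L]))
      }
      cls[names(classes)] <- as.integer(classes)
    } else {
      if (length(classes) != length(sample_ids)) {
        abort_argument("unnamed `classes` must have one entry per sample")
      }
      cls[] <- as.integer(classes)
    }
    bad <- !is.na(cls) & !(cls %in% c(1L, 2L))
    if (any(bad)) abort_argument("class labels must be 1, 2 or NA")
  }
  structure(list(values = values, classes = cls),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  n1 <- sum(x$classes == 1L, na.rm = TRUE)
  n2 <- sum(x$classes == 2L, na.rm = TRUE)
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (class 1: %d, class 2: %d, unassigned: %d)\n",
    nrow(x$values), ncol(x$values), n1, n2,
    sum(is.na(x$classes))))
  invisible(x)
}

#' Dataset accessors
#'
#' @param dataset an `expression_dataset`.
#' @return `gene_ids()` and `sample_ids()` return character vectors;
#'   `n_genes()`/`n_samples()` integer counts; `sample_classes()` the named
#'   class vector (`NA` = unassigned).
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
gene_ids <- function(dataset) rownames(dataset$values)

#' @rdname dataset-accessors
#' @export
sample_ids <- function(dataset) colnames(dataset$values)

#' @rdname dataset-accessors
#' @export
n_genes <- function(dataset) nrow(dataset$values)

#' @rdname dataset-accessors
#' @export
n_samples <- function(dataset) ncol(dataset$values)

#' @rdname dataset-accessors
#' @export
sample_classes <- function(dataset) dataset$classes

# ids of samples assigned to either class, in dataset column order
labeled_sample_ids <- function(dataset) {
  sample_ids(dataset)[!is.na(dataset$classes)]
}

# guard used by every training entry point
require_two_classes <- function(dataset) {
  n1 <- sum(dataset$classes == 1L, na.rm = TRUE)
  n2 <- sum(dataset$classes == 2L, na.rm = TRUE)
  if (n1 < 1L || n2 < 1L) {
    abort_precondition(sprintf(
      "training requires samples in both classes (class 1: %d, class 2: %d)",
      n1, n2))
  }
  invisible(dataset)
}

#' Rank the genes within one sample
#'
#' Per-sample rank transform: rank 1 is the lowest expression value and
#' tied values receive the average of the ranks they span. Ranks over `n`
#' genes therefore always sum to `n(n+1)/2`. All four classifiers operate
#' on functions of these within-sample ranks, which is what makes them
#' invariant to any strictly monotone per-sample normalisation.
#'
#' @param dataset an `expression_dataset`.
#' @param sample_id a sample identifier present in the dataset.
#' @return named numeric vector of ranks (one per gene).
#' @export
rank_sample <- function(dataset, sample_id) {
  if (!sample_id %in% sample_ids(dataset)) {
    abort_lookup(sprintf("unknown sample id: %s", sample_id))
  }
  r <- rank(dataset$values[, sample_id], ties.method = "average")
  names(r) <- gene_ids(dataset)
  r
}

# all samples at once: genes x samples matrix of within-sample ranks
sample_rank_matrix <- function(values) {
  apply(values, 2L, rank, ties.method = "average")
}

#' Subset a dataset by sample
#'
#' Keeps the requested samples (in the requested order), preserves gene
#' order, and carries class labels through. Used internally to build
#' cross-validation folds.
#'
#' @param dataset an `expression_dataset`.
#' @param keep_ids character vector of sample ids to retain (non-empty).
#' @return an `expression_dataset`.
#' @export
subset_samples <- function(dataset, keep_ids) {
  keep_ids <- as.character(keep_ids)
  if (length(keep_ids) == 0L) {
    abort_argument("cannot subset to an empty sample set")
  }
  unknown <- setdiff(keep_ids, sample_ids(dataset))
  if (length(unknown)) {
    abort_lookup(sprintf("unknown sample id: %s", unknown[1L]))
  }
  if (anyDuplicated(keep_ids)) {
    abort_argument("duplicate sample id in subset request")
  }
  expression_dataset(dataset$values[, keep_ids, drop = FALSE],
                     classes = dataset$classes[keep_ids])
}

# gene subset, preserving dataset gene order when `preserve_order` is TRUE
subset_genes <- function(dataset, keep_genes) {
  unknown <- setdiff(keep_genes, gene_ids(dataset))
  if (length(unknown)) {
    abort_lookup(sprintf("unknown gene id: %s", unknown[1L]))
  }
  expression_dataset(dataset$values[keep_genes, , drop = FALSE],
                     classes = dataset$classes)
}

#' Assign class labels directly
#'
#' @param dataset an `expression_dataset`.
#' @param class1_ids,class2_ids sample ids for class 1 and class 2; any
#'   sample in neither list becomes unassigned.
#' @return the relabelled dataset.
#' @export
assign_classes <- function(dataset, class1_ids, class2_ids) {
  class1_ids <- as.character(class1_ids)
  class2_ids <- as.character(class2_ids)
  both <- intersect(class1_ids, class2_ids)
  if (length(both)) {
    abort_conflict(sprintf("samples claimed by both classes: %s",
                           paste(both, collapse = ", ")))
  }
  unknown <- setdiff(c(class1_ids, class2_ids), sample_ids(dataset))
  if (length(unknown)) {
    abort_lookup(sprintf("unknown sample id: %s", unknown[1L]))
  }
  if (length(class1_ids) == 0L || length(class2_ids) == 0L) {
    abort_precondition("both classes need at least one sample")
  }
  cls <- rep(NA_integer_, n_samples(dataset))
  names(cls) <- sample_ids(dataset)
  cls[class1_ids] <- 1L
  cls[class2_ids] <- 2L
  expression_dataset(dataset$values, classes = cls)
}

# training-sample views used by the learners
class_sample_ids <- function(dataset, class_label) {
  sample_ids(dataset)[!is.na(dataset$classes) & dataset$classes == class_label]
}

class_values <- function(dataset, class_label) {
  dataset$values[, class_sample_ids(dataset, class_label), drop = FALSE]
}

class_priors <- function(dataset) {
  c(n1 = sum(dataset$classes == 1L, na.rm = TRUE),
    n2 = sum(dataset$classes == 2L, na.rm = TRUE))
}

# deterministic tie rule shared by all classifiers: prefer the larger
# training class, then class 1
majority_class <- function(priors) {
  if (priors[["n2"]] > priors[["n1"]]) 2L else 1L
}
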