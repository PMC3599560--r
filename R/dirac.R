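# Differential Rank Conservation (DIRAC). Works on predefined gene
# sets ("networks", e.g. pathways from a GMT file) rather than searched
# pairs/triples. Per network and class a binary rank template records,
# for every gene pair, which gene is higher in the majority of that
# class's samples; a sample's rank matching score against a template is
# the fraction of pairs it agrees with. Networks whose templates
# separate the classes well (high training classification rate under
# the two-template rule) are kept and vote on new samples.

network_genes_present <- function(dataset, network_genes) {
  network_genes[network_genes %in% gene_ids(dataset)]
}

#' Build a class rank template for a network
#'
#' For every pair (i, j) of network genes present in the dataset (i
#' before j in network gene order) the template bit is 1 iff gene i is
#' expressed above gene j in strictly more than half of the class's
#' samples (ties within a sample count 0.5 toward the fraction; a
#' fraction of exactly 0.5 gives bit 0, so templates are deterministic
#' for even class sizes).
#'
#' @param dataset an `expression_dataset`.
#' @param class_label 1 or 2.
#' @param network_genes character vector of the network's genes; genes
#'   absent from the dataset are dropped (at least 2 must remain).
#' @return a list with `genes`, `pairs` (2-column character matrix) and
#'   `bits` (integer 0/1 vector), of class `rank_template`.
#' @export
rank_template <- function(dataset, class_label, network_genes) {
  genes <- network_genes_present(dataset, network_genes)
  if (length(genes) < 2L) {
    abort_precondition("network has fewer than 2 genes present in the dataset")
  }
  v <- class_values(dataset, class_label)[genes, , drop = FALSE]
  if (ncol(v) == 0L) abort_precondition(sprintf("class %d has no samples", class_label))
  pairs <- t(utils::combn(length(genes), 2L))
  frac <- vapply(seq_len(nrow(pairs)), function(r) {
    vi <- v[pairs[r, 1L], ]
    vj <- v[pairs[r, 2L], ]
    mean((vi > vj) + 0.5 * (vi == vj))
  }, numeric(1L))
  structure(list(
    genes = genes,
    pairs = cbind(genes[pairs[, 1L]], genes[pairs[, 2L]]),
    bits = as.integer(frac > 0.5)
  ), class = "rank_template")
}

#' Rank matching score of a sample against a template
#'
#' Fraction of the template's gene pairs whose ordering in the sample
#' agrees with the template bit; a tied pair in the sample matches
#' neither orientation and contributes 0.
#'
#' @param sample_vector named numeric expression vector containing all
#'   template genes.
#' @param template a `rank_template`.
#' @return a real in \[0, 1\].
#' @export
rank_matching_score <- function(sample_vector, template) {
  v <- get_sample_values(sample_vector, template$genes)
  vi <- v[template$pairs[, 1L]]
  vj <- v[template$pairs[, 2L]]
  observed_up <- vi > vj
  tied <- vi == vj
  mean(!tied & (observed_up == (template$bits == 1L)))
}

#' Rank conservation index of a network within a class
#'
#' Mean rank matching score of the class's samples against their own
#' class template: 1 when every sample orders the network identically,
#' lower as the within-class ordering becomes less conserved.
#'
#' @inheritParams rank_template
#' @return a real in \[0, 1\].
#' @export
rank_conservation_index <- function(dataset, class_label, network_genes) {
  template <- rank_template(dataset, class_label, network_genes)
  ids <- class_sample_ids(dataset, class_label)
  mean(vapply(ids, function(s) {
    rank_matching_score(dataset$values[, s], template)
  }, numeric(1L)))
}

# two-template decision for one sample; tie -> larger class, then class 1
dirac_network_vote <- function(sample_vector, t1, t2, priors = NULL) {
  s1 <- rank_matching_score(sample_vector, t1)
  s2 <- rank_matching_score(sample_vector, t2)
  if (s1 > s2) return(1L)
  if (s2 > s1) return(2L)
  if (is.null(priors)) return(NA_integer_)   # network abstains
  majority_class(priors)
}

#' Apparent classification rate of one network
#'
#' Builds both class templates from the labelled samples, assigns every
#' labelled sample to the class whose template it matches better
#' (tie -> larger class, then class 1), and returns the fraction
#' classified correctly. This is the score used to rank networks during
#' DIRAC training.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param network_genes character vector of the network's genes.
#' @return a real in \[0, 1\].
#' @export
network_classification_rate <- function(dataset, network_genes) {
  require_two_classes(dataset)
  t1 <- rank_template(dataset, 1L, network_genes)
  t2 <- rank_template(dataset, 2L, network_genes)
  priors <- class_priors(dataset)
  ids <- labeled_sample_ids(dataset)
  pred <- vapply(ids, function(s) {
    dirac_network_vote(dataset$values[, s], t1, t2, priors)
  }, integer(1L))
  mean(pred == dataset$classes[ids])
}

#' Train a DIRAC classifier
#'
#' Scores every eligible network (at least `min_size` genes present in
#' the dataset) by its training classification rate and keeps the top
#' `m`, ties resolved by collection order. Both class templates are
#' stored per kept network; classification is by majority vote of the
#' kept networks' two-template decisions.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param gene_sets a `gene_set_collection`.
#' @param params list: `min_size` (default 3) minimum network size after
#'   intersecting with the dataset's genes; `m` (default 1) number of
#'   networks kept for classification.
#' @return an object of class `dirac_model`; element `networks` holds,
#'   per kept network, its name, templates and training rate, and
#'   `network_ranking` records the rate of every eligible network.
#' @export
train_dirac <- function(dataset, gene_sets, params = list()) {
  require_two_classes(dataset)
  if (!inherits(gene_sets, "gene_set_collection")) {
    abort_argument("`gene_sets` must be a gene_set_collection")
  }
  min_size <- params[["min_size"]] %||% 3L
  m <- params[["m"]] %||% 1L
  if (!is_count(m) || m < 1L) abort_argument("m must be >= 1")
  if (!is_count(min_size) || min_size < 2L) {
    abort_argument("min_size must be >= 2")
  }
  eligible <- Filter(function(s) {
    length(network_genes_present(dataset, s$genes)) >= min_size
  }, gene_sets$sets)
  if (length(eligible) == 0L) {
    abort_precondition(sprintf(
      "no network has >= %d genes present in the dataset (min_size)", min_size))
  }
  rates <- vapply(eligible, function(s) {
    network_classification_rate(dataset, s$genes)
  }, numeric(1L))
  ord <- order(-round_score(rates), seq_along(rates))  # ties -> collection order
  if (m > length(eligible)) {
    message(sprintf("only %d eligible networks; keeping all of them",
                    length(eligible)))
    m <- length(eligible)
  }
  kept <- lapply(ord[seq_len(m)], function(i) {
    s <- eligible[[i]]
    list(name = s$name,
         genes = network_genes_present(dataset, s$genes),
         template1 = rank_template(dataset, 1L, s$genes),
         template2 = rank_template(dataset, 2L, s$genes),
         rate = rates[i])
  })
  ranking <- data.frame(
    network = vapply(eligible, `[[`, character(1L), "name")[ord],
    rate = rates[ord], stringsAsFactors = FALSE)
  structure(list(networks = kept, m = m, min_size = min_size,
                 network_ranking = ranking,
                 class_priors = class_priors(dataset)),
            class = c("dirac_model", "relexp_model"))
}

#' @export
print.dirac_model <- function(x, ...) {
  cat(sprintf("DIRAC classifier: %d network(s), min_size = %d\n",
              x$m, x$min_size))
  for (nw in x$networks) {
    cat(sprintf("  %s (%d genes)  training rate = %.3f\n",
                nw$name, length(nw$genes), nw$rate))
  }
  invisible(x)
}

#' @rdname classify
#' @export
classify.dirac_model <- function(model, sample_vector) {
  votes <- vapply(model$networks, function(nw) {
    dirac_network_vote(sample_vector, nw$template1, nw$template2)
  }, integer(1L))
  votes <- votes[!is.na(votes)]             # tied networks abstain
  n1 <- sum(votes == 1L)
  n2 <- sum(votes == 2L)
  if (n1 > n2) return(1L)
  if (n2 > n1) return(2L)
  majority_class(model$class_priors)
}
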