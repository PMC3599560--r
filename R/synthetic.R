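# Synthetic two-class expression data with planted rank signals. The
# generator emulates, at desk scale, the kind of curated two-cohort
# microarray comparison the classifiers are aimed at: a genes-by-samples
# table of continuous expression values in which most genes carry no
# class information and a few carry a planted relative-expression
# signal of one of three kinds:
#   pair_reversal   - the ordering of two genes flips between classes
#                     (the TSP signal),
#   triple_cycle    - a gene triple whose per-sample ordering is drawn
#                     from the 3 cyclic permutations in class 1 and the
#                     3 anti-cyclic ones in class 2; every pairwise
#                     delta is capped at 1/3 while the triple separates
#                     the classes perfectly (the TST-vs-TSP fixture),
#   network_rerank  - a named gene set whose expression ladder is fully
#                     reversed between classes (the DIRAC signal).

#' Planted signal constructors
#'
#' Build planted-signal descriptions for [synthetic_spec()]. Genes are
#' referenced by index into the generated dataset.
#'
#' @param gene_i,gene_j,gene_k gene indices.
#' @param gap positive expression offset between the pair genes (same
#'   units as the values; the reversal is clean when
#'   `gap >= 6 * noise_sd`).
#' @param network_name name of the planted gene set.
#' @param genes integer vector of gene indices (>= 2).
#' @return a list describing the signal.
#' @name planted-signals
NULL

#' @rdname planted-signals
#' @export
pair_reversal <- function(gene_i, gene_j, gap) {
  if (gap <= 0) abort_argument("gap must be positive")
  list(type = "pair_reversal", genes = c(gene_i, gene_j), gap = gap)
}

#' @rdname planted-signals
#' @export
triple_cycle <- function(gene_i, gene_j, gene_k) {
  list(type = "triple_cycle", genes = c(gene_i, gene_j, gene_k))
}

#' @rdname planted-signals
#' @export
network_rerank <- function(network_name, genes) {
  if (length(genes) < 2L) abort_argument("a planted network needs >= 2 genes")
  list(type = "network_rerank", name = network_name, genes = genes)
}

#' Specification of a synthetic dataset
#'
#' Defaults describe the standard study condition used throughout the
#' package's own validation: 100 genes, 20 samples per class, unit
#' Gaussian noise on per-gene baselines drawn uniformly from
#' \[4, 10\] (a log2-intensity-like scale).
#'
#' @param n_genes number of genes.
#' @param n_samples_per_class samples in each of the two classes.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param planted list of planted signals, see [pair_reversal()],
#'   [triple_cycle()], [network_rerank()]. A gene may carry at most one
#'   signal.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param n_decoy_networks number of additional gene sets made of
#'   signal-free background genes (DIRAC decoys).
#' @param decoy_network_size genes per decoy network.
#' @param noise_model `"normal"` (default) or `"lognormal"` (values are
#'   exponentiated base 2 after generation, mimicking raw intensity
#'   scale; rank structure is unchanged).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 100L, n_samples_per_class = 20L,
                           noise_sd = 1, planted = list(), seed = 1L,
                           n_decoy_networks = 0L, decoy_network_size = 5L,
                           noise_model = c("normal", "lognormal")) {
  noise_model <- match.arg(noise_model)
  if (!is_count(n_genes) || n_genes < 2L) abort_argument("n_genes must be >= 2")
  if (!is_count(n_samples_per_class) || n_samples_per_class < 1L) {
    abort_argument("n_samples_per_class must be >= 1")
  }
  if (noise_sd <= 0) abort_argument("noise_sd must be positive")
  used <- integer(0L)
  for (sig in planted) {
    g <- sig$genes
    if (any(g < 1L | g > n_genes)) {
      abort_argument("planted signal references a gene outside 1..n_genes")
    }
    if (anyDuplicated(g) || length(intersect(g, used))) {
      abort_argument("planted signals must not share genes")
    }
    used <- c(used, g)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 noise_sd = noise_sd, planted = planted,
                 seed = as.integer(seed),
                 n_decoy_networks = as.integer(n_decoy_networks),
                 decoy_network_size = as.integer(decoy_network_size),
                 noise_model = noise_model),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with planted signals
#'
#' Background genes get a per-gene baseline mean drawn uniformly from
#' \[4, 10\]; planted signals override the class-specific means of
#' their genes (pair reversal: `mean_i = mean_j +/- gap`; triple cycle
#' and network rerank: value ladders spaced `6 * noise_sd` apart so the
#' planted ordering survives the noise essentially always). Gaussian
#' noise with sd `noise_sd` is then added everywhere. Class 1 samples
#' come first in column order; everything is deterministic given the
#' spec's seed.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `dataset` (an `expression_dataset`, classes
#'   assigned) and `gene_sets` (a `gene_set_collection` containing the
#'   planted networks followed by any decoys; empty collection objects
#'   are replaced by `NULL` when there are no networks at all).
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort_argument("`spec` must be a synthetic_spec")
  }
  g <- spec$n_genes
  n <- spec$n_samples_per_class
  m <- 2L * n
  gene_names <- sprintf("g%03d", seq_len(g))
  sample_names <- sprintf("s%03d", seq_len(m))
  cls <- rep(c(1L, 2L), each = n)
  class_cols <- list(`1` = seq_len(n), `2` = n + seq_len(n))
  step <- 6 * spec$noise_sd

  values <- withr::with_seed(spec$seed, {
    means <- matrix(stats::runif(g, 4, 10), g, m)
    for (sig in spec$planted) {
      if (sig$type == "pair_reversal") {
        i <- sig$genes[1L]; j <- sig$genes[2L]
        means[i, class_cols$`1`] <- means[j, class_cols$`1`] + sig$gap
        means[i, class_cols$`2`] <- means[j, class_cols$`2`] - sig$gap
      } else if (sig$type == "triple_cycle") {
        idx <- sig$genes
        base <- 7
        # value orderings: class 1 cyclic, class 2 anti-cyclic. Each
        # class gets the three permutations in balanced (round-robin)
        # proportion, shuffled across its samples, so every permutation
        # of a class's support is represented as evenly as possible.
        cyclic <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
        anti <- list(c(1L, 3L, 2L), c(3L, 2L, 1L), c(2L, 1L, 3L))
        for (cl in c(1L, 2L)) {
          cols <- class_cols[[as.character(cl)]]
          which_perm <- sample(rep_len(1:3, length(cols)))
          for (s in seq_along(cols)) {
            perm <- if (cl == 1L) cyclic[[which_perm[s]]] else
              anti[[which_perm[s]]]
            # perm lists gene positions from lowest to highest value
            means[idx[perm], cols[s]] <- base + step * (0:2)
          }
        }
      } else if (sig$type == "network_rerank") {
        idx <- sig$genes
        ladder <- 7 + step * rev(seq_along(idx))   # first gene highest
        means[idx, class_cols$`1`] <- ladder
        means[idx, class_cols$`2`] <- rev(ladder)
      } else {
        abort_argument(sprintf("unknown planted signal type '%s'", sig$type))
      }
    }
    v <- means + matrix(stats::rnorm(g * m, 0, spec$noise_sd), g, m)
    if (spec$noise_model == "lognormal") v <- 2^v
    v
  })

  dataset <- expression_dataset(values, gene_ids = gene_names,
                                sample_ids = sample_names, classes = cls)

  sets <- list()
  for (sig in spec$planted) {
    if (sig$type == "network_rerank") {
      sets[[length(sets) + 1L]] <- list(
        name = sig$name, description = "planted reranking network",
        genes = gene_names[sig$genes])
    }
  }
  if (spec$n_decoy_networks > 0L) {
    planted_genes <- unlist(lapply(spec$planted, `[[`, "genes"))
    background <- setdiff(seq_len(g), planted_genes)
    decoys <- withr::with_seed(spec$seed + 1L, {
      lapply(seq_len(spec$n_decoy_networks), function(d) {
        sample(background, min(spec$decoy_network_size, length(background)))
      })
    })
    for (d in seq_along(decoys)) {
      sets[[length(sets) + 1L]] <- list(
        name = sprintf("DECOY_%02d", d), description = "background genes",
        genes = gene_names[decoys[[d]]])
    }
  }
  gene_sets <- if (length(sets)) gene_set_collection(sets) else NULL
  list(dataset = dataset, gene_sets = gene_sets)
}

#' Canonical fixture specification
#'
#' The standard validation condition used across the package: 100
#' genes, 20 samples per class, unit noise, with one planted signal of
#' each kind — a pair reversal on genes 1-2 (gap `12 * noise_sd`, wide
#' enough that every reversal involving the planted genes orders
#' decisively), a cyclic/anti-cyclic triple on genes 3-5, a 5-gene
#' reranking network on genes 6-10 — plus 9 decoy networks of
#' background genes.
#'
#' @param seed integer seed.
#' @param noise_sd noise standard deviation.
#' @return a `synthetic_spec`.
#' @export
canonical_fixture_spec <- function(seed = 1L, noise_sd = 1) {
  synthetic_spec(
    n_genes = 100L, n_samples_per_class = 20L, noise_sd = noise_sd,
    planted = list(pair_reversal(1L, 2L, gap = 12 * noise_sd),
                   triple_cycle(3L, 4L, 5L),
                   network_rerank("PLANTED_NET", 6:10)),
    n_decoy_networks = 9L, seed = seed)
}

#' Write a canonical fixture suite to disk
#'
#' Materialises a generated dataset in every supported format: a CSV
#' expression table, a SOFT (GDS-style) file whose subset blocks tag
#' the class-1 samples as cohort `"normal"` and the class-2 samples as
#' `"cancer"`, a GMT file with the planted and decoy networks (when
#' any), and a JSON manifest recording the spec and the identities of
#' the planted signals so end-to-end recovery can be checked after a
#' round trip through the readers.
#'
#' @param directory output directory (created if needed).
#' @param spec a `synthetic_spec`.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_suite <- function(directory, spec = canonical_fixture_spec()) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  gen <- generate_synthetic(spec)
  ds <- gen$dataset
  gene_names <- gene_ids(ds)

  write_expression_csv(ds, file.path(directory, "expression.csv"))
  write_soft_fixture(ds, file.path(directory, "dataset.soft"))
  if (!is.null(gen$gene_sets)) {
    write_gmt(gen$gene_sets, file.path(directory, "networks.gmt"))
  }

  manifest <- list(
    seed = spec$seed,
    n_genes = spec$n_genes,
    n_samples_per_class = spec$n_samples_per_class,
    noise_sd = spec$noise_sd,
    cohorts = list(normal = sample_ids(ds)[sample_classes(ds) == 1L],
                   cancer = sample_ids(ds)[sample_classes(ds) == 2L]),
    planted = lapply(spec$planted, function(sig) {
      out <- list(type = sig$type, genes = gene_names[sig$genes])
      if (!is.null(sig$name)) out$network <- sig$name
      if (!is.null(sig$gap)) out$gap <- sig$gap
      out
    }),
    files = list(csv = "expression.csv", soft = "dataset.soft",
                 gmt = if (!is.null(gen$gene_sets)) "networks.gmt"))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# minimal GDS-style SOFT file: subset blocks for the two cohorts, then
# the dataset table (ID_REF + IDENTIFIER + one column per sample)
write_soft_fixture <- function(dataset, path) {
  cls <- sample_classes(dataset)
  cohorts <- list(normal = sample_ids(dataset)[!is.na(cls) & cls == 1L],
                  cancer = sample_ids(dataset)[!is.na(cls) & cls == 2L])
  lines <- c("^DATABASE = GeoMiame",
             "^DATASET = SYNTH0001",
             "!dataset_title = synthetic two-class fixture")
  for (tag in names(cohorts)) {
    if (length(cohorts[[tag]]) == 0L) next
    lines <- c(lines,
               sprintf("^SUBSET = SYNTH0001_%s", tag),
               sprintf("!subset_description = %s", tag),
               sprintf("!subset_sample_id = %s",
                       paste(cohorts[[tag]], collapse = ",")),
               "!subset_type = disease state")
  }
  header <- paste(c("ID_REF", "IDENTIFIER", sample_ids(dataset)),
                  collapse = "\t")
  body <- vapply(seq_len(n_genes(dataset)), function(i) {
    paste(c(gene_ids(dataset)[i], gene_ids(dataset)[i],
            format_value(dataset$values[i, ])), collapse = "\t")
  }, character(1L))
  lines <- c(lines, "!dataset_table_begin", header, body,
             "!dataset_table_end")
  writeLines(lines, path)
  invisible(path)
}
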