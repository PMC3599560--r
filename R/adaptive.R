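# Adaptive parameter tuning. Candidate runs are Algorithm-Parameter
# Configurations (APCs): an algorithm plus a concrete parameter
# setting. Each APC carries a deterministic abstract cost estimate
# t(x); each algorithm accumulates a history of past cross-validation
# MCCs, mapped linearly to alpha in (0, 1). The next APC to run is the
# one minimising the delta score, which prefers cheap configurations,
# algorithms that have run less often, and algorithms that scored well
# when they did run. The search stops when the unit budget is spent,
# the grid is exhausted, or a run reaches the target (by default
# perfect) cross-validated MCC.

#' Construct an Algorithm-Parameter Configuration
#'
#' @param algorithm one of `"tsp"`, `"ktsp"`, `"tst"`, `"dirac"`.
#' @param ... named parameters for the algorithm: `filter_n`
#'   (tsp/ktsp/tst), `k_max` (ktsp), `min_size` and `m` (dirac).
#' @return an object of class `apc`.
#' @export
apc <- function(algorithm, ...) {
  params <- list(...)
  if (!algorithm %in% c("tsp", "ktsp", "tst", "dirac")) {
    abort_argument(sprintf("unknown algorithm '%s'", algorithm))
  }
  structure(list(algorithm = algorithm, params = params), class = "apc")
}

# canonical parameter tuple used for deterministic tie-breaking
apc_param_tuple <- function(x) {
  switch(x$algorithm,
    tsp = ,
    tst = c(x$params[["filter_n"]] %||% 0),
    ktsp = c(x$params[["filter_n"]] %||% 0, x$params[["k_max"]] %||% 10),
    dirac = c(x$params[["min_size"]] %||% 3, x$params[["m"]] %||% 1))
}

apc_id <- function(x) {
  paste0(x$algorithm, "(", paste(apc_param_tuple(x), collapse = ","), ")")
}

#' @export
print.apc <- function(x, ...) {
  cat("APC:", apc_id(x), "\n")
  invisible(x)
}

#' Abstract cost estimate of an APC
#'
#' Deterministic, hardware-independent cost units proportional to the
#' dominant loop of each algorithm on `M` labelled samples:
#' `filter_n^2 * M` for the pair search (tsp, ktsp), `filter_n^3 * M`
#' for the triple search (tst), and `M * sum(n_g * (n_g - 1) / 2)` over
#' the eligible networks for dirac. `filter_n = 0` (no filtering)
#' counts the full gene set.
#'
#' @param x an `apc`.
#' @param dataset an `expression_dataset`.
#' @param gene_sets a `gene_set_collection` (required for dirac).
#' @return a positive real.
#' @export
estimate_cost <- function(x, dataset, gene_sets = NULL) {
  m <- length(labeled_sample_ids(dataset))
  if (m == 0L) m <- n_samples(dataset)
  effective_n <- function(filter_n) {
    if (is.null(filter_n) || filter_n == 0) n_genes(dataset)
    else min(filter_n, n_genes(dataset))
  }
  switch(x$algorithm,
    tsp = ,
    ktsp = effective_n(x$params[["filter_n"]])^2 * m,
    tst = effective_n(x$params[["filter_n"]])^3 * m,
    dirac = {
      if (is.null(gene_sets)) abort_argument("dirac cost needs gene_sets")
      min_size <- x$params[["min_size"]] %||% 3L
      sizes <- vapply(gene_sets$sets, function(s) {
        length(network_genes_present(dataset, s$genes))
      }, integer(1L))
      sizes <- sizes[sizes >= min_size]
      m * sum(sizes * (sizes - 1) / 2)
    })
}

#' Map an MCC to the open unit interval
#'
#' The linear map `(mcc + 1) / 2`, clamped to
#' `[1e-6, 1 - 1e-6]` so every alpha is strictly inside (0, 1) and
#' products of alphas can never vanish or reach 1.
#'
#' @param mcc_value a real in \[-1, 1\].
#' @return alpha in (0, 1).
#' @export
alpha_of_mcc <- function(mcc_value) {
  if (!is.numeric(mcc_value) || length(mcc_value) != 1L ||
      is.na(mcc_value) || mcc_value < -1 || mcc_value > 1) {
    abort_argument("mcc must lie in [-1, 1]")
  }
  eps <- 1e-6
  min(max((mcc_value + 1) / 2, eps), 1 - eps)
}

#' The adaptive selection score delta
#'
#' Combines an APC's cost estimate with its algorithm's run history.
#' The default `"inverse"` rule, `delta = t / prod(alpha)`, makes an
#' APC less likely to run the more expensive it is, the more often its
#' algorithm has already run, and the worse those runs scored — the
#' behaviour the adaptive scheduler is meant to have. An alternative
#' `"literal"` rule, `delta = t * prod(alpha)`, is kept selectable; it
#' instead favours frequently-run, badly-scoring algorithms (see the
#' methods vignette for the discussion of the two forms).
#'
#' @param cost positive cost estimate `t` of the APC.
#' @param alphas numeric vector of past alpha values for the APC's
#'   algorithm (possibly empty: the product over an empty history is 1).
#' @param rule `"inverse"` (default) or `"literal"`.
#' @return a positive real.
#' @export
delta_score <- function(cost, alphas = numeric(0L),
                        rule = c("inverse", "literal")) {
  rule <- match.arg(rule)
  if (!is.numeric(cost) || cost <= 0) abort_argument("cost must be positive")
  p <- prod(alphas)
  if (rule == "inverse") cost / p else cost * p
}

#' Default APC grid
#'
#' The search space used when no grid is supplied: Mann-Whitney filter
#' sizes 25/50/100/200 for tsp and tst (the cubic tst search is capped
#' at 200 genes), the same filter sizes crossed with `k_max` 5 and 9
#' for ktsp, and `min_size` 3/5 crossed with `m` 1/3/5 for dirac.
#'
#' @param include character vector of algorithms to include.
#' @return list of `apc` objects.
#' @export
default_apc_grid <- function(include = c("tsp", "ktsp", "tst", "dirac")) {
  grid <- list()
  filter_ns <- c(25L, 50L, 100L, 200L)
  if ("tsp" %in% include) {
    grid <- c(grid, lapply(filter_ns, function(n) apc("tsp", filter_n = n)))
  }
  if ("ktsp" %in% include) {
    for (n in filter_ns) {
      for (km in c(5L, 9L)) {
        grid <- c(grid, list(apc("ktsp", filter_n = n, k_max = km)))
      }
    }
  }
  if ("tst" %in% include) {
    grid <- c(grid, lapply(filter_ns, function(n) apc("tst", filter_n = n)))
  }
  if ("dirac" %in% include) {
    for (ms in c(3L, 5L)) {
      for (m in c(1L, 3L, 5L)) {
        grid <- c(grid, list(apc("dirac", min_size = ms, m = m)))
      }
    }
  }
  grid
}

#' Cost-aware adaptive search over APCs
#'
#' Repeatedly: recompute delta for every APC not yet run, run the APC
#' with the smallest delta (ties: alphabetical algorithm name, then
#' ascending parameter tuple), evaluate it by repeated stratified
#' cross-validation, append the resulting alpha to its algorithm's
#' history, and deduct its cost from the budget. Stops when the budget
#' is spent, the grid is exhausted, or a run reaches `target_mcc`
#' (default 1, i.e. perfect cross-validated MCC). The best APC is then
#' retrained on the full labelled data.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param gene_sets a `gene_set_collection` (needed if the grid
#'   contains dirac APCs).
#' @param grid list of `apc` objects (default [default_apc_grid()]).
#' @param budget_units positive unit budget (default `Inf`: run until
#'   exhaustion or target).
#' @param folds,repeats cross-validation setup (defaults 10 and 10).
#' @param seed integer seed for all fold randomness.
#' @param target_mcc stop as soon as a run's mean MCC reaches this
#'   value (default 1).
#' @param delta_rule `"inverse"` (default) or `"literal"`, see
#'   [delta_score()].
#' @return an object of class `adaptive_result`: `best_apc`,
#'   `best_result` (its `evaluation_result`), `model` (best APC
#'   retrained on all labelled samples), `log` (one row per executed
#'   run, in order: APC id, delta at selection, mean MCC, cost) and
#'   `budget_spent`.
#' @export
adaptive_search <- function(dataset, gene_sets = NULL,
                            grid = default_apc_grid(),
                            budget_units = Inf,
                            folds = 10L, repeats = 10L, seed = 1L,
                            target_mcc = 1, delta_rule = "inverse") {
  require_two_classes(dataset)
  if (length(grid) == 0L) abort_argument("APC grid is empty")
  if (budget_units <= 0) abort_argument("budget_units must be positive")

  # eligibility: clamp filter sizes to the gene count; dirac APCs need
  # gene sets and at least one sufficiently large network
  grid <- Filter(function(x) {
    if (x$algorithm != "dirac") return(TRUE)
    !is.null(gene_sets) &&
      estimate_cost(x, dataset, gene_sets) > 0
  }, grid)
  if (length(grid) == 0L) {
    abort_precondition("no APC in the grid is eligible for this dataset")
  }

  costs <- vapply(grid, estimate_cost, numeric(1L),
                  dataset = dataset, gene_sets = gene_sets)
  algorithms <- vapply(grid, `[[`, character(1L), "algorithm")
  tuples <- lapply(grid, apc_param_tuple)
  history <- list(tsp = numeric(0L), ktsp = numeric(0L),
                  tst = numeric(0L), dirac = numeric(0L))
  remaining <- rep(TRUE, length(grid))
  spent <- 0
  log_rows <- list()
  results <- list()

  repeat {
    if (!any(remaining)) break
    idx <- which(remaining)
    deltas <- vapply(idx, function(i) {
      delta_score(costs[i], history[[algorithms[i]]], delta_rule)
    }, numeric(1L))
    # argmin with deterministic tie-breaks
    best <- idx[deltas == min(deltas)]
    if (length(best) > 1L) {
      best <- best[order(algorithms[best],
                         vapply(best, function(i) paste(
                           sprintf("%012.2f", tuples[[i]]), collapse = ","),
                           character(1L)))]
    }
    pick <- best[1L]

    run_params <- grid[[pick]]$params
    if (grid[[pick]]$algorithm == "dirac") run_params$gene_sets <- gene_sets
    result <- cross_validate(dataset, grid[[pick]]$algorithm, run_params,
                             k = folds, repeats = repeats, seed = seed)
    alpha <- alpha_of_mcc(result$mean_mcc)
    history[[algorithms[pick]]] <- c(history[[algorithms[pick]]], alpha)
    remaining[pick] <- FALSE
    spent <- spent + costs[pick]
    results[[length(results) + 1L]] <- list(apc = grid[[pick]], result = result)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      order = length(log_rows) + 1L,
      apc = apc_id(grid[[pick]]),
      algorithm = algorithms[pick],
      delta = deltas[match(pick, idx)],
      cost = costs[pick],
      mean_mcc = result$mean_mcc,
      sd_mcc = result$sd_mcc,
      stringsAsFactors = FALSE)

    if (result$mean_mcc >= target_mcc) break
    if (spent >= budget_units) break
  }

  mccs <- vapply(results, function(r) r$result$mean_mcc, numeric(1L))
  best_i <- which.max(mccs)
  best_apc <- results[[best_i]]$apc
  final_params <- best_apc$params
  if (best_apc$algorithm == "dirac") final_params$gene_sets <- gene_sets
  final_params$seed <- as.integer(seed)
  model <- train_model(dataset, best_apc$algorithm, final_params)
  structure(list(
    best_apc = best_apc,
    best_result = results[[best_i]]$result,
    model = model,
    log = do.call(rbind, log_rows),
    budget_spent = spent
  ), class = "adaptive_result")
}

#' @export
print.adaptive_result <- function(x, ...) {
  cat(sprintf("adaptive search: %d run(s), best %s with mean MCC %.4f\n",
              nrow(x$log), apc_id(x$best_apc), x$best_result$mean_mcc))
  invisible(x)
}
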