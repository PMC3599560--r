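# Evaluation: confusion matrices, the Matthews Correlation Coefficient
# (MCC), and repeated stratified k-fold cross-validation shared by all
# four classifier families. Class 1 is the positive class. Within each
# repeat the per-fold predictions are pooled into a single confusion
# matrix before the MCC is computed (fold-level MCC on tiny folds is
# unstable or undefined); means and standard deviations are then taken
# across repeats.

#' Confusion matrix
#'
#' @param tp,fp,tn,fn non-negative counts; class 1 is the positive
#'   class, so `fp` counts class-2 samples predicted 1 and `fn` class-1
#'   samples predicted 2.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_argument("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

confusion_counts <- function(truth, pred) {
  list(tp = sum(truth == 1L & pred == 1L),
       fp = sum(truth == 2L & pred == 1L),
       tn = sum(truth == 2L & pred == 2L),
       fn = sum(truth == 1L & pred == 2L))
}

#' Tabulate predictions against truth
#'
#' @param truth,pred integer vectors of labels in \{1, 2\}.
#' @return a `confusion_matrix`.
#' @export
confusion_from_labels <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    abort_argument("truth and prediction vectors differ in length")
  }
  cc <- confusion_counts(truth, pred)
  confusion_matrix(cc$tp, cc$fp, cc$tn, cc$fn)
}

#' Matthews Correlation Coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, ranging from
#' -1 (total disagreement) through 0 (chance-level) to 1 (perfect
#' agreement). When any factor of the denominator is zero (e.g. all
#' samples predicted into one class) the MCC is defined as 0, which
#' also keeps the adaptive module's score mapping total.
#'
#' @param confusion a `confusion_matrix`.
#' @return a real in \[-1, 1\].
#' @export
mcc <- function(confusion) {
  tp <- as.numeric(confusion$tp); fp <- as.numeric(confusion$fp)
  tn <- as.numeric(confusion$tn); fn <- as.numeric(confusion$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Pooled accuracy of a confusion matrix
#'
#' @param confusion a `confusion_matrix`.
#' @return `(tp + tn) / total`.
#' @export
accuracy <- function(confusion) {
  total <- confusion$tp + confusion$fp + confusion$tn + confusion$fn
  if (total == 0) abort_argument("empty confusion matrix")
  (confusion$tp + confusion$tn) / total
}

#' Stratified fold assignment
#'
#' Partitions the labelled samples into `k` folds so that each class's
#' samples are spread as evenly as possible (per-class fold counts
#' differ by at most one). Deterministic given `seed`. If a class has
#' fewer than `k` samples, `k` is lowered to the minimum class size
#' with a message; a class with fewer than 2 samples is an error.
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param k requested number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` character vectors of sample ids.
#' @export
stratified_folds <- function(dataset, k, seed) {
  require_two_classes(dataset)
  if (!is_count(k) || k < 2L) abort_argument("k must be >= 2")
  priors <- class_priors(dataset)
  min_class <- min(priors)
  if (min_class < 2L) {
    abort_precondition("each class needs at least 2 samples for cross-validation")
  }
  if (k > min_class) {
    message(sprintf("lowering folds from %d to %d (smallest class size)",
                    k, min_class))
    k <- min_class
  }
  folds <- replicate(k, character(0L), simplify = FALSE)
  withr::with_seed(as.integer(seed), {
    for (cls in c(1L, 2L)) {
      ids <- sample(class_sample_ids(dataset, cls))
      assign_to <- ((seq_along(ids) - 1L) %% k) + 1L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], ids[assign_to == f])
      }
    }
  })
  folds
}

# learner registry: the uniform train/classify contract behind
# cross_validate() and the adaptive search
get_learner <- function(algorithm) {
  switch(algorithm,
    tsp = list(train = function(ds, params) train_tsp(ds, params)),
    ktsp = list(train = function(ds, params) train_ktsp(ds, params)),
    tst = list(train = function(ds, params) train_tst(ds, params)),
    dirac = list(train = function(ds, params) {
      if (is.null(params[["gene_sets"]])) {
        abort_argument("DIRAC requires `gene_sets` in params")
      }
      train_dirac(ds, params[["gene_sets"]], params)
    }),
    abort_argument(sprintf(
      "unknown algorithm '%s' (expected tsp, ktsp, tst or dirac)", algorithm))
  )
}

#' Train any of the four classifiers by name
#'
#' Uniform entry point used by the cross-validation and adaptive
#' modules: `algorithm` selects the learner, `params` carries its
#' parameters (`filter_n` for tsp/ktsp/tst; `k_max`, `inner_folds`,
#' `seed` for ktsp; `min_size`, `m` and `gene_sets` for dirac).
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param algorithm one of `"tsp"`, `"ktsp"`, `"tst"`, `"dirac"`.
#' @param params parameter list for the learner.
#' @return a trained classifier (`relexp_model`).
#' @export
train_model <- function(dataset, algorithm, params = list()) {
  get_learner(algorithm)$train(dataset, params)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat `r` the labelled samples are split into `k`
#' stratified folds using seed `seed + r`; per fold the full training
#' pipeline — gene filtering included — is refit on the k-1 training
#' folds and the held-out fold is predicted. Each repeat's predictions
#' are pooled into one confusion matrix; the summary reports mean and
#' standard deviation of accuracy and MCC across repeats (sd is 0 for
#' a single repeat).
#'
#' @param dataset an `expression_dataset` with both classes non-empty.
#' @param algorithm one of `"tsp"`, `"ktsp"`, `"tst"`, `"dirac"`.
#' @param params parameter list passed to the learner on every fold.
#' @param k number of folds (default 10).
#' @param repeats number of repeated runs (default 10).
#' @param seed integer seed; run `r` uses `seed + r`.
#' @return an object of class `evaluation_result`: `per_run`
#'   data.frame (one row per repeat with counts, accuracy, MCC) and
#'   the four summary fields `mean_mcc`, `sd_mcc`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
cross_validate <- function(dataset, algorithm, params = list(),
                           k = 10L, repeats = 10L, seed = 1L) {
  require_two_classes(dataset)
  learner <- get_learner(algorithm)
  runs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    run_seed <- as.integer(seed) + r
    folds <- suppressMessages(stratified_folds(dataset, k, run_seed))
    truth_all <- integer(0L)
    pred_all <- integer(0L)
    for (f in seq_along(folds)) {
      test_ids <- folds[[f]]
      train_ids <- setdiff(labeled_sample_ids(dataset), test_ids)
      fold_params <- params
      fold_params[["seed"]] <- fold_params[["seed"]] %||% run_seed
      model <- tryCatch(
        learner$train(subset_samples(dataset, train_ids), fold_params),
        relexp_error = function(e) {
          abort_relexp(sprintf("repeat %d fold %d: %s", r, f, conditionMessage(e)),
                       class(e)[1L])
        })
      pred <- vapply(test_ids, function(s) {
        classify(model, dataset$values[, s])
      }, integer(1L))
      truth_all <- c(truth_all, dataset$classes[test_ids])
      pred_all <- c(pred_all, pred)
    }
    conf <- confusion_from_labels(truth_all, pred_all)
    runs[[r]] <- data.frame(
      run = r, seed = run_seed,
      tp = conf$tp, fp = conf$fp, tn = conf$tn, fn = conf$fn,
      accuracy = accuracy(conf), mcc = mcc(conf))
  }
  per_run <- do.call(rbind, runs)
  structure(list(
    algorithm = algorithm,
    per_run = per_run,
    mean_mcc = mean(per_run$mcc),
    sd_mcc = if (repeats > 1L) stats::sd(per_run$mcc) else 0,
    mean_accuracy = mean(per_run$accuracy),
    sd_accuracy = if (repeats > 1L) stats::sd(per_run$accuracy) else 0
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "%s cross-validation (%d repeats): MCC %.4f +/- %.4f, accuracy %.4f +/- %.4f\n",
    x$algorithm, nrow(x$per_run),
    x$mean_mcc, x$sd_mcc, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}
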