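#' Two-class confusion matrix
#'
#' Tallies predictions against truth with a declared positive class.
#' Entries may later be averaged across splits, so they are stored as
#' reals.
#'
#' @param truth,predicted character vectors of equal length, or `truth`
#'   may be omitted by passing counts directly via `tp`, `fp`, `fn`, `tn`.
#' @param positive the positive-class label (the disease being detected).
#'   Default `"cancer"`.
#' @param tp,fp,fn,tn direct counts; used when `truth`/`predicted` are
#'   missing.
#' @return An object of class `"confusion_matrix"`: list with `tp`, `fp`,
#'   `fn`, `tn` and `positive`.
#' @export
confusion_matrix <- function(truth = NULL, predicted = NULL,
                             positive = "cancer",
                             tp = NULL, fp = NULL, fn = NULL, tn = NULL) {
  if (!is.null(truth)) {
    if (length(truth) != length(predicted))
      stop("confusion_matrix: truth and predicted lengths differ")
    tp <- sum(truth == positive & predicted == positive)
    fp <- sum(truth != positive & predicted == positive)
    fn <- sum(truth == positive & predicted != positive)
    tn <- sum(truth != positive & predicted != positive)
  }
  vals <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(vals) || any(vals < 0))
    stop("confusion_matrix: counts must be non-negative")
  if (sum(vals) <= 0)
    stop("confusion_matrix: empty confusion matrix")
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L, byrow = TRUE,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  cat("Confusion matrix (positive = ", x$positive, "):\n", sep = "")
  print(m)
  invisible(x)
}

#' Diagnostic test metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)` and accuracy
#' `(tp+tn)/(tp+fp+fn+tn)`, each as a percentage. A metric whose
#' denominator is zero is undefined and returned as `NA` (never silently
#' propagated as `NaN`); the names of undefined metrics are recorded in
#' the `"undefined"` attribute. Values are unrounded; round only for
#' display.
#'
#' @param cm a [confusion_matrix()], or anything coercible via its `tp`,
#'   `fp`, `fn`, `tn` elements.
#' @return Named numeric vector with elements `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, in percent.
#' @examples
#' diagnostic_metrics(confusion_matrix(tp = 38, fp = 3, fn = 9, tn = 38))
#' @export
diagnostic_metrics <- function(cm) {
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- c(sensitivity = ratio(cm$tp, cm$tp + cm$fn),
           specificity = ratio(cm$tn, cm$tn + cm$fp),
           ppv         = ratio(cm$tp, cm$tp + cm$fp),
           npv         = ratio(cm$tn, cm$tn + cm$fn),
           accuracy    = ratio(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Stratified random train/test split
#'
#' Draws, without replacement, the requested number of training samples
#' from each class; everything not drawn forms the test set. Deterministic
#' given `seed` (a private RNG stream is used). A count equal to a full
#' class size is allowed but leaves that class absent from the test set
#' (flagged with a warning if the whole test set is empty).
#'
#' @param ds a [spectra_dataset()].
#' @param train_per_class named integer vector or list, `label = count`.
#' @param seed integer RNG seed.
#' @return List with elements `train` and `test`, both `spectra_dataset`s
#'   (the `test` element is `NULL` when empty), and `seed`.
#' @examples
#' ds <- simulate_spectra(n_per_class = 10, seed = 1)
#' sp <- random_split(ds, c(cancer = 5, colitis = 5), seed = 7)
#' dim(sp$train); dim(sp$test)
#' @export
random_split <- function(ds, train_per_class, seed = 1L) {
  stopifnot(inherits(ds, "spectra_dataset"))
  counts <- unlist(train_per_class)
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("random_split: train_per_class must be named label = count")
  m <- length(ds$labels)
  train_idx <- integer(0)
  for (lab in names(counts)) {
    pool <- which(ds$labels == lab)
    if (counts[[lab]] > length(pool))
      stop("random_split: requested ", counts[[lab]], " training samples ",
           "of class '", lab, "' but only ", length(pool), " available")
    take <- with_local_seed(
      seed + match(lab, sort(names(counts))) * 1000003L,
      sample(pool, counts[[lab]]))
    train_idx <- c(train_idx, take)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(m), train_idx)
  if (length(test_idx) == 0L)
    warning("random_split: empty test set (all samples used for training)")
  list(train = ds[train_idx],
       test = if (length(test_idx)) ds[test_idx] else NULL,
       seed = seed)
}

fit_and_predict <- function(train, test, model, k, lambda, svm_cost) {
  if (model %in% c("ewhk", "hknn")) {
    fit <- ewhk(train, k = k, lambda = lambda,
                weights = if (model == "ewhk") "entropy" else "uniform")
    predict(fit, test)
  } else if (model == "svm") {
    fit <- e1071::svm(x = train$absorbance, y = factor(train$labels),
                      kernel = "linear", cost = svm_cost, scale = FALSE)
    as.character(predict(fit, test$absorbance))
  } else {
    stop("unknown model '", model, "' (expected ewhk, hknn or svm)")
  }
}

#' Repeated random-split evaluation of a classifier
#'
#' The standard protocol for small diagnostic datasets: repeatedly draw a
#' stratified random train/test split, fit the classifier on the training
#' half, predict the held-out half, and average the resulting diagnostic
#' metrics across repeats. Two aggregations are reported because they are
#' not equivalent: `averaged` is the arithmetic mean of the per-split
#' metrics (and of the per-split confusion matrices), while `pooled`
#' recomputes the metrics from the summed confusion counts of all splits.
#'
#' @param ds a preprocessed [spectra_dataset()].
#' @param model `"ewhk"`, `"hknn"` or `"svm"` (linear kernel baseline).
#' @param train_per_class named vector `label = count` for the stratified
#'   split; default half of each class (rounded down).
#' @param seeds integer vector, one seed per repeat. Default `1:5`.
#' @param k,lambda classifier settings passed to [ewhk()].
#' @param positive positive-class label for the metrics.
#' @param svm_cost cost parameter for the SVM baseline. Default 1.
#' @return An object of class `"ewhk_eval"`: list with `per_split` (data
#'   frame of counts and metrics per split), `averaged` (mean metrics),
#'   `averaged_confusion` (mean counts), `pooled` (metrics from summed
#'   counts), `model` and `split_spec`.
#' @export
repeated_evaluation <- function(ds, model = c("ewhk", "hknn", "svm"),
                                train_per_class = NULL, seeds = 1:5,
                                k = 5L, lambda = 1, positive = "cancer",
                                svm_cost = 1) {
  stopifnot(inherits(ds, "spectra_dataset"))
  model <- match.arg(model)
  if (is.null(train_per_class)) {
    sizes <- table(ds$labels)
    train_per_class <- stats::setNames(as.integer(sizes %/% 2L),
                                       names(sizes))
  }
  rows <- vector("list", length(seeds))
  for (s in seq_along(seeds)) {
    sp <- random_split(ds, train_per_class, seed = seeds[s])
    if (is.null(sp$test))
      stop("repeated_evaluation: split ", s, " produced an empty test set")
    pred <- tryCatch(
      fit_and_predict(sp$train, sp$test, model, k, lambda, svm_cost),
      error = function(e) stop("repeated_evaluation: split ", s, ": ",
                               conditionMessage(e)))
    cm <- confusion_matrix(sp$test$labels, pred, positive = positive)
    met <- diagnostic_metrics(cm)
    rows[[s]] <- data.frame(model = model, split = s, seed = seeds[s],
                            tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
                            t(met))
  }
  per_split <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  averaged <- colMeans(per_split[metric_cols])
  averaged_confusion <- colMeans(per_split[c("tp", "fp", "fn", "tn")])
  pooled_cm <- confusion_matrix(tp = sum(per_split$tp), fp = sum(per_split$fp),
                                fn = sum(per_split$fn), tn = sum(per_split$tn),
                                positive = positive)
  structure(list(per_split = per_split, averaged = averaged,
                 averaged_confusion = averaged_confusion,
                 pooled = diagnostic_metrics(pooled_cm),
                 model = model, positive = positive,
                 split_spec = list(train_per_class = train_per_class,
                                   seeds = seeds, k = k, lambda = lambda)),
            class = "ewhk_eval")
}

#' @export
print.ewhk_eval <- function(x, digits = 2, ...) {
  cat("Repeated-split evaluation: model =", x$model,
      " repeats =", nrow(x$per_split),
      " positive =", x$positive, "\n")
  cat("Averaged confusion matrix (mean counts per split):\n")
  print(round(x$averaged_confusion, digits))
  cat("Averaged metrics (% , mean of per-split metrics):\n")
  print(round(x$averaged, digits))
  cat("Pooled metrics (% , from summed counts):\n")
  print(round(c(x$pooled), digits))
  invisible(x)
}

#' Compare classifiers under identical splits
#'
#' Runs [repeated_evaluation()] for each requested model with the same
#' seeds, so every model sees exactly the same train/test partitions
#' (a paired comparison), and tabulates the averaged metrics.
#'
#' @inheritParams repeated_evaluation
#' @param models character vector of model names from `"ewhk"`, `"hknn"`,
#'   `"svm"`.
#' @return A data frame with one row per model and columns `model`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy` (averaged
#'   percentages). The full `ewhk_eval` objects are attached as attribute
#'   `"evals"`.
#' @export
compare_models <- function(ds, models = c("ewhk", "hknn"),
                           train_per_class = NULL, seeds = 1:5,
                           k = 5L, lambda = 1, positive = "cancer",
                           svm_cost = 1) {
  if (length(models) < 1L) stop("compare_models: no models given")
  bad <- setdiff(models, c("ewhk", "hknn", "svm"))
  if (length(bad))
    stop("compare_models: unknown model(s): ", paste(bad, collapse = ", "))
  evals <- lapply(models, function(mdl)
    repeated_evaluation(ds, model = mdl, train_per_class = train_per_class,
                        seeds = seeds, k = k, lambda = lambda,
                        positive = positive, svm_cost = svm_cost))
  tab <- data.frame(model = models,
                    do.call(rbind, lapply(evals, `[[`, "averaged")))
  rownames(tab) <- NULL
  attr(tab, "evals") <- stats::setNames(evals, models)
  tab
}
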