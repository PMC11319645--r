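# Repeated cluster-aware evaluation, rank-correlation and significance
# machinery, and the cross-context prediction matrix.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, the performance measure used
#' throughout (it is invariant to any strictly monotone transform of either
#' argument, so per-dataset normalization never affects scores). A constant
#' input leaves the correlation undefined: `NaN` is returned with a warning.
#'
#' @param pred,obs equal-length numeric vectors (length >= 3).
#' @return correlation in `[-1, 1]`, or `NaN` for a constant input.
#' @export
spearman_cor <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("spearman_cor(): length mismatch")
  if (length(pred) < 3L) stopf("spearman_cor(): need at least 3 observations")
  if (length(unique(pred)) < 2L || length(unique(obs)) < 2L) {
    warnf("spearman_cor(): constant vector, correlation undefined")
    return(NaN)
  }
  stats::cor(pred, obs, method = "spearman")
}

#' Repeated cluster-aware evaluation of a prediction method
#'
#' The evaluation protocol for small cellular-context datasets: `repeats`
#' times, draw an independent cluster-aware split (whole Hamming clusters at
#' the link threshold, random ordering, a distinct derived seed per repeat),
#' train via the method factory on the training side and score the Spearman
#' correlation of predictions against observations on the held-out test side.
#'
#' @param target a `guide_dataset`.
#' @param method_factory `function(train_ds, seed)` returning a prediction
#'   function `function(test_ds) -> numeric`.
#' @param repeats number of independent repeats.
#' @param test_fraction held-out fraction per repeat.
#' @param link_threshold strict Hamming link threshold for the splits.
#' @param seed global seed; repeat seeds are derived from it.
#' @param method_label,min_test labels/guards: any repeat whose test set has
#'   fewer than `min_test` records aborts.
#' @return an `eval_result`: list with `dataset`, `method`, `per_repeat`
#'   (numeric, `NaN` for degenerate repeats), `mean` (over non-NaN repeats,
#'   count recorded as `n_dropped`), `seeds`.
#' @export
evaluate_repeated <- function(target, method_factory, repeats = 5L,
                              test_fraction = 0.2, link_threshold = 5L,
                              seed = 1L, method_label = "method", min_test = 10L) {
  scores <- numeric(repeats)
  seeds <- vapply(seq_len(repeats), function(r) derive_seed(seed, r), 0L)
  for (r in seq_len(repeats)) {
    plan <- split_dataset(target, test_fraction, link_threshold = link_threshold,
                          ordering = "random", seed = seeds[r])
    if (length(plan$test_ids) < min_test)
      stopf("repeat %d: test set has %d records (< %d)", r, length(plan$test_ids), min_test)
    train_ds <- subset_dataset(target, plan$train_ids)
    test_ds <- subset_dataset(target, plan$test_ids)
    predict_fn <- method_factory(train_ds, seeds[r])
    pred <- predict_fn(test_ds)
    obs <- test_ds$records[[paste0("eff_", target$condition_labels[1L])]]
    scores[r] <- suppressWarnings(spearman_cor(pred, obs))
  }
  ok <- !is.nan(scores)
  structure(list(dataset = target$name, method = method_label,
                 per_repeat = scores, mean = mean(scores[ok]),
                 n_dropped = sum(!ok), seeds = seeds),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s on %s: mean Spearman %.4f over %d repeat(s)%s\n",
              x$method, x$dataset, x$mean, length(x$per_repeat),
              if (x$n_dropped) sprintf(" (%d NaN dropped)", x$n_dropped) else ""))
  invisible(x)
}

#' Compare two score collections by Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on the per-model or
#' per-repeat score collections; the exact null distribution is used for
#' small tie-free samples (n <= 10 per group), the normal approximation
#' otherwise (ties force the approximation). Symmetric in its arguments.
#'
#' @param a,b numeric score vectors or `eval_result` objects.
#' @return the p-value in `(0, 1]`; the full `htest` is attached as
#'   attribute `"test"`.
#' @export
compare_methods <- function(a, b) {
  xa <- if (inherits(a, "eval_result")) a$per_repeat else a
  xb <- if (inherits(b, "eval_result")) b$per_repeat else b
  xa <- xa[!is.nan(xa)]; xb <- xb[!is.nan(xb)]
  exact <- length(xa) <= 10L && length(xb) <= 10L
  ht <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = "two.sided",
                                            exact = exact, correct = !exact))
  p <- ht$p.value
  attr(p, "test") <- ht
  p
}

#' Cross-context prediction matrix
#'
#' Scores every model on every dataset: cell (d, m) is the Spearman
#' correlation of model m's predictions on the complete dataset d (no
#' splitting — this measures generalization across cellular contexts, not
#' held-out performance). Spearman only uses ranks, so datasets need not
#' share an efficiency scale.
#'
#' @param models named list of `crisprtl_ensemble`s (or single models).
#' @param datasets named list of `guide_dataset`s.
#' @param condition condition label used to encode/score each dataset.
#' @return numeric matrix, rows = datasets, cols = models, class
#'   `cross_prediction_matrix`.
#' @export
cross_predict <- function(models, datasets, condition = NULL) {
  M <- matrix(NA_real_, length(datasets), length(models),
              dimnames = list(names(datasets), names(models)))
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    obs <- ds$records[[paste0("eff_", condition %||% ds$condition_labels[1L])]]
    for (m in seq_along(models)) {
      spec <- if (inherits(models[[m]], "crisprtl_ensemble")) models[[m]]$spec else models[[m]]$spec
      batch <- encode_for_model(ds, spec, condition = condition)
      keep <- match(batch$ids, ds$records$id)
      M[d, m] <- suppressWarnings(spearman_cor(predict(models[[m]], batch), obs[keep]))
    }
  }
  structure(M, class = c("cross_prediction_matrix", class(M)))
}

#' Write an evaluation table as TSV
#' @param x an `eval_result` or `cross_prediction_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval <- function(x, path) {
  if (inherits(x, "eval_result")) {
    df <- data.frame(dataset = x$dataset, method = x$method,
                     repeat_ = seq_along(x$per_repeat), seed = x$seeds,
                     spearman = x$per_repeat)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(cbind(dataset = rownames(x), as.data.frame(unclass(x))),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
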