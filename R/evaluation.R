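metrics_from_counts <- function(tp, fp, tn, fn) {
  # doubles: the MCC denominator product overflows 32-bit integers
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  n <- tp + fp + tn + fn
  stopifnot(n > 0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 accuracy = 100 * (tp + tn) / n,
                 sensitivity = sens, specificity = spec, mcc = mcc),
            class = "metrics_report")
}

#' Confusion-matrix performance metrics
#'
#' Counts true/false positives and negatives by direct comparison and
#' derives accuracy `= 100 (TP+TN)/N`, sensitivity `= 100 TP/(TP+FN)`,
#' specificity `= 100 TN/(TN+FP)` and the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' MCC is reported as 0 when any factor of its denominator is 0;
#' sensitivity/specificity are `NA` (undefined) when their own
#' denominators are 0.
#'
#' @param labels Logical vector of true labels.
#' @param predictions Logical vector of predicted labels (same length).
#' @return Object of class `metrics_report`: list with counts `tp`,
#'   `fp`, `tn`, `fn`, `n` and metrics `accuracy`, `sensitivity`,
#'   `specificity` (percentages) and `mcc`.
#' @export
compute_metrics <- function(labels, predictions) {
  labels <- as.logical(labels)
  predictions <- as.logical(predictions)
  if (length(labels) != length(predictions) || length(labels) == 0L) {
    stop("labels and predictions must have equal nonzero length",
         call. = FALSE)
  }
  metrics_from_counts(tp = sum(labels & predictions),
                      fp = sum(!labels & predictions),
                      tn = sum(!labels & !predictions),
                      fn = sum(labels & !predictions))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report: N=%d  TP=%d FP=%d TN=%d FN=%d\n  accuracy %.2f%%  sensitivity %s  specificity %s  MCC %.4f\n",
    x$n, x$tp, x$fp, x$tn, x$fn, x$accuracy,
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.2f%%", x$sensitivity)),
    ifelse(is.na(x$specificity), "NA", sprintf("%.2f%%", x$specificity)),
    x$mcc))
  invisible(x)
}

#' ROC curve over a score sweep
#'
#' Sweeps the decision threshold over the sorted unique scores (with
#' sentinels at `+Inf` and `-Inf` so the curve spans `(0,0)` to `(1,1)`),
#' classifying positive by the strict-greater rule `score > threshold` -
#' the same rule the Naive Bayes classifier applies to its posterior
#' odds, so each ROC point corresponds to a `theta = exp(threshold)`
#' operating point when scores are log posterior-odds ratios.
#' Consecutive duplicate points are collapsed.  AUC is the trapezoidal
#' area under (FPR, TPR).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical true labels; both classes must be present.
#' @return Object of class `roc_curve`: data frame with columns
#'   `threshold`, `fpr`, `tpr`, and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("ROC requires both classes in `labels`", call. = FALSE)
  }
  np <- sum(labels); nn <- sum(!labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(labels & scores > t) / np, 0)
  fpr <- vapply(thr, function(t) sum(!labels & scores > t) / nn, 0)
  keep <- c(TRUE, diff(tpr) != 0 | diff(fpr) != 0)
  thr <- thr[keep]; tpr <- tpr[keep]; fpr <- fpr[keep]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr),
            auc = auc, class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#'
#' @param roc A `roc_curve`.
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Write a ROC curve as TSV (threshold, fpr, tpr)
#'
#' @param roc A `roc_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(as.data.frame(roc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Leave-one-protein-out cross-validation
#'
#' Evaluates the full pipeline with grouping by chain: in each fold one
#' chain is held out, the remaining chains are encoded, min-max
#' normalized (normalizer fitted on the training fold only) and used to
#' fit the Naive Bayes model, and the held-out chain is scored.
#' Per-chain confusion counts are accumulated into a pooled
#' (micro-averaged) report; residues of one chain never appear on both
#' sides of a split.  A fold whose training set loses a class is skipped
#' with a warning.
#'
#' @param chains List of chain inputs.  Each element is a list with
#'   `chain_id`, `labels` (logical per residue) and either `profile`
#'   (a [pssm_profile()], for `encoder = "pssm"`) or `sequence`
#'   (one-letter string, for `"blosum62"`/`"properties"`).
#' @param encoder One of `"pssm"`, `"blosum62"`, `"properties"`.
#' @param k Window half-width (default 2: the window-size-5 optimum for
#'   this task).
#' @param theta Decision threshold on the posterior-odds ratio.
#' @param table Property table for `encoder = "properties"`.
#' @param padding Flank padding rule, see [encode_properties()].
#' @param normalize Min-max normalize per fold (default TRUE).
#' @param priors Optional prior override passed to [nb_fit()].
#' @return Object of class `lopo_result`: list with `per_chain` (data
#'   frame: chain_id, n, tp, fp, tn, fn, sensitivity, specificity,
#'   accuracy, mcc), `pooled` (a `metrics_report` from the summed
#'   counts), and `scores` (data frame: chain_id, seq_index, log_ratio,
#'   label, truth - suitable for [roc_curve()]).
#' @export
lopo_cv <- function(chains, encoder = c("pssm", "blosum62", "properties"),
                    k = 2, theta = 1, table = NULL,
                    padding = c("mean", "zero"), normalize = TRUE,
                    priors = NULL) {
  encoder <- match.arg(encoder)
  padding <- match.arg(padding)
  stopifnot(length(chains) >= 2L)
  if (encoder == "properties" && is.null(table)) {
    table <- default_property_table()
  }
  enc <- lapply(chains, function(ch) {
    switch(encoder,
           pssm = encode_pssm(ch$profile, ch$labels, k = k,
                              padding = padding, chain_id = ch$chain_id),
           blosum62 = encode_blosum(ch$sequence, ch$labels, k = k,
                                    padding = padding,
                                    chain_id = ch$chain_id),
           properties = encode_properties(ch$sequence, ch$labels,
                                          table = table, k = k,
                                          padding = padding,
                                          chain_id = ch$chain_id))
  })
  ids <- vapply(chains, `[[`, "", "chain_id")
  per <- list()
  scores <- list()
  for (j in seq_along(enc)) {
    train <- bind_datasets(enc[-j])
    if (!any(train$labels) || all(train$labels)) {
      warning("fold '", ids[j],
              "': training set lost a class; fold skipped")
      next
    }
    test <- enc[[j]]
    if (normalize) {
      norm <- fit_normalizer(train)
      train <- apply_normalizer(norm, train)
      test <- apply_normalizer(norm, test)
    }
    model <- nb_fit(train, theta = theta, priors = priors)
    pred <- nb_predict(model, test)
    m <- compute_metrics(test$labels, pred$label)
    per[[length(per) + 1L]] <-
      data.frame(chain_id = ids[j], n = m$n, tp = m$tp, fp = m$fp,
                 tn = m$tn, fn = m$fn, sensitivity = m$sensitivity,
                 specificity = m$specificity, accuracy = m$accuracy,
                 mcc = m$mcc, stringsAsFactors = FALSE)
    scores[[length(scores) + 1L]] <-
      data.frame(chain_id = ids[j],
                 seq_index = test$provenance$seq_index,
                 log_ratio = pred$log_ratio, label = pred$label,
                 truth = test$labels, stringsAsFactors = FALSE)
  }
  if (length(per) == 0L) stop("no evaluable folds", call. = FALSE)
  per <- do.call(rbind, per)
  pooled <- metrics_from_counts(sum(per$tp), sum(per$fp),
                                sum(per$tn), sum(per$fn))
  structure(list(per_chain = per, pooled = pooled,
                 scores = do.call(rbind, scores)),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat("lopo_result over ", nrow(x$per_chain), " chains; pooled:\n",
      sep = "")
  print(x$pooled)
  invisible(x)
}

#' Write LOPO-CV results as TSV
#'
#' One row per chain (id, residues, sensitivity, specificity, accuracy,
#' mcc) followed by a `pooled` row built from the summed counts.
#'
#' @param result A `lopo_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(result, path) {
  p <- result$per_chain
  pool <- result$pooled
  df <- rbind(
    data.frame(chain_id = p$chain_id, n_residues = p$n,
               sensitivity = p$sensitivity, specificity = p$specificity,
               accuracy = p$accuracy, mcc = p$mcc,
               stringsAsFactors = FALSE),
    data.frame(chain_id = "pooled", n_residues = pool$n,
               sensitivity = pool$sensitivity,
               specificity = pool$specificity,
               accuracy = pool$accuracy, mcc = pool$mcc,
               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
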