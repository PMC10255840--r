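#' Classification report from truth and predictions
#'
#' Builds the 5x5 confusion matrix (rows = truth, columns = prediction)
#' and derives overall accuracy, per-class true-positive rate (recall,
#' the row-normalised diagonal) and per-class precision.  Classes absent
#' from the truth get `NA` TPR; classes never predicted get `NA`
#' precision.
#'
#' @param truth factor or character vector of true labels.
#' @param predicted factor or character vector of predicted labels.
#' @param classes class levels (default [fall_labels()]).
#' @return an object of class `classification_report` with elements
#'   `confusion`, `accuracy`, `tpr`, `precision`, `n_samples`.
#' @export
classification_report <- function(truth, predicted,
                                  classes = fall_labels()) {
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (length(truth) != length(predicted))
    stopf("truth and predicted lengths differ")
  if (any(is.na(truth)) || any(is.na(predicted)))
    stopf("labels outside the declared classes")
  conf <- table(truth = truth, predicted = predicted)
  report_from_confusion(unclass(conf), classes)
}

#' @rdname classification_report
#' @param confusion square count matrix, rows = truth.
#' @export
report_from_confusion <- function(confusion, classes = rownames(confusion)) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(confusion)))
  dimnames(confusion) <- list(truth = classes, predicted = classes)
  rs <- rowSums(confusion)
  cs <- colSums(confusion)
  tpr <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  prec <- ifelse(cs > 0, diag(confusion) / cs, NA_real_)
  names(tpr) <- names(prec) <- classes
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 tpr = tpr, precision = prec,
                 n_samples = sum(confusion)),
            class = "classification_report")
}

#' Evaluate a fitted classifier on held-out data
#'
#' @param model a fitted [fall_cnn()].
#' @param x_rt,x_dt image arrays `c(S, S, 3, N)`.
#' @param truth true labels.
#' @return a [classification_report()].
#' @export
evaluate_classifier <- function(model, x_rt, x_dt, truth) {
  pred <- predict(model, x_rt, x_dt)
  classification_report(truth, pred, model$classes)
}

#' @export
print.classification_report <- function(x, digits = 4, ...) {
  cat(sprintf("Classification report (n = %d)\n", x$n_samples))
  tab <- data.frame(ACC = sprintf("%.2f%%", 100 * x$accuracy),
                    t(vapply(seq_along(x$tpr), function(i)
                      sprintf("%.2f%%", 100 * x$tpr[i]), character(1))))
  names(tab)[-1] <- paste0("TPR-", names(x$tpr))
  print(tab, row.names = FALSE)
  cat("\nConfusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialise a classification report
#'
#' Writes per-class metrics as CSV and the full report (including the
#' confusion matrix) as JSON.
#'
#' @param report a [classification_report()].
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return the report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "classification_report"))
  if (!is.null(csv_path)) {
    df <- data.frame(class = names(report$tpr), tpr = report$tpr,
                     precision = report$precision,
                     support = rowSums(report$confusion))
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(accuracy = report$accuracy,
                              n_samples = report$n_samples,
                              tpr = as.list(report$tpr),
                              precision = as.list(report$precision),
                              confusion = report$confusion),
                         json_path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(report)
}
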