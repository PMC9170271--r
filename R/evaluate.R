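# Q-score metrics, confusion matrices with marginal frequencies, and
# tab-separated report rendering.

#' Q-k accuracy
#'
#' Percentage of residues whose predicted state is correct.  For
#' `k = 3` both streams are coarsened with [map_q8_to_q3()] first (Q8
#' input is detected by states outside \{H,E,C\}).
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   states over real residues.
#' @param k 3 or 8.
#' @return Accuracy in percent.
#' @export
#' @examples
#' q_score(c("H", "H", "E"), c("H", "E", "E"), k = 8)  # 66.67
q_score <- function(true_labels, predicted_labels, k = 8L) {
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels)) stop("length mismatch")
  if (k == 3L) {
    if (any(!true_labels %in% Q3_STATES)) true_labels <- map_q8_to_q3(true_labels)
    if (any(!predicted_labels %in% Q3_STATES)) predicted_labels <- map_q8_to_q3(predicted_labels)
  } else if (k != 8L) {
    stop("k must be 3 or 8")
  }
  100 * mean(true_labels == predicted_labels)
}

#' Confusion matrix as percent of total
#'
#' Cross-tabulates predicted (rows) against true (columns) states, each
#' cell as `100 * count / N`, with marginal predicted- and true-label
#' frequency vectors.  The trace equals the Q-k accuracy.
#'
#' @inheritParams q_score
#' @return Object of class `ss_confusion`: list with `percent` and
#'   `counts` matrices, `pred_freq`, `true_freq`, `accuracy`, `n`.
#' @export
ss_confusion <- function(true_labels, predicted_labels, k = 8L) {
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels)) stop("length mismatch")
  states <- if (k == 3L) {
    if (any(!true_labels %in% Q3_STATES)) true_labels <- map_q8_to_q3(true_labels)
    if (any(!predicted_labels %in% Q3_STATES)) predicted_labels <- map_q8_to_q3(predicted_labels)
    c("C", "E", "H")
  } else {
    Q8_STATES
  }
  counts <- table(factor(predicted_labels, levels = states),
                  factor(true_labels, levels = states))
  n <- sum(counts)
  percent <- 100 * counts / n
  structure(list(
    percent = unclass(percent), counts = unclass(counts),
    pred_freq = rowSums(unclass(percent)),
    true_freq = colSums(unclass(percent)),
    accuracy = sum(diag(unclass(percent))),
    n = as.integer(n), k = as.integer(k)
  ), class = "ss_confusion")
}

#' @export
print.ss_confusion <- function(x, ...) {
  cat(format_confusion_tsv(x), sep = "\n")
  invisible(x)
}

#' Format a confusion matrix as a tab-separated report
#'
#' Mirrors the benchmark report layout: accuracy and predicted-label
#' frequencies down the side, true-label frequencies across the top.
#'
#' @param x An [ss_confusion()] object.
#' @return Character vector of report lines.
#' @export
format_confusion_tsv <- function(x) {
  states <- colnames(x$percent)
  lines <- c(
    paste(c(sprintf("Accuracy\tPred freq."), states), collapse = "\t"),
    paste(c(sprintf("%.2f\t100%%", x$accuracy),
            sprintf("%.2f", x$true_freq)), collapse = "\t")
  )
  for (s in states) {
    lines <- c(lines, paste(c(s, sprintf("%.2f", x$pred_freq[s]),
                              sprintf("%.2f", x$percent[s, ])), collapse = "\t"))
  }
  lines
}

#' Per-state prediction accuracy
#'
#' Recall per Q8 state: among residues whose true label is the state,
#' the percentage predicted correctly.  States absent from the truth are
#' `NA`.
#'
#' @inheritParams q_score
#' @return Named numeric vector (percent) over the Q8 states.
#' @export
per_label_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) stop("length mismatch")
  out <- stats::setNames(rep(NA_real_, length(Q8_STATES)), Q8_STATES)
  for (s in Q8_STATES) {
    sel <- true_labels == s
    if (any(sel)) out[s] <- 100 * mean(predicted_labels[sel] == s)
  }
  out
}

#' Evaluate a fitted model on labelled records
#'
#' Predicts, scores Q8 and Q3 (Q3 by label coarsening on both streams),
#' and builds per-state accuracies and both confusion matrices.  The
#' Q-score / confusion-trace identity is asserted on every call.
#'
#' @param model A fitted `mccm_model`.
#' @param records Labelled [protein_record()] list.
#' @return Object of class `eval_report`: `q3`, `q8`,
#'   `per_label_accuracy`, `confusion_q3`, `confusion_q8`, `n_labels`,
#'   and the raw `predictions`.
#' @export
evaluate_model <- function(model, records) {
  pred <- predict(model, records)
  if (nrow(pred) == 0L) stop("no labelled residues to evaluate")
  if (any(is.na(pred$true))) stop("evaluation requires labelled records")
  if (model$classes == "Q8") {
    q8 <- q_score(pred$true, pred$pred, k = 8L)
    q3 <- q_score(pred$true, pred$pred, k = 3L)
    c8 <- ss_confusion(pred$true, pred$pred, k = 8L)
    pla <- per_label_accuracy(pred$true, pred$pred)
  } else {
    q8 <- NA_real_
    q3 <- q_score(pred$true, pred$pred, k = 3L)
    c8 <- NULL
    pla <- NULL
  }
  c3 <- ss_confusion(pred$true, pred$pred, k = 3L)
  stopifnot(abs(c3$accuracy - q3) < 1e-8)
  if (!is.null(c8)) stopifnot(abs(c8$accuracy - q8) < 1e-8)
  structure(list(q3 = q3, q8 = q8, per_label_accuracy = pla,
                 confusion_q3 = c3, confusion_q8 = c8,
                 n_labels = nrow(pred), predictions = pred),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d labels, Q3 %.2f, Q8 %s>\n", x$n_labels, x$q3,
              if (is.na(x$q8)) "-" else sprintf("%.2f", x$q8)))
  invisible(x)
}

#' Write evaluation reports
#'
#' Writes tab-separated per-label and confusion-matrix reports plus a
#' machine-readable JSON metrics file into a directory.
#'
#' @param report An [evaluate_model()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$per_label_accuracy)) {
    pla <- report$per_label_accuracy
    ord <- Q8_STATES[order(cb513_q8_frequencies()[Q8_STATES], decreasing = TRUE)]
    writeLines(c("Label\tTypes\tAccuracy",
                 sprintf("%s\t%s\t%s", ord, Q8_TYPE_NAMES[ord],
                         ifelse(is.na(pla[ord]), "undefined",
                                sprintf("%.2f", pla[ord])))),
               file.path(dir, "per_label_accuracy.tsv"))
  }
  writeLines(format_confusion_tsv(report$confusion_q3),
             file.path(dir, "confusion_q3.tsv"))
  if (!is.null(report$confusion_q8)) {
    writeLines(format_confusion_tsv(report$confusion_q8),
               file.path(dir, "confusion_q8.tsv"))
  }
  metrics <- list(q3 = report$q3, q8 = report$q8, n_labels = report$n_labels,
                  per_label_accuracy = as.list(report$per_label_accuracy))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
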