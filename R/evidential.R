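# Dirichlet evidence, information-entropy difficulty, the easy/hard
# routing rule and the combined loss.  Evidence is the rectified
# pre-softmax output: e = max(logit, 0), alpha = e + 1, strength
# S = sum(alpha), expectation p = alpha / S, difficulty H = base-2
# Shannon entropy of p.

#' Dirichlet opinion from classifier logits
#'
#' Converts pre-softmax outputs to per-residue Dirichlet opinions:
#' evidence `e = max(logit, 0)`, parameters `alpha = e + 1`, strength
#' `S = sum(alpha)`, expectation `p = alpha / S` and base-2 entropy of
#' `p`.
#'
#' @param logits Numeric vector (one residue) or length x Z matrix.
#' @return Object of class `dirichlet_opinion`: list with matrices
#'   `alpha`, `p`, vectors `strength`, `entropy`, and the `logits`.
#' @export
#' @examples
#' op <- opinion_from_logits(c(-1, -2, -3))
#' op$p  # uniform: all evidence clipped
opinion_from_logits <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (any(!is.finite(logits))) stop("logits must be finite")
  e <- pmax(logits, 0)
  alpha <- e + 1
  S <- rowSums(alpha)
  p <- alpha / S
  structure(list(alpha = alpha, strength = S, p = p,
                 entropy = -rowSums(p * log2(p)),  # alpha >= 1 keeps p > 0
                 logits = logits),
            class = "dirichlet_opinion")
}

#' @export
print.dirichlet_opinion <- function(x, ...) {
  cat(sprintf("<dirichlet_opinion: %d residues, %d states, mean H = %.3f bits>\n",
              nrow(x$p), ncol(x$p), mean(x$entropy)))
  invisible(x)
}

#' Information entropy of an expectation vector
#'
#' Base-2 Shannon entropy `H(p) = -sum p log2 p` with `0 log 0 = 0`;
#' the difficulty signal of the routing rule.
#'
#' @param p Probability vector on the simplex.
#' @return Entropy in bits, in `[0, log2(length(p))]`.
#' @export
#' @examples
#' information_entropy(rep(1 / 3, 3))  # log2(3)
information_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Dirichlet density on the simplex
#'
#' Probability density of `Dir(alpha)` at a point `p` of the simplex;
#' provided for use as a numerical oracle.
#'
#' @param p Probability vector on the simplex.
#' @param alpha Dirichlet parameters (same length, all > 0).
#' @return Density value.
#' @export
dirichlet_density <- function(p, alpha) {
  stopifnot(length(p) == length(alpha), all(alpha > 0))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) return(0)
  logB <- sum(lgamma(alpha)) - lgamma(sum(alpha))
  exp(sum((alpha - 1) * log(pmax(p, 1e-300))) - logB)
}

#' Evidential (Dirichlet) loss
#'
#' Expected Brier score under the Dirichlet opinion:
#' `sum_z (y_z - p_z)^2 + p_z (1 - p_z) / (S + 1)` per residue, averaged
#' over residues when given a batch.
#'
#' @param y One-hot vector, or length x Z one-hot matrix.
#' @param opinion A [opinion_from_logits()] result (matching rows).
#' @return Mean loss (scalar).
#' @export
#' @examples
#' dirichlet_loss(c(1, 0, 0), opinion_from_logits(c(-1, -1, -1)))  # 0.8333
dirichlet_loss <- function(y, opinion) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  stopifnot(inherits(opinion, "dirichlet_opinion"),
            nrow(y) == nrow(opinion$p), ncol(y) == ncol(opinion$p))
  mean(dirichlet_loss_rows(y, opinion$alpha))
}

# per-row loss values
dirichlet_loss_rows <- function(Y, alpha) {
  S <- rowSums(alpha)
  p <- alpha / S
  rowSums((Y - p)^2 + p * (1 - p) / (S + 1))
}

# gradient of the per-row loss w.r.t. the logits (evidence rectification
# gates the gradient on positive logits)
dirichlet_loss_grad <- function(Y, logits) {
  e <- pmax(logits, 0)
  alpha <- e + 1
  S <- rowSums(alpha)
  p <- alpha / S
  A <- -2 * (Y - p) + (1 - 2 * p) / (S + 1)          # dL/dp
  dS <- -rowSums(p * (1 - p)) / (S + 1)^2            # direct dL/dS
  dalpha <- (A - rowSums(A * p)) / S + dS
  dalpha * (logits > 0)
}

#' Cross-entropy loss
#'
#' Softmax over logits followed by the negative log-likelihood of the
#' one-hot targets, averaged over residues.
#'
#' @param y One-hot vector or length x Z one-hot matrix.
#' @param logits Matching logits.
#' @return Mean loss (scalar, nats).
#' @export
#' @examples
#' cross_entropy(c(1, 0), c(1, 0))  # -log(e / (e + 1))
cross_entropy <- function(y, logits) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  stopifnot(all(dim(y) == dim(logits)))
  m <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  lse <- m + log(rowSums(exp(logits - m)))
  mean(-rowSums(y * (logits - lse)))
}

softmax_rows <- function(logits) {
  m <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Routing configuration
#'
#' How residues are divided between the easy and hard classifiers.
#' `"evidential"` routes by Dirichlet-expectation entropy against the
#' `per`-th percentile of batch entropies at training time (and a frozen
#' threshold at test time); `"label"` routes by correctness of the easy
#' prediction (the diagnostic upper-bound variants); `"confidence"`
#' routes by softmax confidence against a fixed threshold (early-exit
#' semantics: confidently-correct residues stay easy).
#'
#' @param mode One of `"evidential"`, `"label"`, `"confidence"`.
#' @param per Percentile of batch entropies used as the training
#'   threshold, in `[0, 100)`; the reference settings are 15, 30, 35.
#' @param confidence_threshold Softmax-confidence threshold of the
#'   confidence mode.
#' @param beta Weight of the evidential loss terms in the combined loss.
#' @return Object of class `routing_config`.
#' @export
routing_config <- function(mode = c("evidential", "label", "confidence"),
                           per = 30, confidence_threshold = 0.9, beta = 1) {
  mode <- match.arg(mode)
  stopifnot(per >= 0, per < 100,
            confidence_threshold > 0, confidence_threshold < 1, beta >= 0)
  structure(list(mode = mode, per = per,
                 confidence_threshold = confidence_threshold, beta = beta),
            class = "routing_config")
}

#' Route residues between the easy and hard classifiers
#'
#' Applies the discrimination rule to per-residue opinions.  At training
#' time in evidential mode a residue is easy iff the easy prediction is
#' correct and its entropy lies strictly below the `per`-th percentile
#' of batch entropies; at test time, iff its entropy lies strictly below
#' the supplied frozen `threshold` (labels are not consulted).  Label
#' mode routes by correctness alone; confidence mode by softmax
#' confidence (and correctness at training time).
#'
#' @param opinion A [opinion_from_logits()] result for the easy head.
#' @param labels Integer true-class indices; required at training time
#'   and in label mode.
#' @param config A [routing_config()].
#' @param phase `"train"` or `"test"`.
#' @param threshold Frozen entropy threshold (bits); required for
#'   evidential routing at test time.
#' @return Object of class `routing_decision`: list with `assignment`
#'   (factor over easy/hard, one per residue) and `threshold_value`.
#' @export
route_samples <- function(opinion, labels = NULL, config = routing_config(),
                          phase = c("train", "test"), threshold = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(opinion, "dirichlet_opinion"))
  n <- nrow(opinion$p)
  need_labels <- config$mode == "label" || phase == "train"
  if (need_labels && is.null(labels)) {
    stop("labels are required for ", config$mode, " routing at ", phase, " time")
  }
  pred <- max.col(opinion$p, ties.method = "first")
  correct <- if (!is.null(labels)) pred == labels else rep(NA, n)
  if (config$mode == "evidential") {
    if (phase == "train") {
      thr <- as.numeric(stats::quantile(opinion$entropy, config$per / 100,
                                        type = 7, names = FALSE))
      easy <- correct & opinion$entropy < thr
    } else {
      if (is.null(threshold)) stop("evidential routing at test time needs a frozen threshold")
      thr <- threshold
      easy <- opinion$entropy < thr
    }
  } else if (config$mode == "label") {
    thr <- NA_real_
    easy <- correct
  } else {  # confidence
    sm <- softmax_rows(opinion$logits)
    conf <- sm[cbind(seq_len(nrow(sm)), max.col(sm, ties.method = "first"))]
    thr <- config$confidence_threshold
    easy <- if (phase == "train") correct & conf >= thr else conf >= thr
  }
  structure(list(
    assignment = factor(ifelse(easy, "easy", "hard"), levels = c("easy", "hard")),
    threshold_value = thr, mode = config$mode, phase = phase
  ), class = "routing_decision")
}

#' @export
print.routing_decision <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("<routing_decision (%s/%s): %d easy, %d hard, threshold %.4g>\n",
              x$mode, x$phase, tab["easy"], tab["hard"], x$threshold_value))
  invisible(x)
}

#' Combined loss breakdown
#'
#' Assembles the four loss components into the combined objective
#' `total = ce_easy + beta * dir_easy + ce_hard + beta * dir_hard`.
#'
#' @param ce_easy,dir_easy Cross-entropy and evidential loss of the easy
#'   classifier over all real residues.
#' @param ce_hard,dir_hard The same for the hard classifier over
#'   hard-routed residues (0 when none).
#' @param beta Evidential loss weight.
#' @return Object of class `loss_breakdown`.
#' @export
total_loss <- function(ce_easy, dir_easy, ce_hard = 0, dir_hard = 0, beta = 1) {
  structure(list(ce_easy = ce_easy, dir_easy = dir_easy,
                 ce_hard = ce_hard, dir_hard = dir_hard, beta = beta,
                 total = ce_easy + beta * dir_easy + ce_hard + beta * dir_hard),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("ce_easy %.4f | dir_easy %.4f | ce_hard %.4f | dir_hard %.4f | total %.4f\n",
              x$ce_easy, x$dir_easy, x$ce_hard, x$dir_hard, x$total))
  invisible(x)
}
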