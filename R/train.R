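# Seeded training loop: Adam optimisation of the combined objective,
# per-batch routing, entropy-threshold tracking and per-epoch history.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the training set.
#' @param batch_size Proteins per batch.
#' @param dropout Dropout probability applied to the block projections
#'   and the hard classifier at training time.
#' @param seed Integer seed governing initialisation, shuffling and
#'   dropout.
#' @param variant Model variant: `"mccm_dir"` (entropy-routed,
#'   deployable), `"mccm"` (label-routed diagnostic upper bound),
#'   `"mccm_easy"` (label-routed, no backpropagation through the hard
#'   loss), `"mccm_conf"` (confidence-routed early-exit baseline) or
#'   `"mccm_c1"` (easy-only ablation: convolutional features and the
#'   easy classifier alone).
#' @param track_scores Record Q3/Q8 on the splits each epoch (an extra
#'   evaluation pass per epoch).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, epochs = 30L, batch_size = 8L,
                         dropout = 0.5, seed = 1L, variant = "mccm_dir",
                         track_scores = TRUE) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L,
            dropout >= 0, dropout < 1)
  variant_mode(variant)  # validates the name
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 seed = as.integer(seed), variant = variant,
                 track_scores = isTRUE(track_scores)),
            class = "train_config")
}

prepare_batch_data <- function(records, levels, physchem, enc_cfg) {
  lapply(records, function(r) {
    x <- assemble_features(r, physchem, enc_cfg)
    labs <- r$q8_labels
    if (identical(levels, Q3_STATES)) {
      ok <- !is.na(labs)
      labs[ok] <- map_q8_to_q3(labs[ok])
    }
    y <- match(labs[r$mask], levels)
    if (any(is.na(y))) stop("record ", r$id, " has labels outside the class set")
    list(x = x, mask = r$mask, y = y, id = r$id)
  })
}

#' Fit a multistage combination classifier
#'
#' Trains the shared extractor and both classifier heads with Adam on
#' the combined objective, routing residues per batch with the
#' configured rule.  For evidential routing the realised per-batch
#' entropy thresholds are averaged over training and frozen into the
#' model for test-time routing.  Deterministic given
#' `control$seed`.
#'
#' @param train_records List of [protein_record()] objects.
#' @param valid_records Optional held-out records scored each epoch.
#' @param classes `"Q8"` or `"Q3"` target states.
#' @param extractor An [extractor_config()]; its dropout is overridden
#'   by `control$dropout`.
#' @param routing A [routing_config()]; its mode is derived from
#'   `control$variant`.
#' @param control A [train_config()].
#' @param physchem Physicochemical lookup table.
#' @param enc_cfg An [encoding_config()].
#' @return Object of class `mccm_model` with elements `params`,
#'   `threshold` (frozen entropy threshold, evidential variants),
#'   `history` (per-epoch loss breakdown and optional Q scores) and the
#'   configurations.
#' @export
fit_mccm <- function(train_records, valid_records = NULL,
                     classes = c("Q8", "Q3"),
                     extractor = extractor_config(),
                     routing = routing_config(),
                     control = train_config(),
                     physchem = physchem_table(),
                     enc_cfg = encoding_config()) {
  classes <- match.arg(classes)
  if (length(train_records) == 0L) stop("empty training set")
  levels <- if (classes == "Q8") Q8_STATES else Q3_STATES
  n_classes <- length(levels)
  extractor$dropout <- control$dropout
  variant <- control$variant

  train_data <- prepare_batch_data(train_records, levels, physchem, enc_cfg)
  valid_data <- if (!is.null(valid_records))
    prepare_batch_data(valid_records, levels, physchem, enc_cfg) else NULL

  params <- init_mccm_params(extractor, n_classes, seed = control$seed,
                             variant = variant)
  opt <- adam_init(params)
  thresholds <- c()
  history <- data.frame()

  with_seed(control$seed + 1L, {
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(length(train_data))
      starts <- seq(1L, length(ord), by = control$batch_size)
      ep <- c(ce_easy = 0, dir_easy = 0, ce_hard = 0, dir_hard = 0, total = 0)
      nb <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + control$batch_size - 1L, length(ord))]
        res <- batch_loss_and_grads(params, train_data[idx], extractor, routing,
                                    variant, n_classes, train = TRUE)
        if (!is.finite(res$breakdown$total)) {
          stop("training diverged at epoch ", epoch,
               ": non-finite loss (", res$breakdown$total, ")")
        }
        if (variant == "mccm_dir") thresholds <- c(thresholds, res$routing$threshold_value)
        st <- adam_step(params, res$grads, opt, control$learning_rate)
        params <- st$params; opt <- st$state
        b <- res$breakdown
        ep <- ep + c(b$ce_easy, b$dir_easy, b$ce_hard, b$dir_hard, b$total)
        nb <- nb + 1L
      }
      row <- as.data.frame(as.list(ep / nb))
      row$epoch <- epoch
      # backpropagated objective: what the optimiser actually descends
      row$backprop_loss <- if (variant == "mccm_easy") {
        row$ce_easy + routing$beta * row$dir_easy
      } else row$total
      if (control$track_scores) {
        model_now <- new_mccm_model(params, extractor, routing, control, classes,
                                    levels,
                                    threshold = if (length(thresholds)) mean(thresholds) else NA_real_,
                                    history = NULL, physchem = physchem,
                                    enc_cfg = enc_cfg)
        tr_pred <- predict(model_now, train_records)
        row$q8_train <- q_score(tr_pred$true, tr_pred$pred, k = if (classes == "Q8") 8L else 3L)
        if (!is.null(valid_data)) {
          va_pred <- predict(model_now, valid_records)
          row$q8_valid <- q_score(va_pred$true, va_pred$pred,
                                  k = if (classes == "Q8") 8L else 3L)
        }
      }
      history <- rbind(history, row)
    }
  })

  new_mccm_model(params, extractor, routing, control, classes, levels,
                 threshold = if (length(thresholds)) mean(thresholds) else NA_real_,
                 history = history, physchem = physchem, enc_cfg = enc_cfg)
}

new_mccm_model <- function(params, extractor, routing, control, classes,
                           levels, threshold, history, physchem, enc_cfg) {
  structure(list(params = params, extractor = extractor, routing = routing,
                 control = control, classes = classes, levels = levels,
                 threshold = threshold, history = history,
                 physchem = physchem, enc_cfg = enc_cfg,
                 seed = control$seed, variant = control$variant),
            class = "mccm_model")
}

#' @export
print.mccm_model <- function(x, ...) {
  cat(sprintf("<mccm_model %s: %s classes, seed %d, frozen threshold %.4g bits>\n",
              x$variant, x$classes, x$seed, x$threshold))
  if (!is.null(x$history) && nrow(x$history)) {
    cat(sprintf("  trained %d epochs, final total loss %.4f\n",
                nrow(x$history), x$history$total[nrow(x$history)]))
  }
  invisible(x)
}

#' Predict secondary structure with a trained cascade
#'
#' Runs the extractor in evaluation mode, routes residues with the
#' variant's test-time rule (entropy-only for the evidential variant,
#' against the frozen threshold), and reads the final call from the
#' easy classifier for easy-routed residues and the hard classifier for
#' hard-routed residues.  The easy-only readout is always included.
#'
#' @param object A fitted `mccm_model`.
#' @param records List of [protein_record()] objects; all-padding
#'   records yield no rows.
#' @param ... Unused.
#' @return Data frame (class `mccm_prediction`) with one row per real
#'   residue: `protein`, `pos`, `true` (state or `NA`), `pred`
#'   (cascade readout), `pred_easy`, `routed`, `entropy` (bits).
#' @export
predict.mccm_model <- function(object, records, ...) {
  levels <- object$levels
  n_classes <- length(levels)
  variant <- object$variant
  mode <- variant_mode(variant)
  out <- list()
  for (r in records) {
    if (r$length == 0L || !any(r$mask)) next
    x <- assemble_features(r, object$physchem, object$enc_cfg)
    cache <- forward_protein(object$params, x, r$mask, object$extractor,
                             train = FALSE, variant = variant)
    m <- which(r$mask)
    easy_logits <- cache$easy_logits[m, , drop = FALSE]
    opinion <- opinion_from_logits(easy_logits)
    true <- r$q8_labels[m]
    if (object$classes == "Q3") {
      ok <- !is.na(true)
      true[ok] <- map_q8_to_q3(true[ok])
    }
    if (is.na(mode)) {
      assignment <- factor(rep("easy", length(m)), levels = c("easy", "hard"))
    } else if (mode == "label") {
      if (any(is.na(true))) {
        stop("label routing at test time requires labelled records (", r$id, ")")
      }
      y <- match(true, levels)
      rc <- object$routing; rc$mode <- "label"
      dec <- route_samples(opinion, labels = y, config = rc, phase = "test")
      assignment <- dec$assignment
    } else if (mode == "evidential") {
      if (is.na(object$threshold)) stop("evidential prediction needs a frozen threshold")
      rc <- object$routing; rc$mode <- "evidential"
      dec <- route_samples(opinion, config = rc, phase = "test",
                           threshold = object$threshold)
      assignment <- dec$assignment
    } else {
      rc <- object$routing; rc$mode <- "confidence"
      dec <- route_samples(opinion, config = rc, phase = "test")
      assignment <- dec$assignment
    }
    pred_easy_idx <- max.col(opinion$p, ties.method = "first")
    pred_idx <- pred_easy_idx
    if (variant != "mccm_c1") {
      hard_logits <- cache$hard_logits[m, , drop = FALSE]
      hard_idx <- which(assignment == "hard")
      if (length(hard_idx)) {
        pred_idx[hard_idx] <- max.col(hard_logits[hard_idx, , drop = FALSE],
                                      ties.method = "first")
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      protein = r$id, pos = m, true = true,
      pred = levels[pred_idx], pred_easy = levels[pred_easy_idx],
      routed = assignment, entropy = opinion$entropy,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(protein = character(), pos = integer(), true = character(),
               pred = character(), pred_easy = character(),
               routed = factor(character(), levels = c("easy", "hard")),
               entropy = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("mccm_prediction", class(res))
  res
}
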