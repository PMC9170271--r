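# Batch objective and gradients: wires the extractor forward/backward
# to the cascade losses under the routing rule.

variant_mode <- function(variant) {
  switch(variant,
         mccm = "label", mccm_easy = "label",
         mccm_dir = "evidential", mccm_conf = "confidence",
         mccm_c1 = NA_character_,
         stop("unknown variant: ", variant))
}

onehot_rows <- function(idx, k) {
  Y <- matrix(0, length(idx), k)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

# batch: list of list(x = length x 50, mask, y = integer class indices
# over masked rows).  Returns losses, routing, gradients.
batch_loss_and_grads <- function(params, batch, cfg, rcfg, variant,
                                 n_classes, train = TRUE, with_grads = TRUE) {
  caches <- lapply(batch, function(b)
    forward_protein(params, b$x, b$mask, cfg, train = train, variant = variant))
  row_map <- list(); easy_rows <- list(); hard_rows <- list(); y_all <- list()
  for (i in seq_along(batch)) {
    m <- batch[[i]]$mask
    easy_rows[[i]] <- caches[[i]]$easy_logits[m, , drop = FALSE]
    hard_rows[[i]] <- if (variant != "mccm_c1")
      caches[[i]]$hard_logits[m, , drop = FALSE] else NULL
    y_all[[i]] <- batch[[i]]$y
    row_map[[i]] <- which(m)
  }
  easy_logits <- do.call(rbind, easy_rows)
  y <- unlist(y_all)
  n <- length(y)
  if (n == 0L) stop("batch contains no real residues")
  Y <- onehot_rows(y, n_classes)
  opinion <- opinion_from_logits(easy_logits)

  mode <- variant_mode(variant)
  if (is.na(mode)) {
    routing <- structure(list(assignment = factor(rep("easy", n),
                                                  levels = c("easy", "hard")),
                              threshold_value = NA_real_,
                              mode = "none", phase = "train"),
                         class = "routing_decision")
  } else {
    rc <- rcfg; rc$mode <- mode
    routing <- route_samples(opinion, labels = y, config = rc, phase = "train")
  }
  hard_idx <- which(routing$assignment == "hard")

  ce_easy <- cross_entropy(Y, easy_logits)
  dir_easy <- mean(dirichlet_loss_rows(Y, opinion$alpha))
  ce_hard <- dir_hard <- 0
  if (variant != "mccm_c1" && length(hard_idx) > 0L) {
    hard_logits <- do.call(rbind, hard_rows)
    hl <- hard_logits[hard_idx, , drop = FALSE]
    Yh <- Y[hard_idx, , drop = FALSE]
    ce_hard <- cross_entropy(Yh, hl)
    dir_hard <- mean(dirichlet_loss_rows(Yh, pmax(hl, 0) + 1))
  }
  breakdown <- total_loss(ce_easy, dir_easy, ce_hard, dir_hard, rcfg$beta)

  out <- list(breakdown = breakdown, routing = routing, opinion = opinion,
              n_residues = n, n_hard = length(hard_idx))
  if (!with_grads) return(out)

  d_easy <- (softmax_rows(easy_logits) - Y) / n +
    rcfg$beta * dirichlet_loss_grad(Y, easy_logits) / n
  d_hard_all <- NULL
  backprop_hard <- variant %in% c("mccm", "mccm_dir", "mccm_conf") &&
    length(hard_idx) > 0L
  if (backprop_hard) {
    hard_logits <- do.call(rbind, hard_rows)
    d_hard_all <- matrix(0, n, n_classes)
    hl <- hard_logits[hard_idx, , drop = FALSE]
    Yh <- Y[hard_idx, , drop = FALSE]
    nh <- length(hard_idx)
    d_hard_all[hard_idx, ] <- (softmax_rows(hl) - Yh) / nh +
      rcfg$beta * dirichlet_loss_grad(Yh, hl) / nh
  }

  grads <- NULL
  offset <- 0L
  for (i in seq_along(batch)) {
    ni <- length(row_map[[i]])
    rows <- offset + seq_len(ni)
    offset <- offset + ni
    de <- matrix(0, nrow(batch[[i]]$x), n_classes)
    de[row_map[[i]], ] <- d_easy[rows, , drop = FALSE]
    dh <- NULL
    if (variant != "mccm_c1") {
      dh <- matrix(0, nrow(batch[[i]]$x), n_classes)
      if (backprop_hard) dh[row_map[[i]], ] <- d_hard_all[rows, , drop = FALSE]
      if (variant == "mccm_easy") dh <- dh * 0
    }
    gi <- backward_protein(params, caches[[i]], batch[[i]]$x, batch[[i]]$mask,
                           cfg, de, dh, variant)
    grads <- tree_add(grads, gi)
  }
  out$grads <- grads
  out
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(w) w * 0, params),
       v = tree_map(function(w) w * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  list(params = tree_map2(`-`, params, upd), state = state)
}
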