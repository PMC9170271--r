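# Multilevel feature extractor and classifier heads: seeded
# initialisation, forward passes with caches, and hand-derived backward
# passes.  All maths is plain matrix algebra; correctness is anchored by
# a finite-difference gradient check in the test suite.

#' Feature-extractor configuration
#'
#' Widths of the multilevel feature extractor and the hard classifier.
#' Defaults follow the reference architecture: per-block linear widths
#' 64/128/32/16 for one-hot / profile / physicochemical / conservation,
#' three same-length 1-D convolutions of 64 channels with kernel sizes
#' 5/9/13 (easy feature width 192), a bidirectional gated recurrent
#' layer of hidden size 256 (context width 512), an attention hidden
#' size of 256, and a 512/1024 multilayer perceptron for the hard
#' classifier.  Dropout (probability `dropout`) applies to the four
#' block projections and the perceptron layers at training time only.
#'
#' @param branch_hidden Four positive integers: block projection widths.
#' @param conv_hidden Channels per convolution kernel.
#' @param conv_kernels Odd kernel sizes.
#' @param recurrent_hidden Hidden size per recurrent direction.
#' @param attention_hidden Attention hidden size.
#' @param mlp_hidden Two hidden widths of the hard classifier.
#' @param dropout Dropout probability in `[0, 1)`.
#' @return Object of class `extractor_config`.
#' @export
extractor_config <- function(branch_hidden = c(64L, 128L, 32L, 16L),
                             conv_hidden = 64L,
                             conv_kernels = c(5L, 9L, 13L),
                             recurrent_hidden = 256L,
                             attention_hidden = 256L,
                             mlp_hidden = c(512L, 1024L),
                             dropout = 0.5) {
  stopifnot(length(branch_hidden) == 4L, all(branch_hidden >= 1L),
            conv_hidden >= 1L, length(conv_kernels) >= 1L,
            recurrent_hidden >= 1L, attention_hidden >= 1L,
            length(mlp_hidden) == 2L, all(mlp_hidden >= 1L),
            dropout >= 0, dropout < 1)
  if (any(conv_kernels %% 2L == 0L)) stop("convolution kernel sizes must be odd")
  structure(list(branch_hidden = as.integer(branch_hidden),
                 conv_hidden = as.integer(conv_hidden),
                 conv_kernels = as.integer(conv_kernels),
                 recurrent_hidden = as.integer(recurrent_hidden),
                 attention_hidden = as.integer(attention_hidden),
                 mlp_hidden = as.integer(mlp_hidden),
                 dropout = dropout),
            class = "extractor_config")
}

# derived widths
cfg_widths <- function(cfg) {
  cw <- cfg$conv_hidden * length(cfg$conv_kernels)
  hw <- 2L * cfg$recurrent_hidden
  list(l = sum(cfg$branch_hidden), c = cw, h = hw, v = cw + 2L * hw)
}

affine <- function(x, W, b) x %*% W + rep(b, each = nrow(x))

rmat <- function(nr, nc, s) matrix(stats::runif(nr * nc, -s, s), nr, nc)

init_linear <- function(n_in, n_out) {
  s <- 1 / sqrt(n_in)
  list(W = rmat(n_in, n_out, s), b = stats::runif(n_out, -s, s))
}

init_gru <- function(n_in, h) {
  s_c <- 1 / sqrt(n_in); s_h <- 1 / sqrt(h)
  list(Wcr = rmat(n_in, h, s_c), Whr = rmat(h, h, s_h), br = stats::runif(h, -s_h, s_h),
       Wcu = rmat(n_in, h, s_c), Whu = rmat(h, h, s_h), bu = stats::runif(h, -s_h, s_h),
       Wch = rmat(n_in, h, s_c), Whh = rmat(h, h, s_h), bh = stats::runif(h, -s_h, s_h))
}

#' Initialise model parameters
#'
#' Seeded uniform fan-in initialisation of every trainable weight of the
#' extractor and both classifier heads.  The `"mccm_c1"` ablation keeps
#' only the block projections, convolutions and the easy head.
#'
#' @param config An [extractor_config()].
#' @param n_classes Number of output states (8 or 3).
#' @param seed Integer seed.
#' @param variant One of `"mccm"`, `"mccm_easy"`, `"mccm_dir"`,
#'   `"mccm_conf"`, `"mccm_c1"`.
#' @return Nested parameter list.
#' @export
init_mccm_params <- function(config = extractor_config(), n_classes = 8L,
                             seed = 1L, variant = "mccm_dir") {
  w <- cfg_widths(config)
  with_seed(seed, {
    p <- list(
      branch = list(init_linear(21L, config$branch_hidden[1]),
                    init_linear(21L, config$branch_hidden[2]),
                    init_linear(7L, config$branch_hidden[3]),
                    init_linear(1L, config$branch_hidden[4])),
      conv = lapply(config$conv_kernels,
                    function(f) init_linear(f * w$l, config$conv_hidden)),
      easy = init_linear(w$c, n_classes)
    )
    if (variant != "mccm_c1") {
      s_a <- 1 / sqrt(w$h)
      p$gru_f <- init_gru(w$c, config$recurrent_hidden)
      p$gru_b <- init_gru(w$c, config$recurrent_hidden)
      p$attn <- list(Wa = rmat(w$h, config$attention_hidden, s_a),
                     ba = stats::runif(config$attention_hidden, -s_a, s_a),
                     sa = stats::runif(config$attention_hidden,
                                       -1 / sqrt(config$attention_hidden),
                                       1 / sqrt(config$attention_hidden)))
      p$mlp <- list(init_linear(w$v, config$mlp_hidden[1]),
                    init_linear(config$mlp_hidden[1], config$mlp_hidden[2]),
                    init_linear(config$mlp_hidden[2], n_classes))
    }
    p
  })
}

# ---- dropout -------------------------------------------------------------

draw_dropout <- function(nr, nc, tau, train) {
  if (!train || tau <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= tau) / (1 - tau), nr, nc)
}

apply_dropout <- function(x, mask) if (is.null(mask)) x else x * mask

# ---- block projections (Eq-4 stage) --------------------------------------

branch_fwd <- function(x, p, cfg, train = FALSE) {
  blocks <- list(x[, 1:21, drop = FALSE], x[, 22:42, drop = FALSE],
                 x[, 43:49, drop = FALSE], x[, 50, drop = FALSE])
  outs <- vector("list", 4L)
  masks <- vector("list", 4L)
  for (i in 1:4) {
    o <- affine(blocks[[i]], p$branch[[i]]$W, p$branch[[i]]$b)
    masks[i] <- list(draw_dropout(nrow(o), ncol(o), cfg$dropout, train))
    outs[[i]] <- apply_dropout(o, masks[[i]])
  }
  list(l = do.call(cbind, outs), blocks = blocks, masks = masks)
}

branch_bwd <- function(cache, dl, p, cfg) {
  g <- list()
  hid <- cfg$branch_hidden
  off <- c(0L, cumsum(hid))
  for (i in 1:4) {
    d <- dl[, (off[i] + 1L):off[i + 1L], drop = FALSE]
    d <- apply_dropout(d, cache$masks[[i]])
    g[[i]] <- list(W = crossprod(cache$blocks[[i]], d), b = colSums(d))
  }
  g
}

# ---- multiscale same-length 1-D convolution ------------------------------

im2col <- function(l, f) {
  n <- nrow(l); m <- ncol(l); pad <- (f - 1L) %/% 2L
  lp <- rbind(matrix(0, pad, m), l, matrix(0, pad, m))
  out <- matrix(0, n, f * m)
  for (j in seq_len(f)) {
    out[, ((j - 1L) * m + 1L):(j * m)] <- lp[j:(j + n - 1L), , drop = FALSE]
  }
  out
}

col2im <- function(dX, f, n, m) {
  pad <- (f - 1L) %/% 2L
  dlp <- matrix(0, n + 2L * pad, m)
  for (j in seq_len(f)) {
    dlp[j:(j + n - 1L), ] <- dlp[j:(j + n - 1L), ] +
      dX[, ((j - 1L) * m + 1L):(j * m), drop = FALSE]
  }
  dlp[(pad + 1L):(pad + n), , drop = FALSE]
}

conv_fwd <- function(l, p, cfg) {
  outs <- vector("list", length(cfg$conv_kernels))
  cache <- vector("list", length(cfg$conv_kernels))
  for (k in seq_along(cfg$conv_kernels)) {
    f <- cfg$conv_kernels[k]
    X <- im2col(l, f)
    pre <- affine(X, p$conv[[k]]$W, p$conv[[k]]$b)
    act <- pre > 0
    outs[[k]] <- pre * act
    cache[[k]] <- list(X = X, act = act)
  }
  list(c = do.call(cbind, outs), cache = cache)
}

conv_bwd <- function(cache, dc, p, cfg, n, m) {
  g <- vector("list", length(cfg$conv_kernels))
  dl <- matrix(0, n, m)
  ch <- cfg$conv_hidden
  for (k in seq_along(cfg$conv_kernels)) {
    f <- cfg$conv_kernels[k]
    d <- dc[, ((k - 1L) * ch + 1L):(k * ch), drop = FALSE] * cache[[k]]$act
    g[[k]] <- list(W = crossprod(cache[[k]]$X, d), b = colSums(d))
    dl <- dl + col2im(d %*% t(p$conv[[k]]$W), f, n, m)
  }
  list(grad = g, dl = dl)
}

# ---- gated recurrent pass (one direction) --------------------------------
# Gate algebra exactly as the reference formulation, candidate bias
# inside the recurrent product:
#   r_t = sigm(c_t Wcr + h_{t-1} Whr + br)
#   u_t = sigm(c_t Wcu + h_{t-1} Whu + bu)
#   s_t = r_t * h_{t-1} + bh
#   htil_t = tanh(c_t Wch + s_t Whh)
#   h_t = u_t * h_{t-1} + (1 - u_t) * htil_t
# Masked-false positions hold the state (features there are zero anyway).

gru_fwd <- function(cmat, mask, g, H) {
  n <- nrow(cmat)
  R <- U <- Htil <- S_ <- Hout <- matrix(0, n, H)
  # input-side gate contributions for every position at once
  in_r <- cmat %*% g$Wcr + rep(g$br, each = n)
  in_u <- cmat %*% g$Wcu + rep(g$bu, each = n)
  in_h <- cmat %*% g$Wch
  h <- matrix(0, 1L, H)
  for (t in seq_len(n)) {
    if (mask[t]) {
      r <- stats::plogis(in_r[t, ] + h %*% g$Whr)
      u <- stats::plogis(in_u[t, ] + h %*% g$Whu)
      s <- r * h + rep(g$bh, each = 1L)
      htil <- tanh(in_h[t, ] + s %*% g$Whh)
      R[t, ] <- r; U[t, ] <- u; S_[t, ] <- s; Htil[t, ] <- htil
      h <- u * h + (1 - u) * htil
    }
    Hout[t, ] <- h
  }
  list(H = Hout, R = R, U = U, S = S_, Htil = Htil)
}

gru_bwd <- function(cache, cmat, mask, dH, g, H) {
  n <- nrow(cmat)
  dAr <- dAu <- dAh <- dS <- matrix(0, n, H)
  tWhh <- t(g$Whh); tWhr <- t(g$Whr); tWhu <- t(g$Whu)
  Hprev <- rbind(matrix(0, 1L, H), cache$H[-n, , drop = FALSE])
  dh <- matrix(0, 1L, H)
  for (t in rev(seq_len(n))) {
    dh <- dh + dH[t, , drop = FALSE]
    if (!mask[t]) next
    hprev <- Hprev[t, , drop = FALSE]
    r <- cache$R[t, ]; u <- cache$U[t, ]; htil <- cache$Htil[t, ]
    da_u <- dh * (hprev - htil) * u * (1 - u)
    da_h <- dh * (1 - u) * (1 - htil^2)
    ds <- da_h %*% tWhh
    da_r <- ds * hprev * r * (1 - r)
    dAr[t, ] <- da_r; dAu[t, ] <- da_u; dAh[t, ] <- da_h; dS[t, ] <- ds
    dh <- dh * u + ds * r + da_r %*% tWhr + da_u %*% tWhu
  }
  gr <- list(Wcr = crossprod(cmat, dAr), Whr = crossprod(Hprev, dAr),
             br = colSums(dAr),
             Wcu = crossprod(cmat, dAu), Whu = crossprod(Hprev, dAu),
             bu = colSums(dAu),
             Wch = crossprod(cmat, dAh), Whh = crossprod(cache$S, dAh),
             bh = colSums(dS))
  dC <- dAr %*% t(g$Wcr) + dAu %*% t(g$Wcu) + dAh %*% t(g$Wch)
  list(grad = gr[names(g)], dC = dC)
}

bigru_fwd <- function(cmat, mask, p, cfg) {
  H <- cfg$recurrent_hidden
  fwd <- gru_fwd(cmat, mask, p$gru_f, H)
  rev_idx <- rev(seq_len(nrow(cmat)))
  bwd <- gru_fwd(cmat[rev_idx, , drop = FALSE], mask[rev_idx], p$gru_b, H)
  h <- cbind(fwd$H, bwd$H[rev_idx, , drop = FALSE])
  list(h = h, fwd = fwd, bwd = bwd)
}

bigru_bwd <- function(cache, cmat, mask, dh, p, cfg) {
  H <- cfg$recurrent_hidden
  n <- nrow(cmat)
  rev_idx <- rev(seq_len(n))
  gf <- gru_bwd(cache$fwd, cmat, mask, dh[, 1:H, drop = FALSE], p$gru_f, H)
  gb <- gru_bwd(cache$bwd, cmat[rev_idx, , drop = FALSE], mask[rev_idx],
                dh[rev_idx, (H + 1L):(2L * H), drop = FALSE], p$gru_b, H)
  list(grad_f = gf$grad, grad_b = gb$grad,
       dC = gf$dC + gb$dC[rev_idx, , drop = FALSE])
}

# ---- sequential attention ------------------------------------------------

attn_fwd <- function(h, mask, p) {
  if (!any(mask)) stop("attention requires at least one real residue")
  U <- tanh(affine(h, p$attn$Wa, p$attn$ba))
  at <- as.numeric(U %*% p$attn$sa)
  at[!mask] <- -Inf
  a <- exp(at - max(at[mask]))
  a[!mask] <- 0
  alpha <- a / sum(a)
  alpha_h <- as.numeric(crossprod(h, alpha))
  list(alpha = alpha, alpha_h = alpha_h, U = U)
}

attn_bwd <- function(cache, h, mask, dalpha_h, dh_extra, p) {
  # dalpha_h: vector over context width; returns dh and parameter grads
  alpha <- cache$alpha
  dalpha <- as.numeric(h %*% dalpha_h)          # via alpha_h = sum alpha_t h_t
  dh <- outer(alpha, dalpha_h)
  if (!is.null(dh_extra)) dh <- dh + dh_extra
  dat <- alpha * (dalpha - sum(alpha * dalpha)) # softmax backward
  dat[!mask] <- 0
  dU <- outer(dat, p$attn$sa)
  dsa <- as.numeric(crossprod(cache$U, dat))
  dpre <- dU * (1 - cache$U^2)
  list(grad = list(Wa = crossprod(h, dpre), ba = colSums(dpre), sa = dsa),
       dh = dh + dpre %*% t(p$attn$Wa))
}

# ---- classifier heads ----------------------------------------------------

mlp_fwd <- function(v, p, cfg, train = FALSE) {
  pre1 <- affine(v, p$mlp[[1]]$W, p$mlp[[1]]$b)
  act1 <- pre1 > 0
  z1 <- pre1 * act1
  m1 <- draw_dropout(nrow(z1), ncol(z1), cfg$dropout, train)
  z1d <- apply_dropout(z1, m1)
  pre2 <- affine(z1d, p$mlp[[2]]$W, p$mlp[[2]]$b)
  act2 <- pre2 > 0
  z2 <- pre2 * act2
  m2 <- draw_dropout(nrow(z2), ncol(z2), cfg$dropout, train)
  z2d <- apply_dropout(z2, m2)
  logits <- affine(z2d, p$mlp[[3]]$W, p$mlp[[3]]$b)
  list(logits = logits, v = v, act1 = act1, z1d = z1d, m1 = m1,
       act2 = act2, z2d = z2d, m2 = m2)
}

mlp_bwd <- function(cache, dlogits, p) {
  g3 <- list(W = crossprod(cache$z2d, dlogits), b = colSums(dlogits))
  d2 <- apply_dropout(dlogits %*% t(p$mlp[[3]]$W), cache$m2) * cache$act2
  g2 <- list(W = crossprod(cache$z1d, d2), b = colSums(d2))
  d1 <- apply_dropout(d2 %*% t(p$mlp[[2]]$W), cache$m1) * cache$act1
  g1 <- list(W = crossprod(cache$v, d1), b = colSums(d1))
  list(grad = list(g1, g2, g3), dv = d1 %*% t(p$mlp[[1]]$W))
}

# ---- full per-protein forward / backward ---------------------------------

forward_protein <- function(params, x, mask, cfg, train = FALSE,
                            variant = "mccm_dir") {
  br <- branch_fwd(x, params, cfg, train)
  cv <- conv_fwd(br$l, params, cfg)
  easy_logits <- affine(cv$c, params$easy$W, params$easy$b)
  out <- list(branch = br, conv = cv, easy_logits = easy_logits,
              c = cv$c, mask = mask)
  if (variant != "mccm_c1") {
    gr <- bigru_fwd(cv$c, mask, params, cfg)
    at <- attn_fwd(gr$h, mask, params)
    n <- nrow(cv$c)
    v <- cbind(cv$c, gr$h, matrix(at$alpha_h, n, length(at$alpha_h), byrow = TRUE))
    ml <- mlp_fwd(v, params, cfg, train)
    out$gru <- gr; out$attn <- at; out$v <- v; out$mlp <- ml
    out$h <- gr$h
    out$hard_logits <- ml$logits
  }
  out
}

backward_protein <- function(params, cache, x, mask, cfg, d_easy, d_hard,
                             variant = "mccm_dir") {
  w <- cfg_widths(cfg)
  n <- nrow(x)
  grads <- list()
  dc <- d_easy %*% t(params$easy$W)
  grads$easy <- list(W = crossprod(cache$c, d_easy), b = colSums(d_easy))
  if (variant != "mccm_c1" && !is.null(d_hard)) {
    mb <- mlp_bwd(cache$mlp, d_hard, params)
    grads$mlp <- mb$grad
    dv <- mb$dv
    dc <- dc + dv[, 1:w$c, drop = FALSE]
    dh_direct <- dv[, (w$c + 1L):(w$c + w$h), drop = FALSE]
    dalpha_h <- colSums(dv[, (w$c + w$h + 1L):(w$c + 2L * w$h), drop = FALSE])
    ab <- attn_bwd(cache$attn, cache$h, mask, dalpha_h, dh_direct, params)
    grads$attn <- ab$grad
    gb <- bigru_bwd(cache$gru, cache$c, mask, ab$dh, params, cfg)
    grads$gru_f <- gb$grad_f
    grads$gru_b <- gb$grad_b
    dc <- dc + gb$dC
  } else if (variant != "mccm_c1") {
    # hard path present but excluded from the gradient
    grads$mlp <- lapply(params$mlp, function(l) list(W = l$W * 0, b = l$b * 0))
    grads$attn <- lapply(params$attn, function(w_) w_ * 0)
    grads$gru_f <- lapply(params$gru_f, function(w_) w_ * 0)
    grads$gru_b <- lapply(params$gru_b, function(w_) w_ * 0)
  }
  cb <- conv_bwd(cache$conv$cache, dc, params, cfg, n, w$l)
  grads$conv <- cb$grad
  grads$branch <- branch_bwd(cache$branch, cb$dl, params, cfg)
  grads[names(params)]  # align element order with the parameter tree
}

# ---- parameter-tree utilities -------------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else {
    f(a)
  }
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  tree_map2(`+`, a, b)
}

# ---- public operation surfaces ------------------------------------------

#' Project feature blocks through the four linear branches
#'
#' Each of the four feature blocks (one-hot 21, profile 21,
#' physicochemical 7, conservation 1) passes through its own affine map;
#' outputs are concatenated in block order (default width 240).
#'
#' @param features length x 50 matrix from [assemble_features()].
#' @param params Parameters from [init_mccm_params()].
#' @param config The [extractor_config()] used at initialisation.
#' @param train Apply dropout (training mode).
#' @return length x sum(branch_hidden) matrix.
#' @export
branch_project <- function(features, params, config = extractor_config(),
                           train = FALSE) {
  if (ncol(features) != 50L) stop("expected 50 feature columns, got ", ncol(features))
  branch_fwd(features, params, config, train)$l
}

#' Multiscale same-length 1-D convolution
#'
#' Applies one rectified-linear 1-D convolution per kernel size
#' (zero-padded, centred, output length = input length) and concatenates
#' the channel blocks: the easy feature `c` (default width 192).
#'
#' @param l Projected features from [branch_project()].
#' @inheritParams branch_project
#' @return length x (conv_hidden * n_kernels) matrix.
#' @export
multiscale_conv <- function(l, params, config = extractor_config()) {
  conv_fwd(l, params, config)$c
}

#' Bidirectional gated recurrent contexts
#'
#' Runs the gated recurrent pass over positions in both directions and
#' concatenates the two outputs (default width 512).
#'
#' @param c Easy features from [multiscale_conv()].
#' @param mask Logical validity vector (state is held across padding).
#' @inheritParams branch_project
#' @return length x (2 * recurrent_hidden) matrix.
#' @export
recurrent_contexts <- function(c, params, config = extractor_config(),
                               mask = rep(TRUE, nrow(c))) {
  bigru_fwd(c, mask, params, config)$h
}

#' Sequential attention over recurrent contexts
#'
#' Scores each position, softmax-normalises over real residues only,
#' and returns both the position weights and the weighted context sum.
#'
#' @param h Contexts from [recurrent_contexts()].
#' @param mask Logical validity vector; at least one `TRUE`.
#' @inheritParams branch_project
#' @return List with `alpha` (length vector on the simplex) and
#'   `alpha_h` (context-width vector).
#' @export
sequential_attention <- function(h, params, config = extractor_config(),
                                 mask = rep(TRUE, nrow(h))) {
  a <- attn_fwd(h, mask, params)
  list(alpha = a$alpha, alpha_h = a$alpha_h)
}

#' Concatenate the hard feature
#'
#' Per-position concatenation `v = [c, h, alpha_h]` with the
#' per-sequence attention summary tiled across positions (default width
#' 192 + 512 + 512 = 1216).
#'
#' @param c Easy features.
#' @param h Recurrent contexts.
#' @param alpha_h Attention summary vector.
#' @return length x (width(c) + 2 * width(h)) matrix.
#' @export
hard_concat <- function(c, h, alpha_h) {
  if (nrow(c) != nrow(h)) stop("c and h disagree on sequence length")
  if (length(alpha_h) != ncol(h)) stop("alpha_h width must match h")
  cbind(c, h, matrix(alpha_h, nrow(c), length(alpha_h), byrow = TRUE))
}

#' Easy classifier logits
#'
#' Single affine map from the easy feature to class logits.
#'
#' @param c Easy features.
#' @param params Parameters from [init_mccm_params()].
#' @return length x n_classes logit matrix.
#' @export
easy_classify <- function(c, params) {
  if (ncol(c) != nrow(params$easy$W)) stop("easy-feature width mismatch")
  affine(c, params$easy$W, params$easy$b)
}

#' Hard classifier logits
#'
#' Two rectified-linear hidden layers (with dropout at training time)
#' followed by an affine output layer.
#'
#' @param v Hard features from [hard_concat()].
#' @inheritParams branch_project
#' @return length x n_classes logit matrix.
#' @export
hard_classify <- function(v, params, config = extractor_config(), train = FALSE) {
  if (ncol(v) != nrow(params$mlp[[1]]$W)) stop("hard-feature width mismatch")
  mlp_fwd(v, params, config, train)$logits
}
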