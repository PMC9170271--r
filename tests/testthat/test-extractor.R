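test_that("default geometry produces the documented widths", {
  cfg <- extractor_config()
  params <- init_mccm_params(cfg, n_classes = 8L, seed = 1)
  spec <- synthetic_spec(n_proteins = 1, length_range = c(5, 5), seed = 2)
  x <- assemble_features(generate_proteins(spec)[[1]])
  l <- branch_project(x, params, cfg)
  expect_equal(dim(l), c(5L, 240L))
  c_feat <- multiscale_conv(l, params, cfg)
  expect_equal(dim(c_feat), c(5L, 192L))
  h <- recurrent_contexts(c_feat, params, cfg)
  expect_equal(dim(h), c(5L, 512L))
  at <- sequential_attention(h, params, cfg)
  expect_length(at$alpha_h, 512L)
  v <- hard_concat(c_feat, h, at$alpha_h)
  expect_equal(ncol(v), 1216L)
  expect_equal(ncol(easy_classify(c_feat, params)), 8L)
  expect_equal(ncol(hard_classify(v, params, cfg)), 8L)
})

test_that("zero inputs with zero biases map to zero through affine stages", {
  cfg <- tiny_extractor()
  params <- init_mccm_params(cfg, n_classes = 3L, seed = 3)
  params$branch <- lapply(params$branch, function(b) { b$b[] <- 0; b })
  params$conv <- lapply(params$conv, function(b) { b$b[] <- 0; b })
  x <- matrix(0, 4, 50)
  l <- branch_project(x, params, cfg)
  expect_equal(l, matrix(0, 4, sum(cfg$branch_hidden)))
  expect_equal(multiscale_conv(l, params, cfg),
               matrix(0, 4, cfg$conv_hidden * 2L))
  # single-residue protein still yields one projected row
  expect_equal(dim(branch_project(matrix(0, 1, 50), params, cfg)),
               c(1L, sum(cfg$branch_hidden)))
})

test_that("multiscale convolution matches a sliding-window oracle", {
  set.seed(5)
  cfg <- extractor_config(branch_hidden = c(2L, 2L, 1L, 1L), conv_hidden = 4L,
                          conv_kernels = c(3L, 5L), recurrent_hidden = 2L,
                          attention_hidden = 2L, mlp_hidden = c(3L, 3L),
                          dropout = 0)
  params <- init_mccm_params(cfg, 3L, seed = 8)
  m <- sum(cfg$branch_hidden)
  for (n in c(1L, 7L, 20L)) {
    l <- matrix(rnorm(n * m), n, m)
    got <- multiscale_conv(l, params, cfg)
    # brute force: explicit window sum per position/kernel/channel
    for (k in seq_along(cfg$conv_kernels)) {
      f <- cfg$conv_kernels[k]
      pad <- (f - 1L) %/% 2L
      W <- params$conv[[k]]$W; b <- params$conv[[k]]$b
      for (t in seq_len(n)) for (o in seq_len(cfg$conv_hidden)) {
        acc <- b[o]
        for (j in seq_len(f)) {
          src <- t + j - 1L - pad
          if (src >= 1L && src <= n) {
            acc <- acc + sum(l[src, ] * W[((j - 1L) * m + 1L):(j * m), o])
          }
        }
        expect_equal(got[t, (k - 1L) * cfg$conv_hidden + o], max(acc, 0),
                     tolerance = 1e-6)
      }
    }
  }
  expect_error(extractor_config(conv_kernels = c(4L)), "odd")
})

test_that("an identity-like single-channel kernel preserves an impulse", {
  cfg <- extractor_config(branch_hidden = c(1L, 1L, 1L, 1L), conv_hidden = 1L,
                          conv_kernels = 3L, recurrent_hidden = 1L,
                          attention_hidden = 1L, mlp_hidden = c(2L, 2L),
                          dropout = 0)
  params <- init_mccm_params(cfg, 3L, seed = 1)
  m <- 4L
  params$conv[[1]]$W <- matrix(0, 3L * m, 1L)
  params$conv[[1]]$W[m + 1L, 1L] <- 1  # centre tap, first channel
  params$conv[[1]]$b[] <- 0
  l <- matrix(0, 7, m)
  l[4, 1] <- 1
  out <- multiscale_conv(l, params, cfg)
  expect_equal(as.numeric(out), c(0, 0, 0, 1, 0, 0, 0))
})

test_that("gated recurrence obeys its fixed points and a scalar hand oracle", {
  cfg <- extractor_config(branch_hidden = c(1L, 1L, 1L, 1L), conv_hidden = 1L,
                          conv_kernels = 3L, recurrent_hidden = 1L,
                          attention_hidden = 1L, mlp_hidden = c(2L, 2L),
                          dropout = 0)
  base <- list(Wcr = matrix(0.4), Whr = matrix(0.3), br = 0.1,
               Wcu = matrix(-0.2), Whu = matrix(0.5), bu = 0.2,
               Wch = matrix(0.7), Whh = matrix(-0.6), bh = 0.05)
  params <- init_mccm_params(cfg, 3L, seed = 1)
  cmat <- matrix(c(0.5, -0.3), 2, 1)

  # saturated update gate: state never leaves its initial zero
  g1 <- base; g1$bu <- 1e6
  params$gru_f <- g1; params$gru_b <- g1
  h <- recurrent_contexts(cmat, params, cfg)
  expect_equal(h, matrix(0, 2, 2))

  # open update gate: the state equals the candidate at every step
  g0 <- base; g0$bu <- -1e6
  params$gru_f <- g0; params$gru_b <- g0
  h <- recurrent_contexts(cmat, params, cfg)
  htil1 <- tanh(0.7 * 0.5 + (plogis(0.4 * 0.5 + 0.1) * 0 + 0.05) * (-0.6))
  expect_equal(h[1, 1], htil1, tolerance = 1e-12)

  # full scalar hand evaluation of two forward steps
  params$gru_f <- base; params$gru_b <- base
  h <- recurrent_contexts(cmat, params, cfg)
  h0 <- 0
  r1 <- plogis(0.4 * 0.5 + 0.3 * h0 + 0.1)
  u1 <- plogis(-0.2 * 0.5 + 0.5 * h0 + 0.2)
  ht1 <- tanh(0.7 * 0.5 + (r1 * h0 + 0.05) * (-0.6))
  h1 <- u1 * h0 + (1 - u1) * ht1
  r2 <- plogis(0.4 * (-0.3) + 0.3 * h1 + 0.1)
  u2 <- plogis(-0.2 * (-0.3) + 0.5 * h1 + 0.2)
  ht2 <- tanh(0.7 * (-0.3) + (r2 * h1 + 0.05) * (-0.6))
  h2 <- u2 * h1 + (1 - u2) * ht2
  expect_equal(h[, 1], c(h1, h2), tolerance = 1e-12)
  # backward direction processes the reversed sequence with its own pass
  hb1 <- (1 - plogis(-0.2 * (-0.3) + 0.2)) *
    tanh(0.7 * (-0.3) + (plogis(0.4 * (-0.3) + 0.1) * 0 + 0.05) * (-0.6))
  expect_equal(h[2, 2], hb1, tolerance = 1e-12)
})

test_that("attention weights form a simplex and alpha_h stays in the hull", {
  cfg <- extractor_config(branch_hidden = c(1L, 1L, 1L, 1L), conv_hidden = 1L,
                          conv_kernels = 3L, recurrent_hidden = 1L,
                          attention_hidden = 2L, mlp_hidden = c(2L, 2L),
                          dropout = 0)
  params <- init_mccm_params(cfg, 3L, seed = 6)
  set.seed(9)
  h <- matrix(rnorm(8), 4, 2)
  at <- sequential_attention(h, params, cfg)
  expect_equal(sum(at$alpha), 1, tolerance = 1e-12)
  expect_true(all(at$alpha >= 0))
  for (j in 1:2) {
    expect_gte(at$alpha_h[j], min(h[, j]))
    expect_lte(at$alpha_h[j], max(h[, j]))
  }
  # length-1 sequence: full weight on the only position
  at1 <- sequential_attention(h[1, , drop = FALSE], params, cfg)
  expect_equal(at1$alpha, 1)
  expect_equal(at1$alpha_h, h[1, ])
  # uniform scores give uniform weights and the column means
  params$attn$Wa[] <- 0; params$attn$ba[] <- 0
  atu <- sequential_attention(h, params, cfg)
  expect_equal(atu$alpha, rep(1 / 4, 4))
  expect_equal(atu$alpha_h, colMeans(h))
  expect_error(sequential_attention(h, params, cfg, mask = rep(FALSE, 4)),
               "at least one real residue")
})

test_that("hard concatenation tiles alpha_h and is positionwise", {
  set.seed(10)
  c_feat <- matrix(rnorm(12), 4, 3)
  h <- matrix(rnorm(8), 4, 2)
  ah <- c(0.3, -0.7)
  v <- hard_concat(c_feat, h, ah)
  expect_equal(dim(v), c(4L, 7L))
  expect_equal(v[2, ], c(c_feat[2, ], h[2, ], ah))
  perm <- c(3, 1, 4, 2)
  expect_equal(hard_concat(c_feat[perm, ], h[perm, ], ah), v[perm, ])
  expect_equal(hard_concat(c_feat * 0, h * 0, ah * 0), matrix(0, 4, 7))
  expect_error(hard_concat(c_feat, h[1:3, ], ah), "length")
})

test_that("padding rows cannot influence predictions through the encoding", {
  # records differing only in masked-false channels assemble identically,
  # so every downstream stage is invariant to padding content
  onehot <- matrix(0, 5, 21); onehot[cbind(1:3, 1:3)] <- 1
  prof <- matrix(0.5, 5, 21)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  labs <- c("H", "E", "C", NA, NA)
  a <- protein_record("a", onehot, prof, labs, mask)
  onehot2 <- onehot; onehot2[4, 7] <- 1
  prof2 <- prof; prof2[5, ] <- 0.9
  b <- protein_record("b", onehot2, prof2, labs, mask)
  expect_equal(assemble_features(a), assemble_features(b))
})
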