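test_that("opinions from logits follow the evidence algebra", {
  # all evidence clipped: uniform expectation
  op <- opinion_from_logits(c(-1, -2, -3))
  expect_equal(as.numeric(op$alpha), c(1, 1, 1))
  expect_equal(as.numeric(op$p), rep(1 / 3, 3))
  expect_equal(op$strength, 3)
  expect_error(opinion_from_logits(c(1, NaN, 0)), "finite")
  # confident and unconfident worked examples (alpha via logits = alpha - 1)
  conf <- opinion_from_logits(c(13.10, 0.33, 0.21))
  expect_equal(as.numeric(conf$alpha), c(14.10, 1.33, 1.21))
  expect_equal(conf$strength, 16.64)
  expect_equal(as.numeric(conf$p), c(0.8474, 0.0799, 0.0727), tolerance = 1e-4)
  unconf <- opinion_from_logits(c(1.24, 0.82, 0.78))
  expect_equal(unconf$strength, 5.84)
  expect_equal(as.numeric(unconf$p), c(0.3836, 0.3116, 0.3048), tolerance = 1e-4)
  # the confident opinion has strictly lower entropy
  expect_equal(conf$entropy, 0.7689, tolerance = 1e-3)
  expect_equal(unconf$entropy, 1.5769, tolerance = 1e-3)
  expect_lt(conf$entropy, unconf$entropy)
})

test_that("opinion invariants hold over random logits", {
  set.seed(41)
  logits <- matrix(rnorm(400, sd = 3), 50, 8)
  op <- opinion_from_logits(logits)
  expect_true(all(op$alpha >= 1))
  expect_true(all(op$p > 0))
  expect_true(all(abs(rowSums(op$p) - 1) < 1e-10))
  expect_equal(op$strength, rowSums(op$alpha))
  expect_true(all(op$entropy >= 0 & op$entropy <= log2(8) + 1e-12))
})

test_that("information entropy has the right extremes and Schur concavity", {
  expect_equal(information_entropy(rep(1 / 3, 3)), log2(3))
  expect_equal(information_entropy(c(1, 0, 0)), 0)
  expect_error(information_entropy(c(-0.1, 0.6, 0.5)), "non-negative")
  # sharpening towards the mode never increases entropy
  set.seed(43)
  for (i in 1:20) {
    p <- rdirichlet1(rep(1, 5))
    k <- which.max(p)
    for (lam in c(0.2, 0.5, 0.8)) {
      e <- numeric(5); e[k] <- 1
      sharper <- (1 - lam) * p + lam * e
      expect_lte(information_entropy(sharper), information_entropy(p) + 1e-12)
    }
  }
})

test_that("the evidential loss matches hand values and is monotone", {
  expect_equal(dirichlet_loss(c(1, 0, 0), opinion_from_logits(c(-1, -1, -1))),
               5 / 6, tolerance = 1e-12)
  # perfect expectation with unbounded strength drives the loss to zero
  big <- opinion_from_logits(c(1e8, 0, 0))
  expect_lt(dirichlet_loss(c(1, 0, 0), big), 1e-6)
  # growing evidence on the true class strictly reduces the loss
  losses <- sapply(seq(0, 6, by = 0.5), function(a)
    dirichlet_loss(c(1, 0, 0), opinion_from_logits(c(a, 0.4, 0.2))))
  expect_true(all(diff(losses) < 0))
})

test_that("the evidential loss equals the Monte-Carlo Dirichlet Brier score", {
  set.seed(47)
  alpha <- c(2.5, 1.3, 1.7)
  y <- c(1, 0, 0)
  op <- opinion_from_logits(alpha - 1)
  expect_equal(as.numeric(op$alpha), alpha)
  n <- 1e5
  draws <- vapply(seq_len(n), function(i) sum((y - rdirichlet1(alpha))^2),
                  numeric(1))
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - dirichlet_loss(y, op)), 3 * se)
})

test_that("the Dirichlet density integrates to one on the 3-simplex", {
  alpha <- c(2, 3, 1.5)
  d <- 0.005
  grid <- seq(d / 2, 1 - d / 2, by = d)
  total <- 0
  for (p1 in grid) {
    p2 <- grid[grid < 1 - p1]
    if (!length(p2)) next
    total <- total + sum(vapply(p2, function(q)
      dirichlet_density(c(p1, q, 1 - p1 - q), alpha), numeric(1))) * d^2
  }
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("cross entropy matches hand evaluations", {
  expect_equal(cross_entropy(c(1, rep(0, 7)), rep(0, 8)), log(8))
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), log(1 + exp(-1)),
               tolerance = 1e-12)
  expect_lt(cross_entropy(c(1, 0), c(30, 0)), 1e-10)
})

test_that("routing follows the entropy-percentile rule", {
  # hand example: median threshold 0.65 admits the two confident correct
  logits <- rbind(c(6, 0, 0), c(4, 0.5, 0), c(1.2, 1.0, 0.8), c(0.2, 0.1, 0))
  op <- opinion_from_logits(logits)
  op$entropy <- c(0.2, 0.4, 0.9, 1.4)     # fix entropies for the hand case
  dec <- route_samples(op, labels = c(1, 1, 2, 1),
                       config = routing_config(per = 50), phase = "train")
  expect_equal(as.character(dec$assignment), c("easy", "easy", "hard", "hard"))
  expect_equal(dec$threshold_value, 0.65)
  # the zeroth percentile leaves the strict inequality empty: all hard
  dec0 <- route_samples(op, labels = c(1, 1, 2, 1),
                        config = routing_config(per = 0), phase = "train")
  expect_true(all(dec0$assignment == "hard"))
  # label mode: correctness alone decides
  decl <- route_samples(op, labels = c(1, 1, 1, 1),
                        config = routing_config(mode = "label"), phase = "train")
  expect_true(all(decl$assignment == "easy"))
  # routing is a partition of the residues
  expect_true(all(dec$assignment %in% c("easy", "hard")))
  expect_length(dec$assignment, 4)
  # labels are mandatory at training time
  expect_error(route_samples(op, config = routing_config(), phase = "train"),
               "labels")
  # test-time evidential routing uses only the frozen threshold
  dect <- route_samples(op, config = routing_config(), phase = "test",
                        threshold = 1.0)
  expect_equal(as.character(dect$assignment), c("easy", "easy", "easy", "hard"))
  expect_error(route_samples(op, config = routing_config(), phase = "test"),
               "threshold")
})

test_that("confidence routing exits confidently-correct residues early", {
  logits <- rbind(c(8, 0, 0), c(0.5, 0.4, 0.3))
  op <- opinion_from_logits(logits)
  cfgc <- routing_config(mode = "confidence", confidence_threshold = 0.9)
  dec <- route_samples(op, labels = c(1, 1), config = cfgc, phase = "train")
  expect_equal(as.character(dec$assignment), c("easy", "hard"))
  # at test time confidence alone decides
  dect <- route_samples(op, config = cfgc, phase = "test")
  expect_equal(as.character(dect$assignment), c("easy", "hard"))
})

test_that("the combined loss accumulates the four components", {
  lb <- total_loss(1.0, 0.5, 2.0, 0.25, beta = 1)
  expect_equal(lb$total, 3.75)
  expect_equal(total_loss(1.0, 0.5, 2.0, 0.25, beta = 0)$total, 3.0)
  expect_equal(total_loss(0.8, 0.3)$total, 0.8 + 0.3)
  # a hard-routed residue can only gain loss relative to easy-only
  set.seed(53)
  for (i in 1:10) {
    el <- rnorm(3); hl <- rnorm(3)
    y <- c(1, 0, 0)
    easy_only <- cross_entropy(y, el) + dirichlet_loss(y, opinion_from_logits(el))
    with_hard <- easy_only + cross_entropy(y, hl) +
      dirichlet_loss(y, opinion_from_logits(hl))
    expect_gte(with_hard, easy_only)
  }
})
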