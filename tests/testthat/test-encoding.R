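test_that("profile score and probability transforms are mutual inverses", {
  set.seed(7)
  bg <- background_frequencies()
  for (i in 1:50) {
    l <- runif(1, 1e-4, 1 - 1e-4)
    p <- bg[sample(20, 1)]
    s <- profile_score_from_prob(l, p)
    expect_equal(unname(profile_prob_from_score(s, p)), l, tolerance = 1e-10)
  }
  # zero score recovers the background itself
  expect_equal(profile_prob_from_score(0, 0.05), 0.05)
  # all-zero scores with uniform background give the uniform vector
  cfg <- encoding_config(background_probs = rep(1 / 20, 20))
  expect_equal(profile_probs_from_scores(rep(0, 20), cfg), rep(1 / 20, 20))
  expect_error(profile_prob_from_score(Inf, 0.05), "finite")
})

test_that("conservation score has the right extremes and symmetry", {
  expect_equal(conservation_score(rep(1 / 20, 20)), 0)
  expect_equal(conservation_score(c(1, rep(0, 19))), log(20))
  expect_equal(conservation_score(c(0.5, 0.5, rep(0, 18))),
               log(20) - log(2), tolerance = 1e-12)
  set.seed(3)
  p <- rdirichlet1(rep(0.5, 20))
  expect_equal(conservation_score(p), conservation_score(sample(p)))
  expect_gte(conservation_score(p), 0)
  expect_lte(conservation_score(p), log(20))
  expect_error(conservation_score(c(-0.1, rep(1.1 / 19, 19))), "non-negative")
})

test_that("Q8 to Q3 mapping is total, surjective, and coarsens correctness", {
  expect_equal(map_q8_to_q3(c("C", "B", "E", "G", "I", "H", "S", "T")),
               c("C", "E", "E", "H", "H", "H", "C", "C"))
  expect_setequal(unique(map_q8_to_q3(c("C", "B", "E", "G", "I", "H", "S", "T"))),
                  c("H", "E", "C"))
  expect_error(map_q8_to_q3("Z"), "unknown Q8 state")
  # a Q8 confusion within a coarse class is correct at Q3
  expect_equal(map_q8_to_q3("G"), map_q8_to_q3("H"))
  expect_equal(map_q8_to_q3("B"), map_q8_to_q3("E"))
  expect_false(map_q8_to_q3("G") == map_q8_to_q3("T"))
})

test_that("packed-array write/read round-trips generated records", {
  spec <- synthetic_spec(n_proteins = 3, length_range = c(10, 20), seed = 21)
  recs <- generate_proteins(spec)
  f <- tempfile(fileext = ".npy")
  write_fixture(recs, f)
  back <- read_cullpdb_arrays(f)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$residue_onehot, recs[[i]]$residue_onehot)
    expect_equal(back[[i]]$profile_logistic, recs[[i]]$profile_logistic)
    expect_identical(back[[i]]$q8_labels, recs[[i]]$q8_labels)
    expect_identical(back[[i]]$mask, recs[[i]]$mask)
    expect_identical(attr(back[[i]], "hard"), attr(recs[[i]], "hard"))
    expect_equal(back[[i]]$conservation, recs[[i]]$conservation)
  }
  unlink(f)
})

test_that("reader enforces the packed layout and label integrity", {
  f <- tempfile(fileext = ".npy")
  write_npy_matrix(matrix(0, 2, 100), f)
  expect_error(read_cullpdb_arrays(f), "39900")
  # a real residue whose label channels are all zero is a data error
  row <- numeric(700 * 57)
  slot1 <- numeric(57)
  slot1[1] <- 1                        # residue A one-hot, no label set
  slot1[36:56] <- 0.5                  # profile
  row[1:57] <- slot1
  pad <- numeric(57); pad[22] <- 1; pad[31] <- 1
  for (k in 2:700) row[((k - 1) * 57 + 1):(k * 57)] <- pad
  write_npy_matrix(matrix(row, 1, byrow = TRUE), f)
  expect_error(read_cullpdb_arrays(f), "data-integrity")
  unlink(f)
})

test_that("assembled features have the 50-dim layout with zero padding", {
  spec <- synthetic_spec(n_proteins = 1, length_range = c(12, 12), seed = 4)
  rec <- generate_proteins(spec)[[1]]
  x <- assemble_features(rec)
  expect_equal(dim(x), c(12L, 50L))
  expect_equal(x[, 1:21], rec$residue_onehot)
  expect_equal(x[, 22:42], rec$profile_logistic)
  expect_equal(x[, 50], rec$conservation)
  # all-padding protein: all-zero matrix
  pad <- protein_record("pad", matrix(0, 4, 21), matrix(0, 4, 21),
                        rep(NA_character_, 4), mask = rep(FALSE, 4))
  expect_equal(assemble_features(pad), matrix(0, 4, 50))
  # a profile that inverts to the uniform aligned-residue distribution
  # has conservation exactly zero
  bg <- background_frequencies()
  scores <- profile_score_from_prob(rep(1 / 20, 20), bg)
  prof <- matrix(0.5, 1, 21)
  prof[1, which(c(strsplit("ACDEFGHIKLMNPQRSTVWXY", "")[[1]]) != "X")] <- plogis(scores)
  uni <- protein_record("uni", matrix(c(1, rep(0, 20)), 1), prof, "H", TRUE)
  expect_equal(assemble_features(uni)[1, 50], 0, tolerance = 1e-10)
})

test_that("dataset statistics count proteins, labels and frequencies", {
  r1 <- protein_record("a", matrix(rep(c(1, rep(0, 20)), 3), 3, byrow = TRUE),
                       matrix(0.5, 3, 21), c("H", "H", "E"), rep(TRUE, 3))
  r2 <- protein_record("b", matrix(c(1, rep(0, 20)), 1), matrix(0.5, 1, 21),
                       "E", TRUE)
  st <- dataset_statistics(list(r1, r2))
  expect_equal(st$n_proteins, 2L)
  expect_equal(st$n_labels, 4L)
  expect_equal(st$counts[["H"]], 2L)
  expect_equal(st$counts[["E"]], 2L)
  expect_equal(st$frequency[["H"]], 50)
  expect_equal(st$frequency[["E"]], 50)
  expect_error(dataset_statistics(list()), "no records")
  lines <- format_stats_tsv(st)
  expect_match(lines[3], "Label\tTypes\tFrequency")
})
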