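# Shared helpers: a small extractor geometry for fast tests and a
# batch builder matching the training loop's internal format.

tiny_extractor <- function(dropout = 0) {
  extractor_config(branch_hidden = c(3L, 4L, 2L, 2L), conv_hidden = 3L,
                   conv_kernels = c(3L, 5L), recurrent_hidden = 4L,
                   attention_hidden = 3L, mlp_hidden = c(5L, 6L),
                   dropout = dropout)
}

small_extractor <- function(dropout = 0.1) {
  extractor_config(branch_hidden = c(12L, 16L, 6L, 4L), conv_hidden = 12L,
                   conv_kernels = c(5L, 9L, 13L), recurrent_hidden = 16L,
                   attention_hidden = 12L, mlp_hidden = c(32L, 32L),
                   dropout = dropout)
}

records_to_batch <- function(records, levels) {
  lapply(records, function(r) {
    labs <- r$q8_labels
    if (identical(levels, c("H", "E", "C"))) labs <- map_q8_to_q3(labs)
    list(x = assemble_features(r), mask = r$mask,
         y = match(labs[r$mask], levels))
  })
}

# draw one Dirichlet sample via gamma normalisation
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}
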