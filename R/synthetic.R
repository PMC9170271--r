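# Seeded generator of protein-like records with planted easy and hard
# residues.  Class signal lives in the profile-score space (plus a mild
# residue-identity preference), so generated records are valid packed
# records: one-hot rows sum to 1, profile entries lie in (0,1), and
# fixtures round-trip exactly through the packed-array writer/reader.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic dataset specification
#'
#' Describes a seeded synthetic dataset: protein count and length range,
#' class set, the fraction of easy residues, the feature-space distance
#' between class centroids for hard residues, and label noise.  Easy
#' residues draw profile scores from well-separated class-conditional
#' Gaussians (centroid separation 6 noise-SD units); hard residues from
#' centroids shrunk so their pairwise distance is `hard_overlap`.
#' Per-state run lengths follow a short-memory Markov process whose
#' stationary distribution matches `frequencies`, so sequence context
#' carries real information about ambiguous residues.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer pair, inclusive residue-count range.
#' @param class_set `"Q8"` or `"Q3"`.
#' @param easy_fraction Fraction of residues planted easy, in \[0,1\].
#' @param hard_overlap Pairwise distance (noise-SD units) between class
#'   centroids for hard residues; 0 = fully overlapping.
#' @param label_noise Probability that an emitted label is replaced by a
#'   uniform draw over the class set (1 = labels independent of
#'   features).
#' @param seed Integer seed; generation is byte-reproducible given it.
#' @param class_states Optional subset of states to restrict the class
#'   set (uniform frequencies unless `frequencies` is given).
#' @param frequencies Optional named stationary label frequencies
#'   (percent or proportions; normalised internally).  Defaults to the
#'   benchmark Q8 frequencies, or the benchmark Q3 marginals for
#'   `class_set = "Q3"`.
#' @param stay_prob Self-transition probability of the label process.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 50L, length_range = c(90L, 110L),
                           class_set = c("Q8", "Q3"), easy_fraction = 0.7,
                           hard_overlap = 1.5, label_noise = 0, seed = 1L,
                           class_states = NULL, frequencies = NULL,
                           stay_prob = 0.75) {
  class_set <- match.arg(class_set)
  if (length_range[1] > length_range[2]) stop("length_range is inverted")
  stopifnot(n_proteins >= 1L, length_range[1] >= 1L,
            length_range[2] <= MAX_LEN,
            easy_fraction >= 0, easy_fraction <= 1,
            hard_overlap >= 0, label_noise >= 0, label_noise <= 1,
            stay_prob >= 0, stay_prob < 1)
  states <- if (!is.null(class_states)) class_states
            else if (class_set == "Q8") Q8_STATES else Q3_STATES
  if (!all(states %in% Q8_STATES)) stop("class states must be Q8 states")
  if (is.null(frequencies)) {
    frequencies <- if (!is.null(class_states)) {
      stats::setNames(rep(1, length(states)), states)
    } else if (class_set == "Q8") {
      cb513_q8_frequencies()
    } else {
      c(H = 34.59, E = 22.65, C = 42.76)  # benchmark Q3 marginals
    }
  }
  if (!all(states %in% names(frequencies))) stop("frequencies must cover every state")
  freq <- frequencies[states] / sum(frequencies[states])
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 class_set = class_set, states = states, freq = freq,
                 easy_fraction = easy_fraction, hard_overlap = hard_overlap,
                 label_noise = label_noise, seed = as.integer(seed),
                 stay_prob = stay_prob),
            class = "synthetic_spec")
}

# orthonormal centroid directions in the 20-dim profile-score space
centroid_directions <- function(k) {
  if (k > 10L) stop("at most 10 classes supported by the centroid scheme")
  u <- matrix(0, nrow = k, ncol = 20L)
  for (i in seq_len(k)) {
    u[i, 2L * i - 1L] <- 1 / sqrt(2)
    u[i, 2L * i] <- -1 / sqrt(2)
  }
  u
}

#' Generate synthetic protein records
#'
#' Draws `spec$n_proteins` records under `spec$seed`.  Ground-truth
#' planted-hard flags are attached as the `"hard"` attribute of each
#' record, and noise-free labels as the `"clean_labels"` attribute.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [protein_record()] objects.
#' @export
generate_proteins <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    k <- length(spec$states)
    u <- centroid_directions(k)
    mu_easy <- 6 * u                                   # pairwise distance 6*sqrt(2)
    mu_hard <- (spec$hard_overlap / sqrt(2)) * u       # pairwise distance = hard_overlap
    std <- which(AA_ORDER != "X")
    # mild class-conditional residue-identity preference for easy residues
    pref <- lapply(seq_len(k), function(i) {
      w <- rep(0.6 / 20, 20)
      w[((i - 1L) %% 20L) + 1L] <- w[((i - 1L) %% 20L) + 1L] + 0.4
      w
    })
    records <- vector("list", spec$n_proteins)
    for (pi in seq_len(spec$n_proteins)) {
      len <- spec$length_range[1] +
        sample.int(spec$length_range[2] - spec$length_range[1] + 1L, 1L) - 1L
      # short-memory label chain with stationary distribution spec$freq
      lab_idx <- integer(len)
      lab_idx[1] <- sample.int(k, 1L, prob = spec$freq)
      if (len > 1L) for (t in 2:len) {
        lab_idx[t] <- if (stats::runif(1) < spec$stay_prob) lab_idx[t - 1L]
                      else sample.int(k, 1L, prob = spec$freq)
      }
      hard <- stats::runif(len) >= spec$easy_fraction
      onehot <- matrix(0, len, 21L)
      profile <- matrix(0, len, 21L)
      for (t in seq_len(len)) {
        cl <- lab_idx[t]
        res <- if (hard[t]) sample(std, 1L) else sample(std, 1L, prob = pref[[cl]])
        onehot[t, res] <- 1
        mu <- if (hard[t]) mu_hard[cl, ] else mu_easy[cl, ]
        profile[t, std] <- stats::plogis(mu + stats::rnorm(20L))
        profile[t, AA_ORDER == "X"] <- stats::plogis(-4 + 0.1 * stats::rnorm(1))
      }
      clean <- spec$states[lab_idx]
      labels <- clean
      if (spec$label_noise > 0) {
        flip <- stats::runif(len) < spec$label_noise
        labels[flip] <- spec$states[sample.int(k, sum(flip), replace = TRUE)]
      }
      rec <- protein_record(
        id = sprintf("SYN%04d", pi),
        residue_onehot = onehot,
        profile_logistic = profile,
        q8_labels = labels,
        mask = rep(TRUE, len),
        hard = hard
      )
      attr(rec, "clean_labels") <- clean
      records[[pi]] <- rec
    }
    records
  })
}

#' Write synthetic records as a packed fixture
#'
#' Serialises records to the 57-channel packed layout read by
#' [read_cullpdb_arrays()]; planted-hard flags occupy an otherwise
#' unused channel so generate/write/read round-trips preserve them.
#'
#' @param records Non-empty list of [protein_record()] objects.
#' @param path Output `.npy` (optionally `.gz`) path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(records, path) {
  write_cullpdb_arrays(records, path)
}
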