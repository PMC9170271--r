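# Reading the packed benchmark arrays and building the 50-dimensional
# per-residue feature encoding: 21 one-hot + 21 profile + 7
# physicochemical + 1 conservation.

#' Encoding configuration
#'
#' Parameters of the profile-probability recovery used for the
#' conservation score: substitution scores are recovered from the
#' logistic-rescaled profile channels, converted to aligned-residue
#' probabilities `L_i = exp(S_i * lambda_u) * P_i` against a background
#' vector `P_i`, renormalised onto the simplex, and summarised as
#' `R = log 20 + sum L_i log L_i` (natural log, range `[0, log 20]`).
#'
#' @param lambda_u Scaling constant of the score/probability transform.
#' @param background_probs Background amino-acid frequencies: positive
#'   20-vector summing to 1 (standard residues, no `X`).
#' @param logistic_rescale Whether profile channels are stored
#'   logistic-rescaled (the benchmark convention) and must be inverted
#'   before score recovery.
#' @return Object of class `encoding_config`.
#' @export
encoding_config <- function(lambda_u = 0.3176,
                            background_probs = background_frequencies(),
                            logistic_rescale = TRUE) {
  stopifnot(is.numeric(lambda_u), length(lambda_u) == 1L, is.finite(lambda_u))
  if (length(background_probs) != 20L || any(background_probs <= 0)) {
    stop("background_probs must be a positive 20-vector")
  }
  if (abs(sum(background_probs) - 1) > 1e-8) {
    stop("background_probs must sum to 1")
  }
  structure(list(lambda_u = lambda_u,
                 background_probs = background_probs,
                 logistic_rescale = isTRUE(logistic_rescale)),
            class = "encoding_config")
}

#' Recover an aligned-residue probability from a substitution score
#'
#' Inverts the profile score transform: `L = exp(score * lambda_u) * P`.
#'
#' @param score Substitution score(s); must be finite.
#' @param background_prob Background probability `P` in (0,1).
#' @param lambda_u Scaling constant.
#' @return Probability (unnormalised when applied channel-wise; see
#'   [profile_probs_from_scores()] for the simplex-renormalised form).
#' @export
#' @examples
#' profile_prob_from_score(0, 0.05)  # 0.05
profile_prob_from_score <- function(score, background_prob, lambda_u = 0.3176) {
  if (any(!is.finite(score))) stop("score must be finite")
  stopifnot(all(background_prob > 0), all(background_prob < 1))
  exp(score * lambda_u) * background_prob
}

#' Substitution score from an aligned-residue probability
#'
#' The forward transform `S = log(L / P) / lambda_u`; exact inverse of
#' [profile_prob_from_score()].
#'
#' @inheritParams profile_prob_from_score
#' @param prob Probability in (0,1).
#' @return Score.
#' @export
profile_score_from_prob <- function(prob, background_prob, lambda_u = 0.3176) {
  stopifnot(all(prob > 0), all(prob < 1))
  log(prob / background_prob) / lambda_u
}

#' Recover a 20-vector of aligned-residue probabilities
#'
#' Applies [profile_prob_from_score()] channel-wise and renormalises the
#' recovered values onto the simplex, as required by the conservation
#' score.
#'
#' @param scores Numeric 20-vector of substitution scores.
#' @param config An [encoding_config()].
#' @return 20-vector on the simplex.
#' @export
profile_probs_from_scores <- function(scores, config = encoding_config()) {
  stopifnot(length(scores) == length(config$background_probs))
  l <- profile_prob_from_score(scores, config$background_probs, config$lambda_u)
  l / sum(l)
}

#' Conservation score of a residue column
#'
#' `R = log 20 + sum_i L_i log L_i` over a 20-vector of aligned-residue
#' probabilities (natural logarithm, `0 log 0 = 0`).  Zero for the
#' uniform column, `log 20` for a perfectly conserved (one-hot) column.
#'
#' @param probs Numeric 20-vector on the simplex.
#' @return Conservation score in nats, in `[0, log 20]`.
#' @export
#' @examples
#' conservation_score(rep(1 / 20, 20))  # 0
conservation_score <- function(probs) {
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (length(probs) != 20L) stop("expected a 20-vector")
  if (abs(sum(probs) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- probs > 0
  log(20) + sum(probs[nz] * log(probs[nz]))
}

# conservation for each masked-true row of a length x 21 logistic profile
conservation_from_profile <- function(profile21, mask, config = encoding_config()) {
  n <- nrow(profile21)
  out <- numeric(n)
  if (n == 0L) return(out)
  std <- which(AA_ORDER != "X")  # 20 standard-residue channels
  p <- profile21[, std, drop = FALSE]
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  scores <- if (config$logistic_rescale) log(p / (1 - p)) else p
  for (i in which(mask)) {
    l <- profile_probs_from_scores(scores[i, ], config)
    out[i] <- conservation_score(l)
  }
  out
}

#' Map an eight-state label to its three-state class
#'
#' DSSP eight-state to three-state coarsening: (B, E) -> E;
#' (G, I, H) -> H; (S, T, C) -> C.
#'
#' @param q8_label Character vector over \{C,B,E,G,I,H,S,T\}.
#' @return Character vector over \{H,E,C\}.
#' @export
#' @examples
#' map_q8_to_q3(c("B", "I", "T"))  # "E" "H" "C"
map_q8_to_q3 <- function(q8_label) {
  map <- c(C = "C", B = "E", E = "E", G = "H", I = "H",
           H = "H", S = "C", T = "C")
  bad <- !(q8_label %in% names(map))
  if (any(bad)) stop("unknown Q8 state: ", paste(unique(q8_label[bad]), collapse = ", "))
  unname(map[q8_label])
}

#' Construct a protein record
#'
#' One protein of the benchmark encoding: residue identities as 21-dim
#' one-hot, logistic-rescaled 21-dim profile, Q8 labels and a validity
#' mask (`TRUE` = real residue, `FALSE` = padding).  The conservation
#' column is derived from the profile at construction.
#'
#' @param id Protein identifier.
#' @param residue_onehot length x 21 binary matrix.
#' @param profile_logistic length x 21 matrix with entries in (0,1) on
#'   masked-true rows.
#' @param q8_labels Character vector of Q8 states (only masked-true
#'   entries are meaningful).
#' @param mask Logical validity vector.
#' @param config [encoding_config()] for the conservation pipeline.
#' @param hard Optional logical vector of planted-hard flags (synthetic
#'   data ground truth), kept as an attribute.
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(id, residue_onehot, profile_logistic, q8_labels,
                           mask, config = encoding_config(), hard = NULL) {
  n <- length(mask)
  stopifnot(nrow(residue_onehot) == n, ncol(residue_onehot) == 21L,
            nrow(profile_logistic) == n, ncol(profile_logistic) == 21L,
            length(q8_labels) == n)
  if (n > MAX_LEN) stop("protein longer than ", MAX_LEN, " residues")
  if (any(mask)) {
    s <- rowSums(residue_onehot[mask, , drop = FALSE])
    if (any(abs(s - 1) > 1e-8)) stop("one-hot rows must sum to 1 on real residues")
    pm <- profile_logistic[mask, , drop = FALSE]
    if (any(pm <= 0 | pm >= 1)) stop("profile entries must lie strictly in (0,1)")
    lm <- q8_labels[mask]
    if (any(!is.na(lm) & !lm %in% Q8_STATES)) stop("invalid Q8 label on a real residue")
  }
  rec <- list(
    id = as.character(id),
    length = n,
    residue_onehot = residue_onehot,
    profile_logistic = profile_logistic,
    q8_labels = q8_labels,
    mask = as.logical(mask),
    conservation = conservation_from_profile(profile_logistic, mask, config)
  )
  if (!is.null(hard)) attr(rec, "hard") <- as.logical(hard)
  structure(rec, class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record %s: %d slots, %d real residues>\n",
              x$id, x$length, sum(x$mask)))
  invisible(x)
}

# unpack one 39900-vector into a 700 x 57 slot matrix
unpack_row <- function(row) matrix(row, nrow = MAX_LEN, ncol = SLOT_WIDTH, byrow = TRUE)

#' Read packed benchmark arrays
#'
#' Reads a CullPDB-style packed dense array (`N x 39900`: 700 residue
#' slots of 57 channels per protein) into protein records.  Slots whose
#' one-hot block is the NoSeq channel (or all zero) become padding;
#' trailing padding is trimmed.  The 22-channel one-hot and profile
#' blocks are reduced to 21 dimensions by dropping the NoSeq channel.
#'
#' @param path `.npy` (optionally `.gz`) file of shape N x 39900.
#' @param limit Optional maximum number of proteins to read.
#' @param config [encoding_config()] for the conservation pipeline.
#' @return List of [protein_record()] objects.
#' @export
read_cullpdb_arrays <- function(path, limit = NULL, config = encoding_config()) {
  mat <- read_npy_matrix(path)
  if (ncol(mat) != ROW_WIDTH) {
    stop("packed array must have ", ROW_WIDTH,
         " columns (700 slots x 57 channels); got ", ncol(mat))
  }
  n <- nrow(mat)
  if (!is.null(limit)) n <- min(n, as.integer(limit))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    slot <- unpack_row(mat[i, ])
    onehot22 <- slot[, CHAN$onehot, drop = FALSE]
    labels9 <- slot[, CHAN$labels, drop = FALSE]
    profile22 <- slot[, CHAN$profile, drop = FALSE]
    noseq <- onehot22[, 22] >= 0.5 | rowSums(abs(slot)) == 0
    mask <- !noseq
    len <- if (any(mask)) max(which(mask)) else 0L
    keep <- seq_len(len)
    mask <- mask[keep]
    lab8 <- labels9[keep, 1:8, drop = FALSE]
    if (any(mask & rowSums(lab8) == 0)) {
      stop("data-integrity error in protein ", i,
           ": real residue with all-zero label channels")
    }
    labs <- rep(NA_character_, len)
    if (any(mask)) labs[mask] <- Q8_STATES[max.col(lab8[mask, , drop = FALSE], ties.method = "first")]
    records[[i]] <- protein_record(
      id = sprintf("P%05d", i),
      residue_onehot = onehot22[keep, 1:21, drop = FALSE],
      profile_logistic = profile22[keep, 1:21, drop = FALSE],
      q8_labels = labs,
      mask = mask,
      config = config
    )
    hard <- slot[keep, CHAN$solvacc[1]]  # hard flags of synthetic fixtures
    if (any(hard > 0)) attr(records[[i]], "hard") <- hard >= 0.5
  }
  records
}

#' Write protein records as a packed benchmark array
#'
#' Serialises records to the same `N x 39900` packed layout read by
#' [read_cullpdb_arrays()]: one-hot + NoSeq, label one-hot + NoSeq,
#' terminal and solvent channels (zero except planted-hard flags, which
#' occupy the first solvent channel in synthetic fixtures), and the
#' logistic profile + NoSeq.  Round-trips exactly through the reader.
#'
#' @param records List of [protein_record()] objects.
#' @param path Output `.npy` (optionally `.gz`) path.
#' @return `path`, invisibly.
#' @export
write_cullpdb_arrays <- function(records, path) {
  if (length(records) == 0L) stop("no records to write")
  out <- matrix(0, nrow = length(records), ncol = ROW_WIDTH)
  for (i in seq_along(records)) {
    r <- records[[i]]
    slot <- matrix(0, nrow = MAX_LEN, ncol = SLOT_WIDTH)
    slot[, CHAN$onehot[22]] <- 1   # NoSeq one-hot everywhere...
    slot[, CHAN$labels[9]] <- 1    # ...and NoSeq label, overwritten below
    if (r$length > 0L) {
      rows <- seq_len(r$length)
      m <- r$mask
      slot[rows[m], CHAN$onehot[22]] <- 0
      slot[rows[m], CHAN$labels[9]] <- 0
      slot[rows, CHAN$onehot[1:21]] <- r$residue_onehot
      slot[rows, CHAN$profile[1:21]] <- r$profile_logistic
      lab_idx <- match(r$q8_labels[m], Q8_STATES)
      ok <- !is.na(lab_idx)
      slot[cbind(rows[m][ok], CHAN$labels[lab_idx[ok]])] <- 1
      hard <- attr(r, "hard")
      if (!is.null(hard)) slot[rows[m][hard[m]], CHAN$solvacc[1]] <- 1
    }
    out[i, ] <- as.numeric(t(slot))
  }
  write_npy_matrix(out, path)
}

#' Assemble the 50-dimensional feature matrix
#'
#' Concatenates, per residue, the 21-dim one-hot, the 21-dim logistic
#' profile, the 7 physicochemical properties of the residue identity and
#' the 1-dim conservation score, in that order.  Padding rows are all
#' zero.
#'
#' @param record A [protein_record()].
#' @param physchem 21 x 7 lookup table with rownames covering the
#'   record's residue symbols (default [physchem_table()]).
#' @param config [encoding_config()]; used only if the record lacks a
#'   stored conservation column.
#' @return length x 50 numeric matrix.
#' @export
assemble_features <- function(record, physchem = physchem_table(),
                              config = encoding_config()) {
  n <- record$length
  feat <- matrix(0, nrow = n, ncol = 50L)
  if (n == 0L || !any(record$mask)) return(feat)
  m <- record$mask
  res_idx <- max.col(record$residue_onehot[m, , drop = FALSE], ties.method = "first")
  res_sym <- AA_ORDER[res_idx]
  missing <- !res_sym %in% rownames(physchem)
  if (any(missing)) stop("physicochemical table lacks a row for residue ",
                         paste(unique(res_sym[missing]), collapse = ", "))
  cons <- record$conservation
  if (is.null(cons)) cons <- conservation_from_profile(record$profile_logistic, m, config)
  feat[m, 1:21] <- record$residue_onehot[m, , drop = FALSE]
  feat[m, 22:42] <- record$profile_logistic[m, , drop = FALSE]
  feat[m, 43:49] <- physchem[res_sym, , drop = FALSE]
  feat[m, 50] <- cons[m]
  feat
}

#' Dataset label statistics
#'
#' Counts proteins and real residues and tabulates per-state Q8 label
#' frequencies in percent.
#'
#' @param records Non-empty list of [protein_record()] objects.
#' @return Object of class `ss_dataset_stats`: a list with `n_proteins`,
#'   `n_labels`, `counts` and `frequency` (percent), both named by Q8
#'   state.
#' @export
dataset_statistics <- function(records) {
  if (length(records) == 0L) stop("no records: cannot compute statistics")
  labs <- unlist(lapply(records, function(r) r$q8_labels[r$mask]))
  counts <- table(factor(labs, levels = Q8_STATES))
  n <- sum(counts)
  structure(list(
    n_proteins = length(records),
    n_labels = as.integer(n),
    counts = as.integer(counts) |> stats::setNames(Q8_STATES),
    frequency = round(100 * as.integer(counts) / n, 2) |> stats::setNames(Q8_STATES)
  ), class = "ss_dataset_stats")
}

Q8_TYPE_NAMES <- c(H = "Alpha-helix", E = "Beta-strand", C = "Coil",
                   T = "Beta-turn", S = "Bend", G = "3-10-helix",
                   B = "Beta-bridge", I = "Pi-helix")

#' Format dataset statistics as a tab-separated report
#'
#' Renders the label / type / frequency table (states ordered by
#' descending frequency) as tab-separated text.
#'
#' @param stats An `ss_dataset_stats` object.
#' @return Character vector of report lines.
#' @export
format_stats_tsv <- function(stats) {
  ord <- order(stats$frequency, decreasing = TRUE)
  states <- names(stats$frequency)[ord]
  c(sprintf("Proteins\t%d", stats$n_proteins),
    sprintf("Labels\t%d", stats$n_labels),
    "Label\tTypes\tFrequency",
    sprintf("%s\t%s\t%.2f", states, Q8_TYPE_NAMES[states], stats$frequency[ord]))
}

#' @export
print.ss_dataset_stats <- function(x, ...) {
  cat(format_stats_tsv(x), sep = "\n")
  invisible(x)
}
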