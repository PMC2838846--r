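# Bit-score computation against profile HMMs.
#
# All scores are log2 odds of the model versus the null model ("bits").
# The dynamic programming runs in log space in compiled code; sequences of
# tens of thousands of residues stay finite.

# precompute the log2-odds tables used by the compiled kernels; column 21 is
# the X wildcard, which emits with null-model probability (zero log-odds)
phmm_logodds <- function(hmm) {
  null <- hmm$null_model
  lM <- log2(sweep(hmm$match_emissions, 2, null, "/"))
  lI <- log2(sweep(hmm$insert_emissions, 2, null, "/"))
  lM <- cbind(lM, 0)
  lI <- cbind(lI, 0)
  lt <- log2(hmm$transitions)
  list(lM = lM, lI = lI, lt = lt)
}

score_one <- function(tables, idx, local, forward) {
  .cpp_phmm_score(tables$lM, tables$lI, tables$lt, idx,
                  local = local, forward = forward)
}

resolve_mode <- function(hmm, mode) {
  if (is.null(mode)) hmm$alignment_mode
  else match.arg(mode, c("local", "glocal"))
}

as_sequences <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be character or an AAStringSet")
  if (any(!nzchar(x))) stop("empty sequence")
  x
}

#' Viterbi bit score of a sequence against a profile HMM
#'
#' Maximum over state paths of `log2(P(seq, path | model) / P(seq | null))`,
#' computed by dynamic programming in log space. In local mode (the default
#' for database searching) the model hit may cover any subsequence; flanking
#' residues are scored by the null model and contribute zero bits, and each
#' match-state fragment carries the uniform entry/exit probability
#' `2 / (L (L + 1))`.
#'
#' @param hmm A `profile_hmm`.
#' @param seq A single protein sequence (character) or an `AAStringSet` /
#'   character vector, in which case one score per sequence is returned.
#' @param mode `"local"` or `"glocal"`; defaults to the model's stored mode.
#' @return Numeric vector of bit scores.
#' @export
viterbi_bit_score <- function(hmm, seq, mode = NULL) {
  validate_profile_hmm(hmm)
  mode <- resolve_mode(hmm, mode)
  seqs <- as_sequences(seq)
  tables <- phmm_logodds(hmm)
  vapply(seqs, function(s)
    score_one(tables, encode_residues(s), local = (mode == "local"),
              forward = FALSE), numeric(1), USE.NAMES = !is.null(names(seqs)))
}

#' Forward bit score of a sequence against a profile HMM
#'
#' As [viterbi_bit_score()] but summing over all state paths
#' (log-sum-exp); always greater than or equal to the Viterbi score.
#' Classification uses the Viterbi score by default; the forward score is
#' provided for parity with HMMER-style searching.
#'
#' @inheritParams viterbi_bit_score
#' @return Numeric vector of bit scores.
#' @export
forward_bit_score <- function(hmm, seq, mode = NULL) {
  validate_profile_hmm(hmm)
  mode <- resolve_mode(hmm, mode)
  seqs <- as_sequences(seq)
  tables <- phmm_logodds(hmm)
  vapply(seqs, function(s)
    score_one(tables, encode_residues(s), local = (mode == "local"),
              forward = TRUE), numeric(1), USE.NAMES = !is.null(names(seqs)))
}

# local Viterbi with hit envelope; returns data.frame(score, start, end)
viterbi_local_hit <- function(hmm, seq) {
  tables <- phmm_logodds(hmm)
  seqs <- as_sequences(seq)
  res <- t(vapply(seqs, function(s)
    .cpp_phmm_local_hit(tables$lM, tables$lI, tables$lt, encode_residues(s)),
    numeric(3)))
  data.frame(score = res[, 1], start = as.integer(res[, 2]),
             end = as.integer(res[, 3]), row.names = NULL)
}

# score a set of sequences against every model in a library; returns a
# sequences x models matrix of local Viterbi bit scores
score_matrix <- function(seqs, models, mode = "local", algorithm = "viterbi") {
  seqs <- as_sequences(seqs)
  idx <- lapply(seqs, encode_residues)
  out <- matrix(NA_real_, length(seqs), length(models),
                dimnames = list(names(seqs),
                                vapply(models, `[[`, character(1), "name")))
  fwd <- identical(algorithm, "forward")
  for (j in seq_along(models)) {
    tables <- phmm_logodds(models[[j]])
    out[, j] <- vapply(idx, function(i)
      score_one(tables, i, local = (mode == "local"), forward = fwd),
      numeric(1))
  }
  out
}
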