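# Profile hidden Markov models: construction, validation, file formats.
#
# A `profile_hmm` is a plain list with class "profile_hmm":
#   name              model name (unique within a library)
#   group             kinase group or domain-type name (may be NA)
#   L                 number of match states
#   match_emissions   L x 20 matrix, rows sum to 1 (columns = AA20)
#   insert_emissions  (L+1) x 20 matrix for insert states I_0..I_L
#   transitions       (L+1) x 7 matrix, columns MM MI MD IM II DM DD; row r
#                     (1-based r = k+1) holds the transitions out of node k,
#                     with node 0 = Begin and the MM/DM entries of the last
#                     row pointing at End
#   null_model        20 background probabilities
#   alignment_mode    "local" or "glocal"
#
# Bit scores are log2 odds of the model against the null model throughout.

TRANSITION_COLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Construct a profile HMM
#'
#' Low-level constructor; validates all probability invariants. Most users
#' will obtain models from [build_from_alignment()], [read_model()] or the
#' synthetic-library generators instead.
#'
#' @param name Model name.
#' @param group Kinase group or domain-type label (or `NA`).
#' @param match_emissions `L x 20` matrix of match emission probabilities.
#' @param insert_emissions `(L+1) x 20` matrix of insert emission
#'   probabilities (states `I_0..I_L`; `I_L` is kept for schema completeness
#'   but never entered by a scoring path).
#' @param transitions `(L+1) x 7` matrix with columns
#'   `MM, MI, MD, IM, II, DM, DD`.
#' @param null_model 20 background probabilities.
#' @param alignment_mode `"local"` (default; free null-scored flanks around
#'   the model hit) or `"glocal"` (the whole sequence must be aligned).
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, group = NA_character_, match_emissions,
                        insert_emissions, transitions, null_model,
                        alignment_mode = c("local", "glocal")) {
  alignment_mode <- match.arg(alignment_mode)
  match_emissions <- as.matrix(match_emissions)
  insert_emissions <- as.matrix(insert_emissions)
  transitions <- as.matrix(transitions)
  colnames(match_emissions) <- AA20
  colnames(insert_emissions) <- AA20
  colnames(transitions) <- TRANSITION_COLS
  hmm <- structure(list(
    name = as.character(name), group = as.character(group),
    L = nrow(match_emissions),
    match_emissions = match_emissions,
    insert_emissions = insert_emissions,
    transitions = transitions,
    null_model = setNames(as.numeric(null_model), AA20),
    alignment_mode = alignment_mode
  ), class = "profile_hmm")
  validate_profile_hmm(hmm)
  hmm
}

#' Validate a profile HMM
#'
#' Checks that every emission row, transition distribution and the null model
#' sums to 1 within `tol`, that all probabilities are non-negative, and that
#' the structural zeros of the last node hold (no `M->D` or `D->D` out of the
#' final node).
#'
#' @param hmm A `profile_hmm`.
#' @param tol Tolerance on probability sums.
#' @return Invisibly, `hmm`; signals an error when invalid.
#' @export
validate_profile_hmm <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "profile_hmm"))
  L <- hmm$L
  if (!is.numeric(L) || L < 1) stop("model length must be >= 1")
  me <- hmm$match_emissions; ie <- hmm$insert_emissions; tr <- hmm$transitions
  if (!identical(dim(me), c(L, 20L)) && !all(dim(me) == c(L, 20)))
    stop("match_emissions must be L x 20")
  if (!all(dim(ie) == c(L + 1, 20))) stop("insert_emissions must be (L+1) x 20")
  if (!all(dim(tr) == c(L + 1, 7))) stop("transitions must be (L+1) x 7")
  if (any(me < 0) || any(ie < 0) || any(tr < 0) || any(hmm$null_model < 0))
    stop("probabilities must be >= 0")
  bad_row <- function(m) which(abs(rowSums(m) - 1) > tol)
  if (length(bad_row(me)) > 0L)
    stop("match emission row(s) do not sum to 1: ",
         paste(bad_row(me), collapse = ", "))
  if (length(bad_row(ie)) > 0L)
    stop("insert emission row(s) do not sum to 1: ",
         paste(bad_row(ie), collapse = ", "))
  msum <- rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE])
  isum <- rowSums(tr[, c("IM", "II"), drop = FALSE])
  dsum <- rowSums(tr[, c("DM", "DD"), drop = FALSE])
  if (any(abs(c(msum, isum, dsum) - 1) > tol))
    stop("transition distribution(s) do not sum to 1")
  if (tr[L + 1, "MD"] > tol || tr[L + 1, "DD"] > tol)
    stop("the final node cannot transition into a delete state")
  if (abs(sum(hmm$null_model) - 1) > tol) stop("null model does not sum to 1")
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s' (group %s): %d match states, %s mode\n",
              x$name, ifelse(is.na(x$group), "-", x$group), x$L,
              x$alignment_mode))
  invisible(x)
}

# degenerate-but-valid transition rows for the final node and helpers
final_node_transitions <- function() c(MM = 1, MI = 0, MD = 0, IM = 1, II = 0,
                                       DM = 1, DD = 0)

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose gap fraction is below `match_column_rule` become match
#' states; other columns are treated as inserts attached to the preceding
#' match state. Emission and transition probabilities are maximum-likelihood
#' counts regularized with an additive (Laplace-style) pseudocount.
#'
#' @param msa Character vector of equal-length gapped sequences (`-` or `.`
#'   as gaps), or an `AAStringSet`.
#' @param name,group Model name and group label.
#' @param match_column_rule Columns with gap fraction strictly below this
#'   value become match states (default 0.5).
#' @param pseudocount Additive pseudocount applied to every emission and
#'   transition count (default 1, i.e. add-one smoothing).
#' @param null Background model: `"msa"` (residue frequencies of the
#'   alignment, smoothed) or `"uniform"`.
#' @param alignment_mode Default scoring mode stored in the model.
#' @return A `profile_hmm`.
#' @examples
#' hmm <- build_from_alignment(c("ACDE", "ACDE", "ACDE", "ACDE"), name = "toy")
#' hmm$L  # 4
#' @export
build_from_alignment <- function(msa, name = "model", group = NA_character_,
                                 match_column_rule = 0.5, pseudocount = 1,
                                 null = c("uniform", "msa"),
                                 alignment_mode = c("local", "glocal")) {
  null <- match.arg(null)
  alignment_mode <- match.arg(alignment_mode)
  msa <- as.character(msa)
  if (length(msa) < 1L) stop("empty alignment")
  msa <- toupper(msa)
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  if (w == 0L) stop("alignment has zero columns")
  chars <- do.call(rbind, strsplit(chartr(".", "-", msa), "", fixed = TRUE))
  chars[!chars %in% c(AA20, "-")] <- "X"
  gap_frac <- colMeans(chars == "-")
  is_match <- gap_frac < match_column_rule
  L <- sum(is_match)
  if (L == 0L) stop("no match columns under the given rule")
  node_of_col <- cumsum(is_match)          # insert columns attach to node k

  nseq <- nrow(chars)
  me <- matrix(pseudocount, L, 20, dimnames = list(NULL, AA20))
  ie <- matrix(pseudocount, L + 1, 20, dimnames = list(NULL, AA20))
  # transition counts; allowed cells get the pseudocount, others stay 0
  tr <- matrix(0, L + 1, 7, dimnames = list(NULL, TRANSITION_COLS))
  tr[1:L, c("MM", "MI", "MD")] <- pseudocount
  tr[1:L, c("IM", "II")] <- pseudocount
  if (L > 1) tr[2:L, c("DM", "DD")] <- pseudocount
  tr[L + 1, "MM"] <- pseudocount          # M_L -> End
  tr[L + 1, "IM"] <- pseudocount
  tr[L + 1, "DM"] <- pseudocount          # D_L -> End

  for (i in seq_len(nseq)) {
    prev <- c("M", 0L)                    # state type, node
    for (j in seq_len(w)) {
      ch <- chars[i, j]
      k <- node_of_col[j]
      if (is_match[j]) {
        st <- if (ch == "-") "D" else "M"
        if (st == "M" && ch != "X") me[k, ch] <- me[k, ch] + 1
      } else {
        if (ch == "-") next               # gap in insert column: no state
        st <- "I"
        if (ch != "X") ie[k + 1, ch] <- ie[k + 1, ch] + 1
      }
      cell <- paste0(prev[1], st)
      row <- as.integer(prev[2]) + 1L
      if (st == "I") row <- k + 1L        # I_k is indexed by its own node
      # D<->I transitions are not part of the architecture; drop them
      if (cell %in% TRANSITION_COLS) tr[row, cell] <- tr[row, cell] + 1
      prev <- c(st, k)
    }
    cell <- paste0(prev[1], "M")          # final transition into End
    tr[L + 1, cell] <- tr[L + 1, cell] + 1
  }

  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  norm_block <- function(m, cols) {
    s <- rowSums(m[, cols, drop = FALSE])
    ok <- s > 0
    m[ok, cols] <- m[ok, cols, drop = FALSE] / s[ok]
    # structurally unreachable distributions get a degenerate valid row
    if (any(!ok)) m[!ok, cols[1]] <- 1
    m
  }
  tr <- norm_block(tr, c("MM", "MI", "MD"))
  tr <- norm_block(tr, c("IM", "II"))
  tr <- norm_block(tr, c("DM", "DD"))
  tr[L + 1, c("MM", "MI", "MD")] <- c(1, 0, 0)
  tr[L + 1, c("IM", "II")] <- c(1, 0)
  tr[L + 1, c("DM", "DD")] <- c(1, 0)
  if (L >= 1) tr[1, c("DM", "DD")] <- c(1, 0)  # no D_0 state

  nm <- if (null == "uniform") {
    rep(1 / 20, 20)
  } else {
    cnt <- table(factor(chars[chars %in% AA20], levels = AA20)) + pseudocount
    as.numeric(cnt / sum(cnt))
  }
  profile_hmm(name = name, group = group, match_emissions = me,
              insert_emissions = ie, transitions = tr, null_model = nm,
              alignment_mode = alignment_mode)
}
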