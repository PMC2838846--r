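# Kinase identification and group classification.
#
# Fixed-cutoff, maximum-score rule: a protein whose best per-group local
# Viterbi bit score is strictly greater than the cutoff (default 20 bits) is
# called a kinase of the arg-max group; everything else is a no-call. There
# is no fallback "Others" category: missing a borderline kinase is preferred
# to admitting false positives.

#' Advisory bit-score cutoff for a database of a given size
#'
#' Rule of thumb: a score above `log2(n)` bits, where `n` is the number of
#' sequences in the target database, is likely to mark a true homologue. For
#' proteome-scale databases this is on the order of 20 bits, the default
#' fixed cutoff.
#'
#' @param n_sequences Number of sequences in the target database (>= 1).
#' @return The advisory cutoff in bits (`log2(n_sequences)`).
#' @examples
#' recommend_cutoff(1048576) # 20
#' @export
recommend_cutoff <- function(n_sequences) {
  if (!is.numeric(n_sequences) || length(n_sequences) != 1L ||
      is.na(n_sequences) || n_sequences < 1)
    stop("n_sequences must be a single number >= 1")
  log2(n_sequences)
}

# per-group best bit score for one protein (max over the group's models);
# group order follows KINASE_GROUPS for locale-independent determinism
group_scores <- function(scores_row, model_groups) {
  lev <- intersect(KINASE_GROUPS, unique(model_groups))
  vapply(split(scores_row, factor(model_groups, levels = lev)), max, numeric(1))
}

make_call <- function(protein_id, all_scores, cutoff) {
  best <- max(all_scores)
  if (!(best > cutoff)) return(NULL)     # strictly greater than the cutoff
  tied <- names(all_scores)[all_scores == best]
  grp <- tied[order(match(tied, KINASE_GROUPS))][1]  # deterministic tie-break
  list(protein_id = protein_id, group = grp, bit_score = unname(best),
       all_scores = all_scores)
}

#' Classify one protein against a kinase group library
#'
#' Scores the protein against every model in the library (local Viterbi bit
#' score), aggregates to one score per group by maximum, and calls the
#' arg-max group when the overall maximum is strictly greater than `cutoff`.
#' Ties between groups at the best score are broken toward the
#' lexicographically smallest group name.
#'
#' @param protein A single protein sequence (character, optionally named) or
#'   a length-1 `AAStringSet`.
#' @param library A `group_library`.
#' @param cutoff Bit-score cutoff (default 20; strict inequality).
#' @return A `kinase_call` (list with `protein_id`, `group`, `bit_score`,
#'   `all_scores`) or `NULL` for a no-call.
#' @export
classify_protein <- function(protein, library, cutoff = 20) {
  stopifnot(inherits(library, "group_library"))
  seqs <- as_sequences(protein)
  if (length(seqs) != 1L) stop("classify_protein takes a single protein")
  id <- if (!is.null(names(seqs))) names(seqs) else "protein"
  sm <- score_matrix(seqs, library$models)
  grp <- vapply(library$models, `[[`, character(1), "group")
  call <- make_call(id, group_scores(sm[1, ], grp), cutoff)
  if (is.null(call)) return(NULL)
  structure(call, class = "kinase_call")
}

#' Extract and classify the kinome of a proteome
#'
#' Applies [classify_protein()] logic to every protein, in input order.
#' Proteins whose best score does not exceed the cutoff are absent from the
#' calls but still counted in `proteome_size`.
#'
#' @param proteome An `AAStringSet` (e.g. from [read_fasta()]) with unique
#'   names.
#' @param species One row of a species table (`data.frame` with at least
#'   `abbreviation` and `clade_label`), or `NULL`.
#' @param library A `group_library`.
#' @param cutoff Bit-score cutoff in bits (strict inequality; default 20).
#' @return A `kinome`: list with `species`, `calls` (data.frame with columns
#'   `protein_id`, `group`, `bit_score`, then `score.<group>` for all twelve
#'   groups), `proteome_size` and `cutoff`.
#' @export
extract_kinome <- function(proteome, species = NULL, library, cutoff = 20) {
  stopifnot(inherits(library, "group_library"))
  seqs <- as_sequences(proteome)
  if (length(seqs) == 0L) stop("empty proteome")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("proteome sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein ids in proteome")
  sm <- score_matrix(seqs, library$models)
  grp <- vapply(library$models, `[[`, character(1), "group")
  lev <- intersect(KINASE_GROUPS, unique(grp))
  gs <- matrix(NA_real_, nrow(sm), length(lev),
               dimnames = list(rownames(sm), lev))         # seq x group
  for (i in seq_len(nrow(sm))) gs[i, ] <- group_scores(sm[i, ], grp)
  present <- colnames(gs)
  best <- apply(gs, 1, max)
  called <- best > cutoff
  pick <- function(row) {
    tied <- present[gs[row, ] == best[row]]
    tied[order(match(tied, KINASE_GROUPS))][1]
  }
  groups_called <- vapply(which(called), pick, character(1))
  full <- matrix(-Inf, sum(called), length(KINASE_GROUPS),
                 dimnames = list(NULL, KINASE_GROUPS))
  if (sum(called) > 0) full[, present] <- gs[called, , drop = FALSE]
  calls <- data.frame(protein_id = names(seqs)[called],
                      group = unname(groups_called),
                      bit_score = unname(best[called]),
                      row.names = NULL, stringsAsFactors = FALSE)
  score_cols <- as.data.frame(full)
  names(score_cols) <- paste0("score.", KINASE_GROUPS)
  calls <- cbind(calls, score_cols)
  structure(list(species = species, calls = calls,
                 proteome_size = length(seqs), cutoff = cutoff),
            class = "kinome")
}

#' @export
print.kinome <- function(x, ...) {
  ab <- if (!is.null(x$species)) x$species$abbreviation else "?"
  cat(sprintf("kinome of %s: %d kinases called out of %d proteins (cutoff %g bits)\n",
              ab, nrow(x$calls), x$proteome_size, x$cutoff))
  invisible(x)
}

#' Write a kinome classification report
#'
#' TSV with one row per called kinase: `protein_id`, `group`, `bit_score`,
#' then one column per group with that group's best score. Scores are printed
#' with 4 decimals; groups never scored (no model in the library) are empty.
#'
#' @param kinome A `kinome`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_kinome_tsv <- function(kinome, path) {
  df <- kinome$calls
  fmt <- function(x) ifelse(is.finite(x), sprintf("%.4f", x), "")
  out <- data.frame(protein_id = df$protein_id, group = df$group,
                    bit_score = fmt(df$bit_score),
                    stringsAsFactors = FALSE)
  for (g in KINASE_GROUPS) out[[g]] <- fmt(df[[paste0("score.", g)]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a kinome classification report
#'
#' @param path TSV written by [write_kinome_tsv()].
#' @param species,proteome_size,cutoff Optional metadata to attach.
#' @return A `kinome` object (score columns at 4-decimal precision).
#' @export
read_kinome_tsv <- function(path, species = NULL, proteome_size = NA_integer_,
                            cutoff = NA_real_) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  calls <- data.frame(protein_id = as.character(df$protein_id),
                      group = df$group, bit_score = as.numeric(df$bit_score),
                      stringsAsFactors = FALSE)
  for (g in KINASE_GROUPS) {
    v <- suppressWarnings(as.numeric(df[[g]]))
    v[is.na(v)] <- -Inf
    calls[[paste0("score.", g)]] <- v
  }
  structure(list(species = species, calls = calls,
                 proteome_size = proteome_size, cutoff = cutoff),
            class = "kinome")
}
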