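# Proteome and species-metadata input/output.
#
# A proteome is held as a Biostrings::AAStringSet whose names are the protein
# ids (first whitespace token of the FASTA header); the full header line is
# kept in the `description` metadata column. Sequences are normalized to the
# 20 standard residues plus X.

# letters accepted after normalization
NONSTANDARD_MAP <- c(B = "X", Z = "X", U = "X", O = "X", J = "X", "." = "X")

normalize_protein <- function(seq) {
  s <- toupper(seq)
  s <- gsub("*", "", s, fixed = TRUE)
  s <- gsub("\\s", "", s)
  s <- chartr("BZUOJ.", "XXXXXX", s)
  # anything still outside the alphabet becomes X
  s <- vapply(strsplit(s, "", fixed = TRUE), function(ch) {
    ch[!ch %in% c(AA20, "X", "-")] <- "X"
    paste(ch[ch != "-"], collapse = "")
  }, character(1))
  s
}

#' Read a protein FASTA file
#'
#' Parses a protein FASTA file into an [Biostrings::AAStringSet]. Headers are
#' split at the first whitespace: the first token becomes the record id, the
#' remainder is stored in the `description` metadata column. Sequences are
#' uppercased, `*` stop characters are stripped, and non-standard residue
#' codes (B, Z, U, O, J, `.` and anything else outside the 20-letter
#' alphabet) are mapped to `X`.
#'
#' @param path Path to a protein FASTA file.
#' @return An `AAStringSet` with unique names and a `description` metadata
#'   column.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a test protein", "MKV", ">b", "GG"), fa)
#' p <- read_fasta(fa)
#' names(p)   # "a" "b"
#' width(p)   # 3 2
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(nonblank[[1]], ">"))
    stop("malformed FASTA (sequence line before any header): ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_protein(as.character(set))
  if (any(!nzchar(seqs))) stop("zero-length sequence after normalization")
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  desc <- sub("^\\S+\\s*", "", headers)
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write a proteome to FASTA
#'
#' @param proteome An `AAStringSet` (e.g. from [read_fasta()]).
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  Biostrings::writeXStringSet(proteome, filepath = path, width = width)
  invisible(path)
}

#' Load a species metadata table
#'
#' Reads a UTF-8 TSV with header columns `name`, `abbreviation`, `phylum`,
#' `subphylum` and `clade_label`, one row per species, preserving row order.
#' The clade label is the categorical used for coloring, clade means and the
#' rank-sum comparison (e.g. Pezizomycotina / Saccharomycotina /
#' Basidiomycota / Taphrinomycotina).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with the five columns above.
#' @export
load_species_table <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  required <- c("name", "abbreviation", "phylum", "subphylum", "clade_label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("species table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, required, drop = FALSE]
  if (anyDuplicated(df$abbreviation))
    stop("duplicate species abbreviation(s): ",
         paste(unique(df$abbreviation[duplicated(df$abbreviation)]), collapse = ", "))
  df
}

#' Write a species metadata table
#'
#' @param species A `data.frame` as returned by [load_species_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_species_table <- function(species, path) {
  write.table(species, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
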