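# Model interchange: native "khmm-1" JSON, best-effort HMMER3 ASCII import,
# and library directories (one JSON model per file).

#' Write a profile HMM to the native JSON format
#'
#' The native interchange format (`"khmm-1"`) stores the full model: name,
#' group, length, alphabet, emission tables, transition table, null model and
#' default alignment mode, at full double precision.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path (conventionally `.json`).
#' @return Invisibly, `path`.
#' @export
write_model <- function(hmm, path) {
  validate_profile_hmm(hmm)
  obj <- list(
    format = "khmm-1",
    name = hmm$name,
    group = hmm$group,
    length = hmm$L,
    alphabet = paste(AA20, collapse = ""),
    alignment_mode = hmm$alignment_mode,
    match_emissions = unname(apply(hmm$match_emissions, 1, c, simplify = FALSE)),
    insert_emissions = unname(apply(hmm$insert_emissions, 1, c, simplify = FALSE)),
    transitions = unname(apply(hmm$transitions, 1, c, simplify = FALSE)),
    transition_order = TRANSITION_COLS,
    null_model = unname(hmm$null_model)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a profile HMM from the native JSON format
#'
#' @param path Path to a `khmm-1` JSON file.
#' @return A validated `profile_hmm`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || !identical(obj$format, "khmm-1"))
    stop("not a khmm-1 model file: ", path)
  as_mat <- function(x, ncol) {
    if (is.list(x)) x <- do.call(rbind, x)
    m <- matrix(as.numeric(x), ncol = ncol, byrow = FALSE)
    if (is.matrix(x)) m <- x
    m
  }
  me <- as_mat(obj$match_emissions, 20)
  ie <- as_mat(obj$insert_emissions, 20)
  tr <- as_mat(obj$transitions, 7)
  profile_hmm(name = obj$name,
              group = if (is.null(obj$group)) NA_character_ else obj$group,
              match_emissions = me, insert_emissions = ie, transitions = tr,
              null_model = as.numeric(obj$null_model),
              alignment_mode = obj$alignment_mode)
}

#' Import a HMMER3 ASCII model (best effort)
#'
#' Maps the fields of a `HMMER3/f` text model onto a `profile_hmm`. The
#' import is best-effort, not bit-exact: HMMER stores negative natural-log
#' probabilities, does not ship its null model in the file, and carries
#' annotation columns this representation does not use. The background is
#' taken from the `COMPO` line when present, otherwise uniform; skipped
#' fields are reported in the `import_warnings` attribute.
#'
#' @param path Path to a HMMER3 ASCII file.
#' @return A `profile_hmm` with an `import_warnings` character attribute.
#' @export
read_hmmer3 <- function(path) {
  if (!file.exists(path)) stop("HMMER3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^HMMER3/f", lines[[1]]))
    stop("not a HMMER3/f ASCII file: ", path)
  warnings_log <- character(0)
  tok <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  header <- list()
  i <- 2L
  while (i <= length(lines) && !grepl("^HMM\\s", lines[[i]])) {
    t <- tok(lines[[i]])
    if (length(t) >= 2) header[[t[1]]] <- t[-1]
    i <- i + 1L
  }
  if (i > length(lines)) stop("no HMM section found in ", path)
  for (f in intersect(names(header), c("STATS", "EFFN", "CKSUM", "GA", "TC", "NC", "MAP", "CONS", "RF", "MM", "CS")))
    warnings_log <- c(warnings_log, paste("ignored header field:", f))
  L <- as.integer(header$LENG[1])
  if (is.na(L) || L < 1) stop("missing or invalid LENG in ", path)
  alpha <- tok(lines[[i]])[-1]           # residue order on the HMM line
  alpha <- alpha[seq_len(20)]
  perm <- match(AA20, toupper(alpha))
  if (anyNA(perm)) stop("unsupported alphabet in ", path)
  i <- i + 2L                            # skip the m->m transition header line
  from_nll <- function(x)
    ifelse(x == "*", 0, exp(-suppressWarnings(as.numeric(x))))

  nm <- rep(1 / 20, 20)
  if (grepl("^\\s*COMPO", lines[[i]])) {
    v <- from_nll(tok(lines[[i]])[2:21])[perm]
    nm <- v / sum(v)
    i <- i + 1L
  } else {
    warnings_log <- c(warnings_log, "no COMPO line; using uniform background")
  }

  ie <- matrix(0, L + 1, 20)
  tr <- matrix(0, L + 1, 7, dimnames = list(NULL, TRANSITION_COLS))
  me <- matrix(0, L, 20)
  # node 0: insert emissions + transitions
  v <- from_nll(tok(lines[[i]])[1:20])[perm]; ie[1, ] <- v / sum(v); i <- i + 1L
  t0 <- from_nll(tok(lines[[i]])[1:7]); i <- i + 1L
  tr[1, ] <- t0                          # HMMER order: mm mi md im ii dm dd
  for (k in seq_len(L)) {
    t <- tok(lines[[i]])
    if (as.integer(t[1]) != k) stop("unexpected node numbering at node ", k)
    v <- from_nll(t[2:21])[perm]; me[k, ] <- v / sum(v)
    if (length(t) > 21)
      warnings_log <- unique(c(warnings_log, "ignored MAP/CONS/RF/MM/CS annotation columns"))
    i <- i + 1L
    v <- from_nll(tok(lines[[i]])[1:20])[perm]; ie[k + 1, ] <- v / sum(v); i <- i + 1L
    tr[k + 1, ] <- from_nll(tok(lines[[i]])[1:7]); i <- i + 1L
  }
  # renormalize transition blocks (HMMER's last node has structural zeros)
  renorm <- function(row, cols) {
    s <- sum(tr[row, cols])
    if (s > 0) tr[row, cols] / s else c(1, rep(0, length(cols) - 1))
  }
  for (r in seq_len(L + 1)) {
    tr[r, c("MM", "MI", "MD")] <- renorm(r, c("MM", "MI", "MD"))
    tr[r, c("IM", "II")] <- renorm(r, c("IM", "II"))
    tr[r, c("DM", "DD")] <- renorm(r, c("DM", "DD"))
  }
  tr[L + 1, c("MM", "MI", "MD")] <- c(1, 0, 0)
  tr[L + 1, c("DM", "DD")] <- c(1, 0)
  hmm <- profile_hmm(name = if (!is.null(header$NAME)) header$NAME[1] else basename(path),
                     group = NA_character_, match_emissions = me,
                     insert_emissions = ie, transitions = tr, null_model = nm,
                     alignment_mode = "local")
  attr(hmm, "import_warnings") <- warnings_log
  hmm
}

#' Read a directory of models as a library
#'
#' Loads every `*.json` model in `dir` (native `khmm-1` format). When
#' `as_group_library = TRUE` the result is a `group_library`: every model
#' must carry one of the twelve kinase group names and each group may hold
#' one or more models (multi-level library semantics).
#'
#' @param dir Directory containing model JSON files.
#' @param as_group_library Validate group names against [KINASE_GROUPS].
#' @return A list of `profile_hmm` (class `model_library`), or a
#'   `group_library`.
#' @export
read_library <- function(dir, as_group_library = FALSE) {
  if (!dir.exists(dir)) stop("library directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop("no model files in ", dir)
  models <- lapply(files, read_model)
  names(models) <- vapply(models, `[[`, character(1), "name")
  if (as_group_library) return(group_library(models))
  structure(models, class = "model_library")
}

#' Write a library of models to a directory
#'
#' @param models List of `profile_hmm` objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_library <- function(models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in models) write_model(m, file.path(dir, paste0(m$name, ".json")))
  invisible(dir)
}

#' Assemble a kinase group library
#'
#' @param models List of `profile_hmm` objects, each labelled with one of the
#'   twelve kinase group names; a group may contribute several models.
#' @return A `group_library` (list with `models` and `groups`).
#' @export
group_library <- function(models) {
  if (length(models) == 0L) stop("empty model list")
  grp <- vapply(models, `[[`, character(1), "group")
  bad <- setdiff(unique(grp), KINASE_GROUPS)
  if (length(bad) > 0L)
    stop("model group(s) outside the twelve kinase groups: ",
         paste(bad, collapse = ", "))
  nms <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate model names in library")
  structure(list(models = setNames(models, nms),
                 groups = sort(unique(grp))),
            class = "group_library")
}

#' @export
print.group_library <- function(x, ...) {
  cat(sprintf("group_library: %d models over %d groups (%s)\n",
              length(x$models), length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}
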