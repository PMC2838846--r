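# Domain annotation of predicted kinases.
#
# Kinase sequences (only proteins already called as kinases, following the
# pipeline order) are scanned against a domain HMM library in local mode.
# Hits with bit score strictly above the threshold are significant. A
# sequence may carry several non-overlapping hits of the same domain (each
# counts); overlapping hits (> 50% of the shorter envelope) are resolved in
# favour of the higher score. Coordinates are 1-based inclusive.

#' Scan kinase sequences for domain hits
#'
#' Every (sequence, model) pair is scored in local mode. For each model,
#' additional non-overlapping hits on the same sequence are found by masking
#' the envelope of each accepted hit (residues set to the X wildcard) and
#' rescanning until the score drops to the threshold. Hits from all models on
#' one sequence are then resolved: hits overlapping a higher-scoring hit by
#' more than half of the shorter envelope are discarded (ties broken by
#' score, then domain name, then start).
#'
#' @param kinases Named character vector or `AAStringSet` of kinase
#'   sequences. An empty input yields an empty inventory.
#' @param domain_library List of `profile_hmm` domain models.
#' @param threshold Significance threshold in bits (strict inequality;
#'   default 20).
#' @param max_hits_per_model Safety bound on repeated rescans per
#'   (sequence, model) pair.
#' @return A `domain_inventory`: list with `hits` (data.frame `kinase_id`,
#'   `domain_name`, `bit_score`, `start`, `end`, `is_catalytic`),
#'   `n_kinases` and `per_type_counts`.
#' @export
scan_domains <- function(kinases, domain_library, threshold = 20,
                         max_hits_per_model = 25L) {
  if (length(kinases) == 0L)
    return(domain_inventory(empty_hits(), n_kinases = 0L))
  seqs <- as_sequences(kinases)
  if (is.null(names(seqs))) stop("kinase sequences must be named")
  for (m in domain_library) validate_profile_hmm(m)
  rows <- list()
  for (m in domain_library) {
    tables <- phmm_logodds(m)
    for (i in seq_along(seqs)) {
      idx <- encode_residues(seqs[[i]])
      for (iter in seq_len(max_hits_per_model)) {
        hit <- .cpp_phmm_local_hit(tables$lM, tables$lI, tables$lt, idx)
        if (!(hit[1] > threshold)) break
        rows[[length(rows) + 1L]] <- data.frame(
          kinase_id = names(seqs)[i], domain_name = m$name,
          bit_score = hit[1], start = as.integer(hit[2]),
          end = as.integer(hit[3]), stringsAsFactors = FALSE)
        idx[hit[2]:hit[3]] <- 21L        # mask the envelope, rescan
      }
    }
  }
  hits <- if (length(rows) == 0L) empty_hits() else do.call(rbind, rows)
  hits <- resolve_overlaps(hits)
  hits$is_catalytic <- hits$domain_name %in% CATALYTIC_DOMAINS
  # deterministic report order: kinase, position, name
  hits <- hits[order(hits$kinase_id, hits$start, hits$domain_name), ,
               drop = FALSE]
  rownames(hits) <- NULL
  domain_inventory(hits, n_kinases = length(seqs))
}

empty_hits <- function() {
  data.frame(kinase_id = character(0), domain_name = character(0),
             bit_score = numeric(0), start = integer(0), end = integer(0),
             is_catalytic = logical(0), stringsAsFactors = FALSE)
}

# keep, per kinase, the higher-scoring hit among pairs whose envelopes
# overlap by > 50% of the shorter hit
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  keep <- logical(nrow(hits))
  ord <- order(-hits$bit_score, hits$domain_name, hits$start)
  for (id in unique(hits$kinase_id)) {
    sel <- which(hits$kinase_id == id)
    sel <- sel[order(match(sel, ord))]
    accepted <- integer(0)
    for (i in sel) {
      ok <- TRUE
      for (j in accepted) {
        ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
        shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j]) + 1L
        if (ov > 0.5 * shorter) { ok <- FALSE; break }
      }
      if (ok) accepted <- c(accepted, i)
    }
    keep[accepted] <- TRUE
  }
  hits[keep, , drop = FALSE]
}

#' Construct a domain inventory
#'
#' @param hits Hit table as produced by [scan_domains()].
#' @param n_kinases Number of kinase sequences scanned (hits or not).
#' @return A `domain_inventory`.
#' @export
domain_inventory <- function(hits, n_kinases) {
  if (!"is_catalytic" %in% names(hits))
    hits$is_catalytic <- hits$domain_name %in% CATALYTIC_DOMAINS
  counts <- table(hits$domain_name)
  per_type <- setNames(as.integer(counts), names(counts))
  structure(list(hits = hits, n_kinases = as.integer(n_kinases),
                 per_type_counts = per_type),
            class = "domain_inventory")
}

#' @export
print.domain_inventory <- function(x, ...) {
  cat(sprintf("domain_inventory: %d hits of %d types on %d kinases\n",
              nrow(x$hits), length(x$per_type_counts), x$n_kinases))
  invisible(x)
}

#' Summarize a domain inventory
#'
#' Corpus-level tallies: total, catalytic and accessory domain counts, mean
#' domains per kinase (unrounded, with a 1-decimal display value), the number
#' of distinct domain types split by catalytic status, and the singleton
#' types (appearing exactly once).
#'
#' @param inventory A `domain_inventory`, or a named integer vector of
#'   per-type counts via [domain_summary_from_counts()].
#' @return A `domain_summary` list.
#' @export
summarize_domains <- function(inventory) {
  stopifnot(inherits(inventory, "domain_inventory"))
  if (inventory$n_kinases == 0L && nrow(inventory$hits) > 0L)
    stop("inventory has hits but zero kinases")
  domain_summary_from_counts(inventory$per_type_counts, inventory$n_kinases)
}

#' Summarize domain tallies from per-type counts
#'
#' Same summary as [summarize_domains()] but computed directly from a named
#' count vector, e.g. an externally tabulated per-type census.
#'
#' @param per_type_counts Named integer vector: domain type -> occurrences.
#' @param n_kinases Number of kinase sequences the counts refer to.
#' @return A `domain_summary` list with fields `total_domains`,
#'   `catalytic_count`, `accessory_count`, `mean_domains_per_kinase`,
#'   `mean_catalytic_per_kinase`, `mean_accessory_per_kinase` (each with a
#'   `*_display` value rounded to 1 decimal), `n_domain_types`,
#'   `n_catalytic_types`, `n_accessory_types` and `singleton_types`.
#' @export
domain_summary_from_counts <- function(per_type_counts, n_kinases) {
  n_kinases <- as.integer(n_kinases)
  cnt <- per_type_counts[per_type_counts > 0]
  is_cat <- names(cnt) %in% CATALYTIC_DOMAINS
  total <- sum(cnt)
  cat_n <- sum(cnt[is_cat])
  acc_n <- sum(cnt[!is_cat])
  mean0 <- function(num) if (n_kinases > 0) num / n_kinases else 0
  s <- list(
    total_domains = as.integer(total),
    catalytic_count = as.integer(cat_n),
    accessory_count = as.integer(acc_n),
    mean_domains_per_kinase = mean0(total),
    mean_catalytic_per_kinase = mean0(cat_n),
    mean_accessory_per_kinase = mean0(acc_n),
    n_domain_types = length(cnt),
    n_catalytic_types = sum(is_cat),
    n_accessory_types = sum(!is_cat),
    singleton_types = sort(names(cnt)[cnt == 1]),
    n_kinases = n_kinases
  )
  s$mean_domains_per_kinase_display <- round(s$mean_domains_per_kinase, 1)
  s$mean_catalytic_per_kinase_display <- round(s$mean_catalytic_per_kinase, 1)
  s$mean_accessory_per_kinase_display <- round(s$mean_accessory_per_kinase, 1)
  structure(s, class = "domain_summary")
}

#' @export
print.domain_summary <- function(x, ...) {
  cat(sprintf(paste0("domain_summary: %d kinases, %d domains ",
                     "(%d catalytic + %d accessory), %.1f per kinase\n"),
              x$n_kinases, x$total_domains, x$catalytic_count,
              x$accessory_count, x$mean_domains_per_kinase))
  invisible(x)
}

#' Fraction of species carrying each domain type
#'
#' @param inventories Named list: species abbreviation -> `domain_inventory`.
#' @return Named numeric vector: domain type -> fraction of species with at
#'   least one occurrence (in `[0, 1]`).
#' @export
domain_prevalence <- function(inventories) {
  if (length(inventories) == 0L) stop("need at least one species")
  types <- sort(unique(unlist(lapply(inventories, function(inv)
    names(inv$per_type_counts)))))
  if (length(types) == 0L) return(setNames(numeric(0), character(0)))
  pres <- vapply(inventories, function(inv)
    types %in% names(inv$per_type_counts)[inv$per_type_counts > 0],
    logical(length(types)))
  pres <- matrix(pres, nrow = length(types))
  setNames(rowMeans(pres), types)
}

#' Write domain hits / summary reports
#'
#' `write_domain_hits_tsv()` emits the hit table (kinase_id, domain_name,
#' bit_score with 4 decimals, start, end, is_catalytic);
#' `write_domain_summary_json()` mirrors the `domain_summary` fields.
#'
#' @param inventory A `domain_inventory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_hits_tsv <- function(inventory, path) {
  df <- inventory$hits
  df$bit_score <- sprintf("%.4f", df$bit_score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_domain_hits_tsv
#' @param summary A `domain_summary`.
#' @export
write_domain_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
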