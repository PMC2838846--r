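# Per-species and cross-species kinome statistics.
#
# Kinome density is reported as a percentage: 100 * kinases / proteome size.
# Normalized frequencies are percentages of each group within the species'
# total kinome and always cover all twelve groups, including structural
# zeros (a group with no representatives is itself a reportable fact).

#' Summarize one kinome
#'
#' @param kinome A `kinome` from [extract_kinome()].
#' @return A `kinome_summary`: list with `species`, `group_counts` (all 12
#'   groups), `total_kinases`, `proteome_size`, `normalized_freq` (percent,
#'   summing to 100 when any kinase was called; all zero with
#'   `undefined_freq = TRUE` otherwise) and `kinome_density` (percent).
#' @export
summarize_kinome <- function(kinome) {
  stopifnot(inherits(kinome, "kinome"))
  if (is.na(kinome$proteome_size) || kinome$proteome_size < 1)
    stop("proteome_size must be >= 1")
  counts <- table(factor(kinome$calls$group, levels = KINASE_GROUPS))
  counts <- setNames(as.integer(counts), KINASE_GROUPS)
  total <- sum(counts)
  undefined <- total == 0L
  freq <- if (undefined) setNames(rep(0, 12), KINASE_GROUPS)
          else 100 * counts / total
  structure(list(
    species = kinome$species,
    group_counts = counts,
    total_kinases = total,
    proteome_size = kinome$proteome_size,
    normalized_freq = freq,
    kinome_density = 100 * total / kinome$proteome_size,
    undefined_freq = undefined
  ), class = "kinome_summary")
}

#' @export
print.kinome_summary <- function(x, ...) {
  ab <- if (!is.null(x$species)) x$species$abbreviation else "?"
  cat(sprintf("kinome_summary %s: %d kinases / %d proteins (density %.3f%%)\n",
              ab, x$total_kinases, x$proteome_size, x$kinome_density))
  invisible(x)
}

#' Cohort tables of counts, frequencies and densities
#'
#' Assembles per-species summaries into cohort-level tables, preserving input
#' order (the species-table ordering convention). Also reports the mean
#' kinome size and mean density per clade label.
#'
#' @param summaries List of `kinome_summary` objects.
#' @return List with `counts` and `frequencies` (species x 12 groups
#'   data.frames with `abbreviation`, `clade_label`, `total_kinases`,
#'   `proteome_size`), `densities` (per species) and `clade_means`.
#' @export
cohort_table <- function(summaries) {
  if (length(summaries) < 1L) stop("need at least one summary")
  ab <- vapply(summaries, function(s)
    if (!is.null(s$species)) as.character(s$species$abbreviation) else NA_character_,
    character(1))
  clade <- vapply(summaries, function(s)
    if (!is.null(s$species)) as.character(s$species$clade_label) else NA_character_,
    character(1))
  meta <- data.frame(abbreviation = ab, clade_label = clade,
                     total_kinases = vapply(summaries, `[[`, numeric(1), "total_kinases"),
                     proteome_size = vapply(summaries, `[[`, numeric(1), "proteome_size"),
                     stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(as.list(s$group_counts))))
  freqs <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(as.list(s$normalized_freq))))
  densities <- data.frame(meta[, c("abbreviation", "clade_label")],
                          kinome_density = vapply(summaries, `[[`, numeric(1),
                                                  "kinome_density"),
                          stringsAsFactors = FALSE)
  clade_means <- do.call(rbind, lapply(split(seq_along(summaries), clade),
    function(ix) data.frame(
      clade_label = clade[ix[1]],
      n_species = length(ix),
      mean_kinome_size = mean(meta$total_kinases[ix]),
      mean_density = mean(densities$kinome_density[ix]),
      stringsAsFactors = FALSE)))
  rownames(clade_means) <- NULL
  list(counts = cbind(meta, counts),
       frequencies = cbind(meta[, c("abbreviation", "clade_label")], freqs),
       densities = densities,
       clade_means = clade_means)
}

#' Unpaired two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin, reproducible wrapper over [stats::wilcox.test()] in unpaired,
#' two-sided mode, with an explicit exact-vs-approximate switch: the exact
#' distribution is used when there are no ties and both sample sizes are at
#' most `exact_limit`; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_limit Largest sample size for which the exact p-value is
#'   computed (default 25).
#' @return A `wilcoxon_result`: list with `U_statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`) and `two_sided = TRUE`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 25L) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && max(length(x), length(y)) <= exact_limit
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", paired = FALSE,
                exact = exact, correct = TRUE))
  p <- res$p.value
  # degenerate case: zero rank variance (all values tied) carries no
  # evidence of a shift
  if (is.nan(p)) p <- 1
  structure(list(U_statistic = unname(res$statistic),
                 p_value = p,
                 method = if (exact) "exact" else "normal_approx",
                 two_sided = TRUE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: U = %g, two-sided p = %.4g (%s)\n",
              x$U_statistic, x$p_value, x$method))
  invisible(x)
}

#' Compare kinome density between two clades
#'
#' Convenience wrapper: picks the density values of two clade labels from a
#' cohort and runs [wilcoxon_rank_sum()].
#'
#' @param densities The `densities` table from [cohort_table()].
#' @param clade_a,clade_b Clade labels to compare.
#' @param exact_limit Passed to [wilcoxon_rank_sum()].
#' @return A `wilcoxon_result` with a `clades` attribute.
#' @export
compare_density <- function(densities, clade_a, clade_b, exact_limit = 25L) {
  xa <- densities$kinome_density[densities$clade_label == clade_a]
  xb <- densities$kinome_density[densities$clade_label == clade_b]
  if (length(xa) == 0L || length(xb) == 0L)
    stop("clade label(s) not found in the density table")
  res <- wilcoxon_rank_sum(xa, xb, exact_limit = exact_limit)
  attr(res, "clades") <- c(clade_a, clade_b)
  res
}
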