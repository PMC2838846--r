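# Prevalence-filtered domain-frequency matrix and principal component
# analysis of species.
#
# Each species' row holds the percentage of each domain type among that
# species' total domain occurrences; only domain types present in at least
# half of the species (configurable) are retained as columns. PCA is run on
# the centered (optionally scaled) rows; species are projected onto the
# first three components with their clade labels for taxonomy overlays.

#' Build the species x domain percentage matrix
#'
#' `cell(s, d) = 100 * count of domain d in species s / total domain
#' occurrences in species s`. Domain types present in fewer than
#' `prevalence_threshold` of the species ("at least half" by default, i.e.
#' a domain in exactly half the species is retained) are dropped. Columns are
#' ordered by descending pooled count, then name; rows follow the input
#' order.
#'
#' @param inventories Named list: species abbreviation -> `domain_inventory`
#'   (at least two species).
#' @param prevalence_threshold Minimum fraction of species carrying the
#'   domain (default 0.5).
#' @return A numeric matrix (species x domains) with a `zero_rows` attribute
#'   naming species that had no domains at all.
#' @export
build_frequency_matrix <- function(inventories, prevalence_threshold = 0.5) {
  if (length(inventories) < 2L) stop("need at least two species")
  if (is.null(names(inventories)) || any(!nzchar(names(inventories))))
    stop("inventories must be named by species")
  prev <- domain_prevalence(inventories)
  keep <- names(prev)[prev >= prevalence_threshold]
  all_types <- names(prev)
  counts <- matrix(0, length(inventories), length(all_types),
                   dimnames = list(names(inventories), all_types))
  for (s in names(inventories)) {
    ptc <- inventories[[s]]$per_type_counts
    counts[s, names(ptc)] <- ptc
  }
  totals <- rowSums(counts)               # all occurrences, pre-filter
  zero_rows <- names(inventories)[totals == 0]
  if (length(zero_rows) > 0L)
    warning("species with zero domains: ", paste(zero_rows, collapse = ", "))
  pooled <- colSums(counts)
  keep <- keep[order(-pooled[keep], keep)]
  vals <- counts[, keep, drop = FALSE]
  vals <- 100 * vals / ifelse(totals > 0, totals, 1)
  rownames(vals) <- names(inventories)
  attr(vals, "zero_rows") <- zero_rows
  vals
}

#' Principal component analysis of a frequency matrix
#'
#' Eigen-analysis of the (centered, optionally variance-scaled) rows,
#' computed via singular value decomposition. Component signs are fixed by
#' making the largest-magnitude loading of each component positive, so
#' results are deterministic across linear-algebra backends.
#'
#' @param matrix Numeric matrix, rows = species (>= 2), columns >= 1.
#' @param center Center columns (default `TRUE`).
#' @param scale Scale columns to unit variance (default `FALSE`).
#' @return A `kinome_pca`: list with `component_loadings` (orthonormal
#'   columns), `scores` (species x components), and
#'   `explained_variance_fraction` (non-increasing, sums to 1).
#' @export
pca_domains <- function(matrix, center = TRUE, scale = FALSE) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L || ncol(m) < 1L) stop("need >= 2 rows and >= 1 column")
  total_var <- sum(apply(m, 2, stats::var))
  if (total_var <= .Machine$double.eps)
    stop("matrix has no variance; PCA is undefined")
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) stop("cannot scale a zero-variance column")
  }
  p <- prcomp(m, center = center, scale. = scale)
  load <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(load))) {       # deterministic sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(component_loadings = load, scores = scores,
                 explained_variance_fraction = evf,
                 center = center, scale = scale),
            class = "kinome_pca")
}

#' @export
print.kinome_pca <- function(x, ...) {
  evf <- x$explained_variance_fraction
  cat(sprintf("kinome_pca: %d components; PC1-PC3 explain %.1f%% of variance\n",
              length(evf), 100 * sum(evf[seq_len(min(3, length(evf)))])))
  invisible(x)
}

#' Project species onto the first three principal components
#'
#' @param result A `kinome_pca`.
#' @param species_table Species table with `abbreviation` and `clade_label`;
#'   must cover every row of the scores.
#' @return data.frame with `abbreviation`, `PC1`, `PC2`, `PC3`,
#'   `clade_label`. When fewer than three components exist the missing
#'   columns are zero and the `padded` attribute is `TRUE` (with a warning).
#' @export
project3 <- function(result, species_table) {
  stopifnot(inherits(result, "kinome_pca"))
  sc <- result$scores
  ids <- rownames(sc)
  if (is.null(ids)) stop("scores have no species ids")
  missing <- setdiff(ids, species_table$abbreviation)
  if (length(missing) > 0L)
    stop("species missing from the table: ", paste(missing, collapse = ", "))
  padded <- ncol(sc) < 3L
  if (padded) {
    warning("fewer than 3 components; padding with zeros")
    sc <- cbind(sc, matrix(0, nrow(sc), 3L - ncol(sc)))
  }
  clade <- species_table$clade_label[match(ids, species_table$abbreviation)]
  out <- data.frame(abbreviation = ids, PC1 = sc[, 1], PC2 = sc[, 2],
                    PC3 = sc[, 3], clade_label = clade,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "padded") <- padded
  out
}

#' Silhouette-style clade separation score
#'
#' For each species: `(b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to its own clade's other members and `b` the smallest mean
#' distance to any other clade; members of singleton clades contribute 0.
#' The mean over species lies in `[-1, 1]`; values near 1 indicate
#' well-separated clades, values near 0 no structure. This is a numeric
#' testing surrogate for the visual cluster assessment of a 3-D PCA plot.
#'
#' @param coords Numeric matrix or data.frame of coordinates (e.g. the PC1-3
#'   columns of [project3()] output).
#' @param labels Clade label per row (>= 2 distinct labels).
#' @return Mean separation score in `[-1, 1]`.
#' @export
cluster_separation <- function(coords, labels) {
  m <- as.matrix(coords)
  labels <- as.character(labels)
  if (nrow(m) != length(labels)) stop("coords and labels lengths differ")
  if (length(unique(labels)) < 2L) stop("need at least two clades")
  d <- as.matrix(dist(m))
  s <- vapply(seq_len(nrow(m)), function(i) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (length(own) == 0L) return(0)     # singleton clade
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(lb)
      mean(d[i, labels == lb]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
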