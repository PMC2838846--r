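# Full-pipeline orchestration: classify -> domains -> stats -> PCA.
#
# A run is a pure function of (inputs, config): reports carry no timestamps
# (those live only in the run log), so reruns with the same inputs and config
# are byte-identical.

#' Assemble a run configuration
#'
#' @param proteome_dir Directory with one `<abbreviation>.fasta` per species.
#' @param group_library Directory of kinase-group model JSON files.
#' @param domain_library Directory of domain model JSON files.
#' @param species_table Path to the species metadata TSV.
#' @param out_dir Output directory for all reports.
#' @param kinase_cutoff,domain_threshold Bit-score cutoffs.
#' @param pca_prevalence,pca_center,pca_scale PCA parameters.
#' @param wilcoxon_clades Length-2 character vector of clade labels to
#'   compare by kinome density, or `NULL` for the two most frequent labels.
#' @param wilcoxon_exact_limit Exact-p sample-size limit.
#' @param seed Integer seed recorded in the config (the analysis itself is
#'   deterministic; the seed matters when the config drives simulation).
#' @return A `run_config` list.
#' @export
run_config <- function(proteome_dir, group_library, domain_library,
                       species_table, out_dir,
                       kinase_cutoff = 20, domain_threshold = 20,
                       pca_prevalence = 0.5, pca_center = TRUE,
                       pca_scale = FALSE, wilcoxon_clades = NULL,
                       wilcoxon_exact_limit = 25L, seed = 1L) {
  structure(list(
    paths = list(proteome_dir = proteome_dir, group_library = group_library,
                 domain_library = domain_library,
                 species_table = species_table, out_dir = out_dir),
    cutoffs = list(kinase_bits = kinase_cutoff, domain_bits = domain_threshold),
    pca = list(prevalence = pca_prevalence, center = pca_center,
               scale = pca_scale),
    wilcoxon = list(clades = wilcoxon_clades, exact_limit = wilcoxon_exact_limit),
    seed = seed,
    version = as.character(utils::packageVersion("kinomeprofiler"))
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.finite(x), formatC(x, digits = digits, format = "f"), "")
}

write_tsv_num <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]], digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full kinome analysis pipeline
#'
#' Stages run in order: kinase extraction/classification per species, domain
#' scan of the called kinases, cohort statistics (counts, normalized
#' frequencies, kinome density, rank-sum test between two clades), and
#' prevalence-filtered domain-frequency PCA. Every stage's TSV/JSON report is
#' written under `config$paths$out_dir`, together with a copy of the config
#' and a run log with per-stage counts. Any stage failure aborts with the
#' stage name and the offending input.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory stage results and the report
#'   paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$paths$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logf <- file.path(out, "run.log")
  cat(sprintf("kinomeprofiler %s run started %s\n", config$version,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = logf)
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  species <- stage("inputs", load_species_table(config$paths$species_table))
  glib <- stage("inputs", read_library(config$paths$group_library,
                                       as_group_library = TRUE))
  dlib <- stage("inputs", read_library(config$paths$domain_library))
  write_run_config(config, file.path(out, "config.yaml"))

  kinomes <- list(); inventories <- list()
  for (i in seq_len(nrow(species))) {
    ab <- species$abbreviation[i]
    fa <- file.path(config$paths$proteome_dir, paste0(ab, ".fasta"))
    proteome <- stage("classify", {
      if (!file.exists(fa)) stop("missing proteome FASTA: ", fa)
      read_fasta(fa)
    })
    kin <- stage("classify",
                 extract_kinome(proteome, species[i, ], glib,
                                cutoff = config$cutoffs$kinase_bits))
    write_kinome_tsv(kin, file.path(out, paste0("kinome_", ab, ".tsv")))
    logmsg("classify %s: %d kinases / %d proteins", ab, nrow(kin$calls),
           kin$proteome_size)
    kin_seqs <- as.character(proteome[kin$calls$protein_id])
    inv <- stage("domains",
                 scan_domains(setNames(kin_seqs, kin$calls$protein_id), dlib,
                              threshold = config$cutoffs$domain_bits))
    write_domain_hits_tsv(inv, file.path(out, paste0("domains_", ab, ".tsv")))
    logmsg("domains %s: %d hits of %d types", ab, nrow(inv$hits),
           length(inv$per_type_counts))
    kinomes[[ab]] <- kin
    inventories[[ab]] <- inv
  }

  summaries <- stage("stats", lapply(kinomes, summarize_kinome))
  tables <- stage("stats", cohort_table(summaries))
  write_tsv_num(tables$counts, file.path(out, "counts.tsv"))
  write_tsv_num(tables$frequencies, file.path(out, "frequencies.tsv"))
  write_tsv_num(tables$densities, file.path(out, "density.tsv"))
  write_tsv_num(tables$clade_means, file.path(out, "clade_means.tsv"))

  clades <- config$wilcoxon$clades
  if (is.null(clades)) {
    tab <- sort(table(species$clade_label), decreasing = TRUE)
    clades <- names(tab)[seq_len(min(2, length(tab)))]
  }
  wres <- NULL
  if (length(clades) == 2 && length(unique(species$clade_label)) >= 2) {
    wres <- stage("stats",
                  compare_density(tables$densities, clades[1], clades[2],
                                  exact_limit = config$wilcoxon$exact_limit))
    jsonlite::write_json(
      list(clade_a = clades[1], clade_b = clades[2],
           U_statistic = wres$U_statistic, p_value = wres$p_value,
           method = wres$method, two_sided = wres$two_sided),
      file.path(out, "wilcoxon.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    logmsg("stats: density %s vs %s, U = %g, p = %g", clades[1], clades[2],
           wres$U_statistic, wres$p_value)
  }

  mat <- stage("pca", build_frequency_matrix(inventories,
                                             config$pca$prevalence))
  pres <- stage("pca", pca_domains(mat, center = config$pca$center,
                                   scale = config$pca$scale))
  proj <- stage("pca", project3(pres, species))
  sep <- stage("pca", if (length(unique(proj$clade_label)) >= 2)
    cluster_separation(proj[, c("PC1", "PC2", "PC3")], proj$clade_label)
    else NA_real_)
  write_tsv_num(data.frame(abbreviation = rownames(mat), mat,
                           check.names = FALSE, stringsAsFactors = FALSE),
                file.path(out, "pca_matrix.tsv"))
  write_tsv_num(proj, file.path(out, "pca_scores.tsv"))
  write_tsv_num(data.frame(
    component = paste0("PC", seq_along(pres$explained_variance_fraction)),
    explained_variance_fraction = pres$explained_variance_fraction,
    stringsAsFactors = FALSE), file.path(out, "pca_variance.tsv"))
  logmsg("pca: %d species x %d domain types, separation %.3f", nrow(mat),
         ncol(mat), sep)
  logmsg("run finished %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  invisible(list(out_dir = out, kinomes = kinomes, inventories = inventories,
                 summaries = summaries, tables = tables, wilcoxon = wres,
                 matrix = mat, pca = pres, projection = proj,
                 cluster_separation = sep))
}

#' Export per-group kinase FASTA files
#'
#' Writes one FASTA per kinase group pooling the called kinases of all
#' species, the input an external alignment/phylogeny stage would consume.
#'
#' @param kinomes Named list of `kinome` objects (abbreviation -> kinome).
#' @param proteome_dir Directory with the `<abbreviation>.fasta` proteomes.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_group_fastas <- function(kinomes, proteome_dir, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pooled <- list()
  for (ab in names(kinomes)) {
    kin <- kinomes[[ab]]
    proteome <- read_fasta(file.path(proteome_dir, paste0(ab, ".fasta")))
    for (g in unique(kin$calls$group)) {
      ids <- kin$calls$protein_id[kin$calls$group == g]
      pooled[[g]] <- c(pooled[[g]], setNames(as.character(proteome[ids]), ids))
    }
  }
  paths <- character(0)
  for (g in names(pooled)) {
    p <- file.path(out_dir, paste0("kinases_", g, ".fasta"))
    write_fasta(Biostrings::AAStringSet(pooled[[g]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
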