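# Synthetic fixtures with full ground truth: toy kinase-group and domain HMM
# libraries, proteomes with planted kinases, and multi-species cohorts with
# clade-specific structure. Every generator is deterministic under its seed.

# 14 commonly present accessory domain types (core of the prevalence filter)
CORE_ACCESSORY <- c("FHA", "FATC", "FAT", "HATPase_c", "C1_1", "PBD", "HEAT",
                    "POLO_box", "Rapamycin_bind", "HR1", "PH", "SH3_1",
                    "WD40", "TPR_1")
# 19 rare accessory types, planted in only a few species each
RARE_ACCESSORY <- c("TPP_enzyme_C", "Fungal_trans", "CNH", "RCC1",
                    paste0("RARE_", sprintf("%02d", 5:19)))

# emission weight on the consensus residue that yields a per-column
# total-variation distance of `divergence` between models with different
# consensus residues (remaining mass spread evenly over the other 19)
consensus_weight <- function(divergence) {
  stopifnot(divergence > 0, divergence <= 1)
  (19 * divergence + 1) / 20
}

# standard toy transition table: mostly match-to-match with light indels
toy_transitions <- function(L) {
  tr <- matrix(0, L + 1, 7, dimnames = list(NULL, TRANSITION_COLS))
  tr[1:L, c("MM", "MI", "MD")] <- rep(c(0.96, 0.02, 0.02), each = L)
  tr[1:L, c("IM", "II")] <- rep(c(0.8, 0.2), each = L)
  tr[1:L, c("DM", "DD")] <- rep(c(0.8, 0.2), each = L)
  tr[1, c("DM", "DD")] <- c(1, 0)        # no D_0 state
  tr[L + 1, ] <- final_node_transitions()
  tr
}

# build one toy model around a consensus index vector
toy_model <- function(name, group, consensus, w) {
  L <- length(consensus)
  me <- matrix((1 - w) / 19, L, 20, dimnames = list(NULL, AA20))
  me[cbind(seq_len(L), consensus)] <- w
  ie <- matrix(1 / 20, L + 1, 20)
  profile_hmm(name = name, group = group, match_emissions = me,
              insert_emissions = ie, transitions = toy_transitions(L),
              null_model = rep(1 / 20, 20), alignment_mode = "local")
}

#' Consensus sequence of a profile HMM
#'
#' @param hmm A `profile_hmm`.
#' @return The string of most probable match-state residues.
#' @export
model_consensus <- function(hmm) {
  paste(AA20[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

#' Generate a toy kinase-group HMM library
#'
#' One model per group. At each model position the groups receive mutually
#' distinct consensus residues (a random assignment without replacement), so
#' pairwise consensus identity is 0% and the per-column total-variation
#' distance between any two group emission profiles equals `divergence`.
#'
#' @param n_groups Number of groups (default 12, the full canonical set).
#' @param model_length Number of match states per model.
#' @param divergence Per-column total-variation separation in `(0, 1]`.
#' @param seed Integer seed; same seed, same library.
#' @return A `group_library`.
#' @export
make_group_library <- function(n_groups = 12, model_length = 40,
                               divergence = 0.9, seed = 1) {
  if (n_groups < 1 || n_groups > 12)
    stop("n_groups must be between 1 and 12")
  if (n_groups > 20) stop("cannot assign distinct consensus residues")
  w <- consensus_weight(divergence)
  groups <- KINASE_GROUPS[seq_len(n_groups)]
  with_seed(seed, {
    cons <- vapply(seq_len(model_length), function(i) sample(20L, n_groups),
                   integer(n_groups))
    cons <- matrix(cons, nrow = n_groups)  # groups x positions
    models <- lapply(seq_len(n_groups), function(g)
      toy_model(paste0(groups[g], "_m1"), groups[g], cons[g, ], w))
    group_library(models)
  })
}

#' Generate a toy domain HMM library
#'
#' Models are named after the seven catalytic kinase domain types plus
#' accessory types (common real accessory names first, then synthetic ones).
#' Consensus residues are drawn independently per model, so expected pairwise
#' consensus identity is 5%.
#'
#' @param n_catalytic Number of catalytic models (up to 7, default 7).
#' @param n_accessory Number of accessory models (default 33, giving the
#'   40-type toy census).
#' @param model_length Match states per model.
#' @param divergence Consensus emission separation, as in
#'   [make_group_library()].
#' @param seed Integer seed.
#' @return List of `profile_hmm` (class `model_library`); catalytic status is
#'   implied by the names (see [CATALYTIC_DOMAINS]).
#' @export
make_domain_library <- function(n_catalytic = 7, n_accessory = 33,
                                model_length = 30, divergence = 0.9,
                                seed = 1) {
  if (n_catalytic < 0 || n_catalytic > 7) stop("n_catalytic must be in 0..7")
  acc_names <- c(CORE_ACCESSORY, RARE_ACCESSORY)
  if (n_accessory > length(acc_names))
    acc_names <- c(acc_names, paste0("ACC_", sprintf(
      "%02d", seq_len(n_accessory - length(acc_names)))))
  nms <- c(CATALYTIC_DOMAINS[seq_len(n_catalytic)],
           acc_names[seq_len(n_accessory)])
  w <- consensus_weight(divergence)
  with_seed(seed, {
    models <- lapply(nms, function(nm)
      toy_model(nm, NA_character_, sample(20L, model_length, replace = TRUE), w))
    structure(setNames(models, nms), class = "model_library")
  })
}

# sample a sequence from the match states of a model (consensus walk with
# emission noise: each residue drawn from the match emission distribution)
sample_segment <- function(hmm) {
  paste(vapply(seq_len(hmm$L), function(k)
    sample(AA20, 1, prob = hmm$match_emissions[k, ]), character(1)),
    collapse = "")
}

sample_null <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Sample a synthetic proteome with planted kinases
#'
#' Planted kinases are match-state samples from group models embedded in
#' null-model flanks; background sequences are pure null-model. Group labels,
#' planted coordinates and background status are returned as ground truth.
#'
#' @param library A `group_library`.
#' @param n_kinases Number of planted kinases.
#' @param n_background Number of background sequences.
#' @param group_weights Sampling weights over the library's groups (default
#'   uniform).
#' @param seed Integer seed.
#' @param flank Range of null flank lengths on each side of a planted
#'   segment.
#' @param background_length Range of background sequence lengths.
#' @return List with `proteome` (an `AAStringSet`) and `truth` (data.frame
#'   `protein_id`, `label` — a group name or `"background"` — and the planted
#'   segment `start`/`end`, NA for background).
#' @export
sample_proteome <- function(library, n_kinases = 40, n_background = 400,
                            group_weights = NULL, seed = 1,
                            flank = c(15, 40), background_length = c(80, 200)) {
  stopifnot(inherits(library, "group_library"))
  groups <- vapply(library$models, `[[`, character(1), "group")
  by_group <- split(library$models, groups)
  glev <- names(by_group)
  if (is.null(group_weights)) group_weights <- rep(1, length(glev))
  with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    labels <- character(0); starts <- integer(0); ends <- integer(0)
    if (n_kinases > 0) {
      glab <- sample(glev, n_kinases, replace = TRUE, prob = group_weights)
      for (i in seq_len(n_kinases)) {
        mods <- by_group[[glab[i]]]
        m <- mods[[sample.int(length(mods), 1)]]
        f1 <- sample(flank[1]:flank[2], 1)
        f2 <- sample(flank[1]:flank[2], 1)
        seg <- sample_segment(m)
        seqs <- c(seqs, paste0(sample_null(f1), seg, sample_null(f2)))
        ids <- c(ids, sprintf("kin%04d", i))
        labels <- c(labels, glab[i])
        starts <- c(starts, f1 + 1L); ends <- c(ends, f1 + nchar(seg))
      }
    }
    if (n_background > 0) {
      for (i in seq_len(n_background)) {
        n <- sample(background_length[1]:background_length[2], 1)
        seqs <- c(seqs, sample_null(n))
        ids <- c(ids, sprintf("bg%04d", i))
        labels <- c(labels, "background")
        starts <- c(starts, NA_integer_); ends <- c(ends, NA_integer_)
      }
    }
    proteome <- Biostrings::AAStringSet(setNames(seqs, ids))
    S4Vectors::mcols(proteome)$description <- rep("", length(proteome))
    list(proteome = proteome,
         truth = data.frame(protein_id = ids, label = labels, start = starts,
                            end = ends, stringsAsFactors = FALSE))
  })
}

#' Default two-clade cohort design
#'
#' The study conditions of the synthetic cohort: two clades of 8 species;
#' clade kinome-density means of 0.5% and 1.2% (SD 0.1) around 2000
#' background proteins per proteome; a shared, realistic kinase group profile
#' (AGC ~20%, CAMK ~30%, CMGC ~30%, STE ~8%, RGC 0); a Pkinase-dominated
#' catalytic domain profile; clade-specific accessory-domain profiles with a
#' total-variation separation of 0.6 over the 14 common accessory types; a
#' mean of 2 sampled accessory domains per kinase; 21 core domain types
#' guaranteed present in every species and 19 rare types planted in 3 species
#' each, so exactly 21 of the 40 types survive the half-prevalence filter.
#'
#' @param seed Integer seed stored in the design.
#' @param n_species_per_clade,background_per_proteome,accessory_per_kinase
#'   Overridable scale parameters.
#' @return A `cohort_design` list.
#' @export
default_cohort_design <- function(seed = 1, n_species_per_clade = 8,
                                  background_per_proteome = 2000,
                                  accessory_per_kinase = 2) {
  gp <- setNames(c(20, 0.2, 30, 4, 30, 2, 3, 0, 1.5, 8, 0.3, 1) / 100,
                 KINASE_GROUPS)
  cat_p <- setNames(c(0.87, 0.06, 0.03, 0.025, 0.01, 0.004, 0.001),
                    CATALYTIC_DOMAINS)
  accA <- setNames(rep(c(1.6, 0.4) / 14, each = 7), CORE_ACCESSORY)
  accB <- setNames(rep(c(0.4, 1.6) / 14, each = 7), CORE_ACCESSORY)
  structure(list(
    clades = data.frame(
      label = c("CladeA", "CladeB"),
      n_species = c(n_species_per_clade, n_species_per_clade),
      density_mean = c(0.5, 1.2),        # percent
      density_sd = c(0.1, 0.1),
      stringsAsFactors = FALSE),
    group_profiles = list(CladeA = gp, CladeB = gp),
    catalytic_profiles = list(CladeA = cat_p, CladeB = cat_p),
    accessory_profiles = list(CladeA = accA, CladeB = accB),
    accessory_per_kinase = accessory_per_kinase,
    background_per_proteome = background_per_proteome,
    background_length = c(80, 200),
    flank = c(15, 40),
    spacer = c(5, 15),
    core_domains = c(CATALYTIC_DOMAINS, CORE_ACCESSORY),
    rare_domains = RARE_ACCESSORY,
    rare_species_per_domain = 3,
    model_length_group = 40,
    model_length_domain = 30,
    divergence = 0.9,
    seed = seed
  ), class = "cohort_design")
}

# assemble one kinase sequence from planted segments; returns sequence plus
# 1-based coordinates of each planted domain segment
assemble_kinase <- function(group_model, domain_models, domain_names, design) {
  rng <- function(r) sample(r[1]:r[2], 1)
  parts <- sample_null(rng(design$flank))
  seq <- parts
  pos <- nchar(seq)
  seg <- sample_segment(group_model)
  group_start <- pos + 1L
  seq <- paste0(seq, seg)
  pos <- nchar(seq)
  group_end <- pos
  dstart <- integer(length(domain_names)); dend <- integer(length(domain_names))
  for (i in seq_along(domain_names)) {
    sp <- sample_null(rng(design$spacer))
    seg <- sample_segment(domain_models[[domain_names[i]]])
    dstart[i] <- pos + nchar(sp) + 1L
    seq <- paste0(seq, sp, seg)
    pos <- nchar(seq)
    dend[i] <- pos
  }
  seq <- paste0(seq, sample_null(rng(design$flank)))
  list(seq = seq, group_start = group_start, group_end = group_end,
       domains = data.frame(domain_name = domain_names, start = dstart,
                            end = dend, stringsAsFactors = FALSE))
}

#' Generate a synthetic multi-species cohort
#'
#' Emits, under `dir`: one proteome FASTA and one ground-truth JSON sidecar
#' per species, the species metadata table, and the group and domain model
#' libraries. Per-species kinase counts follow the clade density
#' distributions; kinase group labels, catalytic domains and sampled
#' accessory domains follow the clade profiles; the design's core domain
#' types are guaranteed present in every species and its rare types are
#' planted in a fixed small number of species, so the half-prevalence filter
#' has a known outcome.
#'
#' @param design A `cohort_design` (see [default_cohort_design()]).
#' @param dir Output directory (created; must not already contain a cohort).
#' @return Invisibly, a list with `dir`, `species` (the table), `truth`
#'   (per-species ground truth) and the library directories.
#' @export
make_cohort <- function(design, dir) {
  stopifnot(inherits(design, "cohort_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  glib <- make_group_library(n_groups = 12,
                             model_length = design$model_length_group,
                             divergence = design$divergence,
                             seed = design$seed)
  dlib <- make_domain_library(n_catalytic = 7, n_accessory = 33,
                              model_length = design$model_length_domain,
                              divergence = design$divergence,
                              seed = design$seed + 1)
  write_library(glib$models, file.path(dir, "group_library"))
  write_library(dlib, file.path(dir, "domain_library"))

  n_total <- sum(design$clades$n_species)
  clade_of <- rep(design$clades$label, design$clades$n_species)
  abbrevs <- sprintf("sp%02d_%s", seq_len(n_total), tolower(clade_of))
  # deterministic rare-domain placement: domain r in species r, r+1, r+2 (mod n)
  rare_map <- lapply(seq_along(design$rare_domains), function(r)
    ((r - 1 + seq_len(design$rare_species_per_domain) - 1) %% n_total) + 1)

  species <- data.frame(name = paste("Synthetic species", seq_len(n_total)),
                        abbreviation = abbrevs,
                        phylum = "Synthetica",
                        subphylum = clade_of,
                        clade_label = clade_of,
                        stringsAsFactors = FALSE)
  truth <- vector("list", n_total)
  names(truth) <- abbrevs

  with_seed(design$seed + 2, {
    for (s in seq_len(n_total)) {
      cl <- clade_of[s]
      ci <- match(cl, design$clades$label)
      d <- -1
      while (d <= 0.05)
        d <- rnorm(1, design$clades$density_mean[ci], design$clades$density_sd[ci])
      B <- design$background_per_proteome
      n_k <- max(1L, as.integer(round(B * (d / 100) / (1 - d / 100))))
      glab <- sample(names(design$group_profiles[[cl]]), n_k, replace = TRUE,
                     prob = design$group_profiles[[cl]])
      # domain architectures
      archs <- lapply(seq_len(n_k), function(i) {
        cat_d <- sample(names(design$catalytic_profiles[[cl]]), 1,
                        prob = design$catalytic_profiles[[cl]])
        n_acc <- rpois(1, design$accessory_per_kinase)
        acc_d <- if (n_acc > 0)
          sample(names(design$accessory_profiles[[cl]]), n_acc, replace = TRUE,
                 prob = design$accessory_profiles[[cl]]) else character(0)
        c(cat_d, acc_d)
      })
      # guarantee every core domain type at least once per species
      missing_core <- setdiff(design$core_domains, unlist(archs))
      for (j in seq_along(missing_core)) {
        k <- ((j - 1) %% n_k) + 1
        archs[[k]] <- c(archs[[k]], missing_core[j])
      }
      # plant rare domains assigned to this species
      rare_here <- design$rare_domains[vapply(rare_map, function(v) s %in% v,
                                              logical(1))]
      for (j in seq_along(rare_here)) {
        k <- ((j - 1) %% n_k) + 1
        archs[[k]] <- c(archs[[k]], rare_here[j])
      }
      ids <- c(sprintf("%s_kin%04d", abbrevs[s], seq_len(n_k)),
               sprintf("%s_bg%04d", abbrevs[s], seq_len(B)))
      seqs <- character(n_k + B)
      dom_truth <- list()
      for (i in seq_len(n_k)) {
        gm <- glib$models[[paste0(glab[i], "_m1")]]
        asm <- assemble_kinase(gm, dlib, archs[[i]], design)
        seqs[i] <- asm$seq
        dt <- asm$domains
        if (nrow(dt) > 0) dt$kinase_id <- ids[i]
        dom_truth[[i]] <- dt
      }
      for (i in seq_len(B))
        seqs[n_k + i] <- sample_null(sample(
          design$background_length[1]:design$background_length[2], 1))
      proteome <- Biostrings::AAStringSet(setNames(seqs, ids))
      write_fasta(proteome, file.path(dir, paste0(abbrevs[s], ".fasta")))
      tr <- list(
        abbreviation = abbrevs[s], clade = cl, density_true = d,
        n_kinases = n_k, proteome_size = n_k + B,
        proteins = data.frame(protein_id = ids,
                              label = c(glab, rep("background", B)),
                              stringsAsFactors = FALSE),
        domains = do.call(rbind, dom_truth))
      jsonlite::write_json(tr, file.path(dir, paste0(abbrevs[s], ".truth.json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      truth[[s]] <- tr
    }
  })
  write_species_table(species, file.path(dir, "species_table.tsv"))
  yaml::write_yaml(unclass_design(design), file.path(dir, "design.yaml"))
  invisible(list(dir = dir, species = species, truth = truth,
                 group_library = file.path(dir, "group_library"),
                 domain_library = file.path(dir, "domain_library")))
}

# design -> plain list for YAML serialization
unclass_design <- function(design) {
  d <- unclass(design)
  d$clades <- as.list(d$clades)
  d
}
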