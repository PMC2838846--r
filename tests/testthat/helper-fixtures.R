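# Shared fixtures for the test suite. Everything is generated in code under
# fixed seeds; nothing is read from disk.

# internal objects exercised directly by the suite
empty_hits <- kinomeprofiler:::empty_hits
CORE_ACCESSORY <- kinomeprofiler:::CORE_ACCESSORY
RARE_ACCESSORY <- kinomeprofiler:::RARE_ACCESSORY

# random valid profile HMM (for round-trip and property tests)
random_phmm <- function(L, seed, name = "rnd", alignment_mode = "local") {
  set.seed(seed)
  rdist <- function(n) { x <- runif(n, 0.05, 1); x / sum(x) }
  me <- t(vapply(seq_len(L), function(i) rdist(20), numeric(20)))
  ie <- t(vapply(seq_len(L + 1), function(i) rdist(20), numeric(20)))
  tr <- matrix(0, L + 1, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (r in seq_len(L)) {
    tr[r, c("MM", "MI", "MD")] <- rdist(3)
    tr[r, c("IM", "II")] <- rdist(2)
    tr[r, c("DM", "DD")] <- rdist(2)
  }
  tr[1, c("DM", "DD")] <- c(1, 0)
  tr[L + 1, ] <- c(1, 0, 0, 1, 0, 1, 0)
  profile_hmm(name, NA_character_, me, ie, tr, rdist(20),
              alignment_mode = alignment_mode)
}

# small high-margin group library shared across tests
test_group_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- make_group_library(model_length = 40,
                                                 divergence = 0.9, seed = 11)
    lib
  }
})

test_domain_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- make_domain_library(seed = 13)
    lib
  }
})

# compact two-clade cohort for fast pipeline tests (the full-size default
# design is exercised in the acceptance suite)
small_cohort_design <- function(seed = 5) {
  default_cohort_design(seed = seed, n_species_per_clade = 3,
                        background_per_proteome = 120,
                        accessory_per_kinase = 2)
}

make_cohort_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "kp_small_cohort")
      if (dir.exists(dir)) unlink(dir, recursive = TRUE)
      cache <<- make_cohort(small_cohort_design(), dir)
    }
    cache
  }
})
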