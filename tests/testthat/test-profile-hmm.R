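test_that("alignment-derived models have sane structure and probabilities", {
  hmm <- build_from_alignment(rep("ACDE", 4), name = "toy")
  expect_equal(hmm$L, 4L)
  for (k in 1:4)
    expect_equal(unname(which.max(hmm$match_emissions[k, ])),
                 match(substr("ACDE", k, k), c("A", "C", "D", "E", "F", "G",
                                               "H", "I", "K", "L", "M", "N",
                                               "P", "Q", "R", "S", "T", "V",
                                               "W", "Y")))
  expect_equal(rowSums(hmm$match_emissions), rep(1, 4), tolerance = 1e-12)
  expect_equal(rowSums(hmm$insert_emissions), rep(1, 5), tolerance = 1e-12)

  # an all-gap column is not a match state under the default rule, and a
  # column with gap fraction exactly at the rule is an insert column too
  hmm2 <- build_from_alignment(c("A-CE", "A-CE", "A--E", "A-CE"))
  expect_equal(hmm2$L, 3L)
  hmm3 <- build_from_alignment(c("AC", "A-", "AC", "A-"))
  expect_equal(hmm3$L, 1L)

  expect_error(build_from_alignment(character(0)), "empty")
  expect_error(build_from_alignment(c("AC", "ACD")), "unequal")
})

test_that("a null-equal deterministic model scores zero bits in glocal mode", {
  L <- 6
  tr <- matrix(0, L + 1, 7)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tr[, c("MM", "IM", "DM")] <- 1
  hmm <- profile_hmm("null-like", NA, matrix(1 / 20, L, 20),
                     matrix(1 / 20, L + 1, 20), tr, rep(1 / 20, 20), "glocal")
  expect_equal(viterbi_bit_score(hmm, "ACDEFG"), 0)
  expect_equal(forward_bit_score(hmm, "ACDEFG"), 0)
})

test_that("Viterbi and forward agree with brute-force path enumeration", {
  cases <- expand.grid(L = 1:3, n = 1:5, mode = c("local", "glocal"),
                       stringsAsFactors = FALSE)
  set.seed(31)
  alphabet <- c("A", "C", "D", "E")  # reduced test alphabet
  for (i in seq_len(nrow(cases))) {
    L <- cases$L[i]; n <- cases$n[i]; mode <- cases$mode[i]
    hmm <- random_phmm(L, seed = 100 + i)
    seq <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
    expect_equal(viterbi_bit_score(hmm, seq, mode = mode),
                 oracle_viterbi(hmm, seq, mode),
                 tolerance = 1e-6,
                 label = sprintf("viterbi L=%d n=%d %s", L, n, mode))
    expect_equal(forward_bit_score(hmm, seq, mode = mode),
                 oracle_forward(hmm, seq, mode),
                 tolerance = 1e-6,
                 label = sprintf("forward L=%d n=%d %s", L, n, mode))
  }
})

test_that("forward dominates Viterbi and equals it on a single-path model", {
  set.seed(17)
  for (i in 1:10) {
    hmm <- random_phmm(sample(2:5, 1), seed = 300 + i)
    seq <- paste(sample(c("A", "C", "D", "E", "G", "K"), sample(3:12, 1),
                        replace = TRUE), collapse = "")
    for (mode in c("local", "glocal"))
      expect_gte(forward_bit_score(hmm, seq, mode = mode) + 1e-9,
                 viterbi_bit_score(hmm, seq, mode = mode))
  }
  # degenerate single-path model: deterministic M->M chain, glocal, |seq| = L
  L <- 3
  tr <- matrix(0, L + 1, 7)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tr[, c("MM", "IM", "DM")] <- 1
  me <- matrix(0.01 / 19, L, 20); me[, 1] <- 0.81
  me <- me / rowSums(me)
  hmm <- profile_hmm("one-path", NA, me, matrix(1 / 20, L + 1, 20), tr,
                     rep(1 / 20, 20), "glocal")
  expect_equal(forward_bit_score(hmm, "AAA"), viterbi_bit_score(hmm, "AAA"),
               tolerance = 1e-9)
})

test_that("boosting the observed residue's match emission never lowers the score", {
  for (i in 1:5) {
    hmm <- random_phmm(4, seed = 400 + i)
    seq <- "CCCC"
    boosted <- hmm
    me <- boosted$match_emissions
    me[, "C"] <- me[, "C"] * 2
    boosted$match_emissions <- me / rowSums(me)
    for (mode in c("local", "glocal"))
      expect_gte(viterbi_bit_score(boosted, seq, mode = mode) + 1e-9,
                 viterbi_bit_score(hmm, seq, mode = mode))
  }
})

test_that("log-space scoring stays finite on very long sequences", {
  hmm <- test_group_library()$models[[1]]
  set.seed(5)
  seq <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                      10000, replace = TRUE), collapse = "")
  expect_true(is.finite(viterbi_bit_score(hmm, seq)))
  expect_true(is.finite(forward_bit_score(hmm, seq)))
})

test_that("local scores follow the null-flank convention exactly", {
  # flanking residues outside the fragment are null-scored: appending flanks
  # that cannot host a better fragment leaves the score unchanged
  hmm <- test_group_library()$models[[1]]
  core <- model_consensus(hmm)
  base <- viterbi_bit_score(hmm, core)
  # pick a flank residue with minimal emission everywhere in this model
  worst <- names(which.min(colSums(hmm$match_emissions[, 1:20])))
  flank <- paste(rep(worst, 30), collapse = "")
  expect_equal(viterbi_bit_score(hmm, paste0(flank, core, flank)), base,
               tolerance = 1e-9)
})

test_that("model JSON round-trips losslessly and rejects invalid files", {
  hmm <- random_phmm(7, seed = 55, name = "roundtrip")
  f <- withr::local_tempfile(fileext = ".json")
  write_model(hmm, f)
  back <- read_model(f)
  expect_equal(back$match_emissions, hmm$match_emissions,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$insert_emissions, hmm$insert_emissions,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$transitions, hmm$transitions,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(back$null_model), unname(hmm$null_model),
               tolerance = 1e-12)
  expect_identical(back$name, hmm$name)
  expect_identical(back$L, hmm$L)

  # corrupt an emission row so it sums to 0.5
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$match_emissions[1, ] <- obj$match_emissions[1, ] / 2
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(f), "sum to 1")
})

test_that("HMMER3 ASCII import recovers the model dimensions", {
  em <- paste(rep(sprintf("%.5f", 2.99573), 20), collapse = "  ")
  tr7 <- paste(rep("0.69315", 7), collapse = "  ")
  lines <- c(
    "HMMER3/f [3.4 | test]",
    "NAME  mini",
    "LENG  2",
    "ALPH  amino",
    paste("HMM", paste(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                       collapse = "   ")),
    "        m->m m->i m->d i->m i->i d->m d->d",
    paste("  COMPO", em),
    paste("        ", em),
    paste("        ", tr7),
    paste("      1 ", em),
    paste("        ", em),
    paste("        ", tr7),
    paste("      2 ", em),
    paste("        ", em),
    paste("         0.69315  0.69315  *  0.69315  0.69315  0.0  *"),
    "//")
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(lines, f)
  hmm <- read_hmmer3(f)
  expect_equal(hmm$L, 2L)
  expect_equal(hmm$name, "mini")
  expect_equal(rowSums(hmm$match_emissions), rep(1, 2), tolerance = 1e-9)
  expect_true(validate_profile_hmm(hmm) |> inherits("profile_hmm"))
})
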