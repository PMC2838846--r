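fake_kinome <- function(groups, proteome_size, abbreviation = "sp",
                        clade = "Clade") {
  structure(list(
    species = data.frame(abbreviation = abbreviation, clade_label = clade,
                         stringsAsFactors = FALSE),
    calls = data.frame(group = groups, stringsAsFactors = FALSE),
    proteome_size = proteome_size, cutoff = 20), class = "kinome")
}

test_that("kinome summaries report counts, frequencies and density", {
  kin <- fake_kinome(rep(c("AGC", "CAMK", "CMGC", "STE"), c(20, 30, 30, 20)),
                     proteome_size = 10000)
  s <- summarize_kinome(kin)
  expect_equal(s$total_kinases, 100L)
  expect_equal(unname(s$group_counts[c("AGC", "CAMK", "CMGC", "STE", "RGC")]),
               c(20L, 30L, 30L, 20L, 0L))
  expect_equal(unname(s$normalized_freq[c("AGC", "CAMK")]), c(20, 30))
  expect_equal(s$kinome_density, 1)
  expect_equal(sum(s$normalized_freq), 100, tolerance = 1e-9)
  expect_length(s$group_counts, 12)

  one <- summarize_kinome(fake_kinome("TK", 500))
  expect_equal(unname(one$normalized_freq["TK"]), 100)
  expect_equal(sum(one$normalized_freq), 100)
})

test_that("cohort tables preserve species order and average by clade", {
  s1 <- summarize_kinome(fake_kinome(rep("AGC", 10), 1000, "spA", "X"))
  s2 <- summarize_kinome(fake_kinome(rep("CMGC", 30), 1000, "spB", "Y"))
  s3 <- summarize_kinome(fake_kinome(rep("AGC", 20), 1000, "spC", "X"))
  tb <- cohort_table(list(s1, s2, s3))
  expect_equal(tb$counts$abbreviation, c("spA", "spB", "spC"))
  expect_equal(ncol(tb$frequencies), 2 + 12)
  expect_equal(sum(tb$counts$AGC), 30)
  cmx <- tb$clade_means[tb$clade_means$clade_label == "X", ]
  expect_equal(cmx$mean_kinome_size, 15)
  expect_equal(cmx$mean_density, 1.5)
  expect_equal(cmx$n_species, 2L)
  expect_equal(tb$densities$kinome_density, c(1, 3, 2))
})

test_that("the rank-sum test reproduces the textbook exact examples", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$U_statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  expect_true(r$two_sided)

  r2 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$p_value, 0.1, tolerance = 1e-12)

  tie <- wilcoxon_rank_sum(c(5, 5), c(5, 5))
  expect_equal(tie$p_value, 1)
  expect_equal(tie$method, "normal_approx")
})

test_that("the rank-sum p-value is symmetric in its arguments", {
  set.seed(8)
  for (i in 1:5) {
    x <- runif(6); y <- runif(4) + 0.2
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcoxon_rank_sum(y, x)$p_value, tolerance = 1e-12)
  }
})

test_that("exact p-values match full enumeration for small samples", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    v <- sample(1000, n + m)               # untied by construction
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    r <- wilcoxon_rank_sum(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_wilcoxon_exact(x, y), tolerance = 1e-12,
                 label = sprintf("n=%d m=%d", n, m))
  }
})

test_that("the exact/approximate switch follows ties and the size limit", {
  x <- seq(1, 26); y <- seq(26.5, 51.5)    # n = 26 > default limit
  expect_equal(wilcoxon_rank_sum(x, y)$method, "normal_approx")
  expect_equal(wilcoxon_rank_sum(x[1:25], y[1:25])$method, "exact")
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2), c(3, 4))$method, "normal_approx")
  expect_equal(wilcoxon_rank_sum(x[1:5], y[1:5], exact_limit = 4)$method,
               "normal_approx")
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("compare_density picks the requested clades from the table", {
  dens <- data.frame(abbreviation = letters[1:6],
                     clade_label = rep(c("X", "Y"), each = 3),
                     kinome_density = c(0.4, 0.5, 0.6, 1.1, 1.2, 1.3),
                     stringsAsFactors = FALSE)
  r <- compare_density(dens, "X", "Y")
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(attr(r, "clades"), c("X", "Y"))
  expect_error(compare_density(dens, "X", "Z"), "not found")
})
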