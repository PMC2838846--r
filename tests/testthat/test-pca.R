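inv_from_counts <- function(counts) {
  hits <- data.frame(kinase_id = "k",
                     domain_name = rep(names(counts), counts),
                     bit_score = 30, start = 1L, end = 10L,
                     stringsAsFactors = FALSE)
  domain_inventory(hits, n_kinases = 1)
}

test_that("the prevalence filter keeps 'at least half' exactly", {
  invs <- list(
    a = inv_from_counts(c(Pkinase = 3, FHA = 1, WD40 = 1)),
    b = inv_from_counts(c(Pkinase = 2, FHA = 1)),
    c = inv_from_counts(c(Pkinase = 4)),
    d = inv_from_counts(c(Pkinase = 1)))
  m <- build_frequency_matrix(invs)          # threshold 0.5
  expect_true("FHA" %in% colnames(m))        # 2 of 4 species: retained
  expect_false("WD40" %in% colnames(m))      # 1 of 4: dropped
  # frequencies use the species' total occurrences before filtering
  expect_equal(m["a", "Pkinase"], 100 * 3 / 5)
  expect_equal(m["a", "FHA"], 100 * 1 / 5)
  expect_equal(rownames(m), c("a", "b", "c", "d"))
  # columns ordered by descending pooled count
  expect_equal(colnames(m), c("Pkinase", "FHA"))
})

test_that("raising the prevalence threshold only drops columns", {
  invs <- list(
    a = inv_from_counts(c(Pkinase = 3, FHA = 1, WD40 = 1)),
    b = inv_from_counts(c(Pkinase = 2, FHA = 1, HEAT = 2)),
    c = inv_from_counts(c(Pkinase = 4, HEAT = 1)),
    d = inv_from_counts(c(Pkinase = 1, FHA = 2)))
  lo <- build_frequency_matrix(invs, prevalence_threshold = 0.5)
  hi <- build_frequency_matrix(invs, prevalence_threshold = 0.75)
  expect_true(all(colnames(hi) %in% colnames(lo)))
  expect_lte(ncol(hi), ncol(lo))
})

test_that("a species with no domains is flagged as a zero row", {
  invs <- list(a = inv_from_counts(c(Pkinase = 2)),
               b = domain_inventory(empty_hits(), n_kinases = 3))
  expect_warning(m <- build_frequency_matrix(invs), "zero domains")
  expect_equal(attr(m, "zero_rows"), "b")
  expect_equal(unname(m["b", ]), 0)
})

test_that("perfectly collinear rows put all variance on PC1", {
  m <- outer(1:5, c(2, -1, 0.5))            # rank-1 after centering
  p <- pca_domains(m)
  expect_equal(p$explained_variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("PCA agrees with an independent SVD/eigen oracle", {
  set.seed(42)
  m <- matrix(rnorm(6 * 4), 6, 4)
  rownames(m) <- paste0("s", 1:6)
  p <- pca_domains(m)
  # oracle: eigendecomposition of the covariance of the centered matrix
  mc <- scale(m, center = TRUE, scale = FALSE)
  eg <- eigen(cov(mc), symmetric = TRUE)
  k <- ncol(p$component_loadings)
  for (j in seq_len(k)) {
    v <- p$component_loadings[, j]; w <- eg$vectors[, j]
    expect_lt(min(sqrt(sum((v - w)^2)), sqrt(sum((v + w)^2))), 1e-8)
  }
  expect_equal(p$explained_variance_fraction,
               (eg$values / sum(eg$values))[seq_len(k)], tolerance = 1e-8)
  # scores are the centered data in the loading basis
  expect_equal(unname(p$scores), unname(mc %*% p$component_loadings),
               tolerance = 1e-8)
})

test_that("loadings are orthonormal and reconstruct the centered matrix", {
  set.seed(43)
  m <- matrix(runif(8 * 5), 8, 5)
  rownames(m) <- paste0("s", 1:8)
  p <- pca_domains(m)
  ld <- p$component_loadings
  expect_equal(unname(t(ld) %*% ld), diag(ncol(ld)), tolerance = 1e-10)
  mc <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(p$scores %*% t(ld)), unname(mc), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(p$explained_variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(p$explained_variance_fraction) <= 1e-12))
})

test_that("degenerate matrices are rejected", {
  flat <- matrix(5, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  expect_error(pca_domains(flat), "no variance")
  m <- matrix(c(1, 2, 3, 7, 7, 7), 3, 2,
              dimnames = list(paste0("s", 1:3), NULL))
  expect_error(pca_domains(m, scale = TRUE), "zero-variance")
  expect_error(pca_domains(m[1, , drop = FALSE]), ">= 2 rows")
})

test_that("3-D projection pads missing components with zeros, flagged", {
  m <- matrix(c(0, 1, 2, 0, 2, 4), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))   # rank 1
  sp <- data.frame(abbreviation = c("a", "b", "c"),
                   clade_label = c("X", "X", "Y"), stringsAsFactors = FALSE)
  p <- pca_domains(m)
  if (ncol(p$scores) < 3) {
    expect_warning(pr <- project3(p, sp), "padding")
    expect_true(attr(pr, "padded"))
    expect_equal(pr$PC3, rep(0, 3))
  }
  set.seed(44)
  m2 <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  sp2 <- data.frame(abbreviation = paste0("s", 1:5),
                    clade_label = rep(c("X", "Y"), c(3, 2)),
                    stringsAsFactors = FALSE)
  pr2 <- project3(pca_domains(m2), sp2)
  expect_equal(pr2$abbreviation, paste0("s", 1:5))
  expect_equal(pr2$clade_label, sp2$clade_label)
  expect_error(project3(pca_domains(m2), sp2[1:3, ]), "missing")
})

test_that("cluster separation is high for separated clouds, near zero shuffled", {
  set.seed(45)
  a <- matrix(rnorm(8 * 3, mean = 0, sd = 0.3), 8, 3)
  b <- matrix(rnorm(8 * 3, mean = 6, sd = 0.3), 8, 3)
  coords <- rbind(a, b)
  labels <- rep(c("X", "Y"), each = 8)
  expect_gt(cluster_separation(coords, labels), 0.8)
  # label permutation invariance of the rows
  ix <- sample(16)
  expect_equal(cluster_separation(coords[ix, ], labels[ix]),
               cluster_separation(coords, labels), tolerance = 1e-12)
  # random labels carry no structure on average
  shuffled <- vapply(1:20, function(i)
    cluster_separation(coords, sample(labels)), numeric(1))
  expect_lt(abs(mean(shuffled)), 0.2)
  expect_error(cluster_separation(coords, rep("X", 16)), "two clades")
})
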