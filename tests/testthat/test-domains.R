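plant <- function(models, names, seed = 1, flank = 20, spacer = 8) {
  set.seed(seed)
  null <- function(n) paste(sample(c("A", "C", "D", "E", "G", "K", "L", "S"),
                                   n, replace = TRUE), collapse = "")
  seq <- null(flank)
  coords <- data.frame(domain_name = names, start = NA_integer_,
                       end = NA_integer_)
  for (i in seq_along(names)) {
    seg <- model_consensus(models[[names[i]]])
    coords$start[i] <- nchar(seq) + 1L
    seq <- paste0(seq, seg)
    coords$end[i] <- nchar(seq)
    if (i < length(names)) seq <- paste0(seq, null(spacer))
  }
  list(seq = paste0(seq, null(flank)), coords = coords)
}

test_that("a planted catalytic domain is found with exact coordinates", {
  lib <- test_domain_library()
  px <- plant(lib, "Pkinase", seed = 3)
  inv <- scan_domains(setNames(px$seq, "k1"), lib)
  hit <- inv$hits[inv$hits$domain_name == "Pkinase", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, px$coords$start[1])
  expect_equal(hit$end, px$coords$end[1])
  expect_true(hit$is_catalytic)
  expect_gt(hit$bit_score, 20)
})

test_that("pure null sequences produce at most one spurious hit in 100", {
  lib <- test_domain_library()
  set.seed(9)
  seqs <- setNames(vapply(1:100, function(i)
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 sample(80:200, 1), replace = TRUE), collapse = ""),
    character(1)), sprintf("n%03d", 1:100))
  inv <- scan_domains(seqs, lib)
  expect_lte(nrow(inv$hits), 1L)
})

test_that("catalytic plus accessory segments give two disjoint flagged hits", {
  lib <- test_domain_library()
  px <- plant(lib, c("Pkinase", "FHA"), seed = 5)
  inv <- scan_domains(setNames(px$seq, "k1"), lib)
  hits <- inv$hits[inv$hits$domain_name %in% c("Pkinase", "FHA"), ]
  expect_equal(sort(hits$domain_name), c("FHA", "Pkinase"))
  expect_equal(unname(hits$is_catalytic[order(hits$domain_name)]),
               c(FALSE, TRUE))
  h1 <- hits[1, ]; h2 <- hits[2, ]
  expect_true(h1$end < h2$start || h2$end < h1$start)
})

test_that("repeated copies of one domain on one kinase all count", {
  lib <- test_domain_library()
  px <- plant(lib, c("Pkinase", "Pkinase"), seed = 7)
  inv <- scan_domains(setNames(px$seq, "k1"), lib)
  expect_equal(unname(inv$per_type_counts["Pkinase"]), 2L)
  pk <- inv$hits[inv$hits$domain_name == "Pkinase", ]
  expect_equal(sort(pk$start), px$coords$start)
})

test_that("domain summaries count catalytic vs accessory correctly", {
  # 3 kinases with hits {Pkinase, Pkinase, FHA}
  s <- domain_summary_from_counts(c(Pkinase = 2L, FHA = 1L), n_kinases = 3)
  expect_equal(s$total_domains, 3L)
  expect_equal(s$catalytic_count, 2L)
  expect_equal(s$accessory_count, 1L)
  expect_equal(s$n_domain_types, 2L)
  expect_equal(s$singleton_types, "FHA")
  expect_equal(s$mean_domains_per_kinase, 1)
  expect_equal(s$mean_catalytic_per_kinase_display, 0.7)
})

test_that("empty inventories summarize to zeros and zero kinases are guarded", {
  inv <- scan_domains(character(0), test_domain_library())
  expect_equal(inv$n_kinases, 0L)
  expect_equal(nrow(inv$hits), 0L)
  s <- summarize_domains(domain_inventory(empty_hits(), n_kinases = 5))
  expect_equal(s$total_domains, 0L)
  expect_equal(s$mean_domains_per_kinase, 0)
  expect_equal(length(s$singleton_types), 0L)
  bad <- domain_inventory(
    data.frame(kinase_id = "k", domain_name = "Pkinase", bit_score = 30,
               start = 1L, end = 10L, stringsAsFactors = FALSE),
    n_kinases = 0)
  expect_error(summarize_domains(bad), "zero kinases")
})

test_that("prevalence is the fraction of species carrying each type", {
  mk <- function(types) domain_inventory(
    data.frame(kinase_id = "k", domain_name = types,
               bit_score = 30, start = 1L, end = 10L,
               stringsAsFactors = FALSE), n_kinases = 1)
  invs <- list(a = mk(c("Pkinase", "FHA")), b = mk("Pkinase"),
               c = mk(c("Pkinase", "FHA", "WD40")), d = mk("Pkinase"))
  prev <- domain_prevalence(invs)
  expect_equal(unname(prev["Pkinase"]), 1)
  expect_equal(unname(prev["FHA"]), 0.5)
  expect_equal(unname(prev["WD40"]), 0.25)
})

test_that("raising the threshold can only remove hits", {
  lib <- test_domain_library()
  px <- plant(lib, c("Pkinase", "FHA", "WD40"), seed = 11)
  h20 <- scan_domains(setNames(px$seq, "k1"), lib, threshold = 20)$hits
  h40 <- scan_domains(setNames(px$seq, "k1"), lib, threshold = 40)$hits
  key <- function(h) paste(h$kinase_id, h$domain_name, h$start, h$end)
  expect_true(all(key(h40) %in% key(h20)))
})

test_that("hit tables are invariant to the input sequence order", {
  lib <- test_domain_library()
  p1 <- plant(lib, c("Pkinase", "FHA"), seed = 13)
  p2 <- plant(lib, c("RIO1", "HEAT"), seed = 15)
  seqs <- c(ka = p1$seq, kb = p2$seq)
  inv_fwd <- scan_domains(seqs, lib)
  inv_rev <- scan_domains(rev(seqs), lib)
  expect_identical(inv_fwd$hits, inv_rev$hits)
  expect_identical(inv_fwd$per_type_counts, inv_rev$per_type_counts)
})
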