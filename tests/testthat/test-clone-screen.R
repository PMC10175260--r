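make_ct <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1L]], gene = r[[2L]], ct = as.numeric(r[[3L]]),
               stringsAsFactors = FALSE)
  }))
  ct_table(df, reference_gene = "RPPH1", calibrator_sample = "WTC")
}

test_that("delta-delta-Ct recovers hand-computed relative copy numbers", {
  tbl <- make_ct(list(
    list("clone", "TBX1", 27), list("clone", "RPPH1", 20),
    list("WTC", "TBX1", 26), list("WTC", "RPPH1", 20)))
  rcn <- relative_copy_number(tbl)
  expect_equal(rcn$rcn[rcn$sample == "clone" & rcn$gene == "TBX1"], 0.5)
  expect_equal(rcn$rcn[rcn$sample == "WTC" & rcn$gene == "TBX1"], 1.0)

  # replicates averaged before the delta chain
  tbl2 <- make_ct(list(
    list("clone", "TBX1", 26.9), list("clone", "TBX1", 27.1),
    list("clone", "RPPH1", 20),
    list("WTC", "TBX1", 26), list("WTC", "RPPH1", 20)))
  rcn2 <- relative_copy_number(tbl2)
  expect_equal(rcn2$rcn[rcn2$sample == "clone" & rcn2$gene == "TBX1"], 0.5)

  # a sample identical to the calibrator has RCN 1 everywhere
  tbl3 <- make_ct(list(
    list("c2", "TBX1", 26), list("c2", "RPPH1", 20),
    list("WTC", "TBX1", 26), list("WTC", "RPPH1", 20)))
  expect_true(all(relative_copy_number(tbl3)$rcn == 1))
})

test_that("the reference gene has RCN 1 for every sample, always", {
  set.seed(41)
  cn <- matrix(sample(c(1L, 2L), 20, replace = TRUE), nrow = 5,
               dimnames = list(paste0("s", 1:5), c("A", "B", "C", "D")))
  cn[1L, ] <- 2L
  tbl <- simulate_ct(cn, base_ct = c(A = 24, B = 25, C = 26, D = 27,
                                     RPPH1 = 20),
                     calibrator_sample = "s1", noise_sd = 0.3, seed = 42)
  rcn <- relative_copy_number(tbl)
  expect_true(all(rcn$rcn[rcn$gene == "RPPH1"] == 1))
})

test_that("missing cells raise an explicit error naming them", {
  df <- data.frame(sample = c("clone", "clone", "WTC"),
                   gene = c("TBX1", "RPPH1", "RPPH1"),
                   ct = c(27, 20, 20))
  tbl <- ct_table(df, calibrator_sample = "WTC")
  expect_error(relative_copy_number(tbl), "WTC/TBX1")
  expect_error(ct_table(df, reference_gene = "GAPDH",
                        calibrator_sample = "WTC"), "GAPDH")
  expect_error(ct_table(df, calibrator_sample = "nope"), "nope")
  expect_error(ct_table(transform(df, ct = c(27, -1, 20)),
                        calibrator_sample = "WTC"), "> 0")
})

test_that("clone calls follow the in-region / flanking thresholds", {
  rcn <- data.frame(
    sample = rep(c("del", "wt", "amb"), each = 2),
    gene = rep(c("TBX1", "CRKL"), 3),
    rcn = c(0.5, 1.0, 1.0, 1.0, 0.75, 1.0))
  calls <- classify_clones(rcn, "TBX1", "CRKL")
  got <- setNames(calls$call, calls$sample)
  expect_identical(got[c("del", "wt", "amb")],
                   c(del = "deletion", wt = "no_deletion",
                     amb = "ambiguous"))
  expect_error(classify_clones(rcn, character(0), "CRKL"), "non-empty")
  expect_error(classify_clones(rcn, "TBX1", "TBX1"), "disjoint")
  expect_error(classify_clones(rcn, "TBX1", "MAPK1"), "absent")
})

test_that("noise-free simulated screens are recovered exactly", {
  cn <- matrix(c(1L, 2L, 2L, 2L), nrow = 2,
               dimnames = list(c("clone1", "WTC"), c("TBX1", "CRKL")))
  tbl <- simulate_ct(cn, base_ct = c(TBX1 = 26, CRKL = 25, RPPH1 = 20),
                     calibrator_sample = "WTC", noise_sd = 0, seed = 1)
  rcn <- relative_copy_number(tbl)
  expect_identical(rcn$rcn[rcn$sample == "clone1" & rcn$gene == "TBX1"],
                   0.5)
  expect_true(all(rcn$rcn[rcn$sample == "WTC"] == 1))
  calls <- classify_clones(rcn, "TBX1", "CRKL",
                           exclude_samples = "WTC")
  expect_identical(calls$call, "deletion")
})

test_that("RCN error stays within 10% when Ct noise is small", {
  # the delta-delta-Ct chain sums four triplicate means, so the estimate's
  # log2 sd is 2*sigma/sqrt(3); at sigma = 0.05 cycles that is 0.058,
  # putting ~98% of cells within |log2 rcn - log2 target| <= log2(1.1)
  set.seed(43)
  n <- 50L
  cn <- matrix(2L, nrow = n + 1L, ncol = 2L,
               dimnames = list(c(paste0("c", 1:n), "WTC"),
                               c("TBX1", "CRKL")))
  cn[seq(1L, n, 2L), "TBX1"] <- 1L
  tbl <- simulate_ct(cn, base_ct = c(TBX1 = 26, CRKL = 25, RPPH1 = 20),
                     calibrator_sample = "WTC", noise_sd = 0.05,
                     replicates = 3L, seed = 44)
  rcn <- relative_copy_number(tbl)
  rcn <- rcn[rcn$gene != "RPPH1" & rcn$sample != "WTC", ]
  target <- ifelse(rcn$gene == "TBX1" &
                     rcn$sample %in% paste0("c", seq(1L, n, 2L)), 0.5, 1.0)
  expect_gte(mean(abs(rcn$rcn - target) / target <= 0.10), 0.95)
})

test_that("in-silico PCR matches constructed templates and conventions", {
  f <- "CCCTTACCTACCCGAGTGGA"; r <- "AAGACGCCCATTTCTCCCAG"
  tmpl <- paste0(f, strrep("A", 30), oracle_revcomp(r))
  amps <- insilico_pcr(c(t = tmpl), f, r)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$length, nchar(f) + 30L + nchar(r))
  expect_identical(amps$strand_of_forward, "+")
  expect_identical(amps$start, 0L)

  # reverse site absent: nothing amplifies
  expect_identical(nrow(insilico_pcr(c(t = paste0(f, strrep("A", 50))),
                                     f, r)), 0L)
  # template on the opposite strand is still found, same length
  amps2 <- insilico_pcr(c(t = oracle_revcomp(tmpl)), f, r)
  expect_identical(amps2$length, 70L)
  expect_identical(amps2$strand_of_forward, "-")
  # products over max_product are suppressed
  long <- paste0(f, strrep("A", 6000), oracle_revcomp(r))
  expect_identical(nrow(insilico_pcr(c(t = long), f, r)), 0L)
  expect_error(insilico_pcr(c(t = tmpl), "ACGU", r), "A,C,G,T")
})

test_that("the shipped screening panel reproduces its printed sizes on
          synthetic reconstructions", {
  panel <- read_primer_panel(system.file("extdata",
                                         "qpcr_primers_22q11.tsv",
                                         package = "scoredel"))
  expect_identical(panel$gene,
                   c("TBX1", "HIRA", "COMT", "CRKL", "BID", "MAPK1",
                     "RPPH1"))
  expect_identical(panel$expected_size,
                   c(101L, 84L, 83L, 103L, 78L, 70L, 120L))
  # synthetic amplicon templates at the printed spacing
  set.seed(45)
  templates <- setNames(lapply(seq_len(nrow(panel)), function(i) {
    gap <- panel$expected_size[i] - nchar(panel$forward[i]) -
      nchar(panel$reverse[i])
    expect_gte(gap, 0L)
    paste0(rand_dna(40), panel$forward[i], rand_dna(gap),
           oracle_revcomp(panel$reverse[i]), rand_dna(40))
  }), panel$gene)
  amps <- panel_pcr(unlist(templates), panel)
  expect_identical(nrow(amps), nrow(panel))
  expect_identical(amps$length[match(panel$gene, amps$gene)],
                   panel$expected_size)
  expect_true(all(amps$size_matches))
})
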