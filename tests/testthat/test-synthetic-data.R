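test_that("simulated loci are bit-reproducible from their seed", {
  a <- simulate_locus(lcr_length = 500L, inter_lcr_length = 1000L,
                      flank_length = 600L, decoy_spec = c(2L, 3L),
                      seed = 61)
  b <- simulate_locus(lcr_length = 500L, inter_lcr_length = 1000L,
                      flank_length = 600L, decoy_spec = c(2L, 3L),
                      seed = 61)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)
  c <- simulate_locus(lcr_length = 500L, inter_lcr_length = 1000L,
                      flank_length = 600L, decoy_spec = c(2L, 3L),
                      seed = 62)
  expect_false(identical(a$genomes, c$genomes))
})

test_that("the truth table is consistent with a rescan of the genome", {
  loc <- simulate_locus(lcr_length = 800L, inter_lcr_length = 3000L,
                        flank_length = 1200L, n_planted = 2L,
                        decoy_spec = c(1L, 3L, 4L), seed = 63)
  lcr_a <- loc$intervals[loc$intervals$name == "LCR_A", ]
  lcr_b <- loc$intervals[loc$intervals$name == "LCR_B", ]
  ga <- enumerate_guides(loc$genomes, lcr_a)
  gb <- enumerate_guides(loc$genomes, lcr_b)
  tr <- loc$truth
  # each repeat contains exactly the planted guides, at recorded offsets
  expect_identical(sort(ga$protospacer),
                   sort(tr$planted_guides$protospacer))
  expect_identical(sort(gb$protospacer),
                   sort(tr$planted_guides$protospacer))
  ord <- match(tr$planted_guides$protospacer, ga$protospacer)
  expect_identical(ga$start[ord] - lcr_a$start,
                   tr$planted_guides$offset_in_lcr)
  expect_identical(gb$start[ord] - lcr_b$start,
                   tr$planted_guides$offset_in_lcr)
  expect_true(all(ga$strand == "+"))
  # decoys re-extract at the recorded distance from their source
  genome <- loc$genomes[[1L]]
  for (i in seq_len(nrow(tr$decoys))) {
    d <- tr$decoys[i, ]
    mer <- substr(genome, d$location + 1L, d$location + 20L)
    expect_identical(mer, d$protospacer)
    expect_identical(count_mismatches(d$source, mer), d$mismatches)
    expect_identical(substr(genome, d$location + 22L, d$location + 23L),
                     "GG")
  }
  # planted cut pair reproduces the recorded deletion size
  shared <- find_shared_guides(loc$genomes, lcr_a, lcr_b)
  g1 <- shared[[match(tr$planted_guides$protospacer[1L],
                      vapply(shared, `[[`, character(1L),
                             "protospacer"))]]
  expect_identical(
    g1$occurrences_b$cut_boundary - g1$occurrences_a$cut_boundary,
    tr$expected_deletion_size)
})

test_that("repeat divergence never touches planted footprints", {
  loc <- simulate_locus(lcr_length = 1000L, identity = 0.9,
                        inter_lcr_length = 2000L, flank_length = 500L,
                        seed = 64)
  tr <- loc$truth
  expect_identical(length(tr$mutated_positions), 100L)
  lcr_a <- loc$intervals[loc$intervals$name == "LCR_A", ]
  lcr_b <- loc$intervals[loc$intervals$name == "LCR_B", ]
  # the planted guide survives divergence and is still shared
  shared <- find_shared_guides(loc$genomes, lcr_a, lcr_b)
  expect_true(tr$planted_guides$protospacer %in%
                vapply(shared, `[[`, character(1L), "protospacer"))
})

test_that("shared-guide count is non-increasing as identity decreases", {
  counts <- vapply(c(1, 0.98, 0.9, 0.7), function(id) {
    loc <- simulate_locus(lcr_length = 1000L, identity = id,
                          inter_lcr_length = 2000L, flank_length = 500L,
                          n_planted = 3L, seed = 65)
    lcr_a <- loc$intervals[loc$intervals$name == "LCR_A", ]
    lcr_b <- loc$intervals[loc$intervals$name == "LCR_B", ]
    length(find_shared_guides(loc$genomes, lcr_a, lcr_b))
  }, numeric(1L))
  expect_identical(counts[1L], 3)
  expect_true(all(diff(counts) <= 0))
})

test_that("locus files round-trip through FASTA/BED/JSON", {
  loc <- simulate_locus(lcr_length = 300L, inter_lcr_length = 500L,
                        flank_length = 300L, seed = 66)
  dir <- withr::local_tempdir()
  paths <- write_locus(loc, dir)
  expect_identical(read_fasta(paths["fasta"]), loc$genomes)
  expect_identical(
    read_intervals(paths["bed"], "synthetic")[, c("contig", "start",
                                                  "end", "name")],
    loc$intervals[, c("contig", "start", "end", "name")])
  js <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(js$expected_deletion_size,
               loc$truth$expected_deletion_size)
  expect_identical(js$planted_guides$protospacer,
                   loc$truth$planted_guides$protospacer)
})

test_that("capacity and argument validation fail loudly", {
  expect_error(simulate_locus(lcr_length = 50L), ">= 100")
  expect_error(simulate_locus(identity = 0), "identity")
  expect_error(simulate_locus(lcr_length = 100L, n_planted = 50L),
               "too many")
  expect_error(simulate_ct(matrix(1L, 1, 1,
                                  dimnames = list("s", "g")),
                           base_ct = c(g = 25, RPPH1 = 20),
                           noise_sd = -1), "noise_sd")
})

test_that("simulated Ct tables follow the copy-number closed form", {
  cn <- matrix(c(1L, 2L, 2L, 2L), nrow = 2,
               dimnames = list(c("clone", "WTC"), c("TBX1", "CRKL")))
  tbl <- simulate_ct(cn, base_ct = c(TBX1 = 26, CRKL = 25, RPPH1 = 20),
                     calibrator_sample = "WTC", noise_sd = 0, seed = 67)
  # copy number 1 adds exactly one cycle
  d <- tbl$data
  expect_identical(unique(d$ct[d$sample == "clone" & d$gene == "TBX1"]),
                   27)
  expect_identical(unique(d$ct[d$sample == "WTC" & d$gene == "TBX1"]), 26)
  same <- simulate_ct(cn, base_ct = c(TBX1 = 26, CRKL = 25, RPPH1 = 20),
                      calibrator_sample = "WTC", noise_sd = 0.2,
                      seed = 68)
  again <- simulate_ct(cn, base_ct = c(TBX1 = 26, CRKL = 25, RPPH1 = 20),
                       calibrator_sample = "WTC", noise_sd = 0.2,
                       seed = 68)
  expect_identical(same$data, again$data)
  expect_error(simulate_ct(cn, base_ct = c(TBX1 = 26, RPPH1 = 20)),
               "missing genes")
  # calibrator must be diploid
  cn2 <- cn; cn2["WTC", "TBX1"] <- 1L
  expect_error(simulate_ct(cn2, base_ct = c(TBX1 = 26, CRKL = 25,
                                            RPPH1 = 20),
                           calibrator_sample = "WTC"), "diploid")
})

test_that("expression matrices are reproducible with coordinates in place", {
  a <- simulate_expression(n_in_region = 30L, n_flanking = 60L, seed = 69)
  b <- simulate_expression(n_in_region = 30L, n_flanking = 60L, seed = 69)
  expect_identical(a$matrix$values, b$matrix$values)
  ft <- a$matrix$features
  inr <- a$truth$in_region
  expect_true(all(ft$start[inr] >= a$region$start &
                    ft$end[inr] <= a$region$end))
  expect_true(all(ft$end[!inr] <= a$region$start |
                    ft$start[!inr] >= a$region$end))
})
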