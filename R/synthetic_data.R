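# Seeded generators for every input the toolkit consumes: two-repeat
# synthetic loci with planted guides and graded off-target decoys, qPCR
# Ct tables with known copy number, and expression matrices carrying a
# heterozygous dosage effect.  Each generator returns a machine-readable
# truth table and is bit-reproducible from (params, seed).

random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Repeat background free of guide sites: excluding the dinucleotides GG
# and CC excludes every NGG PAM on either strand, so the only Cas9 sites
# inside a repeat are the ones deliberately planted.  Base composition is
# uniform subject to that constraint.
pamfree_dna <- function(n) {
  if (n == 0L) return("")
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  out[1L] <- sample(bases, 1L)
  for (i in seq_len(n - 1L)) {
    prev <- out[i]
    allowed <- if (prev == "G") c("A", "C", "T")
      else if (prev == "C") c("A", "G", "T") else bases
    out[i + 1L] <- sample(allowed, 1L)
  }
  paste(out, collapse = "")
}

# Mutate a sequence at exactly `m` distinct positions (each to a
# different base), avoiding `protected` 1-based positions.
mutate_positions <- function(seq, m, protected = integer(0)) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  candidates <- setdiff(seq_along(chars), protected)
  if (m > length(candidates)) stop("not enough mutable positions")
  pos <- if (m > 0L) sample(candidates, m) else integer(0)
  for (i in pos) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  list(seq = paste(chars, collapse = ""), positions = sort(pos))
}

#' Simulate a two-repeat deletion locus with planted guides
#'
#' Builds a single contig laid out as
#' `flank | LCR_A | spacer | LCR_B | flank`, where LCR_B is LCR_A mutated
#' down to the requested identity (planted-guide footprints protected).
#' Each planted guide is a PAM-free-background-compatible 20-mer with an
#' AGG PAM injected at the same offset, plus strand, in both repeats;
#' repeat background contains no other Cas9 site by construction, so with
#' identity 1 the planted guides are exactly the shared guides.  Decoy
#' off-target sites are copies of the first planted protospacer mutated
#' to the requested Hamming distances and injected (with AGG PAMs) into
#' the flanks, outside any exempt region.
#'
#' Default dimensions follow the engineered 22q11.2 locus scaled to desk
#' size: ~5-kb repeats separated by a 50-kb spacer standing in for the
#' ~1.5-Mb A-B segment.
#'
#' @param lcr_length Repeat length in bp (>= 100; default 5000).
#' @param identity Fraction of identical bases between the two repeat
#'   copies, in (0, 1] (default 1).
#' @param inter_lcr_length Spacer between the repeats (default 50000).
#' @param flank_length Flank on each side (default 10000).
#' @param n_planted Number of planted shared guides (default 1).
#' @param decoy_spec Integer vector of Hamming distances; one decoy per
#'   entry is planted in the flanks (default none).
#' @param gc GC fraction of flanks and spacer (default 0.5).
#' @param seed Integer seed; all randomness derives from it.
#' @param contig Contig name (default `"chrSim"`).
#' @return List with `genomes` (named character vector), `intervals`
#'   (BED-style data.frame: LCR_A, LCR_B, CNV region), and `truth` (class
#'   `synthetic_locus_truth`): planted guides (protospacer,
#'   offset_in_lcr, strand), decoys (protospacer, source, location,
#'   mismatches), `expected_deletion_size`, `seed`.
#' @export
simulate_locus <- function(lcr_length = 5000L, identity = 1,
                           inter_lcr_length = 50000L,
                           flank_length = 10000L, n_planted = 1L,
                           decoy_spec = integer(0), gc = 0.5,
                           seed = 1L, contig = "chrSim") {
  if (lcr_length < 100L) stop("lcr_length must be >= 100")
  if (inter_lcr_length < 1L) stop("inter_lcr_length must be >= 1")
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  set.seed(as.integer(seed))

  # plant slots: 25-nt blocks (guard + 20-mer + AGG + guard), non-adjacent
  slot <- 25L
  n_slots <- (lcr_length - 2L) %/% (slot + 4L)
  if (n_planted > n_slots) stop("too many planted guides for this repeat")
  slot_starts <- sort(sample(n_slots, n_planted)) * (slot + 4L) -
    (slot + 4L) + 2L                               # 1-based guard position
  lcr_a <- strsplit(pamfree_dna(lcr_length), "", fixed = TRUE)[[1L]]
  planted <- data.frame(protospacer = character(), offset_in_lcr = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  protected <- integer(0)
  for (s in slot_starts) {
    proto <- pamfree_dna(PROTOSPACER_LEN)
    block <- c("A", strsplit(proto, "", fixed = TRUE)[[1L]],
               c("A", "G", "G"), "A")
    lcr_a[s:(s + slot - 1L)] <- block
    protected <- c(protected, s:(s + slot - 1L))
    planted <- rbind(planted, data.frame(
      protospacer = proto, offset_in_lcr = s, strand = "+",
      stringsAsFactors = FALSE))                  # 0-based: (s+1)-1 = s
  }
  lcr_a <- paste(lcr_a, collapse = "")
  n_mut <- round((1 - identity) * lcr_length)
  mut <- mutate_positions(lcr_a, n_mut, protected = protected)
  lcr_b <- mut$seq

  flank_l <- strsplit(random_dna(flank_length, gc), "", fixed = TRUE)[[1L]]
  flank_r <- strsplit(random_dna(flank_length, gc), "", fixed = TRUE)[[1L]]
  spacer <- random_dna(inter_lcr_length, gc)

  # decoys: mutated copies of the first planted protospacer, AGG PAM,
  # split across the two flanks at non-overlapping slots
  decoys <- data.frame(protospacer = character(), source = character(),
                       location = integer(), mismatches = integer(),
                       stringsAsFactors = FALSE)
  if (length(decoy_spec)) {
    if (n_planted < 1L) stop("decoys need a planted source guide")
    src <- planted$protospacer[1L]
    d_slots <- (flank_length - 2L) %/% (slot + 4L)
    if (length(decoy_spec) > 2L * d_slots) stop("too many decoys for flanks")
    which_flank <- rep(c(1L, 2L), length.out = length(decoy_spec))
    slots_l <- sample(d_slots, sum(which_flank == 1L)) * (slot + 4L) -
      (slot + 4L) + 2L
    slots_r <- sample(d_slots, sum(which_flank == 2L)) * (slot + 4L) -
      (slot + 4L) + 2L
    i_l <- 0L; i_r <- 0L
    for (j in seq_along(decoy_spec)) {
      m <- as.integer(decoy_spec[j])
      dproto <- mutate_positions(src, m)$seq
      block <- c("A", strsplit(dproto, "", fixed = TRUE)[[1L]],
                 c("A", "G", "G"), "A")
      if (which_flank[j] == 1L) {
        i_l <- i_l + 1L
        s <- slots_l[i_l]
        flank_l[s:(s + slot - 1L)] <- block
        loc0 <- s                                  # genome starts at flank_l
      } else {
        i_r <- i_r + 1L
        s <- slots_r[i_r]
        flank_r[s:(s + slot - 1L)] <- block
        loc0 <- flank_length + lcr_length + inter_lcr_length + lcr_length + s
      }
      decoys <- rbind(decoys, data.frame(
        protospacer = dproto, source = src, location = loc0,
        mismatches = m, stringsAsFactors = FALSE))
    }
  }

  genome <- paste0(paste(flank_l, collapse = ""), lcr_a, spacer, lcr_b,
                   paste(flank_r, collapse = ""))
  a_start <- flank_length
  b_start <- flank_length + lcr_length + inter_lcr_length
  intervals <- data.frame(
    contig = contig,
    start = c(a_start, b_start, a_start + lcr_length),
    end = c(a_start + lcr_length, b_start + lcr_length, b_start),
    name = c("LCR_A", "LCR_B", "CNV_region"),
    assembly = "synthetic", stringsAsFactors = FALSE)

  truth <- structure(list(
    lcr_a = intervals[1L, ], lcr_b = intervals[2L, ],
    planted_guides = planted, decoys = decoys,
    # same-offset plus-strand plants cut at lcr_start + offset + 17 in
    # both copies, so the deletion spans repeat-start to repeat-start
    expected_deletion_size = b_start - a_start,
    identity = identity, mutated_positions = mut$positions,
    seed = as.integer(seed)
  ), class = "synthetic_locus_truth")

  list(genomes = setNames(genome, contig), intervals = intervals,
       truth = truth)
}

#' Write a simulated locus to FASTA + BED + truth JSON
#'
#' @param locus Output of [simulate_locus()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"locus"`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_locus <- function(locus, dir, prefix = "locus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  bed <- file.path(dir, paste0(prefix, ".bed"))
  js <- file.path(dir, paste0(prefix, ".truth.json"))
  write_fasta(locus$genomes, fa)
  write_intervals(locus$intervals, bed)
  jsonlite::write_json(unclass(locus$truth), js, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(fasta = fa, bed = bed, truth = js))
}

#' Simulate a qPCR Ct table with known copy number
#'
#' `Ct = base_ct(gene) - log2(copy_number / 2) + N(0, noise_sd)` per
#' replicate, so a heterozygous locus (copy number 1) sits one cycle
#' above diploid and the delta-delta-Ct chain recovers RCN = 0.5 exactly
#' at zero noise.  The reference gene is diploid in every sample.
#'
#' @param copy_number Integer matrix (values 1 or 2), rows = samples,
#'   columns = assayed genes (reference gene excluded).
#' @param base_ct Named numeric vector of per-gene baseline Cts; must
#'   cover all assayed genes and the reference gene.
#' @param reference_gene Reference gene name (default `"RPPH1"`).
#' @param calibrator_sample Which sample is the calibrator; must be
#'   all-diploid.  Defaults to the first all-diploid row.
#' @param noise_sd Gaussian Ct noise, cycles (default 0.1).
#' @param replicates Technical replicates per reaction (default 3).
#' @param seed Integer seed.
#' @return A [ct_table()].
#' @export
simulate_ct <- function(copy_number, base_ct, reference_gene = "RPPH1",
                        calibrator_sample = NULL, noise_sd = 0.1,
                        replicates = 3L, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(is.matrix(copy_number), all(copy_number %in% c(1L, 2L)))
  samples <- rownames(copy_number)
  genes <- colnames(copy_number)
  if (is.null(samples) || is.null(genes)) {
    stop("copy_number needs sample rownames and gene colnames")
  }
  if (reference_gene %in% genes) {
    stop("the reference gene is diploid by assumption; ",
         "leave it out of copy_number")
  }
  need <- c(genes, reference_gene)
  if (!all(need %in% names(base_ct))) {
    stop("base_ct missing genes: ",
         paste(setdiff(need, names(base_ct)), collapse = ", "))
  }
  diploid <- rowSums(copy_number == 2L) == ncol(copy_number)
  if (is.null(calibrator_sample)) {
    if (!any(diploid)) stop("no all-diploid sample to use as calibrator")
    calibrator_sample <- samples[which(diploid)[1L]]
  } else if (!diploid[calibrator_sample]) {
    stop("calibrator sample must be diploid at every assayed gene")
  }
  set.seed(as.integer(seed))
  all_genes <- c(genes, reference_gene)
  grid <- expand.grid(replicate = seq_len(replicates), gene = all_genes,
                      sample = samples, stringsAsFactors = FALSE)
  cn <- rep(2L, nrow(grid))
  assayed <- grid$gene != reference_gene
  cn[assayed] <- copy_number[cbind(grid$sample[assayed],
                                   grid$gene[assayed])]
  grid$ct <- base_ct[grid$gene] - log2(cn / 2) +
    rnorm(nrow(grid), sd = noise_sd)
  grid <- grid[, c("sample", "gene", "replicate", "ct")]
  ct_table(grid, reference_gene = reference_gene,
           calibrator_sample = calibrator_sample)
}

#' Simulate an expression matrix with a heterozygous dosage effect
#'
#' Control-group means are drawn log-normally; deletion-group means for
#' in-region features are scaled by `dosage_factor` (0.5 emulates losing
#' one of two copies); counts are negative-binomial with the given
#' dispersion.  In-region features are placed inside a declared region
#' interval, flanking features outside it on the same contig.
#'
#' @param n_in_region,n_flanking Feature counts (defaults 200 / 1000).
#' @param dosage_factor Multiplicative effect on in-region deletion-group
#'   means (default 0.5).
#' @param n_per_group Samples per group (default 3).
#' @param dispersion NB dispersion; variance = mu + dispersion * mu^2
#'   (default 0.1).
#' @param mean_log,sd_log Log-normal parameters of control means
#'   (defaults log(500), 1).
#' @param seed Integer seed.
#' @param contig Contig name (default `"chrSim"`).
#' @return List with `matrix` (a [feature_matrix()]), `region` (one-row
#'   interval data.frame), and `truth` (dosage_factor, per-feature set).
#' @export
simulate_expression <- function(n_in_region = 200L, n_flanking = 1000L,
                                dosage_factor = 0.5, n_per_group = 3L,
                                dispersion = 0.1, mean_log = log(500),
                                sd_log = 1, seed = 1L, contig = "chrSim") {
  stopifnot(n_in_region > 0L, n_flanking > 0L, n_per_group > 0L,
            dispersion >= 0)
  set.seed(as.integer(seed))
  region <- data.frame(contig = contig, start = 1000000L, end = 2000000L,
                       name = "CNV_region", stringsAsFactors = FALSE)
  n <- n_in_region + n_flanking
  in_region <- c(rep(TRUE, n_in_region), rep(FALSE, n_flanking))
  starts <- integer(n)
  width <- 1000L
  starts[in_region] <- sort(sample(seq(region$start,
                                       region$end - width), n_in_region))
  left <- sample(seq(0L, region$start - width), ceiling(n_flanking / 2))
  right <- sample(seq(region$end, 3000000L - width),
                  floor(n_flanking / 2))
  starts[!in_region] <- sort(c(left, right))
  features <- data.frame(
    feature = sprintf("gene_%04d", seq_len(n)), contig = contig,
    start = starts, end = starts + width, stringsAsFactors = FALSE)

  mu_ctl <- rlnorm(n, meanlog = mean_log, sdlog = sd_log)
  mu_del <- mu_ctl * ifelse(in_region, dosage_factor, 1)
  samples <- c(paste0("del_", seq_len(n_per_group)),
               paste0("ctl_", seq_len(n_per_group)))
  groups <- setNames(rep(c("deletion", "control"), each = n_per_group),
                     samples)
  draw <- function(mu) {
    if (dispersion == 0) mu else rnbinom(length(mu), mu = mu,
                                         size = 1 / dispersion)
  }
  values <- matrix(0, nrow = n, ncol = length(samples),
                   dimnames = list(features$feature, samples))
  for (s in samples) {
    mu <- if (groups[s] == "deletion") mu_del else mu_ctl
    values[, s] <- draw(mu)
  }
  list(matrix = feature_matrix(features, values, groups),
       region = region,
       truth = list(dosage_factor = dosage_factor,
                    in_region = setNames(in_region, features$feature),
                    seed = as.integer(seed)))
}
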