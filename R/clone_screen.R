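# Clone screening after editing: delta-delta-Ct relative copy number from
# genomic qPCR, deletion calls from in-region vs flanking marker genes,
# and exact-match in-silico PCR to validate the screening primer panel.

#' Construct a Ct table
#'
#' Replicate Ct measurements keyed by (sample, gene), with a designated
#' endogenous reference gene (default RPPH1, which lies outside the
#' deletion) and a calibrator sample assumed diploid at every assayed
#' locus.
#'
#' @param data Data.frame with columns `sample`, `gene`, `ct` and
#'   optionally `replicate`.
#' @param reference_gene Endogenous reference gene name.
#' @param calibrator_sample Calibrator (unedited) sample name.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(data, reference_gene = "RPPH1", calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(data)))
  if (!reference_gene %in% data$gene) {
    stop("reference gene '", reference_gene, "' absent from Ct table")
  }
  if (!calibrator_sample %in% data$sample) {
    stop("calibrator sample '", calibrator_sample, "' absent from Ct table")
  }
  if (any(!is.finite(data$ct)) || any(data$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  structure(list(data = data, reference_gene = reference_gene,
                 calibrator_sample = calibrator_sample),
            class = "ct_table")
}

#' Read a Ct table from TSV
#'
#' Expects columns `sample`, `gene`, `replicate`, `ct`.
#'
#' @param path Path to the TSV file.
#' @inheritParams ct_table
#' @return A `ct_table`.
#' @export
read_ct_table <- function(path, reference_gene = "RPPH1",
                          calibrator_sample) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ct_table(df, reference_gene = reference_gene,
           calibrator_sample = calibrator_sample)
}

#' Relative copy number by the delta-delta-Ct method
#'
#' Replicate Cts are averaged per (sample, gene); within each sample,
#' `dCt = meanCt(gene) - meanCt(reference)`; against the calibrator,
#' `ddCt = dCt(sample) - dCt(calibrator)`; relative copy number is
#' `2^-ddCt`.  The reference gene's RCN is 1 for every sample by
#' construction.  A heterozygous deletion is expected at RCN 0.5.
#'
#' @param table A [ct_table()].
#' @return Data.frame with columns `sample`, `gene`, `mean_ct`,
#'   `delta_ct`, `delta_delta_ct`, `rcn`.
#' @export
relative_copy_number <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  d <- table$data
  mean_ct <- aggregate(ct ~ sample + gene, data = d, FUN = mean)
  samples <- unique(d$sample)
  genes <- unique(d$gene)
  full <- expand.grid(sample = samples, gene = genes,
                      stringsAsFactors = FALSE)
  merged <- merge(full, mean_ct, all.x = TRUE)
  if (any(is.na(merged$ct))) {
    miss <- merged[is.na(merged$ct), c("sample", "gene")]
    stop("missing Ct cells: ",
         paste(paste0(miss$sample, "/", miss$gene), collapse = ", "))
  }
  ref <- merged[merged$gene == table$reference_gene, ]
  ref_ct <- setNames(ref$ct, ref$sample)
  merged$delta_ct <- merged$ct - ref_ct[merged$sample]
  cal <- merged[merged$sample == table$calibrator_sample, ]
  cal_dct <- setNames(cal$delta_ct, cal$gene)
  merged$delta_delta_ct <- merged$delta_ct - cal_dct[merged$gene]
  merged$rcn <- 2^(-merged$delta_delta_ct)
  out <- merged[order(merged$sample, merged$gene),
                c("sample", "gene", "ct", "delta_ct", "delta_delta_ct",
                  "rcn")]
  names(out)[3L] <- "mean_ct"
  rownames(out) <- NULL
  out
}

#' Call deletion status from relative copy numbers
#'
#' A clone is called `deletion` when every in-region gene's RCN is at or
#' below `del_max` while every flanking gene sits in the diploid band
#' `[normal_min, normal_max]`; `no_deletion` when every gene sits in the
#' diploid band; otherwise `ambiguous`.  The default thresholds are
#' midpoints between the heterozygous expectation (0.5) and diploid (1.0).
#'
#' @param rcn Output of [relative_copy_number()].
#' @param in_region_genes,flanking_genes Disjoint character vectors of
#'   marker genes inside / outside the deletion.
#' @param thresholds List with `del_max` (default 0.7), `normal_min`
#'   (0.8), `normal_max` (1.2).
#' @param exclude_samples Samples not to call (default: none).
#' @return Data.frame with one row per sample: `sample`, `call`, plus one
#'   `rcn_<gene>` column per marker gene.
#' @export
classify_clones <- function(rcn, in_region_genes, flanking_genes,
                            thresholds = list(del_max = 0.7,
                                              normal_min = 0.8,
                                              normal_max = 1.2),
                            exclude_samples = character()) {
  if (length(in_region_genes) == 0L || length(flanking_genes) == 0L) {
    stop("both gene lists must be non-empty")
  }
  if (length(intersect(in_region_genes, flanking_genes))) {
    stop("in-region and flanking gene lists must be disjoint")
  }
  genes <- c(in_region_genes, flanking_genes)
  missing <- setdiff(genes, rcn$gene)
  if (length(missing)) {
    stop("genes absent from RCN table: ", paste(missing, collapse = ", "))
  }
  samples <- setdiff(unique(rcn$sample), exclude_samples)
  in_band <- function(x) {
    x >= thresholds$normal_min & x <= thresholds$normal_max
  }
  rows <- lapply(samples, function(s) {
    v <- setNames(rcn$rcn[rcn$sample == s][match(genes,
                    rcn$gene[rcn$sample == s])], genes)
    call <- if (all(v[in_region_genes] <= thresholds$del_max) &&
                all(in_band(v[flanking_genes]))) {
      "deletion"
    } else if (all(in_band(v))) {
      "no_deletion"
    } else {
      "ambiguous"
    }
    out <- data.frame(sample = s, call = call, stringsAsFactors = FALSE)
    for (g in genes) out[[paste0("rcn_", g)]] <- unname(v[g])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a primer panel TSV
#'
#' Expects columns `gene`, `forward`, `reverse` and optionally
#' `expected_size`.  The seven-gene 22q11.2 screening panel ships with the
#' package: `system.file("extdata", "qpcr_primers_22q11.tsv",
#' package = "scoredel")`.
#'
#' @param path Path to the TSV.
#' @return Data.frame of primer pairs.
#' @export
read_primer_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "forward", "reverse") %in% names(df)))
  df$forward <- toupper(df$forward)
  df$reverse <- toupper(df$reverse)
  bad <- grepl("[^ACGT]", df$forward) | grepl("[^ACGT]", df$reverse)
  if (any(bad)) stop("primer with non-ACGT characters for gene ",
                     df$gene[which(bad)[1L]])
  short <- nchar(df$forward) < 15L | nchar(df$reverse) < 15L
  if (any(short)) stop("primer shorter than 15 nt for gene ",
                       df$gene[which(short)[1L]])
  df
}

#' Exact-match in-silico PCR
#'
#' Finds all products a primer pair would amplify from a template by
#' exact matching: the forward primer on one strand and the reverse
#' complement of the reverse primer downstream on the same strand.  Both
#' orientations are searched.  Product length is the inclusive span from
#' the forward primer's 5' end through the reverse primer's 5'-most
#' template base, the convention under which the panel's printed sizes
#' (e.g. TBX1 101 bp) are reproduced.  Primer sites may not overlap.
#'
#' @param genomes Named character vector of templates/contigs, an
#'   `assembly_context`, or a single unnamed sequence string.
#' @param forward,reverse Primer sequences, 5' to 3', {A,C,G,T}.
#' @param max_product Maximum product length reported (default 5000).
#' @return Data.frame of amplicons: `contig`, `start`, `end` (0-based
#'   half-open outer-primer span), `length`, `strand_of_forward`.  Empty
#'   when nothing amplifies.
#' @export
insilico_pcr <- function(genomes, forward, reverse, max_product = 5000L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse)) {
    stop("primers must be {A,C,G,T} only")
  }
  if (inherits(genomes, "assembly_context")) genomes <- genomes$genomes
  if (is.null(names(genomes))) names(genomes) <- "template"
  lf <- nchar(forward); lr <- nchar(reverse)
  find_starts <- function(pattern, subject) {
    # 0-based starts of exact occurrences
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject))
    as.integer(Biostrings::start(m)) - 1L
  }
  rows <- list()
  for (contig in names(genomes)) {
    # exact matching (fixed = TRUE): genomic N matches nothing since the
    # primers are N-free
    seq <- genomes[[contig]]
    f_plus <- find_starts(forward, seq)
    r_plus_rc <- find_starts(reverse_complement(reverse), seq)
    # plus-orientation products: forward site then revcomp(reverse) site
    for (f in f_plus) {
      for (r in r_plus_rc) {
        if (r >= f + lf) {
          len <- r + lr - f
          if (len <= max_product) {
            rows[[length(rows) + 1L]] <- data.frame(
              contig = contig, start = f, end = f + len, length = len,
              strand_of_forward = "+", stringsAsFactors = FALSE)
          }
        }
      }
    }
    # minus-orientation: reverse primer on plus strand, forward's revcomp
    # downstream
    r_plus <- find_starts(reverse, seq)
    f_plus_rc <- find_starts(reverse_complement(forward), seq)
    for (r in r_plus) {
      for (f in f_plus_rc) {
        if (f >= r + lr) {
          len <- f + lf - r
          if (len <= max_product) {
            rows[[length(rows) + 1L]] <- data.frame(
              contig = contig, start = r, end = r + len, length = len,
              strand_of_forward = "-", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig = character(), start = integer(), end = integer(),
               length = integer(), strand_of_forward = character(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run in-silico PCR for a whole primer panel
#'
#' @param genomes Template sequences (see [insilico_pcr()]).
#' @param panel Primer panel data.frame (see [read_primer_panel()]).
#' @param max_product Maximum product length.
#' @return Data.frame of amplicons with a leading `gene` column and, when
#'   the panel carries `expected_size`, a `size_matches` flag.
#' @export
panel_pcr <- function(genomes, panel, max_product = 5000L) {
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    amps <- insilico_pcr(genomes, panel$forward[i], panel$reverse[i],
                         max_product = max_product)
    if (nrow(amps) == 0L) return(NULL)
    amps <- cbind(gene = panel$gene[i], amps)
    if ("expected_size" %in% names(panel) &&
        !is.na(panel$expected_size[i])) {
      amps$size_matches <- amps$length == panel$expected_size[i]
    }
    amps
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(gene = character(), contig = character(),
                      start = integer(), end = integer(),
                      length = integer(), strand_of_forward = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
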