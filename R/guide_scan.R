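# SpCas9 guide-site enumeration: 20-mer protospacer immediately followed
# (3' in spacer orientation) by a PAM, scanned on both strands.  The blunt
# cut is placed 3 bp 5' of the PAM, i.e. between protospacer positions
# 17 and 18 -- the standard SpCas9 convention.

PROTOSPACER_LEN <- 20L
PAM_LEN <- 3L
SITE_LEN <- PROTOSPACER_LEN + PAM_LEN

#' PAM rule
#'
#' A 3-letter IUPAC pattern describing the protospacer-adjacent motif.
#' Defaults to SpCas9's NGG.
#'
#' @param pattern 3-letter IUPAC string.
#' @return An object of class `pam_rule`.
#' @export
pam_rule <- function(pattern = "NGG") {
  pattern <- toupper(pattern)
  if (nchar(pattern) != PAM_LEN || grepl("[^ACGTRYSWKMBDHVN]", pattern)) {
    stop("PAM pattern must be 3 IUPAC letters, got '", pattern, "'")
  }
  structure(list(pattern = pattern), class = "pam_rule")
}

# Vectorised IUPAC match of a fixed pattern against genome characters at
# positions `at`, `at+1`, ... (1-based).  Genomic N matches nothing.
pam_match_at <- function(chars, at, pattern_chars) {
  ok <- rep(TRUE, length(at))
  for (i in seq_along(pattern_chars)) {
    ok <- ok & chars[at + i - 1L] %in% IUPAC_SETS[[pattern_chars[i]]]
  }
  ok
}

#' Enumerate Cas9 guide sites within an interval
#'
#' Returns every position, on either strand, where a 20-mer protospacer
#' followed by a PAM-matching 3-mer lies entirely inside the interval.
#' Protospacers containing N are skipped.  Results are sorted by
#' `start` (the protospacer's leftmost genomic base, 0-based) then strand.
#'
#' @param genomes Named character vector of contig sequences, or an
#'   `assembly_context`.
#' @param interval One-row interval data.frame (`contig`, `start`, `end`,
#'   `name`), 0-based half-open.
#' @param pam A [pam_rule()].
#' @return A data.frame with columns `protospacer`, `pam`, `contig`,
#'   `strand`, `start`, `cut_boundary`, `source_interval`.  `cut_boundary`
#'   is the 0-based inter-base coordinate of the blunt cut.
#' @examples
#' g <- c(chr = "AGGTGCCGTCGAGAAGCGCCATGGAA")
#' iv <- data.frame(contig = "chr", start = 0, end = 26, name = "toy")
#' enumerate_guides(g, iv)
#' @export
enumerate_guides <- function(genomes, interval, pam = pam_rule()) {
  stopifnot(inherits(pam, "pam_rule"))
  interval <- as.list(interval[1L, c("contig", "start", "end", "name")])
  seq <- get_contig(genomes, interval$contig)
  if (interval$start < 0L || interval$end > nchar(seq)) {
    stop("interval '", interval$name, "' is outside contig '",
         interval$contig, "'")
  }
  region <- substr(seq, interval$start + 1L, interval$end)
  empty <- data.frame(protospacer = character(), pam = character(),
                      contig = character(), strand = character(),
                      start = integer(), cut_boundary = integer(),
                      source_interval = character(),
                      stringsAsFactors = FALSE)
  L <- nchar(region)
  if (L < SITE_LEN) return(empty)
  chars <- strsplit(region, "", fixed = TRUE)[[1L]]
  pat <- strsplit(pam$pattern, "", fixed = TRUE)[[1L]]
  rc_pat <- strsplit(reverse_string(iupac_complement(pam$pattern)), "",
                     fixed = TRUE)[[1L]]
  p <- seq_len(L - SITE_LEN + 1L)   # 1-based site start within region

  rows <- list()
  # plus strand: protospacer at p..p+19, PAM at p+20..p+22
  hit <- p[pam_match_at(chars, p + PROTOSPACER_LEN, pat)]
  if (length(hit)) {
    proto <- substring(region, hit, hit + PROTOSPACER_LEN - 1L)
    keep <- !grepl("N", proto, fixed = TRUE)
    if (any(keep)) {
      hit <- hit[keep]
      start0 <- interval$start + hit - 1L
      rows$plus <- data.frame(
        protospacer = proto[keep],
        pam = substring(region, hit + PROTOSPACER_LEN, hit + SITE_LEN - 1L),
        contig = interval$contig, strand = "+",
        start = start0, cut_boundary = start0 + 17L,
        source_interval = interval$name, stringsAsFactors = FALSE)
    }
  }
  # minus strand: on the plus strand we see revcomp(PAM) at q..q+2 followed
  # by the protospacer footprint at q+3..q+22
  hit <- p[pam_match_at(chars, p, rc_pat)]
  if (length(hit)) {
    fp <- substring(region, hit + PAM_LEN, hit + SITE_LEN - 1L)
    keep <- !grepl("N", fp, fixed = TRUE)
    if (any(keep)) {
      hit <- hit[keep]
      start0 <- interval$start + hit + PAM_LEN - 1L
      rows$minus <- data.frame(
        protospacer = reverse_complement(fp[keep]),
        pam = reverse_complement(substring(region, hit, hit + PAM_LEN - 1L)),
        contig = interval$contig, strand = "-",
        start = start0, cut_boundary = start0 + 3L,
        source_interval = interval$name, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cut boundary of a guide site
#'
#' The 0-based inter-base coordinate of the blunt Cas9 cut, 3 bp 5' of the
#' PAM in spacer orientation: `start + 17` on the plus strand, `start + 3`
#' on the minus strand.
#'
#' @param strand `"+"` or `"-"` (vectorised).
#' @param start 0-based protospacer start (leftmost genomic base).
#' @return Integer vector of cut boundaries.
#' @export
cut_coordinate <- function(strand, start) {
  stopifnot(all(strand %in% c("+", "-")))
  as.integer(start) + ifelse(strand == "+", 17L, 3L)
}

#' Write a guide table as BED6
#'
#' The protospacer footprint is reported; the name column holds the
#' protospacer and the score column is 0.
#'
#' @param guides Guide data.frame from [enumerate_guides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides_bed <- function(guides, path) {
  bed <- data.frame(guides$contig, guides$start,
                    guides$start + PROTOSPACER_LEN, guides$protospacer,
                    0L, guides$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
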