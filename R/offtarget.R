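# Mismatch-tolerant off-target search and the specificity filter: a guide
# is rejected when any PAM-adjacent site outside the designated on-target
# (exempt) intervals lies at Hamming distance below the minimum-mismatch
# threshold (default 4, i.e. "fewer than four mismatches" is disqualifying).

#' Specificity policy
#'
#' @param min_mismatches A guide is rejected when a non-exempt site has
#'   fewer than this many mismatches (default 4).
#' @param pam PAM rule applied at candidate off-target sites (default NGG).
#' @param exempt_intervals Interval data.frame of on-target regions (the
#'   two flanking repeats and, typically, the intervening CNV segment);
#'   sites whose protospacer footprint overlaps any of these are exempt.
#' @param max_scan_mismatches Scan depth; defaults to
#'   `min_mismatches - 1`, the largest distance that can disqualify.
#' @param allow_nag Also admit NAG PAMs at off-target sites (default
#'   FALSE: NGG only, the stricter choice).
#' @return An object of class `specificity_policy`.
#' @export
specificity_policy <- function(min_mismatches = 4L, pam = pam_rule(),
                               exempt_intervals = NULL,
                               max_scan_mismatches = min_mismatches - 1L,
                               allow_nag = FALSE) {
  min_mismatches <- as.integer(min_mismatches)
  if (min_mismatches < 1L) stop("min_mismatches must be >= 1")
  stopifnot(inherits(pam, "pam_rule"))
  pams <- list(pam)
  if (allow_nag) pams <- c(pams, list(pam_rule("NAG")))
  structure(list(min_mismatches = min_mismatches,
                 pam = pam, pam_rules = pams,
                 exempt_intervals = exempt_intervals,
                 max_scan_mismatches = as.integer(max_scan_mismatches),
                 allow_nag = allow_nag),
            class = "specificity_policy")
}

#' Hamming distance between two 20-mer protospacers
#'
#' N (on either side) counts as a mismatch at its position.
#'
#' @param guide_protospacer,site_20mer 20-character DNA strings.
#' @return Integer mismatch count, 0--20.
#' @export
count_mismatches <- function(guide_protospacer, site_20mer) {
  if (nchar(guide_protospacer) != PROTOSPACER_LEN ||
      nchar(site_20mer) != PROTOSPACER_LEN) {
    stop("both sequences must be exactly ", PROTOSPACER_LEN, " nt")
  }
  a <- strsplit(guide_protospacer, "", fixed = TRUE)[[1L]]
  b <- strsplit(site_20mer, "", fixed = TRUE)[[1L]]
  sum(a != b | a == "N" | b == "N")
}

# One strand of the shift-comparison scan: mismatch counts for every
# 20-mer start in `chars`, plus a PAM test at offset +20.
scan_strand <- function(chars, gchars, pam_rules, maxmm) {
  n <- length(chars)
  if (n < SITE_LEN) {
    return(data.frame(pos = integer(), mism = integer(), pam = character(),
                      stringsAsFactors = FALSE))
  }
  s <- seq_len(n - SITE_LEN + 1L)
  mism <- integer(length(s))
  for (k in seq_len(PROTOSPACER_LEN)) {
    ck <- chars[s + k - 1L]
    mism <- mism + as.integer(ck != gchars[k] | ck == "N" |
                                gchars[k] == "N")
  }
  pam_ok <- rep(FALSE, length(s))
  for (rule in pam_rules) {
    pat <- strsplit(rule$pattern, "", fixed = TRUE)[[1L]]
    pam_ok <- pam_ok | pam_match_at(chars, s + PROTOSPACER_LEN, pat)
  }
  keep <- which(mism <= maxmm & pam_ok)
  data.frame(
    pos = keep,                                   # 1-based 20-mer start
    mism = mism[keep],
    pam = vapply(keep, function(i) {
      paste(chars[(i + PROTOSPACER_LEN):(i + SITE_LEN - 1L)], collapse = "")
    }, character(1L)),
    stringsAsFactors = FALSE)
}

footprint_exempt <- function(contig, start0, exempt) {
  if (is.null(exempt) || nrow(exempt) == 0L) {
    return(rep(FALSE, length(start0)))
  }
  out <- rep(FALSE, length(start0))
  for (i in seq_len(nrow(exempt))) {
    if (length(start0) == 0L) break
    same <- contig == exempt$contig[i]
    out <- out | (same & start0 < exempt$end[i] &
                    (start0 + PROTOSPACER_LEN) > exempt$start[i])
  }
  out
}

#' Genome-wide mismatch-tolerant off-target scan
#'
#' Finds every site, on both strands of every contig, whose adjacent
#' 3-mer matches the policy's PAM rule(s) and whose 20-mer lies within
#' `policy$max_scan_mismatches` of the guide protospacer.  Each site is
#' labelled exempt when its protospacer footprint overlaps a designated
#' on-target interval.
#'
#' Two interchangeable engines are provided: `"shift"`, a vectorised
#' shift-comparison scan, and `"bruteforce"`, a position-by-position
#' reference scan that is exact by construction.  They return identical
#' results and are equivalence-tested against each other.
#'
#' @param guide_protospacer 20-nt protospacer (spacer orientation).
#' @param assembly `assembly_context` or named character vector of contigs.
#' @param policy A [specificity_policy()].
#' @param method `"shift"` (default) or `"bruteforce"`.
#' @return Data.frame with columns `contig`, `strand`, `start` (0-based
#'   protospacer start), `mismatches`, `pam`, `exempt`, sorted by contig,
#'   start, strand.
#' @export
scan_offtargets <- function(guide_protospacer, assembly, policy,
                            method = c("shift", "bruteforce")) {
  method <- match.arg(method)
  stopifnot(inherits(policy, "specificity_policy"))
  if (nchar(guide_protospacer) != PROTOSPACER_LEN ||
      grepl("[^ACGTN]", guide_protospacer)) {
    stop("guide protospacer must be a 20-nt {A,C,G,T,N} string")
  }
  genomes <- if (inherits(assembly, "assembly_context")) {
    assembly$genomes
  } else assembly
  gchars <- strsplit(guide_protospacer, "", fixed = TRUE)[[1L]]
  maxmm <- policy$max_scan_mismatches
  rows <- list()
  for (contig in names(genomes)) {
    seq <- genomes[[contig]]
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    if (method == "shift") {
      fwd <- scan_strand(chars, gchars, policy$pam_rules, maxmm)
      rc_chars <- strsplit(reverse_complement(seq), "", fixed = TRUE)[[1L]]
      rev <- scan_strand(rc_chars, gchars, policy$pam_rules, maxmm)
    } else {
      fwd <- brute_scan_strand(seq, guide_protospacer, policy, maxmm)
      rev <- brute_scan_strand(reverse_complement(seq), guide_protospacer,
                               policy, maxmm)
    }
    if (nrow(fwd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, strand = "+", start = fwd$pos - 1L,
        mismatches = fwd$mism, pam = fwd$pam, stringsAsFactors = FALSE)
    }
    if (nrow(rev)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, strand = "-",
        start = n - rev$pos - PROTOSPACER_LEN + 1L,
        mismatches = rev$mism, pam = rev$pam, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig = character(), strand = character(), start = integer(),
               mismatches = integer(), pam = character(),
               stringsAsFactors = FALSE)
  }
  out$exempt <- footprint_exempt(out$contig, out$start,
                                 policy$exempt_intervals)
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Reference engine: explicit per-position substring comparison.  Kept
# deliberately simple so its correctness is inspectable.
brute_scan_strand <- function(seq, guide, policy, maxmm) {
  n <- nchar(seq)
  empty <- data.frame(pos = integer(), mism = integer(), pam = character(),
                      stringsAsFactors = FALSE)
  if (n < SITE_LEN) return(empty)
  starts <- seq_len(n - SITE_LEN + 1L)
  mers <- substring(seq, starts, starts + PROTOSPACER_LEN - 1L)
  pams <- substring(seq, starts + PROTOSPACER_LEN, starts + SITE_LEN - 1L)
  gc <- strsplit(guide, "", fixed = TRUE)[[1L]]
  keep <- integer(0); mm <- integer(0)
  for (i in seq_along(starts)) {
    ok <- FALSE
    for (rule in policy$pam_rules) {
      pat <- strsplit(rule$pattern, "", fixed = TRUE)[[1L]]
      pc <- strsplit(pams[i], "", fixed = TRUE)[[1L]]
      if (all(mapply(function(p, c) c %in% IUPAC_SETS[[p]], pat, pc))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    sc <- strsplit(mers[i], "", fixed = TRUE)[[1L]]
    d <- sum(sc != gc | sc == "N" | gc == "N")
    if (d <= maxmm) {
      keep <- c(keep, starts[i])
      mm <- c(mm, d)
    }
  }
  if (!length(keep)) return(empty)
  data.frame(pos = keep, mism = mm,
             pam = substring(seq, keep + PROTOSPACER_LEN,
                             keep + SITE_LEN - 1L),
             stringsAsFactors = FALSE)
}

#' Partition shared guides by the specificity filter
#'
#' A guide is rejected iff any non-exempt site lies at fewer than
#' `policy$min_mismatches` mismatches; the rejection record lists every
#' offending site.  On-target occurrences inside exempt intervals never
#' disqualify a guide.
#'
#' @param guides A `score_guide_set` (or list of `score_guide`s).
#' @param assembly `assembly_context` or named contig vector.
#' @param policy A [specificity_policy()].
#' @param method Scan engine, see [scan_offtargets()].
#' @return A list with elements `accepted` (score_guide list), `rejected`
#'   (list of `list(guide, offending_sites)`), and `sites` (named list of
#'   full scan results per protospacer).
#' @export
apply_specificity_filter <- function(guides, assembly, policy,
                                     method = "shift") {
  stopifnot(inherits(policy, "specificity_policy"))
  accepted <- list(); rejected <- list(); sites <- list()
  for (g in guides) {
    hits <- scan_offtargets(g$protospacer, assembly, policy, method = method)
    sites[[g$protospacer]] <- hits
    bad <- hits[!hits$exempt & hits$mismatches < policy$min_mismatches, ,
                drop = FALSE]
    if (nrow(bad)) {
      rejected[[length(rejected) + 1L]] <-
        list(guide = g, offending_sites = bad)
    } else {
      accepted[[length(accepted) + 1L]] <- g
    }
  }
  list(accepted = structure(accepted, class = "score_guide_set"),
       rejected = rejected, sites = sites)
}

#' Write an off-target report TSV
#'
#' @param sites Named list of scan results (see
#'   [apply_specificity_filter()]) or a single scan data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offtarget_report <- function(sites, path) {
  if (is.data.frame(sites)) sites <- list(guide = sites)
  rows <- lapply(names(sites), function(g) {
    s <- sites[[g]]
    if (nrow(s) == 0L) return(NULL)
    cbind(guide = g, s)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(guide = character(), contig = character(),
                      strand = character(), start = integer(),
                      mismatches = integer(), pam = character(),
                      exempt = logical())
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
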