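# Independent reference implementations used as oracles.  These are kept
# deliberately naive (per-position loops, explicit complement tables) and
# share no code with the package internals they check.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  if (nchar(s) == 0L) return("")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  paste(rev(unname(ORACLE_COMP[chars])), collapse = "")
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_pam_ok <- function(pam3, patterns) {
  pc <- strsplit(pam3, "", fixed = TRUE)[[1L]]
  for (pattern in patterns) {
    pt <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    # genomic N matches nothing
    if (all(vapply(1:3, function(i) pc[i] %in% ORACLE_IUPAC[[pt[i]]],
                   logical(1L)))) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ca != cb | ca == "N" | cb == "N")
}

# exhaustive both-strand guide enumeration within [start, end) of seq
# (0-based half-open); returns the same columns as enumerate_guides()
oracle_enumerate <- function(seq, start = 0L, end = nchar(seq),
                             pattern = "NGG") {
  region <- substr(seq, start + 1L, end)
  L <- nchar(region)
  rows <- list()
  if (L >= 23L) {
    for (p in 0:(L - 23L)) {
      mer <- substr(region, p + 1L, p + 20L)
      pam <- substr(region, p + 21L, p + 23L)
      if (!grepl("N", mer, fixed = TRUE) && oracle_pam_ok(pam, pattern)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protospacer = mer, pam = pam, strand = "+",
          start = start + p, cut_boundary = start + p + 17L,
          stringsAsFactors = FALSE)
      }
      # minus strand: protospacer+PAM read off the reverse complement,
      # occupying plus-strand bases [p, p+23)
      rc <- oracle_revcomp(substr(region, p + 1L, p + 23L))
      mer_m <- substr(rc, 1L, 20L)
      pam_m <- substr(rc, 21L, 23L)
      if (!grepl("N", mer_m, fixed = TRUE) &&
          oracle_pam_ok(pam_m, pattern)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protospacer = mer_m, pam = pam_m, strand = "-",
          start = start + p + 3L, cut_boundary = start + p + 6L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(protospacer = character(), pam = character(),
               strand = character(), start = integer(),
               cut_boundary = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive position-by-position off-target search on one contig
oracle_offtargets <- function(seq, guide, max_mismatches,
                              patterns = "NGG") {
  n <- nchar(seq)
  rows <- list()
  if (n >= 23L) {
    for (p in 0:(n - 23L)) {
      mer <- substr(seq, p + 1L, p + 20L)
      pam <- substr(seq, p + 21L, p + 23L)
      if (oracle_pam_ok(pam, patterns)) {
        d <- oracle_hamming(guide, mer)
        if (d <= max_mismatches) {
          rows[[length(rows) + 1L]] <- data.frame(
            strand = "+", start = p, mismatches = d, pam = pam,
            stringsAsFactors = FALSE)
        }
      }
      rc <- oracle_revcomp(substr(seq, p + 1L, p + 23L))
      pam_m <- substr(rc, 21L, 23L)
      if (oracle_pam_ok(pam_m, patterns)) {
        d <- oracle_hamming(guide, substr(rc, 1L, 20L))
        if (d <= max_mismatches) {
          rows[[length(rows) + 1L]] <- data.frame(
            strand = "-", start = p + 3L, mismatches = d, pam = pam_m,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(strand = character(), start = integer(),
               mismatches = integer(), pam = character(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
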