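# Core of the single-guide deletion design: protospacers shared verbatim
# by the two CNV-flanking repeats, and the rearrangement products implied
# by cutting both occurrences at once.

#' Find guides shared by two flanking repeats
#'
#' A guide is "shared" when its exact 20-mer protospacer (spacer
#' orientation) has at least one PAM-compatible occurrence inside each of
#' the two repeat intervals.  Near-matches are deliberately not considered
#' here; they belong to the off-target module.  Guides whose occurrences
#' sit on opposite strands in the two repeats are kept but flagged, since
#' the junction model assumes direct-orientation repeats.
#'
#' @param assembly An `assembly_context` (or named character vector of
#'   contigs).
#' @param lcr_a,lcr_b One-row interval data.frames; `lcr_a` must lie
#'   entirely left of `lcr_b` on the same contig.
#' @param pam A [pam_rule()].
#' @return An object of class `score_guide_set`: a list of guides, each
#'   with `protospacer`, `occurrences_a`, `occurrences_b` (guide
#'   data.frames), `multi_site` and `opposite_strand` flags.  Ordered
#'   lexicographically by protospacer.
#' @export
find_shared_guides <- function(assembly, lcr_a, lcr_b, pam = pam_rule()) {
  lcr_a <- lcr_a[1L, , drop = FALSE]
  lcr_b <- lcr_b[1L, , drop = FALSE]
  if (lcr_a$contig != lcr_b$contig) {
    stop("flanking repeats must lie on the same contig")
  }
  if (lcr_a$end > lcr_b$start) {
    stop("repeat intervals overlap or are out of order: '", lcr_a$name,
         "' must end before '", lcr_b$name, "' starts")
  }
  ga <- enumerate_guides(assembly, lcr_a, pam)
  gb <- enumerate_guides(assembly, lcr_b, pam)
  shared <- sort(intersect(ga$protospacer, gb$protospacer))
  guides <- lapply(shared, function(p) {
    occ_a <- ga[ga$protospacer == p, , drop = FALSE]
    occ_b <- gb[gb$protospacer == p, , drop = FALSE]
    structure(list(
      protospacer = p,
      occurrences_a = occ_a,
      occurrences_b = occ_b,
      multi_site = nrow(occ_a) > 1L || nrow(occ_b) > 1L,
      opposite_strand = length(intersect(occ_a$strand, occ_b$strand)) == 0L
    ), class = "score_guide")
  })
  structure(guides, class = "score_guide_set",
            lcr_a = lcr_a$name, lcr_b = lcr_b$name,
            n_enumerated = c(a = nrow(ga), b = nrow(gb)))
}

#' @export
print.score_guide_set <- function(x, ...) {
  cat("<score_guide_set> ", length(x), " shared guide(s) between '",
      attr(x, "lcr_a"), "' and '", attr(x, "lcr_b"), "'\n", sep = "")
  for (g in head(x, 10L)) {
    cat("  ", g$protospacer, "  occ A/B: ", nrow(g$occurrences_a), "/",
        nrow(g$occurrences_b),
        if (g$multi_site) "  [multi-site]" else "",
        if (g$opposite_strand) "  [opposite-strand]" else "", "\n", sep = "")
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Flatten a score_guide_set to a data.frame
#'
#' One row per shared guide with occurrence counts and, when each repeat
#' holds exactly one occurrence, the predicted deletion size.
#'
#' @param x A `score_guide_set`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.score_guide_set <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(protospacer = character(), n_occ_a = integer(),
                      n_occ_b = integer(), multi_site = logical(),
                      opposite_strand = logical(),
                      deletion_size = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x, function(g) {
    size <- if (nrow(g$occurrences_a) == 1L && nrow(g$occurrences_b) == 1L) {
      g$occurrences_b$cut_boundary - g$occurrences_a$cut_boundary
    } else NA_integer_
    data.frame(protospacer = g$protospacer,
               n_occ_a = nrow(g$occurrences_a),
               n_occ_b = nrow(g$occurrences_b),
               multi_site = g$multi_site,
               opposite_strand = g$opposite_strand,
               deletion_size = as.integer(size),
               stringsAsFactors = FALSE)
  }))
}

#' Predict deletion and inversion products of a cut pair
#'
#' Simultaneous cuts at two boundaries, rejoined by non-homologous end
#' joining, yield a deletion (intervening segment lost) or an inversion
#' (intervening segment reverse-complemented in place).  For each product
#' the junction is reported as a `2k`-base window centred on the rejoined
#' boundary at `cut_a`: for the deletion this is
#' `genome[cut_a-k, cut_a) + genome[cut_b, cut_b+k)`, for the inversion
#' `genome[cut_a-k, cut_a) + revcomp(genome[cut_b-k, cut_b))`.  Flanks are
#' clipped at contig ends.
#'
#' @param genomes Named character vector of contigs or `assembly_context`.
#' @param contig Contig id.
#' @param cut_a,cut_b 0-based cut boundaries, `cut_a < cut_b`.
#' @param k Junction flank length in bases (default 30).
#' @return A data.frame with one row per product (`deletion`,
#'   `inversion`): `kind`, `contig`, `cut_a`, `cut_b`, `size`, `junction`.
#' @export
predict_products <- function(genomes, contig, cut_a, cut_b, k = 30L) {
  seq <- get_contig(genomes, contig)
  n <- nchar(seq)
  cut_a <- as.integer(cut_a); cut_b <- as.integer(cut_b); k <- as.integer(k)
  if (cut_a < 0L || cut_b > n) stop("cut boundaries outside contig bounds")
  if (cut_a >= cut_b) stop("cut_a must be strictly left of cut_b")
  left <- substr(seq, max(1L, cut_a - k + 1L), cut_a)
  del_j <- paste0(left, substr(seq, cut_b + 1L, min(n, cut_b + k)))
  inv_right <- reverse_complement(substr(seq, max(1L, cut_b - k + 1L), cut_b))
  inv_j <- paste0(left, substr(inv_right, 1L, k))
  data.frame(kind = c("deletion", "inversion"), contig = contig,
             cut_a = cut_a, cut_b = cut_b, size = cut_b - cut_a,
             junction = c(del_j, inv_j), stringsAsFactors = FALSE)
}

#' Apply a rearrangement to a contig sequence
#'
#' Returns the full sequence after the deletion (segment `[cut_a, cut_b)`
#' removed) or inversion (segment reverse-complemented in place).  Mainly
#' useful on small synthetic loci and in tests.
#'
#' @inheritParams predict_products
#' @param kind `"deletion"` or `"inversion"`.
#' @return A single character string.
#' @export
apply_rearrangement <- function(genomes, contig, cut_a, cut_b,
                                kind = c("deletion", "inversion")) {
  kind <- match.arg(kind)
  seq <- get_contig(genomes, contig)
  n <- nchar(seq)
  cut_a <- as.integer(cut_a); cut_b <- as.integer(cut_b)
  if (cut_a < 0L || cut_b > n || cut_a >= cut_b) {
    stop("invalid cut boundaries")
  }
  pre <- substr(seq, 1L, cut_a)
  post <- substr(seq, cut_b + 1L, n)
  mid <- if (kind == "deletion") "" else {
    reverse_complement(substr(seq, cut_a + 1L, cut_b))
  }
  paste0(pre, mid, post)
}

#' Enumerate products over all cut pairs of a shared guide
#'
#' When a repeat holds several occurrences of the guide, every
#' (occurrence-A, occurrence-B) pair is enumerated; the `multi_site` flag
#' is carried into the output.
#'
#' @param assembly An `assembly_context` or named contig vector.
#' @param guide A `score_guide` (element of a `score_guide_set`).
#' @param k Junction flank length.
#' @return A data.frame of products, one deletion + one inversion row per
#'   cut pair, with `protospacer` and `multi_site` columns.
#' @export
guide_products <- function(assembly, guide, k = 30L) {
  stopifnot(inherits(guide, "score_guide"))
  rows <- list()
  for (i in seq_len(nrow(guide$occurrences_a))) {
    for (j in seq_len(nrow(guide$occurrences_b))) {
      a <- guide$occurrences_a[i, ]
      b <- guide$occurrences_b[j, ]
      pr <- predict_products(assembly, a$contig, a$cut_boundary,
                             b$cut_boundary, k = k)
      pr$protospacer <- guide$protospacer
      pr$multi_site <- guide$multi_site
      rows[[length(rows) + 1L]] <- pr
    }
  }
  do.call(rbind, rows)
}
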