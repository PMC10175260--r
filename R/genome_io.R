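# FASTA / BED input-output and the coordinate conventions used throughout:
# sequences are uppercase strings over {A,C,G,T,N}; intervals are 0-based
# half-open [start, end), exactly as in BED.

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased on load (soft-masked lowercase is treated as
#' ordinary sequence).  IUPAC ambiguity codes other than N are either
#' rejected or mapped to N.
#'
#' @param path Path to a FASTA file.
#' @param ambiguous Either `"error"` (default) to reject ambiguity codes
#'   other than N, or `"N"` to silently map them to N.
#' @return A named character vector, one uppercase sequence per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, ambiguous = c("error", "N")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  # keep the first whitespace-delimited token of each header, as aligners do
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  amb <- grepl("[^ACGTN]", seqs)
  if (any(amb)) {
    if (ambiguous == "error") {
      stop("sequence '", names(seqs)[which(amb)[1L]],
           "' contains IUPAC codes other than N; ",
           "use ambiguous = \"N\" to mask them")
    }
    seqs[amb] <- gsub("[^ACGTN]", "N", seqs[amb])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genomic intervals from a BED3+ file
#'
#' BED's native 0-based half-open coordinates are kept unchanged.  Column 4
#' supplies the interval name when present; otherwise names are
#' `region_<i>`.  `track`, `browser` and `#` lines are skipped.  Input
#' record order is preserved.
#'
#' @param path Path to a BED file.
#' @param assembly Assembly label to stamp on every interval.
#' @return A data.frame with columns `contig`, `start`, `end`, `name`,
#'   `assembly`.
#' @export
read_intervals <- function(path, assembly = NA_character_) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) stop("no interval records in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("BED record ", i, " in '", path, "' has fewer than 3 columns")
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("BED record ", i, " in '", path, "' has non-numeric coordinates")
    }
    if (start < 0L || start >= end) {
      stop("BED record ", i, " in '", path,
           "' is not a valid half-open interval (start=", start,
           ", end=", end, ")")
    }
    name <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else paste0("region_", i)
    out[[i]] <- data.frame(contig = f[1L], start = start, end = end,
                           name = name, assembly = assembly,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write intervals as BED
#'
#' @param intervals Interval data.frame as returned by [read_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end", "name") %in% names(intervals)))
  write.table(intervals[, c("contig", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' Alphabet is restricted to {A,C,G,T,N}; N maps to N.  Vectorised over
#' `seq`.
#'
#' @param seq Character vector of DNA sequences (may include `""`).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGTGCCGTCGAGAAGCGCCA")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         seq[which(bad)[1L]])
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Bundle a genome with its region annotations
#'
#' An assembly context pairs a set of contig sequences with the LCR /
#' region intervals annotated on them, under one assembly label.  Every
#' annotation must resolve against a loaded contig and annotation names
#' must be unique.
#'
#' @param label Assembly label, e.g. `"GRCh38"`.
#' @param genomes Named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param intervals Interval data.frame (see [read_intervals()]).
#' @return An object of class `assembly_context`.
#' @export
assembly_context <- function(label, genomes, intervals) {
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  stopifnot(all(c("contig", "start", "end", "name") %in% names(intervals)))
  if (anyDuplicated(intervals$name)) {
    stop("annotation names must be unique within an assembly; duplicated: ",
         intervals$name[duplicated(intervals$name)][1L])
  }
  missing <- setdiff(intervals$contig, names(genomes))
  if (length(missing)) {
    stop("annotation contig(s) not present in genome: ",
         paste(missing, collapse = ", "))
  }
  lens <- nchar(genomes)[intervals$contig]
  over <- intervals$end > lens
  if (any(over)) {
    stop("annotation '", intervals$name[which(over)[1L]],
         "' extends beyond its contig")
  }
  intervals$assembly <- label
  structure(list(assembly = label, genomes = genomes,
                 lcr_annotations = intervals),
            class = "assembly_context")
}

#' @export
print.assembly_context <- function(x, ...) {
  cat("<assembly_context> ", x$assembly, "\n", sep = "")
  cat("  contigs: ", length(x$genomes), " (",
      format(sum(nchar(x$genomes)), big.mark = ","), " bp)\n", sep = "")
  cat("  annotations: ", nrow(x$lcr_annotations), " [",
      paste(head(x$lcr_annotations$name, 6L), collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Load an assembly context from FASTA + BED paths
#'
#' @inheritParams assembly_context
#' @param fasta Path to the genome FASTA.
#' @param bed Path to the annotation BED.
#' @param ambiguous Passed to [read_fasta()].
#' @return An `assembly_context`.
#' @export
load_assembly <- function(label, fasta, bed, ambiguous = "error") {
  assembly_context(label, read_fasta(fasta, ambiguous = ambiguous),
                   read_intervals(bed, assembly = label))
}

# Look up a named annotation; used by the cross-assembly verifier.
get_annotation <- function(ctx, name) {
  stopifnot(inherits(ctx, "assembly_context"))
  hit <- ctx$lcr_annotations[ctx$lcr_annotations$name == name, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("assembly '", ctx$assembly, "' lacks annotation '", name, "'")
  }
  hit[1L, , drop = FALSE]
}

get_contig <- function(genomes, contig) {
  if (inherits(genomes, "assembly_context")) genomes <- genomes$genomes
  if (!contig %in% names(genomes)) {
    stop("contig '", contig, "' not present in genome")
  }
  genomes[[contig]]
}
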