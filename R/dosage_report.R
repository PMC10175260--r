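# Region-dosage summaries: per-feature log2 fold change (deletion vs
# control) and the mean over features inside vs outside the deleted
# interval, the computation behind "transcripts/proteins encoded within
# the deletion show lower expression" figures.

#' Construct a feature matrix
#'
#' Normalized, non-negative abundances per (feature, sample) with genomic
#' coordinates per feature and a deletion/control label per sample.
#'
#' @param features Data.frame with columns `feature`, `contig`, `start`,
#'   `end` (0-based half-open; NA coordinates allowed, such features are
#'   excluded from summaries with a warning count).
#' @param values Numeric matrix, rows = features (rownames must equal
#'   `features$feature`), columns = samples.
#' @param groups Named character vector mapping each sample to
#'   `"deletion"` or `"control"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, values, groups) {
  stopifnot(all(c("feature", "contig", "start", "end") %in% names(features)))
  stopifnot(is.matrix(values), nrow(values) == nrow(features))
  if (is.null(rownames(values))) rownames(values) <- features$feature
  stopifnot(identical(rownames(values), features$feature))
  stopifnot(all(colnames(values) %in% names(groups)))
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("deletion", "control"))) {
    stop("group labels must be 'deletion' or 'control'")
  }
  if (!all(c("deletion", "control") %in% groups)) {
    stop("both groups need at least one sample")
  }
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  structure(list(features = features, values = values, groups = groups),
            class = "feature_matrix")
}

#' Region-dosage log2 fold-change summary
#'
#' Per feature, `l2fc = log2((mean_deletion + pseudocount) /
#' (mean_control + pseudocount))`.  Features overlapping the region are
#' `in_region`; all other features on the same contig are `flanking`;
#' features on other contigs or without coordinates are excluded (their
#' count is reported).  A heterozygous deletion is expected to put the
#' in-region mean near -1 and the flanking mean near 0.
#'
#' @param fm A [feature_matrix()].
#' @param region One-row interval data.frame (the deleted region).
#' @param pseudocount Stabilizer added to both group means (default 0.5).
#' @return An object of class `dosage_summary`: list with `per_feature`
#'   (data.frame: feature, contig, start, end, set, l2fc),
#'   `in_region_mean`, `flanking_mean`, `n_excluded`, `region`.
#' @export
region_log2fc <- function(fm, region, pseudocount = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  region <- region[1L, , drop = FALSE]
  del <- fm$values[, fm$groups == "deletion", drop = FALSE]
  ctl <- fm$values[, fm$groups == "control", drop = FALSE]
  l2fc <- log2((rowMeans(del) + pseudocount) /
                 (rowMeans(ctl) + pseudocount))
  ft <- fm$features
  has_coord <- !is.na(ft$contig) & !is.na(ft$start) & !is.na(ft$end)
  same_contig <- has_coord & ft$contig == region$contig
  overlaps <- same_contig & ft$start < region$end & ft$end > region$start
  set <- rep("excluded", nrow(ft))
  set[same_contig] <- "flanking"
  set[overlaps] <- "in_region"
  n_excluded <- sum(set == "excluded")
  if (n_excluded > 0L) {
    warning(n_excluded,
            " feature(s) without usable coordinates on the region contig ",
            "were excluded from the dosage summary")
  }
  per <- data.frame(feature = ft$feature, contig = ft$contig,
                    start = ft$start, end = ft$end, set = set,
                    l2fc = unname(l2fc), stringsAsFactors = FALSE)
  structure(list(
    per_feature = per,
    in_region_mean = mean(per$l2fc[per$set == "in_region"]),
    flanking_mean = mean(per$l2fc[per$set == "flanking"]),
    n_excluded = n_excluded,
    region = region,
    pseudocount = pseudocount
  ), class = "dosage_summary")
}

#' @export
print.dosage_summary <- function(x, ...) {
  cat("<dosage_summary> region ", x$region$name, " (", x$region$contig,
      ":", x$region$start, "-", x$region$end, ")\n", sep = "")
  cat(sprintf("  in-region mean log2FC: %.3f over %d features\n",
              x$in_region_mean, sum(x$per_feature$set == "in_region")))
  cat(sprintf("  flanking  mean log2FC: %.3f over %d features\n",
              x$flanking_mean, sum(x$per_feature$set == "flanking")))
  if (x$n_excluded) cat("  excluded (no coordinates):", x$n_excluded, "\n")
  invisible(x)
}

#' Read a feature matrix from TSV plus a group map
#'
#' The matrix TSV carries columns `feature`, `contig`, `start`, `end`
#' followed by one numeric column per sample; the group map TSV has
#' columns `sample` and `group`.
#'
#' @param matrix_path,groups_path Paths to the two TSV files.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(matrix_path, groups_path) {
  df <- read.delim(matrix_path, stringsAsFactors = FALSE)
  gm <- read.delim(groups_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(gm)))
  meta <- c("feature", "contig", "start", "end")
  stopifnot(all(meta %in% names(df)))
  samples <- setdiff(names(df), meta)
  values <- as.matrix(df[, samples, drop = FALSE])
  rownames(values) <- df$feature
  feature_matrix(df[, meta], values, setNames(gm$group, gm$sample))
}

#' Write a dosage summary (TSV + JSON)
#'
#' @param summary A `dosage_summary`.
#' @param tsv,json Output paths (either may be NULL).
#' @return `summary`, invisibly.
#' @export
write_dosage_summary <- function(summary, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    write.table(summary$per_feature, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      region = summary$region,
      in_region_mean = summary$in_region_mean,
      flanking_mean = summary$flanking_mean,
      n_in_region = sum(summary$per_feature$set == "in_region"),
      n_flanking = sum(summary$per_feature$set == "flanking"),
      n_excluded = summary$n_excluded,
      pseudocount = summary$pseudocount
    ), json, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
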