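# Cross-assembly verification: run the shared-guide search and the
# specificity filter independently per assembly and demand that every
# assembly agrees.  Assemblies are linked by annotation *names*, never by
# coordinates, so no liftover is involved.

#' Default exempt region for a repeat pair
#'
#' The two flanking repeats plus the intervening CNV segment, as a single
#' interval spanning from the start of the left repeat to the end of the
#' right one.  On-target cutting inside this span is the point of the
#' design and must not count against specificity.
#'
#' @param lcr_a,lcr_b One-row interval data.frames (left, right repeat).
#' @return A one-row interval data.frame.
#' @export
exempt_span <- function(lcr_a, lcr_b) {
  data.frame(contig = lcr_a$contig[1L], start = lcr_a$start[1L],
             end = lcr_b$end[1L], name = "on_target_span",
             stringsAsFactors = FALSE)
}

#' Verify guides across genome assemblies
#'
#' For each assembly, checks (i) that the protospacer is still shared by
#' the two named repeat annotations and (ii) that it passes the
#' specificity filter on that assembly.  The overall verdict is the strict
#' conjunction over assemblies, mirroring a design cross-checked against
#' e.g. GRCh38 and GRCh37 to rule out reference-update artifacts.
#'
#' @param guides A `score_guide_set`, or character vector of protospacers.
#' @param assemblies List of `assembly_context` objects.
#' @param lcr_names Character(2): the annotation names of the left and
#'   right repeat, which must exist in every assembly.
#' @param policy A [specificity_policy()]; its `exempt_intervals` are
#'   recomputed per assembly as the repeat-pair span.
#' @param method Off-target scan engine.
#' @return An object of class `verification_report`: list with
#'   `per_assembly` (data.frame: protospacer, assembly, shared_in_lcrs,
#'   specificity_pass, n_occ_a, n_occ_b) and `overall` (data.frame:
#'   protospacer, overall_pass).
#' @export
verify_guides <- function(guides, assemblies, lcr_names,
                          policy = specificity_policy(), method = "shift") {
  stopifnot(length(lcr_names) == 2L, length(assemblies) >= 1L)
  protos <- if (is.character(guides)) guides else {
    vapply(guides, function(g) g$protospacer, character(1L))
  }
  per <- list()
  for (ctx in assemblies) {
    stopifnot(inherits(ctx, "assembly_context"))
    lcr_a <- get_annotation(ctx, lcr_names[1L])
    lcr_b <- get_annotation(ctx, lcr_names[2L])
    shared <- find_shared_guides(ctx, lcr_a, lcr_b, pam = policy$pam)
    shared_protos <- vapply(shared, function(g) g$protospacer, character(1L))
    pol <- specificity_policy(
      min_mismatches = policy$min_mismatches, pam = policy$pam,
      exempt_intervals = exempt_span(lcr_a, lcr_b),
      max_scan_mismatches = policy$max_scan_mismatches,
      allow_nag = policy$allow_nag)
    for (p in protos) {
      idx <- match(p, shared_protos)
      n_a <- n_b <- 0L
      if (!is.na(idx)) {
        n_a <- nrow(shared[[idx]]$occurrences_a)
        n_b <- nrow(shared[[idx]]$occurrences_b)
      }
      hits <- scan_offtargets(p, ctx, pol, method = method)
      bad <- hits[!hits$exempt & hits$mismatches < pol$min_mismatches, ,
                  drop = FALSE]
      per[[length(per) + 1L]] <- data.frame(
        protospacer = p, assembly = ctx$assembly,
        shared_in_lcrs = !is.na(idx),
        specificity_pass = nrow(bad) == 0L,
        n_occ_a = n_a, n_occ_b = n_b, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  pass <- tapply(per$shared_in_lcrs & per$specificity_pass,
                 per$protospacer, all)
  overall <- data.frame(protospacer = names(pass),
                        overall_pass = as.logical(pass),
                        stringsAsFactors = FALSE)
  overall <- overall[match(unique(protos), overall$protospacer), ,
                     drop = FALSE]
  rownames(overall) <- NULL
  structure(list(per_assembly = per, overall = overall),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("<verification_report> ", nrow(x$overall), " guide(s) across ",
      length(unique(x$per_assembly$assembly)), " assembly(ies)\n", sep = "")
  print(x$overall)
  invisible(x)
}

#' Write a verification report (TSV + JSON)
#'
#' @param report A `verification_report`.
#' @param tsv,json Output paths (either may be NULL to skip).
#' @return `report`, invisibly.
#' @export
write_verification_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    write.table(report$per_assembly, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(per_assembly = report$per_assembly, overall = report$overall),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
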