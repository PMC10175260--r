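# End-to-end orchestration: shared-guide search -> specificity filter ->
# cross-assembly verification -> product prediction, with TSV/BED/JSON
# outputs and a run report whose stage counts are monotone
# (accepted <= post-filter <= shared <= enumerated).

#' Read a run configuration from YAML
#'
#' Expected layout:
#' ```yaml
#' assemblies:
#'   - {label: GRCh38, fasta: genome38.fa, bed: lcrs38.bed}
#'   - {label: GRCh37, fasta: genome37.fa, bed: lcrs37.bed}
#' lcr_pair: [LCR_A, LCR_B]
#' policy: {min_mismatches: 4, allow_nag: false, pam: NGG}
#' junction_flank: 30
#' out_dir: results
#' seed: 1
#' ```
#'
#' @param path Path to a YAML file.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$assemblies) || length(cfg$assemblies) < 1L) {
    stop("config needs at least one assembly (label, fasta, bed)")
  }
  if (is.null(cfg$lcr_pair) || length(cfg$lcr_pair) != 2L) {
    stop("config needs exactly one lcr_pair of two annotation names")
  }
  cfg$policy <- cfg$policy %||% list()
  cfg$policy$min_mismatches <- cfg$policy$min_mismatches %||% 4L
  cfg$policy$allow_nag <- isTRUE(cfg$policy$allow_nag)
  cfg$policy$pam <- cfg$policy$pam %||% "NGG"
  cfg$junction_flank <- cfg$junction_flank %||% 30L
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full deletion-design pipeline
#'
#' Loads the configured assemblies, finds guides shared by the two named
#' repeat annotations on the first assembly, filters them for
#' specificity, cross-verifies against every configured assembly (when
#' more than one), and predicts the rearrangement products of the
#' verified guides.  Writes `guides.tsv`, `guides.bed`, `products.tsv`
#' and `report.json` into `out_dir`.  An empty final guide set is a
#' warning, not an error.
#'
#' @param config A configuration list (see [read_run_config()]) or path
#'   to a YAML file.
#' @return The run report list, invisibly.
#' @export
run_design <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  assemblies <- lapply(cfg$assemblies, function(a) {
    load_assembly(a$label, a$fasta, a$bed)
  })
  primary <- assemblies[[1L]]
  lcr_a <- get_annotation(primary, cfg$lcr_pair[[1L]])
  lcr_b <- get_annotation(primary, cfg$lcr_pair[[2L]])
  pam <- pam_rule(cfg$policy$pam)
  policy <- specificity_policy(
    min_mismatches = cfg$policy$min_mismatches, pam = pam,
    exempt_intervals = exempt_span(lcr_a, lcr_b),
    allow_nag = cfg$policy$allow_nag)

  shared <- find_shared_guides(primary, lcr_a, lcr_b, pam = pam)
  filt <- apply_specificity_filter(shared, primary, policy)
  post_filter <- filt$accepted

  if (length(assemblies) > 1L) {
    ver <- verify_guides(post_filter, assemblies, unlist(cfg$lcr_pair),
                         policy = policy)
    keep <- ver$overall$protospacer[ver$overall$overall_pass]
    accepted <- structure(
      Filter(function(g) g$protospacer %in% keep, post_filter),
      class = "score_guide_set")
  } else {
    ver <- NULL
    accepted <- post_filter
  }

  products <- do.call(rbind, lapply(accepted, function(g) {
    guide_products(primary, g, k = cfg$junction_flank)
  }))
  if (is.null(products)) {
    products <- data.frame(kind = character(), contig = character(),
                           cut_a = integer(), cut_b = integer(),
                           size = integer(), junction = character(),
                           protospacer = character(),
                           multi_site = logical())
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  guides_df <- as.data.frame(accepted)
  write.table(guides_df, file.path(cfg$out_dir, "guides.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  occ <- do.call(rbind, lapply(accepted, function(g) {
    rbind(g$occurrences_a, g$occurrences_b)
  }))
  if (!is.null(occ)) {
    write_guides_bed(occ, file.path(cfg$out_dir, "guides.bed"))
  } else {
    file.create(file.path(cfg$out_dir, "guides.bed"))
  }
  write.table(products, file.path(cfg$out_dir, "products.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  n_enum <- attr(shared, "n_enumerated")
  report <- list(
    tool = "scoredel",
    version = as.character(utils::packageVersion("scoredel")),
    parameters = list(
      lcr_pair = unlist(cfg$lcr_pair),
      min_mismatches = policy$min_mismatches,
      allow_nag = policy$allow_nag, pam = pam$pattern,
      junction_flank = cfg$junction_flank,
      assemblies = vapply(assemblies, function(a) a$assembly,
                          character(1L)),
      seed = cfg$seed %||% NA),
    input_digests = lapply(cfg$assemblies, function(a) {
      list(label = a$label,
           fasta_md5 = unname(tools::md5sum(a$fasta)),
           bed_md5 = unname(tools::md5sum(a$bed)))
    }),
    counts = list(
      enumerated = unname(n_enum["a"] + n_enum["b"]),
      shared = length(shared),
      post_filter = length(post_filter),
      accepted = length(accepted)),
    accepted_protospacers = vapply(accepted, function(g) g$protospacer,
                                   character(1L)),
    verification = if (is.null(ver)) NULL else ver$overall
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (length(accepted) == 0L) {
    warning("no guide passed the design filters; outputs are empty")
  }
  invisible(report)
}
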