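#' Intersect gate, expression and DEG evidence into candidate targets
#'
#' Implements the candidate-intersection chain of the Venn workflow:
#' genes passing the active-promoter gate exclusively in the focal
#' condition, restricted to genes expressed in the focal cells, intersected
#' with genes differentially expressed (TF-positive vs TF-negative)
#' exclusively in the focal condition. The report stores every intermediate
#' set, so the per-step cardinalities are derived views.
#'
#' @param gate_ledger A [gene_set_ledger()] of gated gene sets per
#'   condition (one set per condition).
#' @param deg_ledger A [gene_set_ledger()] of DEG gene sets per condition.
#' @param expressed Character vector: genes expressed in the focal cells.
#' @param focal Name of the focal condition; must key a set in both
#'   ledgers.
#' @param config Optional arbitrary configuration object; hashed into the
#'   provenance block.
#' @param deg_table Optional [diff_expr()] result used to annotate and
#'   order the candidate table.
#' @param per_mark_sets Optional named list of per-mark gene sets for the
#'   focal condition (gate evidence columns in the candidate table).
#' @param seed Optional integer recorded in the provenance block.
#' @return An object of class `discovery_report` with elements `focal`,
#'   `sets` (named list: per-condition gate sets, `gate_focal_only`,
#'   `expressed_filtered`, `deg_focal_only`, `candidates`),
#'   `cardinalities`, `candidate_table`, `provenance`.
#' @export
discover_targets <- function(gate_ledger, deg_ledger, expressed, focal,
                             config = NULL, deg_table = NULL,
                             per_mark_sets = NULL, seed = NULL) {
  stopifnot(inherits(gate_ledger, "gene_set_ledger"),
            inherits(deg_ledger, "gene_set_ledger"))
  if (!focal %in% names(gate_ledger$sets)) {
    stop("focal condition '", focal, "' absent from the gate ledger")
  }
  if (!focal %in% names(deg_ledger$sets)) {
    stop("focal condition '", focal, "' absent from the DEG ledger")
  }
  expressed <- sort(unique(as.character(expressed)))
  gate_focal_only <- exclusive_membership(gate_ledger, focal)
  deg_focal_only <- exclusive_membership(deg_ledger, focal)
  expressed_filtered <- intersect(gate_focal_only, expressed)
  candidates <- sort(intersect(expressed_filtered, deg_focal_only))

  sets <- c(
    stats::setNames(gate_ledger$sets, paste0("gate_", names(gate_ledger$sets))),
    list(gate_focal_only = gate_focal_only,
         expressed_filtered = sort(expressed_filtered),
         deg_focal_only = deg_focal_only,
         candidates = candidates)
  )
  tab <- data.frame(gene_id = candidates, stringsAsFactors = FALSE)
  if (!is.null(per_mark_sets)) {
    for (mk in names(per_mark_sets)) {
      tab[[paste0("has_", mk)]] <- tab$gene_id %in% per_mark_sets[[mk]]
    }
  }
  if (!is.null(deg_table)) {
    idx <- match(tab$gene_id, deg_table$gene_id)
    tab$log2_fold_change <- deg_table$log2_fold_change[idx]
    tab$p_value <- deg_table$p_value[idx]
    tab$q_value <- deg_table$q_value[idx]
    # deterministic ordering: strongest fold change first, ties by id
    ord <- order(-abs(tab$log2_fold_change), tab$gene_id)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
  }
  report <- structure(
    list(
      focal = focal,
      sets = sets,
      cardinalities = vapply(sets, length, integer(1)),
      candidate_table = tab,
      provenance = list(
        config_hash = rlang::hash(config),
        input_digest = rlang::hash(list(gate_ledger$sets, deg_ledger$sets,
                                        expressed)),
        seed = seed
      )
    ),
    class = "discovery_report"
  )
  validate_report(report)
  report
}

#' Assert the internal consistency of a discovery report
#'
#' Checks the subset chain
#' `candidates <= expressed_filtered <= gate_focal_only <= gate_<focal>`,
#' `candidates <= deg_focal_only`, and that every stored cardinality equals
#' the length of its set.
#'
#' @param report A `discovery_report`.
#' @return `report`, invisibly; errors if any invariant fails.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "discovery_report"))
  s <- report$sets
  gate_focal <- s[[paste0("gate_", report$focal)]]
  stopifnot(
    all(s$gate_focal_only %in% gate_focal),
    all(s$expressed_filtered %in% s$gate_focal_only),
    all(s$candidates %in% s$expressed_filtered),
    all(s$candidates %in% s$deg_focal_only),
    identical(unname(report$cardinalities),
              unname(vapply(s, length, integer(1))))
  )
  invisible(report)
}

#' @exportS3Method base::print
print.discovery_report <- function(x, ...) {
  cat("<discovery_report> focal condition:", x$focal, "\n")
  for (nm in names(x$cardinalities)) {
    cat(sprintf("  %-20s %d\n", nm, x$cardinalities[[nm]]))
  }
  invisible(x)
}

#' Write a discovery report to disk
#'
#' Writes `report.json` (cardinalities, sets, provenance),
#' `candidates.tsv`, `ledger.tsv` (all stored sets) and `venn.tsv`
#' (region counts over the gate ledger's conditions).
#'
#' @param report A `discovery_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "discovery_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(focal = report$focal,
         cardinalities = as.list(report$cardinalities),
         sets = report$sets,
         provenance = report$provenance),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  utils::write.table(report$candidate_table, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ledger(gene_set_ledger(report$sets), file.path(dir, "ledger.tsv"))
  gate_sets <- report$sets[startsWith(names(report$sets), "gate_") &
                             !names(report$sets) %in% "gate_focal_only"]
  if (length(gate_sets) >= 1L && any(lengths(gate_sets) > 0)) {
    utils::write.table(venn_counts(gene_set_ledger(gate_sets)),
                       file.path(dir, "venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
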