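#' Configuration for the active-promoter gate
#'
#' The gate asks, per gene and condition, whether the TF and both activating
#' histone marks (H3K27ac, H3K4me3) each have at least one peak within
#' `window_halfwidth` bp of the TSS, while the repressive mark (H3K27me3)
#' has none. The promoter window is the closed +/- `window_halfwidth`
#' neighbourhood of the TSS, i.e. `2 * window_halfwidth + 1` bp.
#'
#' @param window_halfwidth Half-width of the TSS window in bp (default 1000,
#'   the +/- 1.0 kb convention).
#' @param activation_marks Marks that must all be present.
#' @param repression_mark Mark that must be absent.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(window_halfwidth = 1000L,
                        activation_marks = c("TF", "H3K27ac", "H3K4me3"),
                        repression_mark = "H3K27me3") {
  window_halfwidth <- as.integer(window_halfwidth)
  stopifnot(length(window_halfwidth) == 1L, window_halfwidth > 0L)
  stopifnot(all(activation_marks %in% MARK_LEVELS),
            repression_mark %in% MARK_LEVELS,
            !(repression_mark %in% activation_marks))
  structure(
    list(window_halfwidth = window_halfwidth,
         activation_marks = activation_marks,
         repression_mark = repression_mark),
    class = "gate_config"
  )
}

#' Promoter windows around gene TSSs
#'
#' Returns the 0-based half-open interval `[tss - w, tss + w + 1)` for each
#' gene, left-clipped at 0. The window covers the TSS base itself plus `w`
#' bp on either side; gene strand enters only through the TSS position.
#'
#' @param genes A [gene_table()].
#' @param config A [gate_config()].
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' g <- gene_table("g1", "g1", "chr1", 4000L, 7000L, "+")
#' promoter_window(g, gate_config())  # [3000, 5001)
promoter_window <- function(genes, config = gate_config()) {
  stopifnot(inherits(genes, "gene_table"), inherits(config, "gate_config"))
  w <- config$window_halfwidth
  data.frame(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - w),
    end = genes$tss + w + 1L,
    stringsAsFactors = FALSE
  )
}

#' Genes whose promoter window overlaps at least one peak
#'
#' A gene is included iff at least one peak of the given set overlaps its
#' promoter window by >= 1 bp. Implemented with the interval index of
#' [GenomicRanges::findOverlaps()], but contractually identical to all-pairs
#' overlap testing. Peaks on chromosomes absent from the annotation are
#' dropped with a warning.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_table()].
#' @param config A [gate_config()].
#' @return Sorted character vector of gene ids.
#' @export
genes_with_mark <- function(peaks, genes, config = gate_config()) {
  stopifnot(inherits(peaks, "peak_set"))
  win <- promoter_window(genes, config)
  unknown <- setdiff(unique(peaks$peaks$chrom), unique(genes$chrom))
  pk <- peaks$peaks
  if (length(unknown)) {
    warning("ignoring peaks on chromosome(s) absent from the annotation: ",
            paste(unknown, collapse = ", "))
    pk <- pk[!(pk$chrom %in% unknown), , drop = FALSE]
  }
  if (nrow(pk) == 0L) return(character())
  gr_win <- GenomicRanges::GRanges(win$chrom,
                                   IRanges::IRanges(win$start + 1L, win$end))
  gr_pk <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1L, pk$end))
  hits <- GenomicRanges::findOverlaps(gr_win, gr_pk, minoverlap = 1L)
  sort(unique(win$gene_id[S4Vectors::queryHits(hits)]))
}

#' Apply the four-mark active-promoter gate
#'
#' Given per-mark gene sets for one condition (from [genes_with_mark()]),
#' returns the genes carrying all activation marks and lacking the
#' repressive mark: the intersection over `activation_marks` minus the
#' `repression_mark` set.
#'
#' @param per_mark_sets Named list of gene-id character vectors; must
#'   contain every activation mark and the repression mark as keys.
#' @param config A [gate_config()].
#' @return Sorted character vector of gene ids passing the gate.
#' @export
active_promoter_gate <- function(per_mark_sets, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"))
  need <- c(config$activation_marks, config$repression_mark)
  missing <- setdiff(need, names(per_mark_sets))
  if (length(missing)) {
    stop("per_mark_sets lacks required mark(s): ", paste(missing, collapse = ", "))
  }
  act <- Reduce(intersect, per_mark_sets[config$activation_marks])
  sort(setdiff(act, per_mark_sets[[config$repression_mark]]))
}

#' Per-condition gate over peak sets
#'
#' Convenience wrapper running [genes_with_mark()] for every mark of one
#' condition and applying [active_promoter_gate()].
#'
#' @param peak_sets Named list of [peak_set()] objects for one condition;
#'   names are ignored, marks are read from the objects.
#' @param genes A [gene_table()].
#' @param config A [gate_config()].
#' @return List with `gated` (gene ids passing the gate) and
#'   `per_mark` (named list of per-mark gene sets).
#' @export
gate_condition <- function(peak_sets, genes, config = gate_config()) {
  marks <- vapply(peak_sets, function(p) p$mark, character(1))
  per_mark <- lapply(peak_sets, genes_with_mark, genes = genes, config = config)
  names(per_mark) <- marks
  list(gated = active_promoter_gate(per_mark, config), per_mark = per_mark)
}
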