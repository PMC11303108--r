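#' Configuration for the TF-positive vs TF-negative DEG stage
#'
#' @param tf_gene_id Gene id of the transcription factor used to split cells.
#' @param alpha_fdr FDR threshold on BH q-values for calling a DEG
#'   (default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 0.25).
#' @param positive_threshold Minimal raw TF count for a cell to be called
#'   TF-positive (default 1).
#' @param expressed_min_fraction A gene counts as expressed when detected
#'   (raw count > 0) in at least this fraction of the relevant cells
#'   (default 0.01).
#' @param pseudocount Pseudocount added on the counts-per-10k scale before
#'   the log fold change (default 1).
#' @return An object of class `deg_config`.
#' @export
deg_config <- function(tf_gene_id = NULL, alpha_fdr = 0.05,
                       min_abs_log2fc = 0.25, positive_threshold = 1L,
                       expressed_min_fraction = 0.01, pseudocount = 1) {
  stopifnot(alpha_fdr > 0, alpha_fdr < 1, min_abs_log2fc >= 0,
            positive_threshold > 0, expressed_min_fraction > 0,
            pseudocount > 0)
  structure(
    list(tf_gene_id = tf_gene_id, alpha_fdr = alpha_fdr,
         min_abs_log2fc = min_abs_log2fc,
         positive_threshold = as.integer(positive_threshold),
         expressed_min_fraction = expressed_min_fraction,
         pseudocount = pseudocount),
    class = "deg_config"
  )
}

#' Library-size normalize and log-transform counts
#'
#' Each cell is scaled to 10,000 total counts (CP10K) and log1p-transformed.
#' Cells with zero total counts cannot be scaled and are dropped with a
#' warning.
#'
#' @param x A [cell_matrix()].
#' @return An object of class `norm_matrix`: a list with `mat` (sparse
#'   cells x genes log1p CP10K), `cell_meta` (for the kept cells) and
#'   `dropped_cells`.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  if (nrow(x$counts) == 0L || ncol(x$counts) == 0L) stop("empty count matrix")
  totals <- Matrix::rowSums(x$counts)
  drop <- totals == 0
  if (any(drop)) {
    warning(sum(drop), " cell(s) with zero total counts excluded")
  }
  keep <- !drop
  counts <- x$counts[keep, , drop = FALSE]
  sf <- 1e4 / totals[keep]
  scaled <- Matrix::Diagonal(x = sf) %*% counts
  mat <- methods::as(log1p(scaled), "CsparseMatrix")
  dimnames(mat) <- dimnames(counts)
  structure(
    list(mat = mat,
         cell_meta = x$cell_meta[keep, , drop = FALSE],
         dropped_cells = rownames(x$counts)[drop]),
    class = "norm_matrix"
  )
}

#' Classify cells by marker-gene scores
#'
#' Per cell and cell type, the score is the mean normalized expression over
#' the type's marker genes; the label is the argmax. A cell is labelled
#' `"unassigned"` when the top score exceeds the runner-up by less than
#' `min_score_margin` (so exact ties are always unassigned).
#'
#' @param nm A [normalize_counts()] result.
#' @param markers Named list mapping cell type to character vector of marker
#'   gene ids (a marker map). Markers absent from the matrix are dropped
#'   with a warning; a type with no present markers is an error, as is a
#'   marker map with no present markers at all.
#' @param min_score_margin Minimal top-minus-runner-up score margin
#'   (default 0.1, on the log1p CP10K scale).
#' @return Character vector of labels, named by cell id.
#' @export
classify_cells <- function(nm, markers, min_score_margin = 0.1) {
  stopifnot(inherits(nm, "norm_matrix"), is.list(markers), length(markers) >= 1L)
  present <- lapply(markers, intersect, colnames(nm$mat))
  absent <- unlist(mapply(setdiff, markers, present, SIMPLIFY = FALSE))
  if (sum(lengths(present)) == 0L) stop("no marker genes found in the matrix")
  if (length(absent)) {
    warning("marker gene(s) absent from matrix: ", paste(absent, collapse = ", "))
  }
  empty <- names(present)[lengths(present) == 0L]
  if (length(empty)) {
    stop("no markers present for cell type(s): ", paste(empty, collapse = ", "))
  }
  scores <- vapply(present, function(g) {
    Matrix::rowMeans(nm$mat[, g, drop = FALSE])
  }, numeric(nrow(nm$mat)))
  if (nrow(nm$mat) == 1L) scores <- matrix(scores, nrow = 1L,
                                           dimnames = list(rownames(nm$mat),
                                                           names(present)))
  top <- max.col(scores, ties.method = "first")
  labels <- colnames(scores)[top]
  ord <- apply(scores, 1L, function(s) sort(s, decreasing = TRUE)[1:2])
  margin <- if (length(present) >= 2L) ord[1L, ] - ord[2L, ] else Inf
  labels[margin < min_score_margin] <- "unassigned"
  stats::setNames(labels, rownames(nm$mat))
}

#' Split a cell subset into TF-positive and TF-negative cells
#'
#' A cell is TF-positive iff its raw count for the TF gene is at least
#' `positive_threshold`. The two returned id vectors partition the subset.
#'
#' @param x A [cell_matrix()].
#' @param cell_subset Character vector of cell ids to split.
#' @param config A [deg_config()] with `tf_gene_id` set.
#' @return List with `positive` and `negative` cell-id vectors.
#' @export
split_by_tf <- function(x, cell_subset, config) {
  stopifnot(inherits(x, "cell_matrix"), inherits(config, "deg_config"))
  if (length(cell_subset) == 0L) stop("empty cell subset")
  if (is.null(config$tf_gene_id) || !config$tf_gene_id %in% colnames(x$counts)) {
    stop("tf_gene_id absent from the matrix: ", config$tf_gene_id)
  }
  missing <- setdiff(cell_subset, rownames(x$counts))
  if (length(missing)) stop("unknown cell id(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  tf <- x$counts[cell_subset, config$tf_gene_id]
  pos <- cell_subset[tf >= config$positive_threshold]
  neg <- setdiff(cell_subset, pos)
  if (length(pos) == 0L) stop("degenerate split: no TF-positive cells in subset")
  if (length(neg) == 0L) stop("degenerate split: no TF-negative cells in subset")
  list(positive = pos, negative = neg)
}

#' TF-positive vs TF-negative differential expression
#'
#' Per gene: a two-sided Mann-Whitney test between the two cell groups on
#' normalized expression (exact enumeration when both groups have at most 8
#' cells, tie-corrected normal approximation otherwise), BH q-values, and a
#' log2 fold change of group mean CP10K with a pseudocount. A gene is
#' flagged as a DEG when `q_value < alpha_fdr` and
#' `|log2_fold_change| >= min_abs_log2fc`.
#'
#' @param nm A [normalize_counts()] result.
#' @param groupA,groupB Disjoint character vectors of cell ids (each >= 3
#'   cells); the fold change is A over B (TF-positive over TF-negative in
#'   the standard workflow).
#' @param config A [deg_config()].
#' @return A `data.frame` of class `deg_table` with columns `gene_id`,
#'   `log2_fold_change`, `test_statistic` (Mann-Whitney U of A over B),
#'   `p_value`, `q_value`, `direction`, `is_deg`.
#' @export
diff_expr <- function(nm, groupA, groupB, config = deg_config()) {
  stopifnot(inherits(nm, "norm_matrix"), inherits(config, "deg_config"))
  if (length(intersect(groupA, groupB))) stop("groups overlap")
  if (length(groupA) < 3L || length(groupB) < 3L) {
    stop("each group needs at least 3 cells")
  }
  missing <- setdiff(c(groupA, groupB), rownames(nm$mat))
  if (length(missing)) stop("unknown cell id(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  matA <- as.matrix(nm$mat[groupA, , drop = FALSE])
  matB <- as.matrix(nm$mat[groupB, , drop = FALSE])
  rs <- rank_sum_matrix(matA, matB)
  # group means back on the linear CP10K scale, then pseudocounted log ratio
  meanA <- colMeans(expm1(matA))
  meanB <- colMeans(expm1(matB))
  lfc <- log2((meanA + config$pseudocount) / (meanB + config$pseudocount))
  q <- stats::p.adjust(rs$p_value, method = "BH")
  out <- data.frame(
    gene_id = rs$gene_id,
    log2_fold_change = lfc,
    test_statistic = rs$U,
    p_value = rs$p_value,
    q_value = q,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
    is_deg = q < config$alpha_fdr & abs(lfc) >= config$min_abs_log2fc,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Genes expressed in a cell subset
#'
#' A gene is expressed when its raw count is positive in at least
#' `expressed_min_fraction` of the subset's cells.
#'
#' @param x A [cell_matrix()].
#' @param cell_subset Character vector of cell ids (non-empty).
#' @param config A [deg_config()].
#' @return Sorted character vector of gene ids.
#' @export
expressed_genes <- function(x, cell_subset, config = deg_config()) {
  stopifnot(inherits(x, "cell_matrix"))
  if (length(cell_subset) == 0L) stop("empty cell subset")
  sub <- x$counts[cell_subset, , drop = FALSE]
  frac <- Matrix::colMeans(sub > 0)
  sort(colnames(sub)[frac >= config$expressed_min_fraction])
}

#' Mean expression of a gene panel across conditions
#'
#' For each panel gene, the mean normalized expression over cells of the
#' focal type (rods, by default) in every condition (group x timepoint),
#' plus row z-scores (population standard deviation) for heatmap display.
#' Panel genes absent from the matrix are flagged and omitted; a condition
#' without focal cells yields `NA` for that column.
#'
#' @param nm A [normalize_counts()] result.
#' @param labels Cell labels from [classify_cells()], named by cell id.
#' @param panel Character vector of panel gene ids.
#' @param cell_type Focal cell type (default `"rod"`).
#' @return List with `means` and `zscores` (gene x condition matrices) and
#'   `missing_genes`.
#' @export
summarize_panel <- function(nm, labels, panel, cell_type = "rod") {
  stopifnot(inherits(nm, "norm_matrix"))
  missing <- setdiff(panel, colnames(nm$mat))
  if (length(missing)) {
    warning("panel gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  panel <- intersect(panel, colnames(nm$mat))
  if (length(panel) == 0L) stop("no panel genes present in the matrix")
  meta <- nm$cell_meta
  cond <- paste(meta$group, meta$timepoint, sep = "_")
  conds <- unique(cond)
  focal <- names(labels)[labels == cell_type]
  means <- sapply(conds, function(cc) {
    cells <- intersect(meta$cell_id[cond == cc], focal)
    if (length(cells) == 0L) return(rep(NA_real_, length(panel)))
    Matrix::colMeans(nm$mat[cells, panel, drop = FALSE])
  })
  means <- matrix(means, nrow = length(panel),
                  dimnames = list(panel, conds))
  rowz <- function(v) {
    mu <- mean(v, na.rm = TRUE)
    sdp <- sqrt(mean((v - mu)^2, na.rm = TRUE))  # population sd
    out <- if (!is.finite(sdp) || sdp == 0) rep(0, length(v)) else (v - mu) / sdp
    out[is.na(v)] <- NA_real_
    out
  }
  z <- means
  for (i in seq_len(nrow(means))) z[i, ] <- rowz(means[i, ])
  list(means = means, zscores = z, missing_genes = missing)
}

#' Read a marker map from YAML or TSV
#'
#' YAML: a mapping from cell type to a list of marker gene ids. TSV: header
#' columns `cell_type` and `gene_id`.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.tsv`.
#' @return Named list of character vectors.
#' @export
read_marker_map <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    mm <- yaml::read_yaml(path)
    mm <- lapply(mm, as.character)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character")
    mm <- split(df$gene_id, df$cell_type)
  }
  if (any(lengths(mm) == 0L)) stop("marker map contains an empty marker list")
  mm
}
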