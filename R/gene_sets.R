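#' Named gene-set ledger
#'
#' A ledger is a named collection of gene-id sets supporting the Venn and
#' exclusive-membership algebra of the candidate-intersection workflow
#' (e.g. gated genes per condition, DEGs per condition).
#'
#' @param sets Named list of character vectors; names must be unique and
#'   non-empty.
#' @param universe Optional character vector; if given, every member of
#'   every set must belong to it.
#' @return An object of class `gene_set_ledger`.
#' @export
#' @examples
#' led <- gene_set_ledger(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' exclusive_membership(led, "A")
gene_set_ledger <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("sets must have unique non-empty names")
  }
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (!is.null(universe)) {
    universe <- sort(unique(as.character(universe)))
    stray <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(stray)) {
      stop("set members outside the declared universe: ",
           paste(utils::head(stray, 5L), collapse = ", "))
    }
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_ledger")
}

#' @exportS3Method base::print
print.gene_set_ledger <- function(x, ...) {
  cat("<gene_set_ledger>\n")
  for (nm in names(x$sets)) cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Condition-exclusive membership
#'
#' Elements belonging to the named set and to no other set in the ledger —
#' the "only OIR P14" operation of the Venn workflow. For a two-set ledger
#' this reduces to the set difference against the other condition.
#'
#' @param ledger A [gene_set_ledger()].
#' @param target_name Name of the focal set.
#' @return Sorted character vector of elements exclusive to the target set.
#' @export
exclusive_membership <- function(ledger, target_name) {
  stopifnot(inherits(ledger, "gene_set_ledger"))
  if (!target_name %in% names(ledger$sets)) {
    stop("unknown set name: ", target_name)
  }
  others <- unlist(ledger$sets[setdiff(names(ledger$sets), target_name)],
                   use.names = FALSE)
  sort(setdiff(ledger$sets[[target_name]], others))
}

#' Counts of every Venn region of a ledger
#'
#' Enumerates all `2^k - 1` non-empty membership patterns over the ledger's
#' `k` sets and counts the elements falling in each region of the set
#' partition. Region counts sum to the size of the union.
#'
#' @param ledger A [gene_set_ledger()] with at most 6 sets.
#' @return A `data.frame` with one row per pattern: one logical column per
#'   set, a `region` label (names joined by `&`), and `count`.
#' @export
venn_counts <- function(ledger) {
  stopifnot(inherits(ledger, "gene_set_ledger"))
  k <- length(ledger$sets)
  if (k > 6L) stop("venn_counts supports at most 6 sets, got ", k)
  nm <- names(ledger$sets)
  universe <- sort(unique(unlist(ledger$sets, use.names = FALSE)))
  member <- vapply(ledger$sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, nm))
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1L, , drop = FALSE]
  colnames(patterns) <- nm
  key <- apply(member, 1L, paste, collapse = "")
  pkey <- apply(patterns, 1L, paste, collapse = "")
  counts <- as.integer(table(factor(key, levels = pkey))[pkey])
  counts[is.na(counts)] <- 0L
  out <- as.data.frame(patterns)
  out$region <- apply(patterns, 1L, function(p) paste(nm[p], collapse = "&"))
  out$count <- counts
  out
}

#' Write a ledger as TSV
#'
#' Two columns, `set_name` and `gene_id`, one row per membership.
#'
#' @param ledger A [gene_set_ledger()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "gene_set_ledger"))
  rows <- do.call(rbind, lapply(names(ledger$sets), function(nm) {
    s <- ledger$sets[[nm]]
    if (length(s) == 0L) return(NULL)
    data.frame(set_name = nm, gene_id = s, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(set_name = character(), gene_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ledger written by [write_ledger()]
#' @param path TSV path with columns `set_name`, `gene_id`.
#' @param set_names Optional character vector forcing the presence (possibly
#'   empty) and order of sets.
#' @return A [gene_set_ledger()].
#' @export
read_ledger <- function(path, set_names = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  sets <- split(df$gene_id, df$set_name)
  if (!is.null(set_names)) {
    sets <- stats::setNames(lapply(set_names, function(nm) {
      if (nm %in% names(sets)) sets[[nm]] else character()
    }), set_names)
  }
  gene_set_ledger(sets)
}
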