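#' Construct a gene table
#'
#' The gene table is the package's internal gene annotation: one row per
#' gene with 0-based half-open coordinates and a strand-aware transcription
#' start site (TSS). For a `+` strand gene the TSS is `start`; for a `-`
#' strand gene it is `end - 1` (the last covered base). All downstream
#' promoter windows are anchored on this TSS.
#'
#' @param gene_id Character vector of unique gene identifiers (the join key
#'   across all pipeline stages).
#' @param gene_name Character vector of display names; collisions allowed.
#' @param chrom Chromosome names.
#' @param start,end Integer 0-based half-open gene span (`end > start`).
#' @param strand `"+"` or `"-"` per gene.
#' @return A `data.frame` of class `gene_table` with columns `gene_id`,
#'   `gene_name`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
#' @examples
#' gene_table("g1", "GeneA", "chr1", 100L, 500L, "+")$tss
gene_table <- function(gene_id, gene_name, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  gene_name <- as.character(gene_name)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  stopifnot(
    length(gene_name) == n, length(chrom) == n, length(start) == n,
    length(end) == n, length(strand) == n
  )
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene_id: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (any(is.na(start) | is.na(end) | start < 0L | end <= start)) {
    stop("invalid gene interval: need 0 <= start < end for every gene")
  }
  if (any(!nzchar(chrom)) || anyNA(chrom)) stop("chrom must be non-empty")
  if (!all(strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  tss <- ifelse(strand == "+", start, end - 1L)
  out <- data.frame(
    gene_id = gene_id, gene_name = gene_name, chrom = chrom,
    start = start, end = end, strand = strand, tss = as.integer(tss),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Read gene annotation from a GTF file
#'
#' Reads gene-level features from a GTF (1-based inclusive coordinates) and
#' converts them to the internal 0-based half-open convention, computing the
#' strand-aware TSS per gene. Only features whose type is `gene` are used.
#'
#' @param path Path to a GTF file.
#' @return A [gene_table()].
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields, got ",
         nfield[which(nfield != 9L)[1L]])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  if (length(gr) == 0L) stop("no gene features found in ", path)
  if (is.null(gr$gene_id)) stop("GTF gene features lack gene_id attributes")
  gname <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  gname[is.na(gname)] <- gr$gene_id[is.na(gname)]
  gene_table(
    gene_id = gr$gene_id,
    gene_name = gname,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write a gene table as GTF
#'
#' Inverse of [read_gtf()]: emits one `gene` feature per row, converting the
#' internal 0-based half-open coordinates back to GTF's 1-based inclusive.
#'
#' @param genes A [gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  stopifnot(inherits(genes, "gene_table"))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "fostarget"
  gr$type <- "gene"
  gr$gene_id <- genes$gene_id
  gr$gene_name <- genes$gene_name
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
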