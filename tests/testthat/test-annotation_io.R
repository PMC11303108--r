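test_that("GTF coordinates convert to 0-based half-open with strand-aware TSS", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t500\t.\t+\t.\tgene_id "gA"; gene_name "A";',
    'chr1\tsrc\tgene\t101\t500\t.\t-\t.\tgene_id "gB"; gene_name "B";'
  ), gtf)
  gt <- read_gtf(gtf)
  expect_equal(gt$start, c(100L, 100L))
  expect_equal(gt$end, c(500L, 500L))
  expect_equal(gt$tss, c(100L, 499L))
})

test_that("malformed GTF lines and duplicate gene ids are rejected", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t500\t.\t+\t.\tgene_id "gA";',
    "chr1\tonly\tthree"
  ), bad)
  expect_error(read_gtf(bad), "line 2")
  dup <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t500\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\tgene\t601\t900\t.\t+\t.\tgene_id "gA";'
  ), dup)
  expect_error(read_gtf(dup), "duplicate gene_id")
})

test_that("GTF write/read round-trips a 50-gene synthetic table field by field", {
  set.seed(11)
  gt <- random_gene_table(50)
  path <- tempfile(fileext = ".gtf")
  write_gtf(gt, path)
  back <- read_gtf(path)
  back <- back[match(gt$gene_id, back$gene_id), ]
  rownames(back) <- NULL
  for (col in c("gene_id", "gene_name", "chrom", "start", "end", "strand", "tss")) {
    expect_equal(back[[col]], gt[[col]], info = col)
  }
})

test_that("TSS strand symmetry: flipping strand maps start <-> end - 1", {
  set.seed(12)
  gt <- random_gene_table(40)
  flipped <- gene_table(gt$gene_id, gt$gene_name, gt$chrom, gt$start, gt$end,
                        ifelse(gt$strand == "+", "-", "+"))
  expect_true(all(
    (gt$strand == "+" & gt$tss == gt$start & flipped$tss == gt$end - 1L) |
    (gt$strand == "-" & gt$tss == gt$end - 1L & flipped$tss == gt$start)
  ))
})

test_that("BED3 parses exactly and narrowPeak extra columns are ignored", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bed)
  ps <- read_peaks(bed, "TF", "OIR", "P14")
  expect_equal(ps$peaks, data.frame(chrom = "chr1", start = 100L, end = 200L))
  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tpk1\t0\t.\t5.5\t3.2\t2.2\t50", np)
  ps2 <- read_peaks(np, "TF", "OIR", "P14")
  expect_equal(ps2$peaks, ps$peaks)
})

test_that("peak reader rejects bad intervals and unknown mark labels", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t200\t200", bed)
  expect_error(read_peaks(bed, "TF", "OIR", "P14"), "end <= start")
  ok <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", ok)
  expect_error(read_peaks(ok, "H3K9me3", "OIR", "P14"))
})

test_that("peak write/read round-trips 500 random peaks bit-exact", {
  set.seed(13)
  df <- random_peaks_df(500)
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  ps <- peak_set(df, "H3K27ac", "normal", "P14")
  path <- tempfile(fileext = ".bed")
  write_peaks(ps, path)
  expect_equal(read_peaks(path, "H3K27ac", "normal", "P14")$peaks, df)
})

test_that("MTX triplet conserves counts, ignores entry order, and round-trips", {
  dirp <- file.path(tempdir(), "mtx_rt")
  set.seed(14)
  m <- Matrix::rsparsematrix(30, 20, density = 0.2,
                             rand.x = function(n) rpois(n, 3) + 1)
  dimnames(m) <- list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:20))
  meta <- data.frame(cell_id = rownames(m),
                     group = rep(c("normal", "OIR"), each = 15),
                     timepoint = "P14", stringsAsFactors = FALSE)
  cm <- cell_matrix(m, meta)
  write_cell_matrix(cm, dirp)
  back <- read_cell_matrix(file.path(dirp, "matrix.mtx"),
                           file.path(dirp, "barcodes.tsv"),
                           file.path(dirp, "genes.tsv"),
                           file.path(dirp, "meta.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_equal(back$cell_meta$group, meta$group)
  expect_equal(sum(back$counts), sum(m))

  # permuting the MTX entry lines leaves the matrix identical
  lines <- readLines(file.path(dirp, "matrix.mtx"))
  hdr <- grep("^%", lines)
  body <- setdiff(seq_along(lines), c(hdr, max(hdr) + 1L))
  set.seed(15)
  perm <- c(lines[c(hdr, max(hdr) + 1L)], sample(lines[body]))
  writeLines(perm, file.path(dirp, "matrix.mtx"))
  back2 <- read_cell_matrix(file.path(dirp, "matrix.mtx"),
                            file.path(dirp, "barcodes.tsv"),
                            file.path(dirp, "genes.tsv"),
                            file.path(dirp, "meta.tsv"))
  expect_equal(as.matrix(back2$counts), as.matrix(cm$counts))
})

test_that("MTX shape mismatches are fatal", {
  dirp <- file.path(tempdir(), "mtx_bad")
  m <- Matrix::Matrix(matrix(0:5, 2, 3), sparse = TRUE)
  dimnames(m) <- list(c("c1", "c2"), c("g1", "g2", "g3"))
  cm <- cell_matrix(m, data.frame(cell_id = c("c1", "c2"), group = "OIR",
                                  timepoint = "P14"))
  write_cell_matrix(cm, dirp)
  writeLines(c("g1", "g2"), file.path(dirp, "genes.tsv"))
  expect_error(
    read_cell_matrix(file.path(dirp, "matrix.mtx"),
                     file.path(dirp, "barcodes.tsv"),
                     file.path(dirp, "genes.tsv"),
                     file.path(dirp, "meta.tsv")),
    "shape mismatch")
})

test_that("FASTA reading upper-cases, trims names, wraps, and round-trips", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">p1 some description", "acgt", ">p2", "ACGTAC", "GTNNAC"), fa)
  seqs <- read_fasta(fa)
  expect_equal(seqs, c(p1 = "ACGT", p2 = "ACGTACGTNNAC"))

  set.seed(16)
  rs <- vapply(sample(40:200, 20), random_seq, character(1))
  names(rs) <- sprintf("s%02d", 1:20)
  path <- tempfile(fileext = ".fa")
  write_fasta(rs, path)
  expect_equal(read_fasta(path), rs)
})

test_that("FASTA rejects empty records and non-ACGTN characters", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">p1", ""), fa)
  expect_error(read_fasta(fa), "empty")
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">p1", "ACGRT"), fa2)
  expect_error(read_fasta(fa2), "invalid character")
})
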