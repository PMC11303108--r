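# Independent brute-force oracles used to cross-check the implementation.

# all-pairs peak-vs-promoter-window overlap (no interval index)
oracle_genes_with_mark <- function(peaks_df, genes, w) {
  hit <- character()
  for (i in seq_len(nrow(genes))) {
    ws <- max(0L, genes$tss[i] - w)
    we <- genes$tss[i] + w + 1L
    for (j in seq_len(nrow(peaks_df))) {
      if (peaks_df$chrom[j] == genes$chrom[i] &&
          peaks_df$start[j] < we && peaks_df$end[j] > ws) {
        hit <- c(hit, genes$gene_id[i])
        break
      }
    }
  }
  sort(unique(hit))
}

# per-gene boolean-formula evaluation of the gate
oracle_gate <- function(per_mark_sets, activation, repression) {
  universe <- sort(unique(unlist(per_mark_sets)))
  keep <- vapply(universe, function(g) {
    all(vapply(activation, function(mk) g %in% per_mark_sets[[mk]], logical(1))) &&
      !(g %in% per_mark_sets[[repression]])
  }, logical(1))
  universe[keep]
}

# element-wise membership counting for exclusivity
oracle_exclusive <- function(sets, target) {
  out <- character()
  for (g in sets[[target]]) {
    n_other <- sum(vapply(setdiff(names(sets), target),
                          function(nm) g %in% sets[[nm]], logical(1)))
    if (n_other == 0L) out <- c(out, g)
  }
  sort(out)
}

# per-element enumeration of Venn regions
oracle_venn <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  pat <- vapply(universe, function(g) {
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = "")
  }, character(1))
  table(pat)
}

# step-up BH, written independently of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# character-by-character sliding scan for a fixed word (no regex, no
# pattern-matching library): candidate start positions are filtered one
# word-letter at a time
oracle_word_scan <- function(sequence, word) {
  chars <- strsplit(sequence, "")[[1L]]
  wchars <- strsplit(word, "")[[1L]]
  k <- length(wchars)
  if (length(chars) < k) return(integer())
  cand <- seq_len(length(chars) - k + 1L)
  for (j in seq_len(k)) {
    cand <- cand[chars[cand + j - 1L] == wchars[j]]
    if (!length(cand)) break
  }
  as.integer(cand - 1L)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# bp-resolution boolean-mask interval algebra on a small span
mask_of <- function(ivs, lo, hi) {
  m <- rep(FALSE, hi - lo)
  for (i in seq_len(nrow(ivs))) {
    idx <- (ivs$start[i] - lo + 1L):(ivs$end[i] - lo)
    m[idx] <- TRUE
  }
  m
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# a fast, small simulation config for unit tests
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 160L, n_chromosomes = 2L,
         chrom_length = 1e6, n_cells_per_condition = 150L,
         n_true_targets = 8L, n_extra_degs = 10L,
         n_shared_active = 8L, n_normal_only = 8L,
         n_repressed = 5L, n_partial = 5L, n_promoters = 4L),
    list(...))
  do.call(sim_config, args)
}

random_gene_table <- function(n, chroms = c("chr1", "chr2"), len = 1e6) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(len - 5000L, n)
  width <- sample(500:3000, n, replace = TRUE)
  gene_table(sprintf("g%03d", seq_len(n)), sprintf("name%03d", seq_len(n)),
             chrom, start, start + width,
             sample(c("+", "-"), n, replace = TRUE))
}

random_peaks_df <- function(n, chroms = c("chr1", "chr2"), len = 1e6) {
  start <- sample.int(len - 2000L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(50:1500, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
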