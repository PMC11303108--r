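#' Configuration for the synthetic multi-omic generator
#'
#' Defines the study-like conditions the generator emulates: a toy genome
#' with non-overlapping genes, per-mark/condition CUT&Tag-style peak sets
#' with planted gate-status classes, a negative-binomial single-cell count
#' matrix with a rod-dominant retinal cell-type structure, a bimodal TF in
#' OIR rods with planted TF-positive-vs-negative DEGs, and promoter
#' sequences with planted TRE full/half sites.
#'
#' @param seed Integer RNG seed (mandatory). Component sub-streams are
#'   derived by fixed offsets so the pieces are independently reproducible.
#' @param n_genes,n_chromosomes,chrom_length Toy genome shape.
#' @param gene_min_width,gene_max_width Gene footprint range in bp.
#' @param min_intergenic_gap Minimal gap between adjacent genes in bp
#'   (default 2000), chosen so that a peak planted in one gene's TSS window
#'   can never overlap a neighbouring gene's window: TSS-window assignment
#'   is unambiguous on the toy genome (bidirectional promoters are
#'   deliberately not emulated).
#' @param n_cells_per_condition Cells simulated per condition (normal and
#'   OIR, both at P14).
#' @param cell_type_proportions Named numeric summing to 1; rod-dominant by
#'   default.
#' @param n_markers_per_type,marker_boost Marker genes per cell type and
#'   their fold boost in the owning type.
#' @param nb_mean_log_mean,nb_mean_log_sd Log-normal law of per-gene
#'   baseline NB means.
#' @param nb_dispersion NB size parameter (smaller = noisier).
#' @param n_true_targets Planted direct targets: OIR-only gate-positive and
#'   DEG.
#' @param n_extra_degs Planted DEGs that are not gate candidates.
#' @param target_effect Fold change of planted DEGs between TF-positive and
#'   TF-negative OIR rods (default 4). Direct targets are up-regulated in
#'   TF-positive cells (an activating TF); of the extra DEGs,
#'   `deg_down_fraction` are planted as down-regulated (divided by the
#'   effect), keeping per-cell library sizes roughly balanced between the
#'   TF groups.
#' @param deg_down_fraction Fraction of the extra DEGs planted as
#'   down-regulated (default 0.5).
#' @param deg_mean_range Baseline-mean range for planted DEG genes (drawn
#'   uniformly), keeping them comfortably detected.
#' @param tf_mu Mean TF count in TF-positive cells (positives draw
#'   `1 + NB(tf_mu - 1)`, so they always pass a count threshold of 1;
#'   negatives are exactly 0 — the bimodal TF law).
#' @param tf_positive_fraction Fraction of OIR rods that are TF-positive.
#' @param tf_positive_fraction_normal Same for normal rods.
#' @param n_shared_active,n_normal_only,n_repressed,n_partial Gate decoy
#'   classes: active in both conditions, active in normal only, all four
#'   marks in OIR (repressed), and only two of three activation marks in
#'   OIR.
#' @param peak_width Planted and background peak width in bp.
#' @param background_peak_rate Expected background peaks per bp per
#'   mark/condition track.
#' @param window_halfwidth TSS window half-width used when planting peaks
#'   (should match the gate's).
#' @param n_promoters,promoter_length Promoter-sequence fixture shape.
#' @param max_planted_full,max_planted_half Per-promoter upper bounds on
#'   planted TRE full/half sites (counts drawn uniformly from 0..max).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 1000L, n_chromosomes = 3L,
                       chrom_length = 3e6, gene_min_width = 1000L,
                       gene_max_width = 4000L,
                       min_intergenic_gap = 2000L,
                       n_cells_per_condition = 600L,
                       cell_type_proportions = c(rod = 0.7, bipolar = 0.1,
                                                 amacrine = 0.1, muller = 0.1),
                       n_markers_per_type = 5L, marker_boost = 10,
                       nb_mean_log_mean = log(1), nb_mean_log_sd = 1,
                       nb_dispersion = 2,
                       n_true_targets = 20L, n_extra_degs = 30L,
                       target_effect = 4, deg_mean_range = c(0.3, 1.2),
                       deg_down_fraction = 0.5,
                       tf_mu = 3, tf_positive_fraction = 0.5,
                       tf_positive_fraction_normal = 0.1,
                       n_shared_active = 30L, n_normal_only = 30L,
                       n_repressed = 15L, n_partial = 15L,
                       peak_width = 400L, background_peak_rate = 2e-6,
                       window_halfwidth = 1000L,
                       n_promoters = 10L, promoter_length = 1100L,
                       max_planted_full = 2L, max_planted_half = 2L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes > 0, cfg$n_chromosomes > 0, cfg$chrom_length > 0,
    cfg$gene_min_width > 0, cfg$gene_max_width >= cfg$gene_min_width,
    cfg$min_intergenic_gap >= 0,
    cfg$n_cells_per_condition > 0,
    all(cfg$cell_type_proportions > 0),
    abs(sum(cfg$cell_type_proportions) - 1) < 1e-8,
    cfg$n_markers_per_type > 0, cfg$marker_boost > 1,
    cfg$nb_dispersion > 0, cfg$target_effect > 0,
    cfg$tf_mu >= 1,
    cfg$tf_positive_fraction > 0, cfg$tf_positive_fraction < 1,
    cfg$peak_width > 0, cfg$background_peak_rate >= 0,
    cfg$window_halfwidth > 0,
    cfg$promoter_length >= 7
  )
  n_roles <- cfg$n_markers_per_type * length(cfg$cell_type_proportions) + 1L +
    cfg$n_true_targets + cfg$n_extra_degs + cfg$n_shared_active +
    cfg$n_normal_only + cfg$n_repressed + cfg$n_partial
  if (n_roles > cfg$n_genes) {
    stop("n_genes too small for the requested planted classes (need >= ",
         n_roles, ")")
  }
  structure(cfg, class = "sim_config")
}

## fixed sub-stream offsets (keeps every component independently seeded)
sim_seed <- function(config, component) {
  off <- c(annotation = 11L, roles = 23L, peaks = 37L, scrna = 51L,
           promoters = 67L)
  (config$seed + off[[component]]) %% .Machine$integer.max
}

#' Generate a toy gene annotation
#'
#' Places non-overlapping genes with random strands uniformly over the toy
#' genome; deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [gene_table()].
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "annotation"))
  n <- config$n_genes
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chromosomes + 1L)))
  rows <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    widths <- sample(seq.int(config$gene_min_width, config$gene_max_width),
                     k, replace = TRUE)
    g0 <- config$min_intergenic_gap
    slack <- config$chrom_length - sum(widths) - (k + 1L) * g0
    if (slack < 0) {
      stop("infeasible packing: chromosome length too small for ", k, " genes")
    }
    gaps <- g0 + floor(diff(c(0, sort(stats::runif(k)), 1)) * slack)
    starts <- cumsum(gaps[seq_len(k)]) + c(0L, cumsum(widths))[seq_len(k)]
    rows[[ci]] <- data.frame(
      chrom = paste0("chr", ci),
      start = as.integer(starts),
      end = as.integer(starts + widths),
      strand = sample(c("+", "-"), k, replace = TRUE)
    )
    gi <- gi + k
  }
  df <- do.call(rbind, rows)
  ids <- sprintf("G%04d", seq_len(nrow(df)))
  gene_table(ids, sub("^G", "Gene", ids), df$chrom, df$start, df$end, df$strand)
}

#' Assign planted roles and build the truth ledger
#'
#' Randomly assigns marker genes per cell type, the TF gene, direct
#' targets, extra DEGs, and the gate decoy classes over the annotation,
#' recording everything in a truth ledger. Direct targets are a subset of
#' the planted DEGs and are gate-active in OIR only.
#'
#' @param genes A [gene_table()].
#' @param config A [sim_config()].
#' @return A list of class `truth_ledger`.
#' @export
generate_truth <- function(genes, config) {
  stopifnot(inherits(genes, "gene_table"), inherits(config, "sim_config"))
  set.seed(sim_seed(config, "roles"))
  pool <- sample(genes$gene_id)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  types <- names(config$cell_type_proportions)
  marker_map <- stats::setNames(
    lapply(types, function(t) sort(take(config$n_markers_per_type))), types)
  tf_gene_id <- take(1L)
  direct_targets <- sort(take(config$n_true_targets))
  extra_degs <- sort(take(config$n_extra_degs))
  n_down <- round(config$deg_down_fraction * length(extra_degs))
  down_degs <- sort(sample(extra_degs, n_down))
  shared_active <- sort(take(config$n_shared_active))
  normal_only <- sort(take(config$n_normal_only))
  repressed <- sort(take(config$n_repressed))
  partial <- sort(take(config$n_partial))
  truth <- structure(list(
    tf_gene_id = tf_gene_id,
    marker_map = marker_map,
    direct_targets = direct_targets,
    planted_degs = sort(c(direct_targets, extra_degs)),
    extra_degs = extra_degs,
    deg_direction = stats::setNames(
      ifelse(c(direct_targets, extra_degs) %in% down_degs, "down", "up"),
      c(direct_targets, extra_degs)),
    gate_active = list(
      normal = sort(c(shared_active, normal_only)),
      OIR = sort(c(direct_targets, shared_active))
    ),
    decoys = list(shared_active = shared_active, normal_only = normal_only,
                  repressed = repressed, partial = partial),
    cell_types = NULL, tf_positive_cells = NULL, promoter_hits = NULL
  ), class = "truth_ledger")
  validate_truth(truth)
  truth
}

#' Assert truth-ledger invariants
#'
#' Direct targets must be a subset of the planted DEGs and gate-active in
#' OIR but not in normal; decoy classes must be disjoint from targets.
#'
#' @param truth A `truth_ledger`.
#' @return `truth`, invisibly; errors if an invariant fails.
#' @export
validate_truth <- function(truth) {
  stopifnot(
    all(truth$direct_targets %in% truth$planted_degs),
    all(truth$direct_targets %in% truth$gate_active$OIR),
    !any(truth$direct_targets %in% truth$gate_active$normal),
    !any(truth$direct_targets %in% unlist(truth$decoys))
  )
  invisible(truth)
}

#' Generate per-mark, per-condition peak sets
#'
#' Plants activation-mark peaks (TF, H3K27ac, H3K4me3) inside the TSS
#' window of every gate-active gene in its condition, all four marks for
#' the repressed decoys, two of three activation marks for the partial
#' decoys, and uniform Poisson background peaks on every track (including
#' IgG, which carries background only).
#'
#' @param genes A [gene_table()].
#' @param truth A `truth_ledger` consistent with `genes`.
#' @param config A [sim_config()].
#' @return Named list of [peak_set()]s, keyed `"<mark>_<group>"`.
#' @export
generate_peaks <- function(genes, truth, config) {
  set.seed(sim_seed(config, "peaks"))
  w <- config$window_halfwidth
  pw <- config$peak_width
  act_marks <- c("TF", "H3K27ac", "H3K4me3")
  tss <- stats::setNames(genes$tss, genes$gene_id)
  chrom <- stats::setNames(genes$chrom, genes$gene_id)

  plant <- function(gene_ids) {
    if (length(gene_ids) == 0L) {
      return(data.frame(chrom = character(), start = integer(), end = integer()))
    }
    center <- tss[gene_ids] + round(stats::runif(length(gene_ids), -w / 2, w / 2))
    start <- pmax(0L, as.integer(center - pw %/% 2L))
    data.frame(chrom = unname(chrom[gene_ids]), start = start,
               end = start + pw, stringsAsFactors = FALSE)
  }
  # which genes get which mark, per condition
  plan <- list()
  for (grp in GROUP_LEVELS) {
    active <- truth$gate_active[[grp]]
    for (mk in act_marks) plan[[paste0(mk, "_", grp)]] <- active
  }
  # repressed decoys: all four marks in OIR
  for (mk in c(act_marks, "H3K27me3")) {
    key <- paste0(mk, "_OIR")
    plan[[key]] <- c(plan[[key]], truth$decoys$repressed)
  }
  # partial decoys: two of the three activation marks in OIR, drawn per gene
  for (g in truth$decoys$partial) {
    for (mk in sample(act_marks, 2L)) {
      key <- paste0(mk, "_OIR")
      plan[[key]] <- c(plan[[key]], g)
    }
  }
  out <- list()
  genome_bp <- config$n_chromosomes * config$chrom_length
  for (mk in MARK_LEVELS) {
    for (grp in GROUP_LEVELS) {
      key <- paste0(mk, "_", grp)
      planted <- plant(unique(plan[[key]]))
      nbg <- stats::rpois(1L, config$background_peak_rate * genome_bp)
      bg <- if (nbg > 0L) {
        ch <- sample(config$n_chromosomes, nbg, replace = TRUE)
        st <- floor(stats::runif(nbg, 0, config$chrom_length - pw))
        data.frame(chrom = paste0("chr", ch), start = as.integer(st),
                   end = as.integer(st + pw), stringsAsFactors = FALSE)
      } else {
        data.frame(chrom = character(), start = integer(), end = integer())
      }
      pk <- rbind(planted, bg)
      pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
      out[[key]] <- peak_set(pk, mark = mk, group = grp, timepoint = "P14")
    }
  }
  out
}

#' Generate the single-cell count matrix
#'
#' Negative-binomial counts for two conditions (normal and OIR at P14) with
#' cell types drawn from the configured proportions, marker genes boosted
#' in their owning type, a bimodal TF gene (positives draw at least one
#' count, negatives exactly zero), and the planted DEG effect applied
#' between TF-positive and TF-negative OIR rods. Updates the truth ledger
#' with per-cell type labels and TF status.
#'
#' @param genes A [gene_table()].
#' @param truth A `truth_ledger`.
#' @param config A [sim_config()].
#' @return List with `cells` (a [cell_matrix()]) and the updated `truth`.
#' @export
generate_scrna <- function(genes, truth, config) {
  set.seed(sim_seed(config, "scrna"))
  gene_ids <- genes$gene_id
  n_genes <- length(gene_ids)
  types <- names(config$cell_type_proportions)

  base_mu <- stats::rlnorm(n_genes, config$nb_mean_log_mean,
                           config$nb_mean_log_sd)
  names(base_mu) <- gene_ids
  # planted DEGs get a comfortably detectable baseline
  base_mu[truth$planted_degs] <- stats::runif(
    length(truth$planted_degs), config$deg_mean_range[1L],
    config$deg_mean_range[2L])
  # mass balance: scale the down-regulated genes' baselines so the expected
  # library mass they lose in TF-positive cells equals the mass the
  # up-regulated genes gain; otherwise TF status confounds library size and
  # normalization turns it into a global rank shift
  dirs_all <- truth$deg_direction
  up_ids <- names(dirs_all)[dirs_all == "up"]
  down_ids <- names(dirs_all)[dirs_all == "down"]
  if (length(down_ids) && config$target_effect != 1) {
    e <- config$target_effect
    up_gain <- sum(base_mu[up_ids]) * (e - 1)
    down_loss <- sum(base_mu[down_ids]) * (1 - 1 / e)
    base_mu[down_ids] <- base_mu[down_ids] * up_gain / down_loss
  }

  n_per <- config$n_cells_per_condition
  meta <- data.frame(
    cell_id = sprintf("C%05d", seq_len(2L * n_per)),
    group = rep(GROUP_LEVELS, each = n_per),
    timepoint = "P14",
    stringsAsFactors = FALSE
  )
  meta$true_type <- sample(types, nrow(meta), replace = TRUE,
                           prob = config$cell_type_proportions)
  is_rod <- meta$true_type == "rod"
  tf_pos <- rep(FALSE, nrow(meta))
  frac <- ifelse(meta$group == "OIR", config$tf_positive_fraction,
                 config$tf_positive_fraction_normal)
  tf_pos[is_rod] <- stats::runif(sum(is_rod)) < frac[is_rod]

  mu <- matrix(base_mu, nrow = nrow(meta), ncol = n_genes, byrow = TRUE,
               dimnames = list(meta$cell_id, gene_ids))
  for (t in types) {
    mk <- truth$marker_map[[t]]
    mu[meta$true_type == t, mk] <- mu[meta$true_type == t, mk] * config$marker_boost
  }
  eff_rows <- tf_pos & is_rod & meta$group == "OIR"
  dirs <- truth$deg_direction[truth$planted_degs]
  eff <- ifelse(dirs == "down", 1 / config$target_effect, config$target_effect)
  mu[eff_rows, truth$planted_degs] <-
    sweep(mu[eff_rows, truth$planted_degs, drop = FALSE], 2L, eff, `*`)

  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = config$nb_dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu))
  # bimodal TF: negatives exactly 0, positives at least 1
  counts[, truth$tf_gene_id] <- 0L
  counts[tf_pos, truth$tf_gene_id] <-
    1L + stats::rnbinom(sum(tf_pos), mu = config$tf_mu - 1,
                        size = config$nb_dispersion)
  truth$cell_types <- stats::setNames(meta$true_type, meta$cell_id)
  truth$tf_positive_cells <- meta$cell_id[tf_pos]
  truth$gene_base_mean <- base_mu
  list(cells = cell_matrix(counts, meta), truth = truth)
}

## draw non-overlapping planting positions with >= 2 bp gaps
plant_positions <- function(L, widths) {
  chosen_start <- integer()
  chosen_end <- integer()
  for (wd in widths) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      p <- sample.int(L - wd + 1L, 1L) - 1L
      if (!any(p < chosen_end + 2L & p + wd > chosen_start - 2L)) {
        chosen_start <- c(chosen_start, p)
        chosen_end <- c(chosen_end, p + wd)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place planted motifs: span too small")
  }
  chosen_start
}

#' Generate promoter sequences with planted TRE sites
#'
#' Random `ACGT` background sequences with TRE full sites and half sites
#' planted at recorded positions; the background is guaranteed free of
#' accidental motif words by an iterative repair loop that re-draws one
#' base inside each offending non-planted match (never touching a planted
#' footprint), so scanning a generated promoter recovers exactly the
#' planted sites.
#'
#' @param truth A `truth_ledger` (updated with the planted hits).
#' @param config A [sim_config()].
#' @return List with `sequences` (named character vector) and the updated
#'   `truth` (element `promoter_hits`: per-promoter hit frames).
#' @export
generate_promoters <- function(truth, config) {
  set.seed(sim_seed(config, "promoters"))
  L <- as.integer(config$promoter_length)
  seqs <- character(config$n_promoters)
  hits <- vector("list", config$n_promoters)
  names(hits) <- sprintf("promoter_%02d", seq_len(config$n_promoters))
  for (i in seq_len(config$n_promoters)) {
    k_full <- sample.int(config$max_planted_full + 1L, 1L) - 1L
    k_half <- sample.int(config$max_planted_half + 1L, 1L) - 1L
    kinds <- c(rep("full_TRE", k_full), rep("half_site", k_half))
    widths <- ifelse(kinds == "full_TRE", 7L, 4L)
    strands <- sample(c("+", "-"), length(kinds), replace = TRUE)
    words <- ifelse(kinds == "full_TRE",
                    ifelse(strands == "+", TRE_PLUS, TRE_MINUS),
                    ifelse(strands == "+", HALF_PLUS, HALF_MINUS))
    pos <- if (length(kinds)) plant_positions(L, widths) else integer()
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (j in seq_along(pos)) {
      s[(pos[j] + 1L):(pos[j] + widths[j])] <- strsplit(words[j], "")[[1L]]
    }
    planted_frame <- motif_hits_frame(position = pos, strand = strands,
                                      kind = kinds, matched_text = words)
    s <- repair_background(s, planted_frame)
    seqs[i] <- paste(s, collapse = "")
    hits[[i]] <- planted_frame
  }
  names(seqs) <- names(hits)
  truth$promoter_hits <- hits
  list(sequences = seqs, truth = truth)
}

## mutate accidental motif words until only the planted sites scan
repair_background <- function(s, planted, max_iter = 200L) {
  is_planted <- rep(FALSE, length(s))
  for (j in seq_len(nrow(planted))) {
    w <- nchar(planted$matched_text[j])
    is_planted[(planted$position[j] + 1L):(planted$position[j] + w)] <- TRUE
  }
  planted_full <- planted$position[planted$kind == "full_TRE"]
  planted_half <- planted$position[planted$kind == "half_site"]
  for (iter in seq_len(max_iter)) {
    txt <- paste(s, collapse = "")
    full <- scan_tre(txt)
    half <- scan_half_sites(txt)
    bad_full <- full[!(full$position %in% planted_full), , drop = FALSE]
    ok_half <- half$position %in% planted_half |
      vapply(half$position, function(q) {
        any(q >= planted_full & q + 4L <= planted_full + 7L)
      }, logical(1))
    bad_half <- half[!ok_half, , drop = FALSE]
    offending <- rbind(bad_full[, c("position", "matched_text")],
                       bad_half[, c("position", "matched_text")])
    if (nrow(offending) == 0L) return(s)
    for (j in seq_len(nrow(offending))) {
      span <- (offending$position[j] + 1L):
        (offending$position[j] + nchar(offending$matched_text[j]))
      free <- span[!is_planted[span]]
      if (length(free) == 0L) next  # cannot occur for planted gaps >= 2 bp
      b <- free[sample.int(length(free), 1L)]
      s[b] <- sample(setdiff(c("A", "C", "G", "T"), s[b]), 1L)
    }
  }
  stop("background repair did not converge in ", max_iter, " iterations")
}

#' Generate a complete synthetic bundle
#'
#' Runs all generator components in order (annotation, roles/truth, peaks,
#' single-cell counts, promoters) under the config's seed and returns them
#' with the finished truth ledger. Byte-deterministic given config.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_bundle`: list with `genes`, `peaks`,
#'   `cells`, `promoters`, `truth`, `config`.
#' @export
#' @examples
#' b <- simulate_bundle(sim_config(seed = 1, n_genes = 60,
#'                                 n_cells_per_condition = 50))
#' b$truth$direct_targets
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- generate_annotation(config)
  truth <- generate_truth(genes, config)
  peaks <- generate_peaks(genes, truth, config)
  sc <- generate_scrna(genes, truth, config)
  pr <- generate_promoters(sc$truth, config)
  validate_truth(pr$truth)
  structure(
    list(genes = genes, peaks = peaks, cells = sc$cells,
         promoters = pr$sequences, truth = pr$truth, config = config),
    class = "sim_bundle"
  )
}

#' Write a synthetic bundle to disk in standard formats
#'
#' Emits exactly the formats the readers consume: `genes.gtf`, one BED3
#' file per peak track under `peaks/`, the MatrixMarket triplet under
#' `counts/`, `promoters.fa`, `markers.yaml`, and `truth.json`.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(bundle$genes, file.path(dir, "genes.gtf"))
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  for (key in names(bundle$peaks)) {
    write_peaks(bundle$peaks[[key]], file.path(dir, "peaks", paste0(key, ".bed")))
  }
  write_cell_matrix(bundle$cells, file.path(dir, "counts"))
  write_fasta(bundle$promoters, file.path(dir, "promoters.fa"))
  yaml::write_yaml(bundle$truth$marker_map, file.path(dir, "markers.yaml"))
  truth_json <- bundle$truth
  truth_json$cell_types <- as.list(truth_json$cell_types)
  truth_json$gene_base_mean <- as.list(truth_json$gene_base_mean)
  truth_json$promoter_hits <- lapply(truth_json$promoter_hits, function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  })
  jsonlite::write_json(unclass(truth_json), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
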