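#' Promoter model in TSS-relative coordinates
#'
#' Coordinates are bp relative to the TSS with negative values upstream;
#' intervals are half-open `[a, b)`. The default span `[-1100, 0)` covers
#' the 1.1 kb immediately upstream of the TSS. An optional sequence (whose
#' first base is the upstream end of the span) and motif-hit frame can be
#' attached; sequence positions map to TSS-relative coordinates as
#' `span_start + position`.
#'
#' @param span Length-2 numeric, `c(start, end)` with `start < end`.
#' @param sequence Optional promoter sequence of length `end - start`.
#' @param hits Optional hit frame from [scan_tre()]/[scan_half_sites()] run
#'   on `sequence`.
#' @return An object of class `promoter_model`.
#' @export
promoter_model <- function(span = c(-1100L, 0L), sequence = NULL, hits = NULL) {
  span <- as.integer(span)
  stopifnot(length(span) == 2L, span[2L] > span[1L])
  if (!is.null(sequence)) {
    stopifnot(nchar(sequence) == span[2L] - span[1L])
  }
  if (!is.null(hits) && nrow(hits)) {
    stopifnot(all(hits$position >= 0L),
              all(hits$position + nchar(hits$matched_text) <= span[2L] - span[1L]))
  }
  structure(list(span = span, sequence = sequence, hits = hits),
            class = "promoter_model")
}

#' Reporter construct: retained promoter intervals plus activity
#'
#' @param name Construct name (e.g. `"d0.3K"`).
#' @param retained `data.frame` with `start`/`end` columns: the promoter
#'   intervals retained after deletion, half-open, TSS-relative. Must be
#'   disjoint; stored sorted and merged.
#' @param activity `"active"`, `"inactive"` or `"unknown"`.
#' @param hits Optional motif hits surviving in the construct.
#' @return An object of class `reporter_construct`.
#' @export
reporter_construct <- function(name, retained,
                               activity = c("unknown", "active", "inactive"),
                               hits = NULL) {
  activity <- match.arg(activity)
  stopifnot(is.data.frame(retained), all(c("start", "end") %in% names(retained)))
  merged <- iv_reduce(iv(retained$start, retained$end))
  if (iv_total_width(merged) != sum(retained$end - retained$start)) {
    stop("retained intervals overlap")
  }
  structure(list(name = name, retained = merged, activity = activity,
                 hits = hits),
            class = "reporter_construct")
}

#' @exportS3Method base::print
print.reporter_construct <- function(x, ...) {
  ivs <- paste(sprintf("[%d,%d)", x$retained$start, x$retained$end),
               collapse = " ")
  cat(sprintf("<reporter_construct> %s: %s (%s)\n", x$name, ivs, x$activity))
  invisible(x)
}

#' Delete a promoter region, yielding a reporter construct
#'
#' Removes `deletion` (half-open, TSS-relative) from the promoter span; the
#' construct retains the complement. Motif hits overlapping the deletion
#' are removed from the construct's hit list.
#'
#' @param promoter A [promoter_model()].
#' @param deletion Length-2 numeric `c(start, end)`; must lie within the
#'   promoter span. `NULL` or a zero-width deletion retains the full span.
#' @param name Construct name.
#' @param activity Activity label for the construct.
#' @return A [reporter_construct()].
#' @export
#' @examples
#' p <- promoter_model(c(-1100, 0))
#' apply_deletion(p, c(-300, 0), name = "d0.8K")$retained   # [-1100, -300)
apply_deletion <- function(promoter, deletion = NULL, name = "construct",
                           activity = "unknown") {
  stopifnot(inherits(promoter, "promoter_model"))
  span <- iv(promoter$span[1L], promoter$span[2L])
  if (is.null(deletion) || diff(as.integer(deletion)) == 0L) {
    retained <- span
  } else {
    deletion <- as.integer(deletion)
    stopifnot(length(deletion) == 2L, deletion[2L] > deletion[1L])
    if (deletion[1L] < promoter$span[1L] || deletion[2L] > promoter$span[2L]) {
      stop(sprintf("deletion [%d,%d) outside promoter span [%d,%d)",
                   deletion[1L], deletion[2L],
                   promoter$span[1L], promoter$span[2L]))
    }
    retained <- iv_setdiff(span, iv(deletion[1L], deletion[2L]))
  }
  hits <- promoter$hits
  if (!is.null(hits) && nrow(hits) && !is.null(deletion) &&
      diff(deletion) > 0L) {
    abs_start <- promoter$span[1L] + hits$position
    abs_end <- abs_start + nchar(hits$matched_text)
    keep <- abs_end <= deletion[1L] | abs_start >= deletion[2L]
    hits <- hits[keep, , drop = FALSE]
  }
  reporter_construct(name, retained, activity, hits = hits)
}

#' Infer the essential promoter region from reporter activities
#'
#' The essential region is what every active construct retains and no
#' inactive construct retains: the intersection of retained intervals over
#' active constructs minus the union over inactive constructs. With no
#' inactive construct the intersection of actives is returned with a
#' warning; with no active construct inference is impossible.
#'
#' @param constructs List of [reporter_construct()]s with known activities.
#' @return A `data.frame` of sorted disjoint half-open intervals
#'   (TSS-relative).
#' @export
infer_essential_region <- function(constructs) {
  acts <- vapply(constructs, function(x) x$activity, character(1))
  if (any(acts == "unknown")) stop("all construct activities must be known")
  active <- constructs[acts == "active"]
  inactive <- constructs[acts == "inactive"]
  if (length(active) == 0L) stop("no active construct: cannot infer an essential region")
  ess <- Reduce(iv_intersect, lapply(active, function(x) x$retained))
  if (length(inactive) == 0L) {
    warning("no inactive construct: essential region is only bounded above")
    return(ess)
  }
  lost <- Reduce(iv_union, lapply(inactive, function(x) x$retained))
  iv_setdiff(ess, lost)
}

#' Predict construct activity from an essential region
#'
#' A construct is predicted active iff its retained intervals cover the
#' essential region completely.
#'
#' @param construct A [reporter_construct()].
#' @param essential Interval `data.frame` from [infer_essential_region()];
#'   must be non-empty.
#' @return `"active"` or `"inactive"`.
#' @export
predict_activity <- function(construct, essential) {
  stopifnot(inherits(construct, "reporter_construct"))
  if (!is.data.frame(essential) || nrow(essential) == 0L) {
    stop("essential region is empty")
  }
  if (iv_covers(construct$retained, iv(essential$start, essential$end))) {
    "active"
  } else {
    "inactive"
  }
}

#' The Adam17 promoter deletion-series experiment
#'
#' Encodes the five luciferase reporter constructs used to map the
#' essential region of the Adam17 promoter: the full 1.1 kb upstream
#' region and four deletion mutants, named by the retained length in kb,
#' with their measured activity pattern. Deletions (TSS-relative):
#' d0.8K removes `[-300, 0)`, d0.6K removes `[-500, 0)`, d0.5K removes
#' `[-1100, -500)`, d0.3K removes `[-1100, -300)`.
#'
#' @return Named list of five [reporter_construct()]s.
#' @export
adam17_reporter_constructs <- function() {
  p <- promoter_model(c(-1100L, 0L))
  list(
    full1.1K = apply_deletion(p, NULL, name = "full1.1K", activity = "active"),
    d0.8K = apply_deletion(p, c(-300L, 0L), name = "d0.8K", activity = "inactive"),
    d0.6K = apply_deletion(p, c(-500L, 0L), name = "d0.6K", activity = "inactive"),
    d0.5K = apply_deletion(p, c(-1100L, -500L), name = "d0.5K", activity = "active"),
    d0.3K = apply_deletion(p, c(-1100L, -300L), name = "d0.3K", activity = "active")
  )
}
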