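## Half-open integer interval sets on the TSS-relative axis (negative =
## upstream). Represented as data.frames with `start` < `end`; set algebra
## delegates to IRanges (which accepts negative coordinates) via the
## half-open <-> closed mapping [a, b) <-> [a, b - 1].

iv <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), all(end > start))
  data.frame(start = start, end = end)
}

iv_empty <- function() data.frame(start = integer(), end = integer())

iv_to_ir <- function(x) IRanges::IRanges(start = x$start, end = x$end - 1L)

ir_to_iv <- function(r) {
  r <- IRanges::reduce(r)
  data.frame(start = IRanges::start(r), end = IRanges::end(r) + 1L)
}

iv_union <- function(x, y) ir_to_iv(c(iv_to_ir(x), iv_to_ir(y)))

iv_intersect <- function(x, y) {
  ir_to_iv(IRanges::intersect(iv_to_ir(x), iv_to_ir(y)))
}

iv_setdiff <- function(x, y) {
  ir_to_iv(IRanges::setdiff(iv_to_ir(x), iv_to_ir(y)))
}

iv_reduce <- function(x) ir_to_iv(iv_to_ir(x))

iv_total_width <- function(x) sum(x$end - x$start)

## TRUE iff every base of y is contained in x
iv_covers <- function(x, y) {
  nrow(iv_setdiff(y, x)) == 0L
}

## TRUE iff x contains interval [a, b) entirely
iv_contains <- function(x, a, b) iv_covers(x, iv(a, b))
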