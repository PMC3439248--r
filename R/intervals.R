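# Interval utilities.
#
# All coordinates are 1-based inclusive (GFF3 convention). An interval set is
# an integer matrix with columns "start" and "end", kept sorted by start.

iv <- function(start = integer(0), end = integer(0)) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == length(end))
  if (any(is.na(start) | is.na(end))) {
    stop("interval coordinates must be non-missing integers", call. = FALSE)
  }
  if (any(end < start)) stop("interval end < start", call. = FALSE)
  if (any(start < 1L)) stop("interval start < 1", call. = FALSE)
  m <- cbind(start = start, end = end)
  m[order(m[, "start"], m[, "end"]), , drop = FALSE]
}

is_iv <- function(m) is.matrix(m) && identical(colnames(m), c("start", "end"))

iv_width <- function(m) {
  if (nrow(m) == 0L) return(0)
  sum(as.numeric(m[, "end"]) - as.numeric(m[, "start"]) + 1)
}

as_iranges <- function(m) IRanges::IRanges(start = m[, "start"], end = m[, "end"])

iv_from_iranges <- function(ir) {
  iv(BiocGenerics::start(ir), BiocGenerics::end(ir))
}

# Union (normalized); merges overlapping and adjacent intervals.
iv_reduce <- function(m) iv_from_iranges(IRanges::reduce(as_iranges(m)))

iv_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(iv())
  if (nrow(b) == 0L) return(iv_reduce(a))
  iv_from_iranges(BiocGenerics::setdiff(as_iranges(a), as_iranges(b)))
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv())
  iv_from_iranges(BiocGenerics::intersect(as_iranges(a), as_iranges(b)))
}

iv_union <- function(a, b) iv_reduce(rbind(a, b))

# Gaps between consecutive intervals of a sorted, non-overlapping set.
iv_gaps <- function(m) {
  if (nrow(m) < 2L) return(iv())
  gs <- m[-nrow(m), "end"] + 1L
  ge <- m[-1L, "start"] - 1L
  keep <- ge >= gs
  iv(gs[keep], ge[keep])
}

# TRUE for each row of `inner` contained in some single row of `outer`.
iv_contained <- function(inner, outer) {
  if (nrow(inner) == 0L) return(logical(0))
  vapply(seq_len(nrow(inner)), function(i) {
    any(outer[, "start"] <= inner[i, "start"] & inner[i, "end"] <= outer[, "end"])
  }, logical(1))
}

# Canonical multiset key for a set of intervals (order-insensitive equality).
iv_key <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  sort(sprintf("%d-%d", m[, "start"], m[, "end"]), method = "radix")
}

iv_multiset_equal <- function(a, b) identical(iv_key(a), iv_key(b))

# Restore sort order everywhere we need byte-stable output, independent of
# the session locale.
sort_c <- function(x) {
  if (is.null(x) || !length(x)) return(character(0))
  sort(x, method = "radix")
}
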