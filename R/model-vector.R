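# Model vectors.
#
# A model vector encodes the structure of one transcript clique across a
# locus as one symbol per genomic position:
#   C coding sequence, F 5'-UTR, T 3'-UTR, I intron, G intergenic.
# Strand is not encoded: a minus-strand transcript's F marks its biological
# 5'-UTR even though it lies at higher genomic coordinates.

MODEL_ALPHABET <- c("C", "F", "G", "I", "T")

#' Encode a transcript clique as a model vector
#'
#' Positions covered by no member transcript are `G`; within a member
#' transcript's span, positions are labeled `C`/`F`/`T`/`I` according to its
#' inferred structure. Member transcripts are mutually disjoint, so no
#' position receives two labels.
#'
#' @param clique A `"transcript_clique"`, a list of `"transcript"` objects,
#'   or `NULL`/empty for the all-intergenic vector of an unannotated source.
#' @param locus A `"gene_locus"` (or any list with `seqid`, `start`, `end`).
#' @return An object of class `"model_vector"`: list with `symbols`
#'   (character vector, one symbol per position), `seqid`, `start`, `end`,
#'   `ids`, and `transcripts`.
#' @export
model_vector <- function(clique, locus) {
  txs <- if (is.null(clique)) {
    list()
  } else if (inherits(clique, "transcript_clique")) {
    clique$transcripts
  } else {
    clique
  }
  L <- locus$end - locus$start + 1L
  sym <- rep("G", L)
  off <- function(m) {
    if (nrow(m) == 0L) return(integer(0))
    unlist(lapply(seq_len(nrow(m)), function(i) {
      seq.int(m[i, "start"], m[i, "end"])
    })) - locus$start + 1L
  }
  for (tx in txs) {
    if (tx$start < locus$start || tx$end > locus$end) {
      stop(sprintf("transcript '%s' extends beyond locus %s:%d-%d",
                   tx$id, locus$seqid, locus$start, locus$end), call. = FALSE)
    }
    sym[off(tx$introns)] <- "I"
    sym[off(tx$utr5)] <- "F"
    sym[off(tx$utr3)] <- "T"
    sym[off(tx$cds)] <- "C"
  }
  ids <- if (length(txs)) sort_c(vapply(txs, `[[`, "", "id")) else character(0)
  structure(
    list(symbols = sym, seqid = locus$seqid, start = locus$start,
         end = locus$end, ids = ids, transcripts = txs),
    class = "model_vector"
  )
}

# The all-G vector standing in for an absent annotation source at a locus.
null_model_vector <- function(locus) model_vector(NULL, locus)

mv_label <- function(mv) {
  if (!length(mv$ids)) "(none)" else paste(mv$ids, collapse = ",")
}

# Pooled segment intervals of a vector's member transcripts, by feature type.
mv_segments <- function(mv, what = c("exons", "cds", "utr")) {
  what <- match.arg(what)
  if (!length(mv$transcripts)) return(iv())
  parts <- lapply(mv$transcripts, function(tx) {
    switch(what, exons = tx$exons, cds = tx$cds, utr = rbind(tx$utr5, tx$utr3))
  })
  m <- do.call(rbind, parts)
  if (is.null(m) || nrow(m) == 0L) return(iv())
  iv(m[, "start"], m[, "end"])
}

# Segment multisets used by structural classification; utr5/utr3 are kept
# separate so that 5' vs 3' role changes break UTR congruence.
mv_segment_key <- function(mv, what) {
  if (what %in% c("exons", "cds")) return(iv_key(mv_segments(mv, what)))
  if (!length(mv$transcripts)) return(character(0))
  k5 <- unlist(lapply(mv$transcripts, function(tx) paste0("5:", iv_key(tx$utr5))))
  k3 <- unlist(lapply(mv$transcripts, function(tx) paste0("3:", iv_key(tx$utr3))))
  sort_c(c(k5, k3))
}

#' @export
print.model_vector <- function(x, ...) {
  cat(sprintf("<model_vector> %s:%d-%d [%s]\n", x$seqid, x$start, x$end,
              mv_label(x)))
  L <- length(x$symbols)
  s <- paste(x$symbols[seq_len(min(60L, L))], collapse = "")
  cat(" ", s, if (L > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.model_vector <- function(x, ...) paste(x$symbols, collapse = "")
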