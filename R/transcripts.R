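# Core in-memory model: transcripts, genes, annotation sets.

#' Construct a transcript
#'
#' A transcript holds the exon and CDS segments of one mRNA, plus the intron
#' and UTR segments inferred from them by [infer_structures()]. All
#' coordinates are 1-based inclusive.
#'
#' @param id Transcript identifier.
#' @param gene_id Identifier of the parent gene.
#' @param seqid Sequence (chromosome/scaffold) identifier.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @param exons,cds Two-column `start`/`end` integer matrices (see [iv()]) or
#'   `NULL`. Exons must be present; CDS segments may be empty.
#' @param utr5,utr3,introns Optional explicit segments from the input
#'   annotation; they are checked against (and superseded by) the inferred
#'   segments.
#' @return An object of class `"transcript"`.
#' @export
new_transcript <- function(id, gene_id, seqid, strand, exons, cds = NULL,
                           utr5 = NULL, utr3 = NULL, introns = NULL) {
  if (is.null(cds)) cds <- iv()
  stopifnot(is_iv(exons), is_iv(cds), nrow(exons) >= 1L)
  strand <- match.arg(strand, c("+", "-", "*"))
  tx <- structure(
    list(
      id = as.character(id), gene_id = as.character(gene_id),
      seqid = as.character(seqid), strand = strand,
      start = min(exons[, "start"]), end = max(exons[, "end"]),
      exons = exons, cds = cds,
      utr5 = iv(), utr3 = iv(), introns = iv(),
      explicit = list(utr5 = utr5, utr3 = utr3, introns = introns)
    ),
    class = "transcript"
  )
  infer_structures(tx)
}

#' Infer introns and UTR segments of a transcript
#'
#' Introns are the gaps between consecutive exons. UTR segments are the
#' exonic positions not covered by CDS, labeled 5' or 3' by their genomic
#' position relative to the CDS span, mirrored on the minus strand. When the
#' transcript carries no CDS, all exonic positions are treated as lying
#' upstream of the (absent) coding region: 5'-UTR on the plus strand, 3'-UTR
#' on the minus strand. Explicit UTR/intron features present in the input are
#' compared against the inferred segments; on disagreement a warning is
#' raised and the inferred segments are kept.
#'
#' @param tx A `"transcript"` object.
#' @return The transcript with `introns`, `utr5` and `utr3` populated.
#' @export
infer_structures <- function(tx) {
  stopifnot(inherits(tx, "transcript"))
  exons <- tx$exons
  cds <- tx$cds
  if (nrow(cds) > 0L && !all(iv_contained(cds, exons))) {
    stop(sprintf("CDS segment not contained in any exon in transcript '%s'", tx$id),
         call. = FALSE)
  }

  introns <- iv_gaps(exons)
  noncds <- iv_setdiff(exons, cds)

  if (nrow(cds) > 0L) {
    cds_lo <- min(cds[, "start"])
    cds_hi <- max(cds[, "end"])
    cds_mid <- (cds_lo + cds_hi) / 2
  } else {
    # Degenerate limit: with no CDS every exonic position is "upstream".
    cds_lo <- Inf
    cds_hi <- -Inf
    cds_mid <- Inf
  }
  up <- noncds[, "end"] < cds_lo
  down <- noncds[, "start"] > cds_hi
  interior <- !up & !down
  if (any(interior)) {
    # Exonic non-CDS islands inside the CDS span: split by span midpoint.
    mids <- (noncds[interior, "start"] + noncds[interior, "end"]) / 2
    up[interior] <- mids < cds_mid
    down[interior] <- !up[interior]
  }
  upstream <- noncds[up, , drop = FALSE]
  downstream <- noncds[down, , drop = FALSE]
  if (tx$strand == "-") {
    utr5 <- downstream
    utr3 <- upstream
  } else {
    utr5 <- upstream
    utr3 <- downstream
  }

  check_explicit(tx, "utr5", utr5)
  check_explicit(tx, "utr3", utr3)
  check_explicit(tx, "introns", introns)

  tx$introns <- introns
  tx$utr5 <- utr5
  tx$utr3 <- utr3
  tx$start <- min(exons[, "start"])
  tx$end <- max(exons[, "end"])
  tx
}

check_explicit <- function(tx, what, inferred) {
  given <- tx$explicit[[what]]
  if (is.null(given)) return(invisible(NULL))
  if (!iv_multiset_equal(iv_reduce(given), iv_reduce(inferred))) {
    warning(sprintf(
      "transcript '%s': explicit %s segments conflict with inferred structure; keeping inferred",
      tx$id, sub("utr", "UTR", what)), call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> %s:%d-%d(%s) exons=%d cds=%d\n",
              x$id, x$seqid, x$start, x$end, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Construct a gene annotation
#'
#' @param id Gene identifier.
#' @param transcripts Non-empty list of `"transcript"` objects.
#' @param source One of `"reference"` or `"prediction"`.
#' @param start,end Optional declared gene coordinates; the stored interval
#'   always spans all member transcripts.
#' @return An object of class `"gene"`.
#' @export
new_gene <- function(id, transcripts, source, start = NULL, end = NULL) {
  stopifnot(length(transcripts) >= 1L)
  source <- match.arg(source, c("reference", "prediction"))
  ord <- order(vapply(transcripts, `[[`, 0, "start"),
               vapply(transcripts, `[[`, 0, "end"),
               vapply(transcripts, `[[`, "", "id"), method = "radix")
  transcripts <- transcripts[ord]
  tx_start <- min(vapply(transcripts, `[[`, 0, "start"))
  tx_end <- max(vapply(transcripts, `[[`, 0, "end"))
  structure(
    list(
      id = as.character(id),
      seqid = transcripts[[1L]]$seqid,
      strand = transcripts[[1L]]$strand,
      start = as.integer(min(c(start, tx_start))),
      end = as.integer(max(c(end, tx_end))),
      transcripts = transcripts,
      source = source
    ),
    class = "gene"
  )
}

#' @export
print.gene <- function(x, ...) {
  cat(sprintf("<gene %s> %s:%d-%d(%s) transcripts=%d [%s]\n",
              x$id, x$seqid, x$start, x$end, x$strand,
              length(x$transcripts), x$source))
  invisible(x)
}

#' Construct an annotation set
#'
#' Groups genes by sequence and sorts them by start coordinate. Duplicate
#' gene identifiers are an error.
#'
#' @param genes List of `"gene"` objects.
#' @param source One of `"reference"` or `"prediction"`.
#' @return An object of class `"annotation_set"`.
#' @export
new_annotation_set <- function(genes, source) {
  source <- match.arg(source, c("reference", "prediction"))
  ids <- vapply(genes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene ID(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  seqids <- vapply(genes, `[[`, "", "seqid")
  starts <- vapply(genes, function(g) g$start, 0L)
  ends <- vapply(genes, function(g) g$end, 0L)
  ord <- order(seqids, starts, ends, ids, method = "radix")
  structure(
    list(source = source, genes = genes[ord]),
    class = "annotation_set"
  )
}

annotation_seqids <- function(set) {
  sort_c(unique(vapply(set$genes, `[[`, "", "seqid")))
}

genes_on <- function(set, seqid) {
  Filter(function(g) g$seqid == seqid, set$genes)
}

n_transcripts <- function(set) {
  sum(vapply(set$genes, function(g) length(g$transcripts), 0L))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set [%s]> %d gene(s), %d transcript(s) on %d sequence(s)\n",
              x$source, length(x$genes), n_transcripts(x),
              length(annotation_seqids(x))))
  invisible(x)
}
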