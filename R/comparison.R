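# Pairwise comparison of reference and prediction model vectors at a locus.

CLASSIFICATIONS <- c("perfect_match", "cds_structure_match",
                     "exon_structure_match", "utr_structure_match", "non_match")

CLASSIFICATION_LABELS <- c(
  perfect_match = "perfect match",
  cds_structure_match = "CDS structure match",
  exon_structure_match = "exon structure match",
  utr_structure_match = "UTR structure match",
  non_match = "non-match"
)

#' Classify the structural congruence of two model vectors
#'
#' A hierarchy of exact-agreement classes: `perfect_match` when the symbol
#' strings are identical; otherwise `cds_structure_match` when the CDS
#' segment coordinates agree exactly; otherwise `exon_structure_match` when
#' the exon coordinates agree (CDS differing, e.g. via alternative start or
#' stop codons); otherwise `utr_structure_match` when the UTR segment
#' coordinates (5' and 3' separately) agree; otherwise `non_match`. Segment
#' coordinates are taken from the cliques' member transcripts, not re-derived
#' from symbol runs, so abutting transcripts cannot merge runs.
#'
#' @param ref,pred `"model_vector"` objects over the same locus.
#' @return One of `"perfect_match"`, `"cds_structure_match"`,
#'   `"exon_structure_match"`, `"utr_structure_match"`, `"non_match"`.
#' @export
classify_comparison <- function(ref, pred) {
  if (identical(ref$symbols, pred$symbols)) return("perfect_match")
  if (identical(mv_segment_key(ref, "cds"), mv_segment_key(pred, "cds"))) {
    return("cds_structure_match")
  }
  if (identical(mv_segment_key(ref, "exons"), mv_segment_key(pred, "exons"))) {
    return("exon_structure_match")
  }
  if (identical(mv_segment_key(ref, "utr"), mv_segment_key(pred, "utr"))) {
    return("utr_structure_match")
  }
  "non_match"
}

#' Compare a reference and a prediction model vector
#'
#' Computes the full statistics panel: nucleotide-level CDS and UTR
#' confusion counts plus overall identity, feature-level exact-match counts
#' for exons, CDS segments, and UTR segments, and the structural
#' classification.
#'
#' @param ref,pred `"model_vector"` objects over the same locus.
#' @param counted Whether this comparison contributes to running totals
#'   (informational panels against the all-intergenic vector do not).
#' @return An object of class `"comparison_result"`.
#' @export
compare_vectors <- function(ref, pred, counted = TRUE) {
  counts <- list(
    nuc_cds = nucleotide_confusion(ref, pred, "CDS"),
    nuc_utr = nucleotide_confusion(ref, pred, "UTR"),
    feat_exon = feature_confusion(mv_segments(ref, "exons"), mv_segments(pred, "exons")),
    feat_cds = feature_confusion(mv_segments(ref, "cds"), mv_segments(pred, "cds")),
    feat_utr = feature_confusion(mv_segments(ref, "utr"), mv_segments(pred, "utr"))
  )
  idy <- overall_identity(ref, pred)
  structure(
    list(
      ref = ref, pred = pred,
      ref_label = mv_label(ref), pred_label = mv_label(pred),
      counts = counts,
      identity = idy,
      identity_matches = sum(ref$symbols == pred$symbols),
      length = length(ref$symbols),
      stats = panel_set(counts, idy),
      classification = classify_comparison(ref, pred),
      counted = counted
    ),
    class = "comparison_result"
  )
}

panel_set <- function(counts, identity = NA_real_) {
  list(
    nuc_cds = annotation_stats(counts$nuc_cds, "nucleotide"),
    nuc_utr = annotation_stats(counts$nuc_utr, "nucleotide"),
    feat_exon = annotation_stats(counts$feat_exon, "feature"),
    feat_cds = annotation_stats(counts$feat_cds, "feature"),
    feat_utr = annotation_stats(counts$feat_utr, "feature"),
    identity = identity
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s | ref {%s} vs pred {%s}\n",
              CLASSIFICATION_LABELS[[x$classification]], x$ref_label,
              x$pred_label))
  invisible(x)
}

#' Splice complexity of a source's transcripts at a locus
#'
#' Mean pairwise structural annotation edit distance over all unordered
#' pairs of transcripts from one source: each transcript is encoded alone as
#' a model vector across the locus, and for each pair the congruence
#' sensitivity (identically-labeled annotated positions over the first
#' transcript's annotated positions) and specificity (same, over the second
#' transcript's) give `AED = 1 - (Sn+Sp)/2`. Zero when fewer than two
#' transcripts are annotated.
#'
#' @param transcripts List of `"transcript"` objects from one source.
#' @param locus The containing `"gene_locus"`.
#' @return Non-negative number.
#' @export
splice_complexity <- function(transcripts, locus) {
  n <- length(transcripts)
  if (n < 2L) return(0)
  vecs <- lapply(transcripts, function(tx) model_vector(list(tx), locus)$symbols)
  total <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- vecs[[i]]
      b <- vecs[[j]]
      ann_a <- a != "G"
      ann_b <- b != "G"
      match_ab <- sum(a == b & ann_a)
      sn <- match_ab / sum(ann_a)
      sp <- match_ab / sum(ann_b)
      total <- total + (1 - (sn + sp) / 2)
      npair <- npair + 1L
    }
  }
  total / npair
}

#' Compare all transcript cliques at a gene locus
#'
#' Builds the model vectors for both sources, scores every reference /
#' prediction vector pair, ranks the pairs (descending overall identity,
#' ties broken by ascending nucleotide CDS AED, then ascending feature-level
#' exon AED, then clique labels), and greedily accepts pairs so that each
#' clique is used at most once. Leftover cliques are reported as unmatched /
#' novel; they receive an informational panel against the all-intergenic
#' vector but contribute nothing to counted statistics. At one-sided loci
#' (genes from a single source) no counted comparison is made.
#'
#' @param locus A `"gene_locus"`.
#' @return An object of class `"locus_comparison"`.
#' @export
compare_locus <- function(locus) {
  ref_txs <- locus_transcripts(locus, "reference")
  pred_txs <- locus_transcripts(locus, "prediction")
  ref_cliques <- transcript_cliques(ref_txs, "reference")
  pred_cliques <- transcript_cliques(pred_txs, "prediction")
  ref_mvs <- lapply(ref_cliques, model_vector, locus = locus)
  pred_mvs <- lapply(pred_cliques, model_vector, locus = locus)
  status <- if (!length(ref_mvs)) "pred_only"
            else if (!length(pred_mvs)) "ref_only"
            else "shared"

  pairs <- list()
  used_r <- rep(FALSE, length(ref_mvs))
  used_p <- rep(FALSE, length(pred_mvs))
  if (status == "shared") {
    grid <- expand.grid(r = seq_along(ref_mvs), p = seq_along(pred_mvs))
    comps <- lapply(seq_len(nrow(grid)), function(k) {
      compare_vectors(ref_mvs[[grid$r[k]]], pred_mvs[[grid$p[k]]])
    })
    aed_key <- function(cmp, panel) {
      v <- cmp$stats[[panel]][["aed"]]
      if (is.na(v)) Inf else v
    }
    ord <- order(
      -vapply(comps, `[[`, 0, "identity"),
      vapply(comps, aed_key, 0, panel = "nuc_cds"),
      vapply(comps, aed_key, 0, panel = "feat_exon"),
      vapply(comps, `[[`, "", "ref_label"),
      vapply(comps, `[[`, "", "pred_label"),
      method = "radix"
    )
    for (k in ord) {
      r <- grid$r[k]
      p <- grid$p[k]
      if (used_r[r] || used_p[p]) next
      used_r[r] <- TRUE
      used_p[p] <- TRUE
      pairs[[length(pairs) + 1L]] <- comps[[k]]
    }
  }

  nullv <- null_model_vector(locus)
  baseline <- function(mv, side) {
    if (side == "ref") compare_vectors(mv, nullv, counted = FALSE)
    else compare_vectors(nullv, mv, counted = FALSE)
  }
  unmatched_ref <- lapply(which(!used_r), function(i) {
    list(clique = ref_cliques[[i]], panel = baseline(ref_mvs[[i]], "ref"))
  })
  unmatched_pred <- lapply(which(!used_p), function(i) {
    list(clique = pred_cliques[[i]], panel = baseline(pred_mvs[[i]], "pred"))
  })

  aggregate <- NULL
  if (length(pairs)) {
    pooled <- Reduce(function(acc, cmp) Map(add_confusion, acc, cmp$counts),
                     pairs[-1L], init = pairs[[1L]]$counts)
    idy <- sum(vapply(pairs, `[[`, 0, "identity_matches")) /
      sum(vapply(pairs, `[[`, 0, "length"))
    aggregate <- panel_set(pooled, idy)
  }

  structure(
    list(
      locus = locus,
      status = status,
      pairs = pairs,
      unmatched_ref = unmatched_ref,
      unmatched_pred = unmatched_pred,
      n_ref_cliques = length(ref_cliques),
      n_pred_cliques = length(pred_cliques),
      aggregate = aggregate,
      splice_complexity_ref = splice_complexity(ref_txs, locus),
      splice_complexity_pred = splice_complexity(pred_txs, locus)
    ),
    class = "locus_comparison"
  )
}

#' @export
print.locus_comparison <- function(x, ...) {
  cat(sprintf("<locus_comparison> %s:%d-%d [%s] pairs=%d unmatched_ref=%d unmatched_pred=%d\n",
              x$locus$seqid, x$locus$start, x$locus$end, x$status,
              length(x$pairs), length(x$unmatched_ref), length(x$unmatched_pred)))
  invisible(x)
}
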