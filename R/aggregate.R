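# Running totals across loci and the aggregate summary.
#
# Aggregate statistics are recomputed from pooled confusion counts, never
# averaged across loci; this is exactly equivalent to a single confusion
# count over the concatenation of all compared vector pairs.

#' Empty running totals
#'
#' @return An object of class `"running_totals"`.
#' @export
new_running_totals <- function() {
  structure(
    list(
      counts = list(
        nuc_cds = confusion(), nuc_utr = confusion(),
        feat_exon = confusion(), feat_cds = confusion(), feat_utr = confusion()
      ),
      identity_matches = 0,
      identity_positions = 0,
      class_tally = stats::setNames(rep(0, length(CLASSIFICATIONS)), CLASSIFICATIONS),
      loci = c(total = 0, shared = 0, ref_only = 0, pred_only = 0, filtered = 0),
      comparisons = 0,
      cliques = c(ref = 0, pred = 0),
      unmatched = c(ref = 0, pred = 0)
    ),
    class = "running_totals"
  )
}

#' Accumulate one locus comparison into the running totals
#'
#' All confusion counts of the locus' accepted pairs are added element-wise
#' and the classification tally updated. Unmatched cliques contribute only
#' their novel/unmatched tallies, never statistic counts. Filtered loci must
#' not be passed here (they contribute nothing but the filtered tally,
#' maintained by the pipeline).
#'
#' @param totals A `"running_totals"` object.
#' @param lc A `"locus_comparison"`.
#' @return The updated `"running_totals"`.
#' @export
accumulate_totals <- function(totals, lc) {
  stopifnot(inherits(totals, "running_totals"), inherits(lc, "locus_comparison"))
  totals$loci["total"] <- totals$loci["total"] + 1
  totals$loci[lc$status] <- totals$loci[lc$status] + 1
  totals$cliques["ref"] <- totals$cliques["ref"] + lc$n_ref_cliques
  totals$cliques["pred"] <- totals$cliques["pred"] + lc$n_pred_cliques
  totals$unmatched["ref"] <- totals$unmatched["ref"] + length(lc$unmatched_ref)
  totals$unmatched["pred"] <- totals$unmatched["pred"] + length(lc$unmatched_pred)
  for (cmp in lc$pairs) {
    if (!isTRUE(cmp$counted)) next
    totals$counts <- Map(add_confusion, totals$counts, cmp$counts)
    totals$identity_matches <- totals$identity_matches + cmp$identity_matches
    totals$identity_positions <- totals$identity_positions + cmp$length
    totals$class_tally[cmp$classification] <-
      totals$class_tally[cmp$classification] + 1
    totals$comparisons <- totals$comparisons + 1
  }
  totals
}

#' Aggregate summary panels from running totals
#'
#' Recomputes every statistics panel from the pooled counts, derives the
#' classification percentage breakdown, and the gene-level sensitivity /
#' specificity (perfect-match comparisons over the total number of
#' reference, respectively prediction, transcript cliques considered).
#'
#' @param totals A `"running_totals"` object.
#' @return A list with elements `panels` (pooled statistic panels plus
#'   overall identity), `classification` (data frame of counts and
#'   percentages), `gene` (gene-level sensitivity/specificity), `loci`,
#'   `comparisons`, `cliques`, and `unmatched`.
#' @export
summarize_totals <- function(totals) {
  stopifnot(inherits(totals, "running_totals"))
  panels <- panel_set(totals$counts,
                      ratio_or_na(totals$identity_matches, totals$identity_positions))
  pct <- if (totals$comparisons > 0) {
    100 * totals$class_tally / totals$comparisons
  } else {
    rep(NA_real_, length(CLASSIFICATIONS))
  }
  classification <- data.frame(
    class = CLASSIFICATIONS,
    label = unname(CLASSIFICATION_LABELS[CLASSIFICATIONS]),
    count = unname(totals$class_tally),
    percent = unname(pct),
    stringsAsFactors = FALSE
  )
  gene <- c(
    sensitivity = ratio_or_na(totals$class_tally[["perfect_match"]],
                              totals$cliques[["ref"]]),
    specificity = ratio_or_na(totals$class_tally[["perfect_match"]],
                              totals$cliques[["pred"]])
  )
  list(panels = panels, classification = classification, gene = gene,
       loci = totals$loci, comparisons = totals$comparisons,
       cliques = totals$cliques, unmatched = totals$unmatched)
}
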