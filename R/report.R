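# Text report rendering.
#
# Reports are plain text with stable field labels and ordering, readable by
# eye and parseable by line prefix. Statistics print with four decimals,
# percentages with one; undefined values print as "--".

fmt4 <- function(x) ifelse(is.na(x), "--", sprintf("%.4f", x))
fmt_pct <- function(x) ifelse(is.na(x), "--", sprintf("%.1f%%", x))

panel_line <- function(label, panel) {
  sprintf("    %-14s Sn %s | Sp %s | F1 %s | AED %s",
          paste0(label, ":"), fmt4(panel[["sensitivity"]]),
          fmt4(panel[["specificity"]]), fmt4(panel[["f1"]]),
          fmt4(panel[["aed"]]))
}

nuc_extra_line <- function(label, panel) {
  sprintf("    %-14s SMC %s | CC %s", paste0(label, ":"),
          fmt4(panel[["smc"]]), fmt4(panel[["cc"]]))
}

render_panels <- function(stats) {
  c("  nucleotide level",
    sprintf("    %-14s %s", "identity:", fmt4(stats$identity)),
    panel_line("CDS", stats$nuc_cds),
    nuc_extra_line("CDS", stats$nuc_cds),
    panel_line("UTR", stats$nuc_utr),
    nuc_extra_line("UTR", stats$nuc_utr),
    "  feature level",
    panel_line("exon", stats$feat_exon),
    panel_line("CDS segment", stats$feat_cds),
    panel_line("UTR segment", stats$feat_utr))
}

gene_inventory <- function(genes, tag) {
  header <- sprintf("%s genes: %d", tag, length(genes))
  if (!length(genes)) return(header)
  c(header, vapply(genes, function(g) {
    sprintf("  - %s (%d transcript%s: %s)", g$id, length(g$transcripts),
            if (length(g$transcripts) == 1L) "" else "s",
            paste(sort_c(vapply(g$transcripts, `[[`, "", "id")), collapse = ", "))
  }, ""))
}

#' Render the report for one gene locus
#'
#' Lists the locus coordinates, the gene and transcript inventories of both
#' sources, one block per accepted comparison (clique labels, nucleotide-
#' and feature-level panels, classification), the unmatched/novel cliques
#' with their informational panels against the all-intergenic vector, and —
#' for loci with several comparisons — the locus-level aggregate panel.
#' Both splice complexity values are always reported. Output is
#' deterministic.
#'
#' @param lc A `"locus_comparison"`.
#' @return Character vector of report lines.
#' @export
render_locus_report <- function(lc) {
  locus <- lc$locus
  out <- c(
    sprintf("#===== locus %s:%d-%d =====#", locus$seqid, locus$start, locus$end),
    sprintf("locus length: %d", locus_length(locus)),
    gene_inventory(locus$ref_genes, "reference"),
    gene_inventory(locus$pred_genes, "prediction")
  )
  if (!length(lc$pairs)) {
    out <- c(out, "comparisons: none (locus annotated by a single source)")
  }
  for (k in seq_along(lc$pairs)) {
    cmp <- lc$pairs[[k]]
    out <- c(out,
      sprintf("comparison %d", k),
      sprintf("  reference clique:  %s", cmp$ref_label),
      sprintf("  prediction clique: %s", cmp$pred_label),
      sprintf("  classification: %s", CLASSIFICATION_LABELS[[cmp$classification]]),
      render_panels(cmp$stats))
  }
  render_unmatched <- function(entries, tag) {
    if (!length(entries)) return(character(0))
    unlist(lapply(entries, function(e) {
      c(sprintf("unmatched %s clique: %s", tag, paste(e$clique$ids, collapse = ",")),
        render_panels(e$panel$stats))
    }))
  }
  out <- c(out,
           render_unmatched(lc$unmatched_ref, "reference"),
           render_unmatched(lc$unmatched_pred, "prediction"))
  if (length(lc$pairs) > 1L) {
    out <- c(out, "locus aggregate", render_panels(lc$aggregate))
  }
  c(out,
    sprintf("splice complexity (reference):  %s", fmt4(lc$splice_complexity_ref)),
    sprintf("splice complexity (prediction): %s", fmt4(lc$splice_complexity_pred)))
}

#' Render the aggregate summary report
#'
#' Locus breakdown (total, shared, unique to either source, filtered),
#' classification table with counts and one-decimal percentages, gene-level
#' sensitivity/specificity, and the pooled nucleotide- and feature-level
#' statistic panels recomputed from the running totals.
#'
#' @param summary Output of [summarize_totals()] (or an
#'   `"annotation_comparison"` object).
#' @return Character vector of report lines.
#' @export
render_summary <- function(summary) {
  if (inherits(summary, "annotation_comparison")) summary <- summary$summary
  loci <- summary$loci
  cls <- summary$classification
  out <- c(
    "#===== annotation comparison summary =====#",
    sprintf("gene loci............................ %d", as.integer(loci[["total"]])),
    sprintf("  shared............................. %d", as.integer(loci[["shared"]])),
    sprintf("  unique to reference................ %d", as.integer(loci[["ref_only"]])),
    sprintf("  unique to prediction............... %d", as.integer(loci[["pred_only"]])),
    sprintf("  filtered out....................... %d", as.integer(loci[["filtered"]])),
    sprintf("reference transcript cliques......... %d", as.integer(summary$cliques[["ref"]])),
    sprintf("prediction transcript cliques........ %d", as.integer(summary$cliques[["pred"]])),
    sprintf("unmatched reference cliques.......... %d", as.integer(summary$unmatched[["ref"]])),
    sprintf("novel prediction cliques............. %d", as.integer(summary$unmatched[["pred"]])),
    sprintf("total comparisons.................... %d", as.integer(summary$comparisons))
  )
  for (i in seq_len(nrow(cls))) {
    out <- c(out, sprintf("  %-33s %d (%s)",
                          paste0(cls$label[i], "es..."), as.integer(cls$count[i]),
                          fmt_pct(cls$percent[i])))
  }
  out <- c(out,
    sprintf("gene sensitivity..................... %s", fmt4(summary$gene[["sensitivity"]])),
    sprintf("gene specificity..................... %s", fmt4(summary$gene[["specificity"]])),
    "pooled statistics",
    render_panels(summary$panels))
  out
}
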