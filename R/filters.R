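# Locus filtering.
#
# A flat key=value configuration file can exclude loci from the reports by
# length, gene count, transcript count, transcripts per gene, exon count, or
# CDS length. Filtered loci are tallied for transparency but contribute
# nothing to comparisons or aggregate statistics.

FILTER_KEYS <- c(
  "MinLocusLength", "MaxLocusLength",
  "MinGeneCount", "MaxGeneCount",
  "MinTranscriptCount", "MaxTranscriptCount",
  "MinTranscriptsPerGene", "MaxTranscriptsPerGene",
  "MinExonCount", "MaxExonCount",
  "MinCDSLength", "MaxCDSLength"
)

#' Read a locus filter configuration
#'
#' The format is flat `Key=Value` text, one per line; `#` starts a comment.
#' Recognized keys: `MinLocusLength`/`MaxLocusLength` (bp),
#' `MinGeneCount`/`MaxGeneCount`, `MinTranscriptCount`/`MaxTranscriptCount`,
#' `MinTranscriptsPerGene`/`MaxTranscriptsPerGene`,
#' `MinExonCount`/`MaxExonCount`, `MinCDSLength`/`MaxCDSLength` (bp).
#' Unknown keys are an error, as is a `Min` bound exceeding its `Max`.
#'
#' @param file Path to the configuration file (or a character vector of
#'   lines).
#' @return Named list of integer bounds, of class `"filter_config"`.
#' @export
read_filter_config <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop(sprintf("invalid filter line: '%s' (expected Key=Value)", ln),
           call. = FALSE)
    }
    key <- trimws(parts[1L])
    if (!key %in% FILTER_KEYS) {
      stop(sprintf("unknown filter key: '%s'", key), call. = FALSE)
    }
    val <- suppressWarnings(as.integer(trimws(parts[2L])))
    if (is.na(val)) {
      stop(sprintf("non-integer value for filter key '%s'", key), call. = FALSE)
    }
    cfg[[key]] <- val
  }
  for (crit in unique(sub("^(Min|Max)", "", FILTER_KEYS))) {
    lo <- cfg[[paste0("Min", crit)]]
    hi <- cfg[[paste0("Max", crit)]]
    if (!is.null(lo) && !is.null(hi) && lo > hi) {
      stop(sprintf("filter Min%s (%d) exceeds Max%s (%d)", crit, lo, crit, hi),
           call. = FALSE)
    }
  }
  structure(cfg, class = "filter_config")
}

locus_filter_features <- function(locus) {
  genes <- c(locus$ref_genes, locus$pred_genes)
  txs <- unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE)
  list(
    LocusLength = locus_length(locus),
    GeneCount = length(genes),
    TranscriptCount = length(txs),
    TranscriptsPerGene = max(vapply(genes, function(g) length(g$transcripts), 0L)),
    ExonCount = sum(vapply(txs, function(t) nrow(t$exons), 0L)),
    CDSLength = max(vapply(txs, function(t) iv_width(t$cds), 0))
  )
}

#' Does a locus satisfy a filter configuration?
#'
#' Gene, transcript, and exon counts are totals over both sources;
#' transcripts-per-gene is the maximum over member genes; CDS length is the
#' maximum single-transcript CDS length at the locus. An empty configuration
#' accepts every locus.
#'
#' @param locus A `"gene_locus"`.
#' @param cfg A `"filter_config"` (or `NULL`).
#' @return `TRUE` iff every configured bound is satisfied.
#' @export
locus_passes_filters <- function(locus, cfg) {
  if (is.null(cfg) || !length(cfg)) return(TRUE)
  feats <- locus_filter_features(locus)
  for (key in names(cfg)) {
    crit <- sub("^(Min|Max)", "", key)
    val <- feats[[crit]]
    if (startsWith(key, "Min") && val < cfg[[key]]) return(FALSE)
    if (startsWith(key, "Max") && val > cfg[[key]]) return(FALSE)
  }
  TRUE
}
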