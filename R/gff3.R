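# GFF3 input/output.
#
# Reading goes through rtracklayer (attribute parsing, escaping, FASTA
# sections); a line-level pre-scan is done first so that structural problems
# can be reported with their line number. Only gene -> mRNA -> segment
# hierarchies are retained for comparison.

TX_SEGMENT_TYPES <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR", "intron")

#' Read a gene structure annotation set from GFF3
#'
#' Parses a GFF3 file and assembles an [new_annotation_set()] of genes with
#' their mRNA transcripts. Implicit structure (introns, UTR segments) is
#' inferred from exon and CDS features via [infer_structures()]. mRNAs with
#' CDS but no exon features get exons synthesized from the CDS segments;
#' mRNAs with neither are skipped with a warning, as are non-mRNA transcript
#' types (tRNA, ncRNA, ...). Standalone mRNAs with no gene parent are
#' wrapped in a synthetic single-mRNA gene. Input order of feature lines is
#' irrelevant (two-pass resolution); coordinates need not be sorted.
#'
#' @param file Path to a GFF3 file.
#' @param source Role of this annotation set: `"reference"` or
#'   `"prediction"`.
#' @return An `"annotation_set"` object.
#' @seealso [read_annotations_text()] for parsing in-memory GFF3 text.
#' @export
read_annotations <- function(file, source = c("reference", "prediction")) {
  source <- match.arg(source)
  if (!file.exists(file)) stop(sprintf("no such file: %s", file), call. = FALSE)
  prescan_gff3(file)
  gr <- tryCatch(
    rtracklayer::import(file, format = "gff3"),
    error = function(e) stop(sprintf("failed to parse GFF3 '%s': %s",
                                     file, conditionMessage(e)), call. = FALSE)
  )
  build_annotation_set(gr, source)
}

#' Read an annotation set from GFF3 text
#'
#' Convenience wrapper around [read_annotations()] for GFF3 held in memory
#' (e.g. output of [simulate_annotation_pair()]).
#'
#' @param lines Character vector of GFF3 lines.
#' @inheritParams read_annotations
#' @return An `"annotation_set"` object.
#' @export
read_annotations_text <- function(lines, source = c("reference", "prediction")) {
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path))
  writeLines(lines, path)
  read_annotations(path, source)
}

# Validate raw lines so errors can name line numbers; rtracklayer does the
# actual parsing afterwards.
prescan_gff3 <- function(file) {
  lines <- readLines(file, warn = FALSE)
  fasta <- grep("^##FASTA", lines)
  if (length(fasta)) lines <- lines[seq_len(fasta[1L] - 1L)]
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body)) return(invisible(NULL))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1L]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                 body[i], nf[i]), call. = FALSE)
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    i <- which(is.na(starts) | is.na(ends))[1L]
    stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", body[i]),
         call. = FALSE)
  }
  if (any(bad <- ends < starts | starts < 1L)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed GFF3 line %d: end (%d) < start (%d)",
                 body[i], ends[i], starts[i]), call. = FALSE)
  }
  invisible(NULL)
}

build_annotation_set <- function(gr, source) {
  n <- length(gr)
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  df$id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, n)
  parents <- if ("Parent" %in% names(mc)) as.list(mc$Parent) else rep(list(character(0)), n)

  is_gene <- df$type == "gene"
  is_mrna <- df$type == "mRNA"
  is_seg <- df$type %in% TX_SEGMENT_TYPES

  # Synthesize missing IDs for container features so children can attach.
  df$id[is_gene & is.na(df$id)] <- sprintf("gene_%d", which(is_gene & is.na(df$id)))
  df$id[is_mrna & is.na(df$id)] <- sprintf("mRNA_%d", which(is_mrna & is.na(df$id)))

  id2row <- seq_len(n)[!is.na(df$id)]
  names(id2row) <- df$id[!is.na(df$id)]
  id2row <- id2row[!duplicated(names(id2row))]  # discontinuous features share IDs

  gene_ids <- df$id[is_gene]

  # mRNA -> parent gene (or synthetic wrapper gene); other transcript types
  # hanging off a gene are skipped with a warning.
  mrna_rows <- which(is_mrna)
  mrna_gene <- character(0)
  for (i in mrna_rows) {
    ps <- parents[[i]]
    if (!length(ps)) {
      mrna_gene[df$id[i]] <- paste0(df$id[i], ".gene")  # standalone mRNA
      next
    }
    for (p in ps) {
      if (!p %in% names(id2row)) {
        stop(sprintf("Parent '%s' of mRNA '%s' references an unknown feature ID",
                     p, df$id[i]), call. = FALSE)
      }
      if (df$type[id2row[[p]]] != "gene") {
        stop(sprintf("mRNA '%s' has non-gene Parent '%s'", df$id[i], p),
             call. = FALSE)
      }
      mrna_gene[df$id[i]] <- p
    }
  }

  skipped_tx <- character(0)
  other <- which(!is_gene & !is_mrna & !is_seg)
  for (i in other) {
    ps <- parents[[i]]
    if (any(ps %in% gene_ids)) {
      warning(sprintf("skipping non-mRNA transcript type '%s'%s",
                      df$type[i],
                      if (is.na(df$id[i])) "" else sprintf(" (ID '%s')", df$id[i])),
              call. = FALSE)
      if (!is.na(df$id[i])) skipped_tx <- c(skipped_tx, df$id[i])
    }
    # Features unrelated to any gene (e.g. chromosome records) are ignored.
  }

  # Attach segment features to their mRNA parents.
  seg_rows <- which(is_seg)
  seg_by_tx <- list()
  for (i in seg_rows) {
    ps <- parents[[i]]
    if (!length(ps)) {
      stop(sprintf("%s feature at %s:%d-%d has no Parent attribute",
                   df$type[i], df$seqid[i], df$start[i], df$end[i]), call. = FALSE)
    }
    for (p in ps) {
      if (p %in% names(mrna_gene)) {
        seg_by_tx[[p]][[df$type[i]]] <-
          rbind(seg_by_tx[[p]][[df$type[i]]], c(df$start[i], df$end[i]))
      } else if (p %in% skipped_tx || p %in% gene_ids) {
        next  # child of a skipped transcript, or segment hung on a gene
      } else if (!p %in% names(id2row)) {
        stop(sprintf("Parent '%s' of %s feature references an unknown feature ID",
                     p, df$type[i]), call. = FALSE)
      }
    }
  }

  # Assemble transcripts.
  tx_by_gene <- list()
  for (tid in names(mrna_gene)) {
    row <- id2row[[tid]]
    segs <- seg_by_tx[[tid]]
    get_iv <- function(type) {
      m <- segs[[type]]
      if (is.null(m)) return(NULL)
      iv_reduce(iv(m[, 1L], m[, 2L]))
    }
    exons <- get_iv("exon")
    cds <- get_iv("CDS")
    if (is.null(exons) && is.null(cds)) {
      warning(sprintf("skipping mRNA '%s': no exon and no CDS features", tid),
              call. = FALSE)
      next
    }
    if (is.null(exons)) exons <- cds  # exons synthesized from CDS
    if (is.null(cds)) cds <- iv()
    tx <- new_transcript(
      id = tid, gene_id = mrna_gene[[tid]],
      seqid = df$seqid[row], strand = df$strand[row],
      exons = exons, cds = cds,
      utr5 = get_iv("five_prime_UTR"),
      utr3 = get_iv("three_prime_UTR"),
      introns = get_iv("intron")
    )
    tx_by_gene[[mrna_gene[[tid]]]] <- c(tx_by_gene[[mrna_gene[[tid]]]], list(tx))
  }

  genes <- list()
  for (gid in sort_c(names(tx_by_gene))) {
    row <- if (gid %in% names(id2row)) id2row[[gid]] else NA_integer_
    genes[[length(genes) + 1L]] <- new_gene(
      id = gid, transcripts = tx_by_gene[[gid]], source = source,
      start = if (is.na(row)) NULL else df$start[row],
      end = if (is.na(row)) NULL else df$end[row]
    )
  }
  new_annotation_set(genes, source)
}

#' Write gene loci as a GFF3 track
#'
#' Emits one `locus` feature per gene locus, carrying the number of
#' reference and prediction genes as attributes. Intended for upload as a
#' genome-browser custom track. Output is sorted by (seqid, start) and is
#' byte-deterministic.
#'
#' @param loci List of `"gene_locus"` objects, or an
#'   `"annotation_comparison"` result.
#' @param file Output path or connection.
#' @return Invisibly, the lines written.
#' @export
write_locus_gff3 <- function(loci, file) {
  if (inherits(loci, "annotation_comparison")) loci <- loci$loci
  seqids <- vapply(loci, `[[`, "", "seqid")
  starts <- vapply(loci, function(l) l$start, 0L)
  ord <- order(seqids, starts, method = "radix")
  lines <- c("##gff-version 3", vapply(loci[ord], function(l) {
    sprintf("%s\tannomatch\tlocus\t%d\t%d\t.\t.\t.\tID=locus_%s_%d-%d;ref_genes=%d;pred_genes=%d",
            l$seqid, l$start, l$end, l$seqid, l$start, l$end,
            length(l$ref_genes), length(l$pred_genes))
  }, ""))
  writeLines(lines, file)
  invisible(lines)
}
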