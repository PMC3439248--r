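# Synthetic paired annotation sets with known ground truth.
#
# The generator lays out non-overlapping multi-exon protein-coding genes
# along one or more sequences and derives the prediction set gene-by-gene
# through a perturbation program. Each perturbation class maps one-to-one
# onto a structural classification, so the pipeline's per-locus
# classifications and pooled confusion counts can be checked exactly.
# Length distributions are uniform over the configured bounds; the point is
# controlled structure, not biological realism.

SIM_EDITS <- c("identical", "utr", "cds", "splice", "drop", "add", "merge")

SIM_EXPECTED_CLASS <- c(
  identical = "perfect_match",
  utr = "cds_structure_match",       # UTR extents change, CDS untouched
  cds = "exon_structure_match",      # start codon moves, exons untouched
  splice = "utr_structure_match",    # internal splice site moves, UTRs untouched
  add = "perfect_match",             # the host gene itself is copied verbatim
  merge = "cds_structure_match"      # two genes fused; CDS segments preserved
)

#' Parameters for the synthetic annotation generator
#'
#' All length parameters are `c(min, max)` bounds of uniform integer
#' distributions, in bp. The perturbation probabilities select, per
#' reference gene, which edit the prediction set applies; their sum must
#' not exceed 1 and the remainder is the identical-copy probability.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param n_genes Total number of reference genes.
#' @param n_seqids Number of sequences the genes are spread over.
#' @param seq_length Optional sequence length cap; generation fails if the
#'   genes do not fit.
#' @param exon_count Bounds on exons per transcript (splice-site edits need
#'   at least 2).
#' @param exon_len,intron_len,utr5_len,utr3_len,gap Length bounds (bp); `gap`
#'   is the intergenic spacing, kept large enough that perturbed genes never
#'   touch their neighbours.
#' @param p_utr,p_cds,p_splice,p_drop,p_add,p_merge Perturbation class
#'   probabilities: UTR-only edit, CDS start shift (codon-preserving),
#'   internal splice-site shift, gene dropped from the prediction, novel
#'   gene added to the prediction, fusion with the following gene.
#' @param explicit_utrs Also emit five_prime_UTR/three_prime_UTR features
#'   (by default only exon and CDS features are written, so UTR inference is
#'   always exercised downstream).
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(seed = 1L, n_genes = 100L, n_seqids = 2L,
                       seq_length = NULL,
                       exon_count = c(2L, 6L), exon_len = c(60L, 300L),
                       intron_len = c(40L, 200L), utr5_len = c(20L, 90L),
                       utr3_len = c(30L, 150L), gap = c(500L, 1500L),
                       p_utr = 0.10, p_cds = 0.10, p_splice = 0.10,
                       p_drop = 0.05, p_add = 0.05, p_merge = 0.05,
                       explicit_utrs = FALSE) {
  p_edit <- c(utr = p_utr, cds = p_cds, splice = p_splice,
              drop = p_drop, add = p_add, merge = p_merge)
  if (any(p_edit < 0) || sum(p_edit) > 1) {
    stop("perturbation probabilities must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  stopifnot(n_genes >= 1L, n_seqids >= 1L, exon_count[1L] >= 1L,
            exon_len[1L] >= 60L, intron_len[1L] >= 40L, gap[1L] >= 500L)
  if (p_splice > 0 && exon_count[1L] < 2L) {
    stop("splice-site edits require at least 2 exons per transcript",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_seqids = as.integer(n_seqids), seq_length = seq_length,
         exon_count = exon_count, exon_len = exon_len,
         intron_len = intron_len, utr5_len = utr5_len, utr3_len = utr3_len,
         gap = gap, p = c(identical = 1 - sum(p_edit), p_edit),
         explicit_utrs = explicit_utrs),
    class = "sim_params"
  )
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

rint <- function(bounds, n = 1L) {
  if (bounds[1L] >= bounds[2L]) rep(bounds[1L], n)
  else sample(seq.int(bounds[1L], bounds[2L]), n, replace = TRUE)
}

# One transcript model: exon layout plus CDS segments. The generator keeps
# its own coordinate records so ground-truth expectations are computed from
# edit arithmetic, independently of the pipeline's vector encoding.
sim_tx_model <- function(exons, cds, strand) {
  noncds <- iv_setdiff(exons, cds)
  lo <- min(cds[, "start"])
  hi <- max(cds[, "end"])
  up <- noncds[, "end"] < lo
  down <- noncds[, "start"] > hi
  interior <- !up & !down
  if (any(interior)) {  # exonic non-CDS islands: split at the CDS-span midpoint
    mids <- (noncds[interior, "start"] + noncds[interior, "end"]) / 2
    up[interior] <- mids < (lo + hi) / 2
    down[interior] <- !up[interior]
  }
  list(
    exons = exons, cds = cds, strand = strand,
    introns = iv_gaps(exons),
    utr5 = noncds[if (strand == "-") down else up, , drop = FALSE],
    utr3 = noncds[if (strand == "-") up else down, , drop = FALSE],
    start = min(exons[, "start"]), end = max(exons[, "end"])
  )
}

sim_ref_gene <- function(p, start) {
  n_ex <- rint(p$exon_count)
  ex_lens <- rint(p$exon_len, n_ex)
  in_lens <- if (n_ex > 1L) rint(p$intron_len, n_ex - 1L) else integer(0)
  ex_starts <- start + cumsum(c(0L, ex_lens[-n_ex] + in_lens))
  exons <- iv(ex_starts, ex_starts + ex_lens - 1L)
  end <- max(exons[, "end"])
  strand <- sample(c("+", "-"), 1L)
  # Both UTRs must stay inside their terminal exon (with >= 10 coding bp
  # left) so every internal exon boundary is coding: the genomic-left UTR is
  # the 5' one on "+", the 3' one on "-".
  left_len <- rint(if (strand == "+") p$utr5_len else p$utr3_len)
  right_len <- rint(if (strand == "+") p$utr3_len else p$utr5_len)
  lo <- start + min(max(left_len, 5L), ex_lens[1L] - 10L)
  hi <- end - min(max(right_len, 5L), ex_lens[n_ex] - 10L)
  sim_tx_model(exons, iv_intersect(exons, iv(lo, hi)), strand)
}

sim_gff3_lines <- function(genes, src, explicit_utrs) {
  out <- "##gff-version 3"
  for (g in genes) {
    gid <- g$id
    tid <- paste0(gid, ".t1")
    m <- g$model
    feat <- function(type, s, e, attrs, phase = ".") {
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$seqid, src, type, s, e, m$strand, phase, attrs)
    }
    out <- c(out,
      feat("gene", m$start, m$end, sprintf("ID=%s", gid)),
      feat("mRNA", m$start, m$end, sprintf("ID=%s;Parent=%s", tid, gid)),
      vapply(seq_len(nrow(m$exons)), function(i) {
        feat("exon", m$exons[i, "start"], m$exons[i, "end"],
             sprintf("Parent=%s", tid))
      }, ""),
      vapply(seq_len(nrow(m$cds)), function(i) {
        feat("CDS", m$cds[i, "start"], m$cds[i, "end"],
             sprintf("ID=%s.cds;Parent=%s", tid, tid), phase = "0")
      }, ""))
    if (explicit_utrs) {
      utr_lines <- function(mat, type) {
        vapply(seq_len(nrow(mat)), function(i) {
          feat(type, mat[i, "start"], mat[i, "end"], sprintf("Parent=%s", tid))
        }, "")
      }
      out <- c(out, utr_lines(m$utr5, "five_prime_UTR"),
               utr_lines(m$utr3, "three_prime_UTR"))
    }
  }
  out
}

pool_models <- function(models) {
  bind <- function(what) {
    m <- do.call(rbind, lapply(models, `[[`, what))
    iv(m[, "start"], m[, "end"])
  }
  list(
    cds = bind("cds"), utr5 = bind("utr5"), utr3 = bind("utr3"),
    introns = bind("introns"),
    extents = iv(vapply(models, `[[`, 0L, "start"),
                 vapply(models, `[[`, 0L, "end"))
  )
}

#' Generate a paired reference/prediction annotation set with ground truth
#'
#' Reference genes are laid out non-overlapping along each sequence; the
#' prediction is derived gene-by-gene via the perturbation program in
#' `params`. The result carries a ground-truth table with the expected
#' locus status and structural classification for every locus, plus the
#' exact coordinate records needed by [expected_confusion()].
#'
#' @param params A [sim_params()] object.
#' @param seed Seed override (defaults to `params$seed`).
#' @return A list of class `"annotation_sim"` with elements `reference` and
#'   `prediction` (GFF3 text lines), `truth` (one row per expected locus:
#'   `seqid`, `start`, `end`, `status`, `expected_class`, `edit`, `ref_ids`,
#'   `pred_ids`), `loci` (coordinate records), and `params`.
#' @export
simulate_annotation_pair <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    per_seq <- diff(floor(seq(0, params$n_genes, length.out = params$n_seqids + 1L)))
    ref <- list()
    gaps_after <- numeric(0)
    idx <- 0L
    for (s in seq_len(params$n_seqids)) {
      seqid <- sprintf("seq%d", s)
      n <- per_seq[s]
      if (n == 0L) next
      gaps <- rint(params$gap, n + 1L)
      cursor <- 0L
      for (k in seq_len(n)) {
        idx <- idx + 1L
        model <- sim_ref_gene(params, cursor + gaps[k])
        ref[[idx]] <- list(id = sprintf("%s.g%d", seqid, k), seqid = seqid,
                           model = model)
        gaps_after[idx] <- gaps[k + 1L]
        cursor <- model$end
      }
      if (!is.null(params$seq_length) &&
          cursor + gaps[n + 1L] > params$seq_length) {
        stop(sprintf("genes do not fit in seq_length %d (need %d on %s)",
                     params$seq_length, cursor + gaps[n + 1L], seqid),
             call. = FALSE)
      }
    }
    n <- length(ref)
    edits <- sample(names(params$p), n, replace = TRUE, prob = params$p)

    pred <- list()
    loci <- list()
    truth <- list()
    consumed <- rep(FALSE, n)
    same_seq_next <- function(i) i < n && ref[[i + 1L]]$seqid == ref[[i]]$seqid

    add_locus <- function(status, edit, ref_models, pred_models,
                          ref_ids, pred_ids, seqid) {
      refp <- if (length(ref_models)) pool_models(ref_models) else NULL
      predp <- if (length(pred_models)) pool_models(pred_models) else NULL
      span <- range(c(if (!is.null(refp)) refp$extents,
                      if (!is.null(predp)) predp$extents))
      loci[[length(loci) + 1L]] <<- list(
        status = status, span = span, ref = refp, pred = predp, seqid = seqid
      )
      truth[[length(truth) + 1L]] <<- data.frame(
        seqid = seqid, start = span[1L], end = span[2L], status = status,
        expected_class = if (status == "shared") SIM_EXPECTED_CLASS[[edit]]
                         else NA_character_,
        edit = edit,
        ref_ids = paste(ref_ids, collapse = ","),
        pred_ids = paste(pred_ids, collapse = ","),
        stringsAsFactors = FALSE
      )
    }

    for (i in seq_len(n)) {
      if (consumed[i]) next
      g <- ref[[i]]
      m <- g$model
      e <- edits[i]
      if (e == "merge" && !(same_seq_next(i) && !consumed[i + 1L])) e <- "identical"
      if (e == "splice" && nrow(m$exons) < 2L) e <- "identical"

      if (e == "identical" || e == "add") {
        pm <- m
      } else if (e == "utr") {
        # extend the genomic-left terminal exon outward: UTR-only change
        delta <- rint(c(5L, 40L))
        exons <- m$exons
        exons[1L, "start"] <- exons[1L, "start"] - delta
        pm <- sim_tx_model(exons, m$cds, m$strand)
      } else if (e == "cds") {
        # move the start codon 1-2 codons into the CDS; exons untouched
        k <- 3L * rint(c(1L, 2L))
        cds_bounds <- if (m$strand == "+") {
          iv(min(m$cds[, "start"]) + k, max(m$cds[, "end"]))
        } else {
          iv(min(m$cds[, "start"]), max(m$cds[, "end"]) - k)
        }
        pm <- sim_tx_model(m$exons, iv_intersect(m$exons, cds_bounds), m$strand)
      } else if (e == "splice") {
        # push an internal exon end into the following intron (coding region)
        j <- if (nrow(m$exons) == 2L) 1L else rint(c(1L, nrow(m$exons) - 1L))
        intron_len <- m$exons[j + 1L, "start"] - m$exons[j, "end"] - 1L
        delta <- rint(c(5L, min(25L, intron_len - 5L)))
        exons <- m$exons
        exons[j, "end"] <- exons[j, "end"] + delta
        cds_bounds <- iv(min(m$cds[, "start"]), max(m$cds[, "end"]))
        pm <- sim_tx_model(exons, iv_intersect(exons, cds_bounds), m$strand)
      } else if (e == "drop") {
        add_locus("ref_only", "drop", list(m), list(), g$id, character(0), g$seqid)
        next
      } else if (e == "merge") {
        nxt <- ref[[i + 1L]]
        consumed[i + 1L] <- TRUE
        fused_exons <- iv(c(m$exons[, "start"], nxt$model$exons[, "start"]),
                          c(m$exons[, "end"], nxt$model$exons[, "end"]))
        fused_cds <- iv(c(m$cds[, "start"], nxt$model$cds[, "start"]),
                        c(m$cds[, "end"], nxt$model$cds[, "end"]))
        pm <- sim_tx_model(fused_exons, fused_cds, m$strand)
        fused <- list(id = sprintf("merge_%s", g$id), seqid = g$seqid, model = pm)
        pred[[length(pred) + 1L]] <- fused
        add_locus("shared", "merge", list(m, nxt$model), list(pm),
                  c(g$id, nxt$id), fused$id, g$seqid)
        next
      }

      pred[[length(pred) + 1L]] <- list(id = g$id, seqid = g$seqid, model = pm)
      add_locus("shared", if (e == "add") "identical" else e,
                list(m), list(pm), g$id, g$id, g$seqid)

      if (e == "add") {
        # novel single-exon gene centred in the following intergenic gap
        width <- rint(c(80L, 160L))
        astart <- m$end + gaps_after[i] %/% 2L - width %/% 2L
        exons <- iv(astart, astart + width - 1L)
        am <- sim_tx_model(exons, iv(astart + 10L, astart + width - 11L),
                           sample(c("+", "-"), 1L))
        novel <- list(id = sprintf("novel_%s", g$id), seqid = g$seqid, model = am)
        pred[[length(pred) + 1L]] <- novel
        add_locus("pred_only", "add", list(), list(am), character(0),
                  novel$id, g$seqid)
      }
    }

    truth <- do.call(rbind, truth)
    ord <- order(truth$seqid, truth$start, method = "radix")
    structure(
      list(
        reference = sim_gff3_lines(ref, "refsim", params$explicit_utrs),
        prediction = sim_gff3_lines(pred, "predsim", params$explicit_utrs),
        truth = truth[ord, , drop = FALSE],
        loci = loci[ord],
        edits = edits,
        params = params,
        seed = seed
      ),
      class = "annotation_sim"
    )
  })
}

#' @export
print.annotation_sim <- function(x, ...) {
  cat(sprintf("<annotation_sim> seed=%d, %d expected loci (%s)\n",
              x$seed, nrow(x$truth),
              paste(sprintf("%s=%d", names(table(x$truth$status)),
                            as.integer(table(x$truth$status))), collapse = ", ")))
  invisible(x)
}

#' Pooled confusion counts implied by the simulated edits
#'
#' Computes, by interval arithmetic over the generator's own coordinate
#' records (never by running the comparison pipeline), the pooled
#' nucleotide-level confusion counts and overall-identity tallies that the
#' pipeline must report for a simulated pair. One-sided loci contribute
#' nothing, mirroring the pipeline's rule that unmatched cliques carry no
#' statistic counts.
#'
#' @param sim An `"annotation_sim"` object.
#' @return List with `nuc_cds` and `nuc_utr` (`"confusion"` objects) and
#'   `identity` (`c(matches, positions)`).
#' @export
expected_confusion <- function(sim) {
  stopifnot(inherits(sim, "annotation_sim"))
  cds <- confusion()
  utr <- confusion()
  matches <- 0
  positions <- 0
  for (rec in sim$loci) {
    if (rec$status != "shared") next
    L <- rec$span[2L] - rec$span[1L] + 1
    conf_for <- function(a, b) {
      tp <- iv_width(iv_intersect(a, b))
      confusion(tp = tp,
                fp = iv_width(b) - iv_width(iv_intersect(a, b)),
                fn = iv_width(a) - tp,
                tn = L - iv_width(iv_union(a, b)))
    }
    utr_ref <- iv_union(rec$ref$utr5, rec$ref$utr3)
    utr_pred <- iv_union(rec$pred$utr5, rec$pred$utr3)
    cds <- add_confusion(cds, conf_for(rec$ref$cds, rec$pred$cds))
    utr <- add_confusion(utr, conf_for(utr_ref, utr_pred))
    ann_ref <- rec$ref$extents
    ann_pred <- rec$pred$extents
    m <- iv_width(iv_intersect(rec$ref$cds, rec$pred$cds)) +
      iv_width(iv_intersect(rec$ref$utr5, rec$pred$utr5)) +
      iv_width(iv_intersect(rec$ref$utr3, rec$pred$utr3)) +
      iv_width(iv_intersect(rec$ref$introns, rec$pred$introns)) +
      (L - iv_width(iv_union(ann_ref, ann_pred)))
    matches <- matches + m
    positions <- positions + L
  }
  list(nuc_cds = cds, nuc_utr = utr,
       identity = c(matches = matches, positions = positions))
}
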