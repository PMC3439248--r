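# Confusion counting and similarity statistics.

#' Confusion counts
#'
#' @param tp,fp,fn,tn Non-negative counts. At feature resolution `tn` is
#'   undefined and held at 0 (it never enters feature-level statistics).
#' @return Named numeric vector of class `"confusion"`.
#' @export
confusion <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  structure(c(tp = as.numeric(tp), fp = as.numeric(fp),
              fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "confusion")
}

add_confusion <- function(a, b) {
  confusion(a["tp"] + b["tp"], a["fp"] + b["fp"], a["fn"] + b["fn"],
            a["tn"] + b["tn"])
}

#' Nucleotide-level confusion counts between two model vectors
#'
#' For class `"CDS"`, a position is in-class when its symbol is `C`; for
#' `"UTR"`, when its symbol is `F` or `T` (both UTR roles pooled). The
#' reference defines the condition, the prediction the call.
#'
#' @param ref,pred `"model_vector"` objects over the same locus.
#' @param class `"CDS"` or `"UTR"`.
#' @return A `"confusion"` object; counts sum to the locus length.
#' @export
nucleotide_confusion <- function(ref, pred, class = c("CDS", "UTR")) {
  class <- match.arg(class)
  r <- ref$symbols
  p <- pred$symbols
  if (length(r) != length(p)) {
    stop("model vectors have different lengths", call. = FALSE)
  }
  members <- if (class == "CDS") "C" else c("F", "T")
  rin <- r %in% members
  pin <- p %in% members
  confusion(tp = sum(rin & pin), fp = sum(!rin & pin),
            fn = sum(rin & !pin), tn = sum(!rin & !pin))
}

#' Overall nucleotide identity between two model vectors
#'
#' Fraction of positions carrying the identical symbol over the full
#' five-letter alphabet.
#'
#' @inheritParams nucleotide_confusion
#' @return A number in `[0, 1]`.
#' @export
overall_identity <- function(ref, pred) {
  if (length(ref$symbols) != length(pred$symbols)) {
    stop("model vectors have different lengths", call. = FALSE)
  }
  mean(ref$symbols == pred$symbols)
}

#' Feature-level confusion counts by exact coordinate matching
#'
#' A prediction segment is a true positive only when both its start and end
#' coordinates exactly equal those of a reference segment; each reference
#' segment can be consumed at most once. Remaining prediction segments are
#' false positives, remaining reference segments false negatives. True
#' negatives are undefined at feature resolution.
#'
#' @param ref_segments,pred_segments Interval matrices (see [iv()]).
#' @return A `"confusion"` object with `tn = 0`.
#' @export
feature_confusion <- function(ref_segments, pred_segments) {
  rk <- iv_key(ref_segments)
  pk <- iv_key(pred_segments)
  tab_r <- table(rk)
  tab_p <- table(pk)
  shared <- intersect(names(tab_r), names(tab_p))
  tp <- sum(pmin(tab_r[shared], tab_p[shared]))
  confusion(tp = tp, fp = length(pk) - tp, fn = length(rk) - tp, tn = 0)
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Similarity statistics from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TP/(TP+FP)` (precision,
#' per the gene-prediction convention), `F1 = 2*TP/(2*TP+FP+FN)`, annotation
#' edit distance `AED = 1 - (Sn+Sp)/2`, and — at nucleotide resolution only —
#' the simple matching coefficient `(TP+TN)/(TP+FP+FN+TN)` and the
#' Matthews-style correlation coefficient. Any statistic with a vanishing
#' denominator is `NA` (rendered as `"--"`; never coerced to 0).
#'
#' @param counts A `"confusion"` object.
#' @param level `"nucleotide"` or `"feature"`.
#' @return Named numeric vector `sensitivity`, `specificity`, `f1`, `aed`,
#'   `smc`, `cc` (the last two `NA` at feature level).
#' @export
annotation_stats <- function(counts, level = c("nucleotide", "feature")) {
  level <- match.arg(level)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  sn <- ratio_or_na(tp, tp + fn)
  sp <- ratio_or_na(tp, tp + fp)
  f1 <- ratio_or_na(2 * tp, 2 * tp + fp + fn)
  aed <- if (is.na(sn) || is.na(sp)) NA_real_ else 1 - (sn + sp) / 2
  smc <- NA_real_
  cc <- NA_real_
  if (level == "nucleotide") {
    smc <- ratio_or_na(tp + tn, tp + fp + fn + tn)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den > 0) cc <- (tp * tn - fp * fn) / sqrt(den)
  }
  c(sensitivity = sn, specificity = sp, f1 = f1, aed = aed, smc = smc, cc = cc)
}
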