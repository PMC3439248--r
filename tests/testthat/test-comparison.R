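test_that("nucleotide confusion counts the four cells exactly", {
  r <- fake_mv(c(rep("C", 60), rep("G", 140)))
  expect_equal(unclass(nucleotide_confusion(r, r, "CDS")),
               c(tp = 60, fp = 0, fn = 0, tn = 140))

  r2 <- fake_mv("CCCCGGGG")
  p2 <- fake_mv("CCGGGGCC")
  expect_equal(unclass(nucleotide_confusion(r2, p2, "CDS")),
               c(tp = 2, fp = 2, fn = 2, tn = 2))

  # both all-intergenic: zero-denominator statistics stay undefined
  g <- fake_mv(strrep("G", 8))
  cc <- nucleotide_confusion(g, g, "CDS")
  expect_equal(unclass(cc), c(tp = 0, fp = 0, fn = 0, tn = 8))
  st <- annotation_stats(cc, "nucleotide")
  expect_true(is.na(st[["sensitivity"]]) && is.na(st[["specificity"]]))

  # UTR class pools F and T
  r3 <- fake_mv("FFTTGG")
  p3 <- fake_mv("TTFFCC")
  expect_equal(unclass(nucleotide_confusion(r3, p3, "UTR")),
               c(tp = 4, fp = 0, fn = 0, tn = 2))

  expect_error(nucleotide_confusion(fake_mv("CC"), fake_mv("C"), "CDS"),
               "different lengths")
})

test_that("overall identity is the matching-position fraction over the full alphabet", {
  expect_equal(overall_identity(fake_mv("GFCIT"), fake_mv("GFCIT")), 1.0)
  expect_equal(overall_identity(fake_mv("GFCIT"), fake_mv("GGCIT")), 0.8)
  expect_equal(overall_identity(fake_mv("CCCC"), fake_mv("GGGG")), 0.0)
})

test_that("feature matching requires exact start and end coordinates", {
  ref <- mk_iv(c(11, 40), c(61, 90), c(101, 130))
  expect_equal(unclass(feature_confusion(ref, ref)),
               c(tp = 3, fp = 0, fn = 0, tn = 0))
  pred <- mk_iv(c(11, 40), c(61, 95))
  expect_equal(unclass(feature_confusion(mk_iv(c(11, 40), c(61, 90)), pred)),
               c(tp = 1, fp = 1, fn = 1, tn = 0))
  expect_equal(unclass(feature_confusion(mk_iv(c(12, 40)), mk_iv(c(11, 40)))),
               c(tp = 0, fp = 1, fn = 1, tn = 0))
  # duplicated coordinates consume one reference segment each
  expect_equal(feature_confusion(mk_iv(c(1, 5)), mk_iv(c(1, 5), c(1, 5)))[["tp"]], 1)
})

test_that("the statistics panel matches its closed forms and limit cases", {
  st <- annotation_stats(confusion(80, 10, 20, 90), "nucleotide")
  expect_equal(st[["sensitivity"]], 0.8, tolerance = 1e-9)
  expect_equal(st[["specificity"]], 80 / 90, tolerance = 1e-9)
  expect_equal(st[["f1"]], 160 / 190, tolerance = 1e-9)
  expect_equal(st[["aed"]], 1 - (0.8 + 80 / 90) / 2, tolerance = 1e-9)
  expect_equal(st[["smc"]], 0.85, tolerance = 1e-9)
  expect_equal(st[["cc"]], 7000 / sqrt(90 * 100 * 100 * 110), tolerance = 1e-9)
  # printed to 4 decimals these are 0.8000 0.8889 0.8421 0.1556 0.8500 0.7035
  expect_equal(round(unname(st), 4),
               c(0.8, 0.8889, 0.8421, 0.1556, 0.85, 0.7035))

  perfect <- annotation_stats(confusion(25, 0, 0, 0), "feature")
  expect_equal(unname(perfect[c("sensitivity", "specificity", "f1", "aed")]),
               c(1, 1, 1, 0))
  expect_true(all(is.na(perfect[c("smc", "cc")])))

  worst <- annotation_stats(confusion(0, 5, 7, 0), "nucleotide")
  expect_equal(unname(worst[c("sensitivity", "specificity", "aed")]), c(0, 0, 1))
})

test_that("structural classification follows the exact-agreement hierarchy", {
  locus <- function(...) mk_locus(1, 120, ref_genes = list(...))
  enc <- function(tx) model_vector(list(tx), mk_locus(1, 120, ref_genes = list(mk_gene(paste0(tx$id, "g"), list(tx)))))

  base <- mk_tx("r", exons = list(c(11, 100)), cds = list(c(31, 90)))
  expect_equal(classify_comparison(enc(base), enc(base)), "perfect_match")

  utr_longer <- mk_tx("p", exons = list(c(21, 100)), cds = list(c(31, 90)))
  expect_equal(classify_comparison(enc(base), enc(utr_longer)), "cds_structure_match")

  cds_shift <- mk_tx("p", exons = list(c(11, 100)), cds = list(c(34, 90)))
  expect_equal(classify_comparison(enc(base), enc(cds_shift)), "exon_structure_match")

  ref2 <- mk_tx("r", exons = list(c(1, 30), c(61, 100)), cds = list(c(11, 30), c(61, 90)))
  utr_same <- mk_tx("p", exons = list(c(1, 30), c(51, 100)), cds = list(c(11, 30), c(51, 90)))
  expect_equal(classify_comparison(enc(ref2), enc(utr_same)), "utr_structure_match")

  off <- mk_tx("p", exons = list(c(12, 101)), cds = list(c(32, 91)))
  expect_equal(classify_comparison(enc(base), enc(off)), "non_match")
})

test_that("perfect match, identity 1, and all-ones panels coincide", {
  sim <- simulate_annotation_pair(sim_params(n_genes = 25, seed = 41))
  res <- sim_comparison(sim)
  for (lc in res$comparisons) {
    for (cmp in lc$pairs) {
      expect_equal(cmp$classification == "perfect_match", cmp$identity == 1)
      if (cmp$classification == "perfect_match") {
        for (panel in cmp$stats[c("nuc_cds", "nuc_utr", "feat_exon", "feat_cds", "feat_utr")]) {
          defined <- panel[!is.na(panel)]
          expected <- ifelse(names(defined) == "aed", 0, 1)
          expect_equal(unname(defined), unname(expected))
        }
      }
      # bounds: everything in [0,1], cc in [-1,1]
      for (panel in cmp$stats[c("nuc_cds", "nuc_utr")]) {
        v <- panel[!is.na(panel)]
        expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
        expect_true(all(v[setdiff(names(v), "cc")] >= 0))
      }
    }
  }
})

test_that("swapping reference and prediction mirrors the statistics", {
  set.seed(19)
  for (k in 1:40) {
    L <- sample(20:120, 1)
    a <- fake_mv(sample(c("C", "F", "G", "I", "T"), L, replace = TRUE))
    b <- fake_mv(sample(c("C", "F", "G", "I", "T"), L, replace = TRUE))
    for (cls in c("CDS", "UTR")) {
      ab <- nucleotide_confusion(a, b, cls)
      ba <- nucleotide_confusion(b, a, cls)
      expect_equal(ab[["fp"]], ba[["fn"]])
      expect_equal(ab[["fn"]], ba[["fp"]])
      s_ab <- annotation_stats(ab, "nucleotide")
      s_ba <- annotation_stats(ba, "nucleotide")
      expect_equal(s_ab[["sensitivity"]], s_ba[["specificity"]])
      expect_equal(s_ab[c("f1", "aed", "smc", "cc")], s_ba[c("f1", "aed", "smc", "cc")])
    }
    expect_equal(overall_identity(a, b), overall_identity(b, a))
    # SMC for the CDS class equals identity over the collapsed {C, not-C} alphabet
    smc <- annotation_stats(nucleotide_confusion(a, b, "CDS"), "nucleotide")[["smc"]]
    expect_equal(smc, mean((a$symbols == "C") == (b$symbols == "C")))
  }
})

test_that("classification is symmetric in the two sources", {
  sim <- simulate_annotation_pair(sim_params(n_genes = 20, seed = 23))
  ref <- read_annotations_text(sim$reference, "reference")
  pred <- read_annotations_text(sim$prediction, "prediction")
  for (locus in identify_loci(ref, pred)) {
    rc <- transcript_cliques(annomatch:::locus_transcripts(locus, "reference"), "reference")
    pc <- transcript_cliques(annomatch:::locus_transcripts(locus, "prediction"), "prediction")
    if (!length(rc) || !length(pc)) next
    mr <- model_vector(rc[[1]], locus)
    mp <- model_vector(pc[[1]], locus)
    expect_identical(classify_comparison(mr, mp), classify_comparison(mp, mr))
  }
})

test_that("clique pairing is greedy, exclusive, and identity-ranked", {
  t1 <- mk_tx("t1", list(c(1, 100)), list(c(1, 100)))
  t2 <- mk_tx("t2", list(c(1, 120)), list(c(1, 120)))
  p1 <- mk_tx("t1", list(c(1, 100)), list(c(1, 100)))
  locus <- mk_locus(1, 120,
                    ref_genes = list(mk_gene("rg", list(t1, t2))),
                    pred_genes = list(mk_gene("pg", list(p1))))
  lc <- compare_locus(locus)
  expect_equal(lc$n_ref_cliques, 2L)
  expect_length(lc$pairs, 1L)
  expect_equal(lc$pairs[[1]]$classification, "perfect_match")
  expect_equal(lc$pairs[[1]]$ref_label, "t1")
  expect_length(lc$unmatched_ref, 1L)
  expect_equal(lc$unmatched_ref[[1]]$clique$ids, "t2")
  expect_length(lc$unmatched_pred, 0L)

  # 1 vs 1: single pair, nothing unmatched
  locus2 <- mk_locus(1, 100,
                     ref_genes = list(mk_gene("rg", list(t1))),
                     pred_genes = list(mk_gene("pg", list(p1))))
  lc2 <- compare_locus(locus2)
  expect_length(lc2$pairs, 1L)
  expect_length(lc2$unmatched_ref, 0L)
})

test_that("a locus with no prediction genes yields no counted comparison", {
  t1 <- mk_tx("t1", list(c(1, 100)), list(c(21, 80)))
  locus <- mk_locus(1, 100, ref_genes = list(mk_gene("rg", list(t1))))
  lc <- compare_locus(locus)
  expect_equal(lc$status, "ref_only")
  expect_length(lc$pairs, 0L)
  expect_length(lc$unmatched_ref, 1L)
  panel <- lc$unmatched_ref[[1]]$panel
  expect_false(panel$counted)
  expect_equal(panel$classification, "non_match")
  expect_equal(panel$stats$nuc_cds[["sensitivity"]], 0)
  expect_equal(panel$counts$nuc_cds[["fn"]], 60)
})

test_that("no clique is ever paired twice on randomized loci", {
  sim <- simulate_annotation_pair(sim_params(n_genes = 30, seed = 47,
                                             p_merge = 0.3, p_add = 0.2))
  res <- sim_comparison(sim)
  for (lc in res$comparisons) {
    refs <- vapply(lc$pairs, `[[`, "", "ref_label")
    preds <- vapply(lc$pairs, `[[`, "", "pred_label")
    expect_false(anyDuplicated(refs) > 0)
    expect_false(anyDuplicated(preds) > 0)
    expect_equal(length(lc$pairs) + length(lc$unmatched_ref), lc$n_ref_cliques)
    expect_equal(length(lc$pairs) + length(lc$unmatched_pred), lc$n_pred_cliques)
  }
})

test_that("splice complexity equals the position-wise pairwise AED", {
  locus <- mk_locus(1, 150, ref_genes = list(mk_gene("g", list(
    mk_tx("t1", list(c(1, 100)), list(c(1, 100)))))))
  t1 <- mk_tx("t1", list(c(1, 100)), list(c(1, 100)))
  t2 <- mk_tx("t2", list(c(1, 120)), list(c(1, 120)))
  t3 <- mk_tx("t3", list(c(1, 40), c(61, 120)), list(c(1, 40), c(61, 120)))

  expect_equal(splice_complexity(list(t1), locus), 0)
  expect_equal(splice_complexity(list(t1, t1), locus), 0)
  # t1 vs t2: 100 shared coding positions; Sn = 1, Sp = 100/120
  expect_equal(splice_complexity(list(t1, t2), locus),
               1 - (1 + 100 / 120) / 2, tolerance = 1e-12)
  # t1 vs t3: intron 41-60 disagrees; 80 matching positions
  expect_equal(splice_complexity(list(t1, t3), locus),
               1 - (80 / 100 + 80 / 120) / 2, tolerance = 1e-12)
  # mean over the three unordered pairs
  aed_23 <- 1 - (100 / 120 + 100 / 120) / 2
  expect_equal(splice_complexity(list(t1, t2, t3), locus),
               mean(c(1 - (1 + 100 / 120) / 2,
                      1 - (80 / 100 + 80 / 120) / 2,
                      aed_23)), tolerance = 1e-12)
})
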