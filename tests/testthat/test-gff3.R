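test_that("a minimal gene/mRNA/exon/CDS file parses into one transcript", {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t11\t90\t.\t+\t.\tParent=t1",
    "chr1\ttest\tCDS\t21\t80\t.\t+\t0\tID=t1.cds;Parent=t1"
  )
  set <- read_annotations_text(lines, "reference")
  expect_length(set$genes, 1L)
  tx <- set$genes[[1]]$transcripts[[1]]
  expect_equal(nrow(tx$exons), 1L)
  expect_equal(nrow(tx$cds), 1L)
  expect_equal(unname(tx$cds[1, ]), c(21L, 80L))
})

test_that("genes are grouped by sequence identifier", {
  lines <- c(tiny_gff3(seqid = "chr1", gid = "g1"),
             tiny_gff3(seqid = "chr2", gid = "g2")[-1])
  set <- read_annotations_text(lines, "reference")
  expect_length(set$genes, 2L)
  expect_equal(annomatch:::annotation_seqids(set), c("chr1", "chr2"))
})

test_that("introns and UTR segments are inferred from exons and CDS", {
  set <- read_annotations_text(tiny_gff3(), "reference")
  tx <- set$genes[[1]]$transcripts[[1]]
  expect_equal(tx$introns, mk_iv(c(41, 60)))
  expect_equal(tx$utr5, mk_iv(c(11, 20)))
  expect_equal(tx$utr3, mk_iv(c(81, 90)))
})

test_that("UTR labeling mirrors on the minus strand", {
  tx <- mk_tx("t1", exons = list(c(11, 40), c(61, 90)),
              cds = list(c(21, 40), c(61, 80)), strand = "-")
  expect_equal(tx$utr5, mk_iv(c(81, 90)))
  expect_equal(tx$utr3, mk_iv(c(11, 20)))
  expect_equal(tx$introns, mk_iv(c(41, 60)))
})

test_that("CDS identical to exons leaves both UTR sets empty", {
  tx <- mk_tx("t1", exons = list(c(11, 40)), cds = list(c(11, 40)))
  expect_equal(nrow(tx$utr5), 0L)
  expect_equal(nrow(tx$utr3), 0L)
})

test_that("exonic CDS/UTR positions partition the exon positions", {
  sim <- simulate_annotation_pair(sim_params(n_genes = 15, seed = 21))
  set <- read_annotations_text(sim$reference, "reference")
  for (g in set$genes) {
    for (tx in g$transcripts) {
      exonic <- sort(unlist(apply(tx$exons, 1, function(r) r[1]:r[2], simplify = FALSE)))
      pieces <- rbind(tx$cds, tx$utr5, tx$utr3)
      covered <- sort(unlist(apply(pieces, 1, function(r) r[1]:r[2], simplify = FALSE)))
      expect_identical(covered, exonic)
      span_minus_exons <- setdiff(tx$start:tx$end, exonic)
      intronic <- sort(unlist(apply(tx$introns, 1, function(r) r[1]:r[2], simplify = FALSE)))
      expect_identical(as.integer(intronic), as.integer(span_minus_exons))
    }
  }
})

test_that("mRNAs lacking exons get exons synthesized from CDS", {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\tCDS\t11\t40\t.\t+\t0\tID=c1;Parent=t1",
    "chr1\ttest\tCDS\t61\t90\t.\t+\t0\tID=c1;Parent=t1"
  )
  set <- read_annotations_text(lines, "reference")
  tx <- set$genes[[1]]$transcripts[[1]]
  expect_equal(tx$exons, tx$cds)
  expect_equal(tx$introns, mk_iv(c(41, 60)))
})

test_that("standalone mRNAs are wrapped in a synthetic gene", {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t1",
    "chr1\ttest\texon\t11\t90\t.\t+\t.\tParent=t1",
    "chr1\ttest\tCDS\t21\t80\t.\t+\t0\tParent=t1"
  )
  set <- read_annotations_text(lines, "reference")
  expect_length(set$genes, 1L)
  expect_equal(set$genes[[1]]$id, "t1.gene")
})

test_that("malformed lines are rejected with their line number", {
  bad_cols <- c("##gff-version 3", "chr1\ttest\tgene\t11\t90\t.\t+\t.")
  expect_error(read_annotations_text(bad_cols, "reference"),
               "line 2.*9 tab-separated")
  bad_coords <- c("##gff-version 3",
                  "chr1\ttest\tgene\t90\t11\t.\t+\t.\tID=g1")
  expect_error(read_annotations_text(bad_coords, "reference"), "line 2.*end")
})

test_that("unknown Parent references are an error", {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t1;Parent=gX"
  )
  expect_error(read_annotations_text(lines, "reference"), "unknown feature ID")
  lines2 <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t11\t90\t.\t+\t.\tParent=tX"
  )
  expect_error(read_annotations_text(lines2, "reference"), "unknown feature ID")
})

test_that("featureless mRNAs and non-mRNA transcript types are skipped with warnings", {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t11\t90\t.\t+\t.\tParent=t1",
    "chr1\ttest\tCDS\t21\t80\t.\t+\t0\tParent=t1",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttest\ttRNA\t11\t50\t.\t+\t.\tID=tr1;Parent=g1",
    "chr1\ttest\texon\t11\t50\t.\t+\t.\tParent=tr1"
  )
  expect_warning(expect_warning(
    set <- read_annotations_text(lines, "reference"),
    "non-mRNA"), "no exon and no CDS")
  expect_length(set$genes[[1]]$transcripts, 1L)
})

test_that("feature line order does not affect the parsed annotation set", {
  lines <- c(tiny_gff3(gid = "g1"),
             tiny_gff3(gid = "g2", start = 211,
                       exons = list(c(211, 260), c(301, 350)),
                       cds = list(c(221, 260), c(301, 340)))[-1])
  set1 <- read_annotations_text(lines, "reference")
  body <- lines[-1]
  set.seed(4)
  for (k in 1:5) {
    set2 <- read_annotations_text(c("##gff-version 3", sample(body)), "reference")
    expect_equal(set1, set2)
  }
})

test_that("explicit UTR features are checked against inference", {
  base <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t90\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t11\t90\t.\t+\t.\tParent=t1",
    "chr1\ttest\tCDS\t21\t80\t.\t+\t0\tParent=t1"
  )
  ok <- c(base, "chr1\ttest\tfive_prime_UTR\t11\t20\t.\t+\t.\tParent=t1")
  expect_no_warning(read_annotations_text(ok, "reference"))
  conflict <- c(base, "chr1\ttest\tfive_prime_UTR\t11\t25\t.\t+\t.\tParent=t1")
  expect_warning(set <- read_annotations_text(conflict, "reference"),
                 "conflict.*keeping inferred")
  expect_equal(set$genes[[1]]$transcripts[[1]]$utr5, mk_iv(c(11, 20)))
})

test_that("CDS segments outside every exon are a structural error", {
  expect_error(
    mk_tx("tbad", exons = list(c(11, 40)), cds = list(c(30, 50))),
    "not contained in any exon.*tbad"
  )
})

test_that("duplicate gene IDs are rejected", {
  g1 <- mk_gene("g1", list(mk_tx("t1", list(c(1, 50)), list(c(1, 50)))))
  g2 <- mk_gene("g1", list(mk_tx("t2", list(c(100, 150)), list(c(100, 150)))))
  expect_error(new_annotation_set(list(g1, g2), "reference"), "duplicate gene ID")
})

test_that("the locus GFF3 track round-trips coordinates and sorts deterministically", {
  loci <- list(
    mk_locus(100, 950, seqid = "chr2",
             ref_genes = list(mk_gene("a", list(mk_tx("ta", list(c(100, 950)))))),
             pred_genes = list()),
    mk_locus(5, 80, seqid = "chr1",
             ref_genes = list(mk_gene("b", list(mk_tx("tb", list(c(5, 80)))))),
             pred_genes = list())
  )
  path <- tempfile(fileext = ".gff3")
  lines <- write_locus_gff3(loci, path)
  expect_equal(lines[1], "##gff-version 3")
  gr <- rtracklayer::import(path, format = "gff3")
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(BiocGenerics::start(gr), c(5L, 100L))
  expect_equal(BiocGenerics::end(gr), c(80L, 950L))
  expect_equal(as.character(gr$type), c("locus", "locus"))
  expect_equal(gr$ref_genes, c("1", "1"))
  # empty input yields a header-only file
  expect_equal(write_locus_gff3(list(), tempfile()), "##gff-version 3")
})
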