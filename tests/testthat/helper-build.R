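# Builders and brute-force oracles shared across the test files.

mk_iv <- function(...) {
  pairs <- list(...)
  if (!length(pairs)) return(annomatch:::iv())
  m <- do.call(rbind, pairs)
  annomatch:::iv(m[, 1L], m[, 2L])
}

mk_tx <- function(id, exons, cds = list(), strand = "+", seqid = "chr1",
                  gene_id = paste0(id, ".g")) {
  new_transcript(
    id = id, gene_id = gene_id, seqid = seqid, strand = strand,
    exons = do.call(mk_iv, exons),
    cds = if (length(cds)) do.call(mk_iv, cds) else annomatch:::iv()
  )
}

mk_gene <- function(id, txs, source = "reference") new_gene(id, txs, source)

mk_locus <- function(start, end, seqid = "chr1",
                     ref_genes = list(), pred_genes = list()) {
  annomatch:::new_gene_locus(seqid, start, end, ref_genes, pred_genes)
}

mv_str <- function(mv) paste(mv$symbols, collapse = "")

# A bare model vector carrying arbitrary symbols (no member transcripts);
# enough for nucleotide-level statistics.
fake_mv <- function(symbols, start = 1L) {
  if (length(symbols) == 1L) symbols <- strsplit(symbols, "")[[1L]]
  structure(
    list(symbols = symbols, seqid = "chrT", start = start,
         end = start + length(symbols) - 1L, ids = character(0),
         transcripts = list()),
    class = "model_vector"
  )
}

# Minimal single-gene GFF3 used by parser and pipeline tests.
tiny_gff3 <- function(seqid = "chr1", gid = "g1", start = 11L,
                      exons = list(c(11, 40), c(61, 90)),
                      cds = list(c(21, 40), c(61, 80)), strand = "+",
                      src = "test") {
  tid <- paste0(gid, ".t1")
  span <- range(unlist(exons))
  lines <- c(
    sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s", seqid, src, span[1], span[2], strand, gid),
    sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", seqid, src, span[1], span[2], strand, tid, gid),
    vapply(exons, function(e) sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                      seqid, src, e[1], e[2], strand, tid), ""),
    vapply(cds, function(e) sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                                    seqid, src, e[1], e[2], strand, tid, tid), "")
  )
  c("##gff-version 3", lines)
}

write_gff3_tmp <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

# Random undirected graph as a symmetric logical adjacency matrix.
rand_adj <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- TRUE
    adj <- adj | t(adj)
  }
  adj
}

# Brute-force maximal clique oracle: test all 2^n - 1 vertex subsets.
brute_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n >= 1L, n <= 16L)
  bit <- as.integer(2^(seq_len(n) - 1L))
  masks <- vapply(seq_len(n), function(v) {
    as.integer(sum(bit[adj[v, ]]))
  }, integer(1))
  out <- list()
  for (m in seq_len(2L^n - 1L)) {
    verts <- which(bitwAnd(m, bit) > 0L)
    is_clique <- all(vapply(verts, function(v) {
      bitwAnd(masks[v], m) == m - bit[v]
    }, logical(1)))
    if (!is_clique) next
    outside <- setdiff(seq_len(n), verts)
    maximal <- !any(vapply(outside, function(u) {
      bitwAnd(masks[u], m) == m
    }, logical(1)))
    if (maximal) out[[length(out) + 1L]] <- verts
  }
  keys <- vapply(out, function(v) paste(sprintf("%06d", v), collapse = ","), "")
  out[order(keys, method = "radix")]
}

# Connected-component oracle: boolean transitive closure by repeated
# squaring of the reachability matrix.
closure_components <- function(n, edges) {
  M <- diag(TRUE, n)
  if (nrow(edges) > 0L) {
    M[edges] <- TRUE
    M[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M > 0)) break
    M <- M2
  }
  groups <- apply(M, 1L, function(r) paste(which(r), collapse = ","))
  comps <- split(seq_len(n), groups)
  comps <- lapply(unname(comps), as.integer)
  comps[order(vapply(comps, min, 0L))]
}

# Parameters for a perturbation program applying a single edit class to
# every gene (edit = "identical" applies none).
single_edit_params <- function(edit, n = 30L, seed = 101L) {
  p <- list(utr = 0, cds = 0, splice = 0, drop = 0, add = 0, merge = 0)
  if (edit != "identical") p[[edit]] <- 1
  sim_params(n_genes = n, seed = seed,
             p_utr = p$utr, p_cds = p$cds, p_splice = p$splice,
             p_drop = p$drop, p_add = p$add, p_merge = p$merge)
}

sim_comparison <- function(sim) {
  ref <- read_annotations_text(sim$reference, "reference")
  pred <- read_annotations_text(sim$prediction, "prediction")
  suppressWarnings(compare_annotations(ref, pred))
}

locus_classifications <- function(res) {
  vapply(res$comparisons, function(lc) {
    if (length(lc$pairs)) lc$pairs[[1L]]$classification else NA_character_
  }, "", USE.NAMES = FALSE)
}
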