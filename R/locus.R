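# Gene locus identification.
#
# Both annotation sources contribute nodes to a joint interval graph; an edge
# joins two genes whose spans share at least one position (strand and source
# are ignored). Each connected component defines one gene locus: the smallest
# genomic region containing every member gene.

#' Build the joint gene-overlap interval graph for one sequence
#'
#' Every gene from either source on `seqid` is a node; an undirected edge
#' joins two genes whose 1-based inclusive spans share at least one position.
#' Overlap is evaluated on gene spans (outermost transcript extent),
#' regardless of strand and regardless of which source each gene came from.
#' Adjacency (end = other start - 1) is not overlap.
#'
#' @param ref,pred `"annotation_set"` objects.
#' @param seqid Sequence identifier to restrict to.
#' @return An object of class `"gene_graph"`: a list with `nodes` (data frame
#'   with `key`, `source`, `id`, `start`, `end`) and `edges` (two-column
#'   matrix of node indices).
#' @export
gene_interval_graph <- function(ref, pred, seqid) {
  gs <- c(genes_on(ref, seqid), genes_on(pred, seqid))
  nodes <- data.frame(
    source = vapply(gs, `[[`, "", "source"),
    id = vapply(gs, `[[`, "", "id"),
    start = vapply(gs, function(g) g$start, 0L),
    end = vapply(gs, function(g) g$end, 0L),
    stringsAsFactors = FALSE
  )
  nodes$key <- paste0(ifelse(nodes$source == "reference", "R:", "P:"), nodes$id)
  ir <- IRanges::IRanges(start = nodes$start, end = nodes$end)
  hits <- IRanges::findOverlaps(ir, ir)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keep <- q < s
  structure(
    list(nodes = nodes, genes = gs,
         edges = cbind(q[keep], s[keep]), seqid = seqid),
    class = "gene_graph"
  )
}

#' Connected components of an undirected graph
#'
#' Union-find over an edge list. Components are returned as integer vectors
#' of node indices, each sorted ascending, ordered by their smallest member.
#'
#' @param n Number of nodes (nodes are `1:n`).
#' @param edges Two-column matrix of edges (may have zero rows).
#' @return List of integer vectors partitioning `1:n`.
#' @export
graph_components <- function(n, edges) {
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L])
      b <- find(edges[k, 2L])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- lapply(unname(split(seq_len(n), roots)), sort)
  comps[order(vapply(comps, min, 0L))]
}

#' Connected components of a gene graph
#'
#' Wrapper around [graph_components()] that orders components by the
#' smallest member gene start (then end, then key) for deterministic output.
#'
#' @param g A `"gene_graph"`.
#' @return List of integer vectors indexing `g$nodes`.
#' @export
gene_graph_components <- function(g) {
  comps <- graph_components(nrow(g$nodes), g$edges)
  if (!length(comps)) return(comps)
  keys <- lapply(comps, function(m) {
    list(start = min(g$nodes$start[m]), end = min(g$nodes$end[m]),
         key = min(g$nodes$key[m]))
  })
  ord <- order(vapply(keys, `[[`, 0L, "start"),
               vapply(keys, `[[`, 0L, "end"),
               vapply(keys, `[[`, "", "key"), method = "radix")
  lapply(comps[ord], function(m) {
    m[order(g$nodes$start[m], g$nodes$end[m], g$nodes$key[m], method = "radix")]
  })
}

#' Define gene loci from graph components
#'
#' Each connected component becomes one locus spanning the smallest genomic
#' region containing every member gene; member genes are partitioned by
#' source.
#'
#' @param g A `"gene_graph"`.
#' @param components Output of [gene_graph_components()].
#' @return List of `"gene_locus"` objects sorted by start.
#' @export
loci_from_components <- function(g, components) {
  lapply(components, function(m) {
    members <- g$genes[m]
    src <- g$nodes$source[m]
    new_gene_locus(
      seqid = g$seqid,
      start = min(g$nodes$start[m]),
      end = max(g$nodes$end[m]),
      ref_genes = members[src == "reference"],
      pred_genes = members[src == "prediction"]
    )
  })
}

new_gene_locus <- function(seqid, start, end, ref_genes, pred_genes) {
  stopifnot(length(ref_genes) + length(pred_genes) >= 1L)
  structure(
    list(seqid = seqid, start = as.integer(start), end = as.integer(end),
         ref_genes = ref_genes, pred_genes = pred_genes),
    class = "gene_locus"
  )
}

locus_length <- function(locus) locus$end - locus$start + 1L

locus_transcripts <- function(locus, source = c("reference", "prediction")) {
  source <- match.arg(source)
  genes <- if (source == "reference") locus$ref_genes else locus$pred_genes
  unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE)
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s:%d-%d ref_genes=%d pred_genes=%d\n",
              x$seqid, x$start, x$end, length(x$ref_genes), length(x$pred_genes)))
  invisible(x)
}

#' Identify gene loci jointly over two annotation sets
#'
#' Runs the interval-graph/connected-component locus construction on every
#' sequence annotated by either source and concatenates the results, sorted
#' by (seqid, start). Locus identification is symmetric in the two sources.
#'
#' @param ref,pred `"annotation_set"` objects (roles `reference` and
#'   `prediction`).
#' @return List of `"gene_locus"` objects.
#' @export
identify_loci <- function(ref, pred) {
  seqids <- sort_c(union(annotation_seqids(ref), annotation_seqids(pred)))
  out <- list()
  for (sq in seqids) {
    g <- gene_interval_graph(ref, pred, sq)
    out <- c(out, loci_from_components(g, gene_graph_components(g)))
  }
  out
}
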