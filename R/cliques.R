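# Transcript cliques.
#
# Within one source at one locus, transcripts are nodes of an undirected
# graph with an edge between every pair of NON-overlapping transcripts (the
# complement of the interval graph). Each maximal clique is a set of
# mutually disjoint transcripts that can be collapsed into a single model
# vector. All maximal cliques are enumerated with the Bron-Kerbosch
# algorithm (with pivoting); per-locus transcript counts are small, so the
# worst-case exponential behavior is immaterial.

#' Transcript non-overlap graph
#'
#' @param transcripts List of `"transcript"` objects from one source at one
#'   locus.
#' @return Logical adjacency matrix; entry `[i, j]` is `TRUE` iff transcripts
#'   `i` and `j` are disjoint.
#' @export
nonoverlap_graph <- function(transcripts) {
  n <- length(transcripts)
  starts <- vapply(transcripts, function(t) t$start, 0L)
  ends <- vapply(transcripts, function(t) t$end, 0L)
  adj <- outer(ends, starts, `<`) | t(outer(ends, starts, `<`))
  diag(adj) <- FALSE
  dimnames(adj) <- rep(list(vapply(transcripts, `[[`, "", "id")), 2L)
  adj
}

#' Enumerate all maximal cliques (Bron-Kerbosch with pivoting)
#'
#' @param adj Symmetric logical adjacency matrix with a `FALSE` diagonal.
#' @return List of integer vectors, each a maximal clique, members sorted
#'   ascending; cliques ordered lexicographically by their member vectors.
#'   For an empty graph (0 nodes) a single empty clique is returned.
#' @export
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(list(integer(0)))
  neigh <- lapply(seq_len(n), function(i) which(adj[i, ]))
  out <- list()
  rec <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible(NULL))
    }
    PX <- c(P, X)
    deg <- vapply(PX, function(u) length(intersect(P, neigh[[u]])), 0L)
    u <- PX[which.max(deg)]
    for (v in setdiff(P, neigh[[u]])) {
      rec(c(R, v), intersect(P, neigh[[v]]), intersect(X, neigh[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  rec(integer(0), seq_len(n), integer(0))
  # Deterministic order: lexicographic on the sorted member vectors.
  keys <- vapply(out, function(m) paste(sprintf("%06d", m), collapse = ","), "")
  out[order(keys, method = "radix")]
}

#' Collapse a source's transcripts at a locus into maximal cliques
#'
#' @param transcripts List of `"transcript"` objects (possibly empty).
#' @param source `"reference"` or `"prediction"`.
#' @return List of `"transcript_clique"` objects (empty when there are no
#'   transcripts). Cliques are ordered lexicographically by their sorted
#'   member transcript IDs.
#' @export
transcript_cliques <- function(transcripts, source = c("reference", "prediction")) {
  source <- match.arg(source)
  if (!length(transcripts)) return(list())
  adj <- nonoverlap_graph(transcripts)
  cliques <- maximal_cliques(adj)
  out <- lapply(cliques, function(m) {
    members <- transcripts[m]
    ids <- sort_c(vapply(members, `[[`, "", "id"))
    structure(list(ids = ids, transcripts = members, source = source),
              class = "transcript_clique")
  })
  keys <- vapply(out, function(cl) paste(cl$ids, collapse = ","), "")
  out[order(keys, method = "radix")]
}

#' @export
print.transcript_clique <- function(x, ...) {
  cat(sprintf("<transcript_clique [%s]> {%s}\n", x$source,
              paste(x$ids, collapse = ", ")))
  invisible(x)
}
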