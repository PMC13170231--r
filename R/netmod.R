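# Dense-module detection on weighted interaction graphs: vertex weighting by
# the highest-k core of each node's neighbourhood, seeded greedy complex
# growth, and the k-core post-filter (the MCODE procedure).

#' Build an interaction graph from an edge data.frame
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `weight`
#'   (confidence in `[0, 1]`).
#' @param minConfidence drop edges below this confidence (default 0.4).
#' @return an undirected [igraph::igraph] with no self-loops.
#' @export
interactionGraph <- function(edges, minConfidence = 0.4) {
  stopifnot(all(c("node_a", "node_b", "weight") %in% names(edges)))
  ed <- edges[edges$weight >= minConfidence & edges$node_a != edges$node_b, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$node_a), to = as.character(ed$node_b),
               weight = ed$weight), directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "max")
}

#' MCODE vertex weights
#'
#' For each node v, take the subgraph induced by v's neighbours (v excluded),
#' find its highest-k core, and set
#' \eqn{weight(v) = k \times density(core)}. Nodes with edgeless
#' neighbourhoods (isolated or pendant nodes) weigh 0.
#'
#' @param graph an undirected [igraph::igraph].
#' @return named numeric vector of weights.
#' @export
mcodeVertexWeights <- function(graph) {
  vn <- igraph::V(graph)$name
  w <- stats::setNames(numeric(length(vn)), vn)
  for (v in vn) {
    nb <- igraph::neighbors(graph, v)$name
    if (length(nb) < 2L) next
    sub <- igraph::induced_subgraph(graph, nb)
    if (igraph::ecount(sub) == 0L) next
    core <- igraph::coreness(sub)
    k <- max(core)
    cs <- igraph::induced_subgraph(sub, names(core)[core >= k])
    n <- igraph::vcount(cs)
    dens <- if (n < 2L) 0 else 2 * igraph::ecount(cs) / (n * (n - 1))
    w[v] <- k * dens
  }
  w
}

#' MCODE complex detection
#'
#' Grows complexes from unvisited seed nodes in descending vertex-weight
#' order (lexicographic node-id tie-break): from each seed, breadth-first
#' inclusion of unvisited neighbours whose weight is at least
#' \eqn{(1 - nodeScoreCutoff) \times weight(seed)}, up to `maxDepth` steps.
#' Included nodes are marked visited. Complexes whose induced subgraph lacks
#' a `kCore`-core are discarded; survivors are ranked by
#' \eqn{score = density \times size}. Nodes with degree below `degreeCutoff`
#' never seed. Edge weights play no role in the core algorithm (apply a
#' confidence filter upstream via [interactionGraph()]).
#'
#' @param graph an undirected [igraph::igraph].
#' @param weights vertex weights; computed by [mcodeVertexWeights()] if
#'   missing.
#' @param degreeCutoff,nodeScoreCutoff,kCore,maxDepth the four standard
#'   parameters (defaults 2, 0.2, 2, 100).
#' @param haircut remove tree-like (degree-1 within complex) fringe nodes
#'   (default FALSE).
#' @param fluff not implemented beyond the flag; reserved (default FALSE).
#' @return data.frame `rank`, `score`, `size`, `seed`, `members`
#'   (comma-separated, sorted), plus the weights as attribute `"weights"`.
#' @export
mcodeComplexes <- function(graph, weights = NULL, degreeCutoff = 2L,
                           nodeScoreCutoff = 0.2, kCore = 2L, maxDepth = 100L,
                           haircut = FALSE, fluff = FALSE) {
  if (igraph::vcount(graph) == 0L)
    return(data.frame(rank = integer(0), score = numeric(0), size = integer(0),
                      seed = character(0), members = character(0)))
  if (is.null(weights)) weights <- mcodeVertexWeights(graph)
  deg <- igraph::degree(graph)
  vn <- igraph::V(graph)$name
  visited <- stats::setNames(rep(FALSE, length(vn)), vn)
  seedOrder <- vn[order(-weights[vn], vn, method = "radix")]
  complexes <- list()
  for (seed in seedOrder) {
    if (visited[seed] || deg[seed] < degreeCutoff || weights[seed] <= 0) next
    thr <- (1 - nodeScoreCutoff) * weights[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < maxDepth) {
      nxt <- character(0)
      for (v in frontier) {
        nb <- igraph::neighbors(graph, v)$name
        nb <- nb[!visited[nb] & weights[nb] >= thr]
        if (length(nb)) {
          visited[nb] <- TRUE
          nxt <- c(nxt, nb)
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(graph, members)
    core <- igraph::coreness(sub)
    if (max(core) < kCore) next
    if (haircut) {
      keep <- names(core)[igraph::degree(sub) >= 2L | names(core) == seed]
      members <- keep
      sub <- igraph::induced_subgraph(graph, members)
    }
    n <- length(members)
    dens <- if (n < 2L) 0 else 2 * igraph::ecount(sub) / (n * (n - 1))
    complexes[[length(complexes) + 1L]] <-
      list(seed = seed, members = sort(members), score = dens * n, size = n)
  }
  if (!length(complexes))
    return(structure(data.frame(rank = integer(0), score = numeric(0),
                                size = integer(0), seed = character(0),
                                members = character(0)), weights = weights))
  out <- data.frame(
    score = vapply(complexes, `[[`, numeric(1), "score"),
    size = vapply(complexes, `[[`, integer(1), "size"),
    seed = vapply(complexes, `[[`, character(1), "seed"),
    members = vapply(complexes, function(x) paste(x$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$seed), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "weights") <- weights
  out
}
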