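#' Cohesiveness of a vertex set in a weighted graph
#'
#' The cohesiveness of a vertex set C is
#' `f(C) = W_in / (W_in + W_bound + penalty)`, where `W_in` is the total
#' weight of edges with both ends in C, `W_bound` the total weight of edges
#' crossing the boundary of C, and the penalty grows linearly with the set
#' size (`node_penalty` per vertex). It is the fraction of the set's incident
#' edge weight that stays internal, discounted for size, and always lies in
#' `[0, 1]`.
#'
#' @param graph A weighted undirected [igraph::graph()].
#' @param members Character vertex names (or integer indices) of the set.
#' @param node_penalty Penalty per vertex (default 2).
#' @return The cohesiveness, a number in `[0, 1]`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b)
#' igraph::E(g)$weight <- 1
#' cohesiveness(g, c("a", "b"))  # 1 / (1 + 0 + 4) = 0.2
cohesiveness <- function(graph, members, node_penalty = 2) {
  W <- weighted_adjacency(graph)
  idx <- if (is.character(members)) match(members, rownames(W)) else as.integer(members)
  if (anyNA(idx)) stop("unknown vertex in `members`", call. = FALSE)
  cohesiveness_idx(W, idx, node_penalty)
}

weighted_adjacency <- function(graph) {
  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  if (is.null(rownames(W))) {
    nm <- igraph::V(graph)$name %||% as.character(seq_len(nrow(W)))
    dimnames(W) <- list(nm, nm)
  }
  W
}

cohesiveness_idx <- function(W, idx, node_penalty) {
  if (length(idx) == 0L) return(0)
  w_in <- sum(W[idx, idx, drop = FALSE]) / 2
  w_bound <- sum(W[idx, -idx, drop = FALSE])
  denom <- w_in + w_bound + node_penalty * length(idx)
  if (denom == 0) 0 else w_in / denom
}

#' Detect cohesive modules by greedy growth (ClusterONE-style)
#'
#' Greedy, fully deterministic cohesive-module detection on a weighted
#' undirected graph. Seeds are taken in descending weighted-degree order
#' (lexicographic names break ties); each seed not yet covered by a grown
#' cluster starts as a singleton and repeatedly applies the single
#' add-or-remove move that most increases the cohesiveness `f(C)` (see
#' [cohesiveness()]) until no move improves it. Grown clusters whose overlap
#' score `|C1 n C2|^2 / (|C1| |C2|)` exceeds `overlap_threshold` are merged
#' (to a fixed point), clusters whose internal weight density falls below
#' `density_threshold` are discarded, and each surviving cluster's
#' cohesiveness is recomputed from the graph.
#'
#' @param graph A weighted undirected [igraph::graph()]; an absent `weight`
#'   attribute means unit weights.
#' @param node_penalty Cohesiveness penalty per vertex (default 2).
#' @param density_threshold Minimum internal weight density
#'   `2 W_in / (|C| (|C| - 1))`; default 0 keeps everything.
#' @param overlap_threshold Merge threshold on the overlap score (default 0.8).
#' @return A tibble of class `"cluster_set"` with columns `cluster`,
#'   `members` (list of vertex names), `size`, `cohesiveness`, `density`.
#' @export
cluster_one <- function(graph, node_penalty = 2, density_threshold = 0,
                        overlap_threshold = 0.8) {
  stopifnot(node_penalty > 0)
  if (igraph::vcount(graph) == 0L) {
    return(empty_cluster_set())
  }
  if (is.null(igraph::E(graph)$weight)) igraph::E(graph)$weight <- 1
  W <- weighted_adjacency(graph)
  n <- nrow(W)
  nm <- rownames(W)
  wdeg <- rowSums(W)
  seed_order <- order(-wdeg, nm)

  covered <- rep(FALSE, n)
  clusters <- list()
  for (seed in seed_order) {
    if (covered[seed]) next
    C <- grow_cluster(W, seed, node_penalty)
    covered[C] <- TRUE
    clusters[[length(clusters) + 1L]] <- sort(C)
  }
  clusters <- unique(clusters)
  clusters <- merge_overlapping(clusters, overlap_threshold)

  rows <- purrr::map(clusters, function(idx) {
    size <- length(idx)
    w_in <- sum(W[idx, idx, drop = FALSE]) / 2
    dens <- if (size > 1L) 2 * w_in / (size * (size - 1L)) else 0
    tibble::tibble(members = list(nm[idx]), size = size,
                   cohesiveness = cohesiveness_idx(W, idx, node_penalty),
                   density = dens)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$density >= density_threshold, ]
  out <- out[order(-out$cohesiveness, purrr::map_chr(out$members, 1L)), ]
  out <- dplyr::mutate(out, cluster = dplyr::row_number(), .before = 1L)
  class(out) <- c("cluster_set", class(out))
  out
}

empty_cluster_set <- function() {
  out <- tibble::tibble(cluster = integer(), members = list(),
                        size = integer(), cohesiveness = double(),
                        density = double())
  class(out) <- c("cluster_set", class(out))
  out
}

# best-improvement greedy growth from one seed vertex; deterministic
# (strict improvement beyond 1e-12, smallest vertex index breaks ties)
grow_cluster <- function(W, seed, node_penalty) {
  C <- seed
  f_cur <- cohesiveness_idx(W, C, node_penalty)
  repeat {
    neighbours <- which(colSums(W[C, , drop = FALSE]) > 0)
    add_cand <- setdiff(neighbours, C)
    rem_cand <- if (length(C) > 1L) C else integer()
    best_f <- f_cur
    best_set <- NULL
    for (v in add_cand) {
      f_new <- cohesiveness_idx(W, c(C, v), node_penalty)
      if (f_new > best_f + 1e-12) { best_f <- f_new; best_set <- c(C, v) }
    }
    for (v in rem_cand) {
      f_new <- cohesiveness_idx(W, setdiff(C, v), node_penalty)
      if (f_new > best_f + 1e-12) { best_f <- f_new; best_set <- setdiff(C, v) }
    }
    if (is.null(best_set)) break
    C <- best_set
    f_cur <- best_f
  }
  C
}

merge_overlapping <- function(clusters, overlap_threshold) {
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]; b <- clusters[[j]]
        ov <- length(intersect(a, b))^2 / (length(a) * length(b))
        if (ov > overlap_threshold) {
          clusters[[i]] <- sort(union(a, b))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(clusters)
  }
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cohesive modules (sizes %s)\n", nrow(x),
              paste(sort(x$size, decreasing = TRUE), collapse = ", ")))
  NextMethod()
}
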