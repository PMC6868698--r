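#' Sigmoid interaction-profile kernel
#'
#' Similarity between two entities computed from their binary interaction
#' profiles in the association matrix: `tanh(scale * <u, v> + offset)`.
#' Drug profiles are the matrix columns (length = number of diseases),
#' disease profiles the rows (length = number of drugs). The default scale is
#' the reciprocal of the profile length and the default offset is 0, so with
#' binary profiles every entry lies in `[0, tanh(1)]`.
#'
#' @param A An [association_matrix()].
#' @param axis `"drugs"` or `"diseases"`: which entity set to compare.
#' @param scale Positive kernel scale; default `1 / profile length`.
#' @param offset Additive kernel offset; default 0.
#' @return A [similarity_matrix()] over the chosen entity set.
#' @export
#' @examples
#' A <- association_matrix(matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 4, 2,
#'                                dimnames = list(paste0("e", 1:4), c("r1", "r2"))))
#' sigmoid_kernel(A, "drugs")[1, 2]  # tanh(2/4)
sigmoid_kernel <- function(A, axis = c("drugs", "diseases"),
                           scale = NULL, offset = 0) {
  axis <- match.arg(axis)
  profiles <- if (axis == "drugs") t(unclass(A)) else unclass(A)
  if (ncol(profiles) == 0L || nrow(profiles) == 0L) {
    stop("association matrix has a zero-length axis", call. = FALSE)
  }
  scale <- scale %||% (1 / ncol(profiles))
  stopifnot(scale > 0)
  K <- tanh(scale * tcrossprod(profiles) + offset)
  K <- (K + t(K)) / 2  # tcrossprod is symmetric up to fp noise; make it exact
  similarity_matrix(K, entity_ids = rownames(profiles))
}

#' Logistic rescaling of a similarity matrix
#'
#' Applies `L(x) = 1 / (1 + exp(steepness * x + shift))` element-wise off the
#' diagonal, leaving the diagonal at its input value. With the default
#' negative steepness the map is monotone increasing: small similarities are
#' pushed towards 0 (weakly informative pairs are silenced) while large ones
#' are pushed towards 1. Defaults `steepness = -15`, `shift = log(9999)`
#' give `L(0) = 1e-4` and `L(1) ~ 0.997`.
#'
#' @param S A [similarity_matrix()].
#' @param steepness Slope multiplier (negative for an increasing map).
#' @param shift Additive term inside the exponential.
#' @return A rescaled [similarity_matrix()].
#' @export
logistic_adjust <- function(S, steepness = -15, shift = log(9999)) {
  assert_scalar_number(steepness, "steepness")
  assert_scalar_number(shift, "shift")
  stopifnot(inherits(S, "sim_matrix"))
  out <- 1 / (1 + exp(steepness * unclass(S) + shift))
  diag(out) <- diag(unclass(S))
  similarity_matrix(out, entity_ids = rownames(S))
}

#' Build the weighted co-association graph for one entity set
#'
#' Vertices are drugs (or diseases); two vertices are connected when they
#' share at least one partner in the association matrix, and the edge weight
#' is the number of shared partners. For drugs this is the off-diagonal of
#' `t(A) %*% A`; for diseases, of `A %*% t(A)`.
#'
#' @inheritParams sigmoid_kernel
#' @return An [igraph::graph()] with vertex names and a `weight` edge
#'   attribute.
#' @export
build_coassociation_graph <- function(A, axis = c("drugs", "diseases")) {
  axis <- match.arg(axis)
  profiles <- if (axis == "drugs") t(unclass(A)) else unclass(A)
  W <- tcrossprod(profiles)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Boost similarities of pairs sharing a cohesive module
#'
#' Pairs that co-occur in at least one detected cluster have their similarity
#' multiplied by `1 + f(C)`, where `f(C)` is the cluster's cohesiveness (the
#' maximum over shared clusters when the clustering overlaps). Any resulting
#' value at or above 1 is replaced by the cap (0.99), so the output stays a
#' valid similarity; applying the cap twice is a no-op.
#'
#' @param S A [similarity_matrix()].
#' @param clusters A [cluster_one()] result over the same entity set.
#' @param cap Replacement for boosted values `>= 1` (default 0.99).
#' @return The enhanced [similarity_matrix()].
#' @export
enhance_similarity <- function(S, clusters, cap = 0.99) {
  stopifnot(inherits(S, "sim_matrix"), inherits(clusters, "cluster_set"))
  ids <- rownames(S)
  out <- unclass(S)
  boost <- matrix(0, nrow(out), ncol(out), dimnames = dimnames(out))
  for (k in seq_len(nrow(clusters))) {
    members <- intersect(clusters$members[[k]], ids)
    if (length(members) < 2L) next
    fc <- clusters$cohesiveness[[k]]
    boost[members, members] <- pmax(boost[members, members], fc)
  }
  diag(boost) <- 0
  out <- out * (1 + boost)
  out[out >= 1] <- cap
  similarity_matrix(out, entity_ids = ids)
}

#' Fuse kernel and side similarity per entity pair
#'
#' For each pair, the sigmoid-kernel similarity is used when both entities
#' have a non-empty interaction profile in the (training-view) association
#' matrix; otherwise the kernel is uninformative (`tanh(0) = 0` against
#' everything) and the side similarity — enhanced structure similarity for
#' drugs, enhanced semantic similarity for diseases — is used instead. The
#' diagonal is fixed at `diag_value` so self-similarity survives the
#' enhancement cap uniformly.
#'
#' @param kernel Sigmoid-kernel [similarity_matrix()].
#' @param side Enhanced structure/semantic [similarity_matrix()] over the
#'   same entities.
#' @param A The [association_matrix()] defining interaction profiles.
#' @param axis `"drugs"` or `"diseases"`.
#' @param diag_value Diagonal convention (default 0.99).
#' @return The fused [similarity_matrix()].
#' @export
fuse_similarity <- function(kernel, side, A, axis = c("drugs", "diseases"),
                            diag_value = 0.99) {
  axis <- match.arg(axis)
  ids <- if (axis == "drugs") colnames(A) else rownames(A)
  if (!identical(rownames(kernel), ids) || !identical(rownames(side), ids)) {
    stop("kernel, side similarity and association matrix must share the same ",
         axis, " identifiers in the same order", call. = FALSE)
  }
  profile_sums <- if (axis == "drugs") colSums(unclass(A)) else rowSums(unclass(A))
  informative <- profile_sums > 0
  use_kernel <- outer(informative, informative, `&`)
  out <- ifelse(use_kernel, unclass(kernel), unclass(side))
  diag(out) <- diag_value
  similarity_matrix(out, entity_ids = ids)
}

#' Compute fused drug and disease similarities from an association matrix
#'
#' Runs the full similarity stage for both entity sets: sigmoid kernels from
#' the association matrix; logistic rescaling of the raw side similarities
#' (chemical structure for drugs, semantic for diseases); cohesive-module
#' detection on the co-association graphs and similarity enhancement; and
#' per-pair fusion of kernel and enhanced side similarity. When
#' cross-validating, pass the training-view matrix so no test information
#' leaks into the similarities.
#'
#' @param A Training-view [association_matrix()].
#' @param drug_side Raw drug structure [similarity_matrix()] (e.g. Tanimoto).
#' @param disease_side Raw disease semantic [similarity_matrix()].
#' @param control A [similarity_control()] list of stage parameters.
#' @return A list with fused `drug` and `disease` similarity matrices plus
#'   the intermediate kernels, enhanced sides and cluster sets.
#' @export
similarity_pipeline <- function(A, drug_side, disease_side,
                                control = similarity_control()) {
  run_axis <- function(axis, side) {
    kern <- sigmoid_kernel(A, axis, scale = control$kernel_scale,
                           offset = control$kernel_offset)
    adj <- logistic_adjust(side, steepness = control$logistic_steepness,
                           shift = control$logistic_shift)
    g <- build_coassociation_graph(A, axis)
    cl <- cluster_one(g, node_penalty = control$node_penalty,
                      density_threshold = control$density_threshold,
                      overlap_threshold = control$overlap_threshold)
    enh <- enhance_similarity(adj, cl, cap = control$cap)
    fused <- fuse_similarity(kern, enh, A, axis, diag_value = control$cap)
    list(kernel = kern, enhanced = enh, clusters = cl, fused = fused)
  }
  drugs <- run_axis("drugs", drug_side)
  diseases <- run_axis("diseases", disease_side)
  list(drug = drugs$fused, disease = diseases$fused,
       drug_kernel = drugs$kernel, disease_kernel = diseases$kernel,
       drug_enhanced = drugs$enhanced, disease_enhanced = diseases$enhanced,
       drug_clusters = drugs$clusters, disease_clusters = diseases$clusters)
}

#' @rdname similarity_pipeline
#' @param kernel_scale,kernel_offset Sigmoid kernel parameters (`NULL` scale
#'   means 1 / profile length).
#' @param logistic_steepness,logistic_shift Logistic rescaling parameters.
#' @param node_penalty,density_threshold,overlap_threshold Cohesive-module
#'   detection parameters (see [cluster_one()]).
#' @param cap Similarity cap after enhancement.
#' @export
similarity_control <- function(kernel_scale = NULL, kernel_offset = 0,
                               logistic_steepness = -15,
                               logistic_shift = log(9999),
                               node_penalty = 2, density_threshold = 0,
                               overlap_threshold = 0.8, cap = 0.99) {
  list(kernel_scale = kernel_scale, kernel_offset = kernel_offset,
       logistic_steepness = logistic_steepness, logistic_shift = logistic_shift,
       node_penalty = node_penalty, density_threshold = density_threshold,
       overlap_threshold = overlap_threshold, cap = cap)
}
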