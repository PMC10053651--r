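#' Threshold schedule for monomer inference
#'
#' Ascending similarity thresholds starting at `min_similarity` and increasing
#' by `step`, strictly below 1 ("nearly 100%").
#'
#' @param min_similarity Minimum similarity threshold (default 0.94).
#' @param step Increment per iteration (default 0.005).
#' @return Numeric vector of thresholds.
#' @export
threshold_schedule <- function(min_similarity = 0.94, step = 0.005) {
  if (min_similarity <= 0 || min_similarity >= 1) {
    stop("'min_similarity' must lie in (0, 1)", call. = FALSE)
  }
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  k <- floor((1 - min_similarity) / step - 1e-9)
  min_similarity + step * (0:k)
}

#' Build the block graph at a similarity threshold
#'
#' Nodes are block representatives; an edge joins two distinct representatives
#' when their similarity strictly exceeds the threshold. Block multiplicity is
#' encoded so that community detection on this graph is equivalent to running
#' it on the expanded per-block graph: a cross edge gets weight
#' `mult_i * mult_j` and each representative with multiplicity `m > 1` a
#' self-loop of weight `choose(m, 2)` (the identical-block pairs, similarity 1,
#' always above any threshold below 1).
#'
#' @param merged A `merged_blocks` object (or a plain similarity matrix, in
#'   which case all multiplicities are 1).
#' @param threshold Similarity threshold in `[0, 1)`.
#' @return An `igraph` undirected graph with edge attribute `weight` and node
#'   attribute `multiplicity`.
#' @export
build_block_graph <- function(merged, threshold) {
  if (threshold < 0 || threshold >= 1) {
    stop("'threshold' must lie in [0, 1)", call. = FALSE)
  }
  if (is.matrix(merged)) {
    S <- merged
    mult <- rep(1L, nrow(S))
  } else {
    S <- merged$similarity
    mult <- merged$multiplicity
  }
  n <- nrow(S)
  idx <- which(upper.tri(S) & S > threshold, arr.ind = TRUE)
  ef <- idx[, 1]
  et <- idx[, 2]
  w <- mult[ef] * mult[et]
  loops <- which(mult > 1L)
  if (length(loops)) {
    ef <- c(ef, loops)
    et <- c(et, loops)
    w <- c(w, mult[loops] * (mult[loops] - 1) / 2)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ef)) {
    g <- igraph::add_edges(g, rbind(ef, et))
    igraph::E(g)$weight <- w
  }
  igraph::V(g)$multiplicity <- mult
  g
}

#' Detect monomers by Louvain community detection
#'
#' Each community of the block graph is one monomer. Monomer IDs are assigned
#' `1..k` by the first occurrence of each community along the array; isolated
#' nodes become singleton monomers.
#'
#' @param graph Graph from [build_block_graph()].
#' @param merged The `merged_blocks` object the graph was built from (used for
#'   first-occurrence ordering); optional when representatives are already in
#'   array order.
#' @param seed Integer seed controlling any randomness in community detection.
#' @return A list of class `monomer_assignment` with `community_of` (monomer
#'   ID per representative), `monomer_count`, and `seed`.
#' @export
detect_monomers <- function(graph, merged = NULL, seed = 1L) {
  set.seed(seed)
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) > 0) {
    cl <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)
    mem <- igraph::membership(cl)
  } else {
    mem <- seq_len(n)
  }
  # first occurrence of each community along the array: representatives are
  # stored in first-occurrence order, so the minimum representative index works
  first_rep <- vapply(split(seq_len(n), mem), min, integer(1))
  ord <- order(first_rep)
  relabel <- integer(length(ord))
  relabel[as.integer(names(first_rep))[ord]] <- seq_along(ord)
  community_of <- relabel[as.integer(mem)]
  structure(list(community_of = community_of,
                 monomer_count = max(community_of),
                 seed = seed),
            class = "monomer_assignment")
}

#' Rewrite the block list as a monomer-ID sequence
#'
#' @param merged A `merged_blocks` object.
#' @param assignment A `monomer_assignment` from [detect_monomers()].
#' @return Integer vector of monomer IDs, one per original block.
#' @export
to_monomer_sequence <- function(merged, assignment) {
  if (length(assignment$community_of) != nrow(merged$representatives)) {
    stop("assignment does not cover the representatives", call. = FALSE)
  }
  assignment$community_of[merged$member_map]
}

#' Sweep monomer inference over a threshold schedule
#'
#' @param merged A `merged_blocks` object.
#' @param min_similarity,step Threshold schedule parameters (defaults 0.94 and
#'   0.005); alternatively pass an explicit `thresholds` vector.
#' @param thresholds Optional explicit thresholds (overrides the schedule).
#' @param seed Integer seed; each threshold uses a sub-seed derived from it.
#' @return List with one element per threshold, each holding `threshold`,
#'   `assignment` and `monomer_sequence`.
#' @export
sweep_thresholds <- function(merged, min_similarity = 0.94, step = 0.005,
                             thresholds = NULL, seed = 1L) {
  if (is.null(thresholds)) {
    thresholds <- threshold_schedule(min_similarity, step)
  }
  lapply(seq_along(thresholds), function(d) {
    t <- thresholds[d]
    g <- build_block_graph(merged, t)
    asg <- detect_monomers(g, merged, seed = (seed %% 10000019L) + d)
    list(threshold = t,
         assignment = asg,
         monomer_sequence = to_monomer_sequence(merged, asg))
  })
}
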