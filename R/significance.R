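# Permutation significance of condition-specific modules: every layer is
# randomized by degree-preserving double-edge swaps, the full GA is re-run on
# each randomized multiplex, and the specificity scores of the resulting
# modules form the null distribution against which observed modules are
# tested (empirical p-values, Benjamini-Hochberg correction).

#' Degree-preserving edge shuffle of one layer
#'
#' Performs `n_swaps` successful double-edge swaps (a-b, c-d -> a-d, c-b),
#' rejecting any swap that would create a self-loop or a multi-edge. The
#' degree sequence is preserved exactly. On weighted layers each edge carries
#' its weight along, so the weight multiset and every node's degree are both
#' preserved (node strengths may change).
#'
#' @param layer symmetric adjacency/weight matrix with >= 2 edges.
#' @param n_swaps number of successful swaps; default 10x the edge count, a
#'   standard mixing heuristic for reaching an effectively random graph with
#'   the same degrees.
#' @return shuffled matrix. Uses the current R generator.
#' @export
degree_preserving_shuffle <- function(layer, n_swaps = NULL) {
  n <- nrow(layer)
  ut <- which(upper.tri(layer) & layer > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2L) stop("need at least 2 edges to shuffle")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (n_swaps == 0L) return(layer)
  ei <- ut[, 1]; ej <- ut[, 2]
  ew <- layer[ut]
  adj <- layer > 0
  done <- 0L
  tries <- 0L
  max_tries <- max(100L * n_swaps, 1000L)
  while (done < n_swaps && tries < max_tries) {
    tries <- tries + 1L
    e <- sample.int(m, 2L)
    a <- ei[e[1]]; b <- ej[e[1]]
    c <- ei[e[2]]; d <- ej[e[2]]
    if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    # propose a-d and c-b
    if (a == d || c == b) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    ei[e[1]] <- min(a, d); ej[e[1]] <- max(a, d)
    ei[e[2]] <- min(c, b); ej[e[2]] <- max(c, b)
    done <- done + 1L
  }
  if (done < n_swaps)
    warning(sprintf("only %d of %d swaps succeeded within the attempt budget",
                    done, n_swaps))
  W <- matrix(0, n, n)
  W[cbind(ei, ej)] <- ew
  W[cbind(ej, ei)] <- ew
  dimnames(W) <- dimnames(layer)
  W
}

#' Shuffle every layer of a multiplex
#'
#' @param multiplex a [multiplex_network()].
#' @param n_swaps per-layer swap count; default 10x that layer's edge count.
#' @return a new [multiplex_network()] with all layers randomized.
#' @export
shuffle_multiplex <- function(multiplex, n_swaps = NULL) {
  layers <- lapply(multiplex$layers, degree_preserving_shuffle,
                   n_swaps = n_swaps)
  multiplex_network(layers, multiplex$node_ids, multiplex$layer_names)
}

#' Condition-specificity score of a module
#'
#' The module's density in the target layer minus its mean density in the
#' other layers: d_m(C) - mean_\{i != m\} d_i(C). Higher means more specific
#' to the target condition. (The permutation framework needs a per-module
#' score; this density-difference score is this package's construction.)
#'
#' @param nodes module node set (ids or indices), at least 2 nodes.
#' @param multiplex a [multiplex_network()].
#' @param m target layer index.
#' @return scalar score.
#' @export
specificity_score <- function(nodes, multiplex, m) {
  idx <- resolve_nodes(nodes, multiplex)
  if (length(idx) < 2L) stop("specificity score needs a module of >= 2 nodes")
  M <- n_layers(multiplex)
  d <- vapply(seq_len(M), function(i) module_density(idx, multiplex, i),
              numeric(1))
  if (M == 1L) return(d[1])
  d[m] - mean(d[-m])
}

#' Empirical p-value against a null score distribution
#'
#' p = (1 + #\{null >= observed\}) / (1 + |null|); the add-one correction
#' keeps p in (0, 1\] with finitely many permutations.
#'
#' @param observed scalar observed score.
#' @param null numeric vector of null scores.
#' @return scalar p-value.
#' @export
empirical_pvalue <- function(observed, null) {
  null <- as.numeric(null)
  if (length(null) == 0L) stop("empty null distribution")
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in the original order.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Null distribution of specificity scores
#'
#' Shuffles every layer (degree-preserving), re-runs the full GA on each
#' randomized multiplex, and pools the specificity scores of all resulting
#' modules with >= 2 nodes.
#'
#' @param multiplex a [multiplex_network()].
#' @param m target layer index.
#' @param n_randomizations number of randomized multiplexes (default 100).
#' @param params a [ga_params()] for the GA runs on randomized data.
#' @param n_swaps per-layer swap count passed to the shuffler.
#' @return numeric vector of null scores.
#' @export
null_specificity_scores <- function(multiplex, m, n_randomizations = 100L,
                                    params = ga_params(), n_swaps = NULL) {
  scores <- vector("list", n_randomizations)
  for (r in seq_len(n_randomizations)) {
    shuffled <- shuffle_multiplex(multiplex, n_swaps = n_swaps)
    pr <- params
    pr$seed <- NULL  # flows from the ambient generator
    res <- run_moga_csm(shuffled, m, pr)
    mods <- res$partition$module_sets
    mods <- mods[lengths(mods) >= 2L]
    scores[[r]] <- vapply(mods, specificity_score, numeric(1),
                          multiplex = shuffled, m = m)
  }
  unlist(scores)
}

#' Significance test for condition-specific modules
#'
#' Scores every observed module with >= 2 nodes, builds the permutation null
#' with [null_specificity_scores()], computes add-one empirical p-values and
#' Benjamini-Hochberg q-values, and flags modules with q <= alpha.
#'
#' @param partition observed [as_partition()] (e.g. from [run_moga_csm()]).
#' @param multiplex a [multiplex_network()].
#' @param m target layer index.
#' @param n_randomizations randomized multiplexes for the null (default 100).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param params a [ga_params()] for the null GA runs.
#' @param n_swaps per-layer swap count for the shuffler.
#' @return data frame with one row per tested module: `module_id`, `size`,
#'   `score`, `p`, `q`, `significant`; attribute `null_scores` carries the
#'   null distribution.
#' @export
significant_modules <- function(partition, multiplex, m,
                                n_randomizations = 100L, alpha = 0.05,
                                params = ga_params(), n_swaps = NULL) {
  check_partition_on(partition, multiplex)
  keep <- which(lengths(partition$module_sets) >= 2L)
  if (length(keep) == 0L)
    return(data.frame(module_id = integer(0), size = integer(0),
                      score = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  obs <- vapply(partition$module_sets[keep], specificity_score, numeric(1),
                multiplex = multiplex, m = m)
  null <- null_specificity_scores(multiplex, m, n_randomizations, params,
                                  n_swaps)
  p <- vapply(obs, empirical_pvalue, numeric(1), null = null)
  q <- bh_adjust(p)
  out <- data.frame(module_id = keep,
                    size = lengths(partition$module_sets[keep]),
                    score = obs, p = p, q = q,
                    significant = q <= alpha)
  attr(out, "null_scores") <- null
  out
}
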