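# Per-layer quantities reused throughout the GA: node strengths s_i and the
# normalization 2W (twice the total edge weight; each undirected edge counted
# in both orientations).
layer_strengths <- function(W) rowSums(W)

# Q contribution of each module: e_c / 2W - (a_c / 2W)^2, where e_c is the
# within-module weight over ordered pairs and a_c the module's total strength.
# Modularity is the sum of these over modules.
q_contributions_memb <- function(memb, W, strength = rowSums(W),
                                 two_w = sum(strength)) {
  if (two_w <= 0) stop("layer has no edges; modularity undefined")
  grp <- factor(memb, levels = seq_len(max(memb)))
  Wc <- rowsum(W, grp)                      # k x n row sums by module
  within <- rowsum(t(Wc), grp)              # k x k block sums
  a <- rowsum(strength, grp)
  as.numeric(diag(within) / two_w - (a / two_w)^2)
}

q_memb <- function(memb, W, strength = rowSums(W), two_w = sum(strength)) {
  sum(q_contributions_memb(memb, W, strength, two_w))
}

#' Weighted Newman-Girvan modularity of a partition in one layer
#'
#' Q = (1/2W) * sum_ij (w_ij - s_i s_j / 2W) delta(c_i, c_j), with W the
#' layer's total weight and s_i the node strengths (degrees on binary
#' layers). Q lies in \[-0.5, 1). The weighted form is used so binary
#' benchmark layers and weighted co-expression layers go through the same
#' code.
#'
#' @param partition a [as_partition()].
#' @param multiplex a [multiplex_network()].
#' @param layer layer index in 1..M. The layer must contain at least one
#'   edge; Q is undefined on an edgeless layer and an error is raised.
#' @return scalar modularity.
#' @export
modularity_q <- function(partition, multiplex, layer) {
  check_partition_on(partition, multiplex)
  W <- multiplex$layers[[layer]]
  q_memb(partition$assignment, W)
}

# per-module Q contributions for a partition (summary output)
module_q_contributions <- function(partition, multiplex, layer) {
  q_contributions_memb(partition$assignment, multiplex$layers[[layer]])
}

#' Module density in one layer
#'
#' Mean pairwise weight over the unordered node pairs of the module:
#' sum_\{i<j in C\} w_ij / (|C| (|C|-1) / 2). On binary layers this is the
#' usual edge-density fraction in \[0, 1\]. A singleton module has density 0
#' by convention.
#'
#' @param nodes node set: character ids or integer indices.
#' @param multiplex a [multiplex_network()].
#' @param layer layer index.
#' @return scalar density.
#' @export
module_density <- function(nodes, multiplex, layer) {
  idx <- resolve_nodes(nodes, multiplex)
  s <- length(idx)
  if (s < 2L) return(0)
  W <- multiplex$layers[[layer]][idx, idx]
  sum(W) / (s * (s - 1))  # sum over ordered pairs / ordered-pair count
}

#' The M-dimensional objective vector of a partition
#'
#' For target condition m the objectives, all maximized, are
#' F_m = Q_m (modularity in the target layer) and F_i = 1 - Q_i for i != m:
#' a good condition-specific partition is modular in the target layer and as
#' non-modular as possible everywhere else.
#'
#' @param partition a [as_partition()].
#' @param multiplex a [multiplex_network()].
#' @param m target layer index.
#' @return numeric vector of length M with attribute `target_layer`, class
#'   `objective_vector`.
#' @export
objective_vector <- function(partition, multiplex, m) {
  check_partition_on(partition, multiplex)
  M <- n_layers(multiplex)
  if (m < 1L || m > M) stop("target layer out of range")
  q <- vapply(seq_len(M), function(i)
    q_memb(partition$assignment, multiplex$layers[[i]]), numeric(1))
  f <- ifelse(seq_len(M) == m, q, 1 - q)
  structure(f, target_layer = as.integer(m), class = "objective_vector")
}

#' Pareto dominance between two objective vectors (maximization)
#'
#' `a` dominates `b` iff a_i >= b_i for every objective and a_i > b_i for at
#' least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("objective vectors differ in length")
  all(a >= b) && any(a > b)
}
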