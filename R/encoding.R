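# Locus-based adjacency encoding: an individual is P = (g_1, ..., g_n) where
# g_i is one neighbor of node i in the target layer (or i itself when i is
# isolated there). The decoded partition is the set of connected components
# of the undirected edge set {(i, g_i)}.

#' Construct a genotype
#'
#' @param loci integer vector; loci\[i\] is a neighbor of node i in the target
#'   layer (itself if isolated).
#' @param target_layer the condition index whose adjacency defines
#'   feasibility.
#' @return object of class `csm_genotype`.
#' @export
genotype <- function(loci, target_layer) {
  structure(list(loci = as.integer(loci),
                 target_layer = as.integer(target_layer)),
            class = "csm_genotype")
}

#' @export
print.csm_genotype <- function(x, ...) {
  cat(sprintf("genotype over %d nodes (target layer %d)\n",
              length(x$loci), x$target_layer))
  invisible(x)
}

# adjacency lists of one layer; isolated nodes get integer(0)
neighbor_list <- function(multiplex, m) {
  W <- multiplex$layers[[m]]
  lapply(seq_len(nrow(W)), function(i) which(W[i, ] > 0))
}

#' Draw a random feasible genotype
#'
#' Each locus g_i is drawn uniformly from the neighbors of node i in the
#' target layer; a node isolated in that layer gets the self-locus g_i = i
#' and therefore decodes to a singleton module.
#'
#' @param multiplex a [multiplex_network()].
#' @param m target layer index.
#' @return a [genotype()]. Uses the current R random number generator.
#' @export
random_genotype <- function(multiplex, m) {
  nb <- neighbor_list(multiplex, m)
  loci <- vapply(seq_along(nb), function(i) {
    cand <- nb[[i]]
    if (length(cand) == 0L) i
    else cand[sample.int(length(cand), 1L)]
  }, integer(1))
  genotype(loci, m)
}

#' Check the genotype feasibility invariant
#'
#' Every locus must be a neighbor of its node in the target layer, except
#' isolated nodes which carry the self-locus.
#'
#' @param g a [genotype()].
#' @param multiplex a [multiplex_network()].
#' @return TRUE invisibly, or an error.
#' @export
validate_genotype <- function(g, multiplex) {
  loci <- g$loci
  n <- n_nodes(multiplex)
  if (length(loci) != n) stop("genotype length does not match vertex set")
  W <- multiplex$layers[[g$target_layer]]
  deg <- rowSums(W > 0)
  ok <- ifelse(deg == 0, loci == seq_len(n),
               W[cbind(seq_len(n), loci)] > 0)
  if (!all(ok))
    stop("infeasible loci at nodes: ",
         paste(which(!ok), collapse = ", "))
  invisible(TRUE)
}

#' Decode a genotype into a partition
#'
#' Modules are the connected components of the undirected graph whose edges
#' are \{(i, g_i) : i in V\}, found with a disjoint-set forest (union by rank
#' with path compression). Module labels are 1..k in order of the smallest
#' node index each module contains, so decoding is deterministic and
#' label-stable.
#'
#' @param g a [genotype()].
#' @param node_ids optional node identifiers to attach to the partition.
#' @return a [as_partition()].
#' @export
decode <- function(g, node_ids = NULL) {
  memb <- decode_membership(g$loci)
  as_partition(memb, node_ids = node_ids)
}
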