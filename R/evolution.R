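#' Genetic-algorithm parameters
#'
#' Defaults follow the published study conditions: crossover rate 0.8,
#' mutation rate 0.2, elite reproduction 10% of the population, 500
#' generations. The population size is not stated there; 100 is standard
#' NSGA-II practice and is the default here.
#'
#' @param population_size individuals per generation (>= 4).
#' @param generations number of generational cycles (0 returns the best
#'   random individual).
#' @param crossover_rate probability a child is produced by uniform
#'   crossover rather than copied from its first parent.
#' @param mutation_rate probability an offspring undergoes a point mutation
#'   (one locus resampled from its node's neighbors).
#' @param elite_fraction fraction of reproduction slots filled by unmodified
#'   copies of the current best individuals.
#' @param seed optional integer seed; when given, [run_moga_csm()] seeds the
#'   R generator so runs are exactly reproducible.
#' @return a list of class `ga_params`.
#' @export
ga_params <- function(population_size = 100L, generations = 500L,
                      crossover_rate = 0.8, mutation_rate = 0.2,
                      elite_fraction = 0.10, seed = NULL) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  if (population_size < 4L) stop("population_size must be >= 4")
  if (generations < 0L) stop("generations must be >= 0")
  for (r in c(crossover_rate, mutation_rate, elite_fraction))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (elite_fraction > 0 && floor(elite_fraction * population_size) < 1L)
    stop("elite_fraction * population_size must be >= 1 when elitism is enabled")
  structure(list(population_size = population_size,
                 generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_fraction = elite_fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ga_params")
}

#' Uniform crossover of two genotypes
#'
#' A random binary mask picks each child locus from one of the two parents,
#' so every child locus is feasible whenever the parents are.
#'
#' @param p1,p2 [genotype()]s on the same multiplex and target layer.
#' @return a child [genotype()].
#' @export
crossover <- function(p1, p2) {
  if (p1$target_layer != p2$target_layer)
    stop("parents target different layers")
  if (length(p1$loci) != length(p2$loci))
    stop("parents have different lengths")
  mask <- runif(length(p1$loci)) < 0.5
  loci <- ifelse(mask, p2$loci, p1$loci)
  genotype(loci, p1$target_layer)
}

#' Neighbor mutation of a genotype
#'
#' With probability `mutation_rate` the genotype is mutated: one uniformly
#' chosen node has its locus resampled uniformly from that node's neighbors
#' in the target layer, so the result is always feasible. A node with a
#' single neighbor is unchanged when selected (the resample is forced);
#' isolated nodes keep the self-locus. This point mutation keeps offspring
#' close to their parents, which is what lets the search refine a partition
#' instead of scrambling it.
#'
#' @param g a [genotype()].
#' @param mutation_rate probability that the genotype is mutated at all.
#' @param multiplex a [multiplex_network()].
#' @return the (possibly) mutated [genotype()].
#' @export
mutate_genotype <- function(g, mutation_rate, multiplex) {
  if (runif(1) >= mutation_rate) return(g)
  nb <- neighbor_list(multiplex, g$target_layer)
  loci <- g$loci
  i <- sample.int(length(loci), 1L)
  cand <- nb[[i]]
  if (length(cand) > 0L)
    loci[i] <- cand[sample.int(length(cand), 1L)]
  genotype(loci, g$target_layer)
}

#' Fast nondominated sorting (iterative front peeling)
#'
#' Rank 0 is the set of nondominated (Pareto-optimal) vectors; rank r the
#' nondominated set once ranks < r are removed. All objectives maximized.
#'
#' @param objs list of equal-length numeric objective vectors, or a matrix
#'   with one row per member.
#' @return integer vector of nondomination ranks, 0-based.
#' @export
nondominated_sort <- function(objs) {
  F <- if (is.matrix(objs)) objs else do.call(rbind, lapply(objs, as.numeric))
  if (is.null(F) || nrow(F) == 0L) stop("empty population")
  p <- nrow(F)
  ge <- matrix(TRUE, p, p)
  gt <- matrix(FALSE, p, p)
  for (k in seq_len(ncol(F))) {
    ge <- ge & outer(F[, k], F[, k], `>=`)
    gt <- gt | outer(F[, k], F[, k], `>`)
  }
  dom <- ge & gt  # dom[i, j]: i dominates j
  ranks <- integer(p)
  remaining <- rep(TRUE, p)
  r <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    nd <- idx[colSums(dom[idx, idx, drop = FALSE]) == 0L]
    ranks[nd] <- r
    remaining[nd] <- FALSE
    r <- r + 1L
  }
  ranks
}

#' NSGA-II crowding distance within one nondominated front
#'
#' Per objective, boundary members get +Inf and interior members accumulate
#' the normalized gap between their two neighbors in that objective's
#' ordering; an objective with zero range contributes nothing. Fronts of one
#' or two members are all +Inf.
#'
#' @param front list of objective vectors, or a matrix with one row each.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(front) {
  F <- if (is.matrix(front)) front
       else do.call(rbind, lapply(front, as.numeric))
  p <- nrow(F)
  if (p <= 2L) return(rep(Inf, p))
  d <- numeric(p)
  for (k in seq_len(ncol(F))) {
    o <- order(F[, k])
    rng <- F[o[p], k] - F[o[1], k]
    if (rng <= 0) next
    d[o[1]] <- Inf
    d[o[p]] <- Inf
    mid <- o[2:(p - 1)]
    d[mid] <- d[mid] + (F[o[3:p], k] - F[o[1:(p - 2)], k]) / rng
  }
  d
}

# (rank asc, crowding desc) ordering used for elites and tournaments
rc_order <- function(rank, crowd) order(rank, -crowd)

# binary tournament winners: length-`k` vector of indices into the population
tournament <- function(rank, crowd, k) {
  n <- length(rank)
  i <- sample.int(n, k, replace = TRUE)
  j <- sample.int(n, k, replace = TRUE)
  iwins <- rank[i] < rank[j] | (rank[i] == rank[j] & crowd[i] >= crowd[j])
  ifelse(iwins, i, j)
}

# sparse per-layer edge lists + strength matrix, precomputed once per run so
# each population evaluation costs O(edges + n) per layer in C++
layer_eval_data <- function(multiplex) {
  layers <- multiplex$layers
  M <- length(layers)
  n <- nrow(layers[[1]])
  ei <- ej <- ew <- vector("list", M)
  strength <- matrix(0, n, M)
  two_w <- numeric(M)
  for (l in seq_len(M)) {
    W <- layers[[l]]
    ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    ei[[l]] <- as.integer(ut[, 1])
    ej[[l]] <- as.integer(ut[, 2])
    ew[[l]] <- W[ut]
    strength[, l] <- rowSums(W)
    two_w[l] <- sum(strength[, l])
  }
  list(ei = ei, ej = ej, ew = ew, strength = strength, two_w = two_w)
}

# evaluate rows of a loci matrix: objective matrix (rows x M) and module counts
evaluate_pop <- function(P, ed, m) {
  evaluate_population(P, ed$ei, ed$ej, ed$ew, ed$strength, ed$two_w,
                      as.integer(m))
}

# NSGA-II environmental selection: indices of the `n_keep` members kept from
# the pool, filling whole fronts and truncating the last by crowding.
environmental_selection <- function(F, n_keep) {
  ranks <- nondominated_sort(F)
  crowd <- numeric(nrow(F))
  for (r in unique(ranks)) {
    idx <- which(ranks == r)
    crowd[idx] <- crowding_distance(F[idx, , drop = FALSE])
  }
  keep <- rc_order(ranks, crowd)[seq_len(n_keep)]
  list(keep = keep, ranks = ranks, crowd = crowd)
}

#' Run the multi-objective GA for condition-specific modules
#'
#' Implements the full evolutionary loop: a population of random feasible
#' genotypes on the target layer is evolved by binary-tournament parent
#' selection on (nondomination rank, crowding distance), uniform crossover,
#' neighbor mutation, and elitist mu+lambda replacement — parents and
#' offspring are pooled, nondominated-sorted, and truncated back to the
#' population size, while `elite_fraction` of each generation's reproduction
#' slots are unmodified copies of the current best individuals. After the
#' final generation the rank-0 (Pareto) front is extracted and the member
#' with maximum modularity in the target layer is returned as the solution.
#'
#' @param multiplex a [multiplex_network()]; the target layer must contain at
#'   least one edge.
#' @param m target layer index.
#' @param params a [ga_params()].
#' @return list of class `moga_result`: `partition` and `objective` of the
#'   selected solution, `pareto_front` (list with `genotype`, `objective`,
#'   `n_modules` per front member), `best_trace` (best target-layer Q per
#'   generation), `params`, `target_layer`.
#' @export
run_moga_csm <- function(multiplex, m, params = ga_params()) {
  M <- n_layers(multiplex)
  if (m < 1L || m > M) stop("target layer out of range")
  ed <- layer_eval_data(multiplex)
  if (ed$two_w[m] <= 0) stop("target layer has no edges")
  if (any(ed$two_w <= 0))
    stop("every layer needs at least one edge (modularity undefined)")
  if (!is.null(params$seed)) set.seed(params$seed)

  n <- n_nodes(multiplex)
  N <- params$population_size
  nb <- neighbor_list(multiplex, m)
  nb_len <- lengths(nb)

  # initial population, one row per individual
  P <- matrix(0L, N, n)
  for (i in seq_len(n)) {
    P[, i] <- if (nb_len[i] == 0L) i
              else nb[[i]][sample.int(nb_len[i], N, replace = TRUE)]
  }
  ev <- evaluate_pop(P, ed, m)
  F <- ev$F; kmod <- ev$kmod
  sel <- environmental_selection(F, N)
  ranks <- sel$ranks; crowd <- sel$crowd

  n_elite <- if (params$elite_fraction > 0)
    max(1L, as.integer(floor(params$elite_fraction * N))) else 0L
  best_trace <- numeric(params$generations)

  for (gen in seq_len(params$generations)) {
    # elite copies fill the first reproduction slots, unmodified
    elite_idx <- if (n_elite > 0L) rc_order(ranks, crowd)[seq_len(n_elite)]
                 else integer(0)
    n_child <- N - n_elite
    pa <- tournament(ranks, crowd, n_child)
    pb <- tournament(ranks, crowd, n_child)
    C <- P[pa, , drop = FALSE]
    do_cx <- runif(n_child) < params$crossover_rate
    if (any(do_cx)) {
      mask <- matrix(runif(sum(do_cx) * n) < 0.5, ncol = n)
      B <- P[pb[do_cx], , drop = FALSE]
      Csub <- C[do_cx, , drop = FALSE]
      Csub[mask] <- B[mask]
      C[do_cx, ] <- Csub
    }
    # point mutation: with prob mutation_rate a child has one random locus
    # resampled from its node's neighbors
    hit <- which(runif(n_child) < params$mutation_rate)
    for (r in hit) {
      i <- sample.int(n, 1L)
      if (nb_len[i] > 0L)
        C[r, i] <- nb[[i]][sample.int(nb_len[i], 1L)]
    }
    evc <- evaluate_pop(C, ed, m)
    pool_P <- rbind(P, P[elite_idx, , drop = FALSE], C)
    pool_F <- rbind(F, F[elite_idx, , drop = FALSE], evc$F)
    pool_k <- c(kmod, kmod[elite_idx], evc$kmod)
    sel <- environmental_selection(pool_F, N)
    keep <- sel$keep
    P <- pool_P[keep, , drop = FALSE]
    F <- pool_F[keep, , drop = FALSE]
    kmod <- pool_k[keep]
    ranks <- sel$ranks[keep]
    crowd <- sel$crowd[keep]
    best_trace[gen] <- max(F[, m])
  }

  front_idx <- which(ranks == min(ranks))
  front <- lapply(front_idx, function(r) list(
    genotype = genotype(P[r, ], m),
    objective = structure(F[r, ], target_layer = m,
                          class = "objective_vector"),
    n_modules = kmod[r]))
  chosen <- select_final(front, m)
  structure(list(partition = decode(chosen$genotype, multiplex$node_ids),
                 objective = chosen$objective,
                 pareto_front = front,
                 best_trace = best_trace,
                 params = params,
                 target_layer = as.integer(m)),
            class = "moga_result")
}

#' Pick the final solution from a Pareto front
#'
#' The returned member maximizes the target-layer objective F_m
#' (equivalently the target-layer modularity); ties are broken by fewer
#' modules, then by lowest member index.
#'
#' @param front nonempty list of members, each a list with `genotype`,
#'   `objective` and optionally `n_modules`.
#' @param m target layer index.
#' @return the selected front member.
#' @export
select_final <- function(front, m) {
  if (length(front) == 0L) stop("empty Pareto front")
  fm <- vapply(front, function(x) as.numeric(x$objective)[m], numeric(1))
  nmod <- vapply(front, function(x) {
    if (!is.null(x$n_modules)) x$n_modules
    else max(decode_membership(x$genotype$loci))
  }, numeric(1))
  ord <- order(-fm, nmod, seq_along(front))
  front[[ord[1]]]
}

#' @export
print.moga_result <- function(x, ...) {
  f <- as.numeric(x$objective)
  cat(sprintf(
    "MOGA-CSM result: target layer %d, Q_target = %.4f, %d module(s), Pareto front of %d\n",
    x$target_layer, f[x$target_layer], x$partition$k, length(x$pareto_front)))
  invisible(x)
}
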