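# Planted-partition benchmark: the classic 128-node / 4-equal-community
# graphs with average degree 16 and a tunable expected inter-community degree
# kout, paired with size-matched Erdos-Renyi companion layers carrying no
# planted structure. kout is the difficulty knob: detection gets harder as it
# grows from 1 to 8.

#' Benchmark specification
#'
#' @param n node count (divisible by `k`).
#' @param k number of equal-size planted communities.
#' @param avg_degree expected total degree per node.
#' @param kout expected number of edges per node leaving its community.
#' @param n_random_layers number of random companion layers (>= 1).
#' @param seed optional integer seed for [make_benchmark_multiplex()].
#' @return list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n = 128L, k = 4L, avg_degree = 16,
                           kout = 1, n_random_layers = 1L, seed = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (n %% k != 0L) stop("n must be divisible by k")
  if (kout < 0 || kout > avg_degree)
    stop("kout must lie in [0, avg_degree]")
  if (n_random_layers < 1L) stop("need at least one random companion layer")
  structure(list(n = n, k = k, avg_degree = avg_degree, kout = kout,
                 n_random_layers = as.integer(n_random_layers),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate one planted-partition graph
#'
#' Bernoulli edges with within-community probability
#' p_in = (avg_degree - kout) / (n/k - 1) and between-community probability
#' p_out = kout / (n - n/k), so the expected total degree is `avg_degree` and
#' the expected external degree is `kout`.
#'
#' @param spec a [benchmark_spec()].
#' @return list with `layer` (binary adjacency matrix) and `planted` (the
#'   ground-truth [as_partition()]). Uses the current R generator.
#' @export
planted_partition_graph <- function(spec) {
  n <- spec$n; k <- spec$k
  size <- n %/% k
  p_in <- (spec$avg_degree - spec$kout) / (size - 1)
  p_out <- spec$kout / (n - size)
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop(sprintf("edge probabilities outside [0,1]: p_in=%.3f p_out=%.3f",
                 p_in, p_out))
  comm <- rep(seq_len(k), each = size)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  same <- comm[ut[, 1]] == comm[ut[, 2]]
  p <- ifelse(same, p_in, p_out)
  edge <- runif(nrow(ut)) < p
  W[ut[edge, , drop = FALSE]] <- 1
  W <- W + t(W)
  list(layer = W, planted = as_partition(comm))
}

#' Size-matched random companion layer
#'
#' An Erdos-Renyi G(n, m) graph with exactly the same node and edge counts as
#' the input layer and no planted structure; edges carry unit weight.
#'
#' @param layer adjacency matrix of the layer to match.
#' @return adjacency matrix of the companion.
#' @export
random_companion <- function(layer) {
  n <- nrow(layer)
  n_edges <- sum(layer[upper.tri(layer)] > 0)
  W <- matrix(0, n, n)
  if (n_edges > 0) {
    ut <- which(upper.tri(W))
    pick <- sample(ut, n_edges)
    W[pick] <- 1
    W <- W + t(W)
  }
  W
}

#' Assemble the benchmark multiplex
#'
#' Layer 1 is the planted-partition graph (the target condition); layers
#' 2..(1 + n_random_layers) are independent size-matched random companions.
#'
#' @param spec a [benchmark_spec()]; its `seed`, when set, makes the whole
#'   multiplex reproducible.
#' @return list with `multiplex` (a [multiplex_network()]) and `planted`
#'   (ground-truth [as_partition()]).
#' @export
make_benchmark_multiplex <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pg <- planted_partition_graph(spec)
  layers <- c(list(pg$layer),
              replicate(spec$n_random_layers, random_companion(pg$layer),
                        simplify = FALSE))
  ids <- paste0("v", seq_len(spec$n))
  mx <- multiplex_network(layers, ids,
                          c("planted",
                            paste0("random", seq_len(spec$n_random_layers))))
  list(multiplex = mx, planted = as_partition(pg$planted$assignment, ids))
}

#' Normalized mutual information between two partitions
#'
#' 2 I(A; B) / (H(A) + H(B)) computed from the contingency table of the two
#' assignments; 1 iff the partitions are identical up to relabeling, 0 when
#' one partition carries no information (e.g. a single module).
#'
#' @param a,b [as_partition()]s (or plain label vectors) over the same
#'   vertex set.
#' @return scalar in \[0, 1\].
#' @export
nmi <- function(a, b) {
  ma <- if (inherits(a, "csm_partition")) a$assignment else as.integer(factor(a))
  mb <- if (inherits(b, "csm_partition")) b$assignment else as.integer(factor(b))
  if (length(ma) != length(mb)) stop("partitions cover different vertex sets")
  n <- length(ma)
  tab <- table(ma, mb) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}

#' Run the benchmark experiment (modularity vs. noise)
#'
#' Generates `runs` independent benchmark multiplexes at the given `kout`,
#' runs the GA targeting the planted layer in each, and records the selected
#' solution's modularity in the planted layer and its NMI against the ground
#' truth. This is the experiment behind the modularity-vs-kout degradation
#' curve and the layer-count robustness check.
#'
#' @param kout expected inter-community degree.
#' @param n_random_layers random companion layers per multiplex.
#' @param runs number of independent repetitions.
#' @param params a [ga_params()] for each run.
#' @param seed integer seed for the whole experiment (graphs and GA runs).
#' @param n,k,avg_degree benchmark graph parameters.
#' @return data frame with one row per run: `run`, `seed`, `kout`, `layers`,
#'   `Q`, `nmi`, `n_modules`.
#' @export
benchmark_experiment <- function(kout, n_random_layers = 1L, runs = 10L,
                                 params = ga_params(), seed = NULL,
                                 n = 128L, k = 4L, avg_degree = 16) {
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, 2L * runs)
  out <- vector("list", runs)
  for (r in seq_len(runs)) {
    spec <- benchmark_spec(n = n, k = k, avg_degree = avg_degree,
                           kout = kout, n_random_layers = n_random_layers,
                           seed = run_seeds[2L * r - 1L])
    bench <- make_benchmark_multiplex(spec)
    pr <- params
    pr$seed <- run_seeds[2L * r]
    res <- run_moga_csm(bench$multiplex, 1L, pr)
    out[[r]] <- data.frame(run = r, seed = pr$seed, kout = kout,
                           layers = 1L + spec$n_random_layers,
                           Q = as.numeric(res$objective)[1L],
                           nmi = nmi(res$partition, bench$planted),
                           n_modules = res$partition$k)
  }
  do.call(rbind, out)
}
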