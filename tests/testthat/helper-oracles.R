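# Independent oracles and small fixture builders used across the suite.

# breadth-first-search connected components of the undirected edge set
# {(i, loci[i])}; labels canonicalized by smallest contained node index
bfs_components <- function(loci) {
  n <- length(loci)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    j <- loci[i]
    if (j != i) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  memb <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (memb[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    memb[s] <- lab
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj[[v]]) if (memb[w] == 0L) {
        memb[w] <- lab
        queue <- c(queue, w)
      }
    }
  }
  memb
}

# O(n^2) direct-sum modularity
brute_modularity <- function(memb, W) {
  two_w <- sum(W)
  s <- rowSums(W)
  n <- nrow(W)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j]) acc <- acc + W[i, j] - s[i] * s[j] / two_w
  acc / two_w
}

# repeated-peeling nondominated sort built on exported dominates()
brute_nds <- function(vecs) {
  p <- length(vecs)
  ranks <- rep(NA_integer_, p)
  r <- 0L
  while (anyNA(ranks)) {
    left <- which(is.na(ranks))
    nd <- left[vapply(left, function(j)
      !any(vapply(left, function(i)
        i != j && dominates(vecs[[i]], vecs[[j]]), logical(1))),
      logical(1))]
    ranks[nd] <- r
    r <- r + 1L
  }
  ranks
}

# brute-force Benjamini-Hochberg step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# direct contingency-table NMI
brute_nmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  ha <- h(pa); hb <- h(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}

# connected components of a full adjacency matrix (BFS)
graph_components <- function(W) {
  n <- nrow(W)
  memb <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (memb[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    memb[s] <- lab
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      nbr <- which(W[v, ] > 0 & memb == 0L)
      memb[nbr] <- lab
      queue <- c(queue, nbr)
    }
  }
  memb
}

# build a multiplex layer matrix from an edge matrix (i, j, w)
layer_from_edges <- function(n, edges) {
  W <- matrix(0, n, n)
  if (length(edges) > 0) {
    edges <- matrix(edges, ncol = 3, byrow = TRUE)
    W[edges[, 1:2, drop = FALSE]] <- edges[, 3]
    W[edges[, 2:1, drop = FALSE]] <- edges[, 3]
  }
  W
}

# random connected-ish simple graph layer for property tests
random_layer <- function(n, p = 0.2) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < p]
  W[on] <- 1
  W <- W + t(W)
  # ensure no fully isolated graph pathologies for modularity (>= 1 edge)
  if (sum(W) == 0) {
    W[1, 2] <- W[2, 1] <- 1
  }
  W
}

tiny_multiplex <- function(n = 7, M = 2, p = 0.3) {
  multiplex_network(replicate(M, random_layer(n, p), simplify = FALSE),
                    paste0("n", seq_len(n)))
}
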