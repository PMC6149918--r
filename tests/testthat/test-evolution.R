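two_cliques_multiplex <- function(size = 5) {
  n <- 2 * size
  W <- matrix(0, n, n)
  W[1:size, 1:size] <- 1
  W[(size + 1):n, (size + 1):n] <- 1
  diag(W) <- 0
  multiplex_network(list(W), paste0("n", 1:n))
}

test_that("ga_params validates rates and sizes", {
  p <- ga_params()
  expect_equal(p$crossover_rate, 0.8)
  expect_equal(p$mutation_rate, 0.2)
  expect_equal(p$elite_fraction, 0.1)
  expect_equal(p$generations, 500)
  expect_error(ga_params(population_size = 2), "population_size")
  expect_error(ga_params(crossover_rate = 1.2), "rates")
  expect_error(ga_params(population_size = 5, elite_fraction = 0.01),
               "elite_fraction")
})

test_that("uniform crossover mixes loci and preserves feasibility", {
  mx <- tiny_multiplex(12, 1, 0.4)
  set.seed(8)
  p1 <- random_genotype(mx, 1)
  p2 <- random_genotype(mx, 1)
  # identical parents -> identical child for any mask
  same <- crossover(p1, p1)
  expect_identical(same$loci, p1$loci)
  # each child locus comes from one of the parents, child stays feasible
  for (rep in 1:100) {
    ch <- crossover(p1, p2)
    expect_true(all(ch$loci == p1$loci | ch$loci == p2$loci))
    expect_silent(validate_genotype(ch, mx))
  }
  expect_error(crossover(p1, genotype(p2$loci, 2)), "target different layers")
})

test_that("mutation keeps genotypes feasible and respects the rate", {
  mx <- tiny_multiplex(10, 1, 0.4)
  set.seed(9)
  g <- random_genotype(mx, 1)
  # rate 0 -> identity
  expect_identical(mutate_genotype(g, 0, mx)$loci, g$loci)
  # mutated output differs in at most one locus and is always feasible
  for (rep in 1:1000) {
    m <- mutate_genotype(g, 1, mx)
    expect_lte(sum(m$loci != g$loci), 1)
    expect_silent(validate_genotype(m, mx))
  }
  # a node with a single neighbor cannot change even when selected
  W <- layer_from_edges(2, c(1, 2, 1))
  mx2 <- multiplex_network(list(W), c("a", "b"))
  g2 <- genotype(c(2L, 1L), 1)
  for (rep in 1:20)
    expect_identical(mutate_genotype(g2, 1, mx2)$loci, g2$loci)
})

test_that("nondominated sort equals the repeated-peeling oracle", {
  expect_identical(nondominated_sort(list(c(1, 2))), 0L)
  # total order chain
  expect_identical(nondominated_sort(list(c(3, 3), c(2, 2), c(1, 1))),
                   c(0L, 1L, 2L))
  expect_error(nondominated_sort(list()), "empty")
  set.seed(12)
  for (rep in 1:50) {
    vecs <- lapply(1:30, function(i) runif(3))
    expect_identical(nondominated_sort(vecs), brute_nds(vecs))
  }
})

test_that("crowding distance matches the hand-evaluated standard formula", {
  expect_equal(crowding_distance(list(c(1, 2))), Inf)
  expect_equal(crowding_distance(list(c(1, 2), c(2, 1))), c(Inf, Inf))
  # 3 collinear equally spaced points: middle = 1 + 1
  f <- list(c(0, 2), c(1, 1), c(2, 0))
  expect_equal(crowding_distance(f), c(Inf, 2, Inf))
  # permutation equivariance
  set.seed(13)
  F <- cbind(runif(6), runif(6))
  d <- crowding_distance(F)
  perm <- sample(6)
  expect_equal(crowding_distance(F[perm, ]), d[perm])
  # zero-range objective contributes nothing
  expect_equal(crowding_distance(cbind(c(1, 1, 1), c(0, 1, 2))),
               c(Inf, 1, Inf))
})

test_that("select_final maximizes target-layer Q with stated tie-breaks", {
  mk <- function(f, nm) list(genotype = genotype(1:3, 1),
                             objective = f, n_modules = nm)
  front <- list(mk(c(0.3, 1), 2), mk(c(0.7, 1), 3), mk(c(0.5, 1), 2))
  expect_identical(select_final(front, 1), front[[2]])
  expect_identical(select_final(front[1], 1), front[[1]])
  tie <- list(mk(c(0.7, 1), 5), mk(c(0.7, 1), 2), mk(c(0.7, 1), 2))
  expect_identical(select_final(tie, 1), tie[[2]])  # fewer modules, then index
  expect_error(select_final(list(), 1), "empty")
})

test_that("the GA's sparse evaluator matches the reference objective path", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 20
    mk <- function() {
      W <- matrix(0, n, n)
      ut <- which(upper.tri(W))
      on <- ut[runif(length(ut)) < 0.3]
      W[on] <- round(runif(length(on)), 2) + 0.1
      W + t(W)
    }
    mx <- multiplex_network(list(mk(), mk(), mk()), paste0("n", 1:n))
    g <- random_genotype(mx, 2)
    ed <- mogacsm:::layer_eval_data(mx)
    fast <- mogacsm:::evaluate_pop(matrix(g$loci, 1), ed, 2)
    ref <- objective_vector(decode(g), mx, 2)
    expect_equal(fast$F[1, ], as.numeric(ref), tolerance = 1e-12)
    expect_equal(fast$kmod[1], decode(g)$k)
  }
})

test_that("the GA recovers two planted cliques in a single-layer network", {
  mx <- two_cliques_multiplex(5)
  truth <- as_partition(rep(1:2, each = 5))
  res <- run_moga_csm(mx, 1, ga_params(population_size = 40,
                                       generations = 30, seed = 99))
  expect_equal(nmi(res$partition, truth), 1)
  expect_equal(as.numeric(res$objective)[1],
               modularity_q(truth, mx, 1), tolerance = 1e-12)
})

test_that("generations = 0 returns the best random individual", {
  mx <- two_cliques_multiplex(4)
  res <- run_moga_csm(mx, 1, ga_params(population_size = 20,
                                       generations = 0, seed = 5))
  expect_length(res$best_trace, 0)
  expect_s3_class(res$partition, "csm_partition")
  expect_true(is.finite(as.numeric(res$objective)[1]))
})

test_that("a fixed seed makes runs bit-identical", {
  set.seed(1)
  spec <- benchmark_spec(n = 32, k = 4, avg_degree = 6, kout = 1, seed = 77)
  b <- make_benchmark_multiplex(spec)
  p <- ga_params(population_size = 20, generations = 25, seed = 123)
  r1 <- run_moga_csm(b$multiplex, 1, p)
  r2 <- run_moga_csm(b$multiplex, 1, p)
  expect_identical(r1$partition$assignment, r2$partition$assignment)
  expect_identical(as.numeric(r1$objective), as.numeric(r2$objective))
  expect_identical(r1$best_trace, r2$best_trace)
})

test_that("elitism makes the best target-layer Q non-decreasing", {
  set.seed(2)
  spec <- benchmark_spec(n = 64, k = 4, avg_degree = 8, kout = 2, seed = 31)
  b <- make_benchmark_multiplex(spec)
  res <- run_moga_csm(b$multiplex, 1,
                      ga_params(population_size = 30, generations = 60,
                                seed = 7))
  expect_true(all(diff(res$best_trace) >= -1e-12))
  # every front member decodes to a feasible genotype
  for (memb in res$pareto_front)
    expect_silent(validate_genotype(memb$genotype, b$multiplex))
})

test_that("the Pareto front of a run is mutually nondominated", {
  mx <- two_cliques_multiplex(4)
  mx2 <- multiplex_network(list(mx$layers[[1]], random_layer(8, 0.4)),
                           mx$node_ids)
  res <- run_moga_csm(mx2, 1, ga_params(population_size = 24,
                                        generations = 20, seed = 3))
  objs <- lapply(res$pareto_front, function(x) as.numeric(x$objective))
  for (i in seq_along(objs)) for (j in seq_along(objs))
    if (i != j) expect_false(dominates(objs[[i]], objs[[j]]))
})
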