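test_that("edge lists are read symmetrically with layer order preserved", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.txt")
  writeLines(c("a", "b", "c"), nodes)
  f1 <- file.path(dir, "l1.tsv")
  writeLines("a\tb\t1.0", f1)
  f2 <- file.path(dir, "l2.tsv")
  writeLines(c("b\tc\t2.5", "a\tc\t0.5"), f2)
  mx <- read_multiplex(c(f1, f2), nodes)
  expect_s3_class(mx, "multiplex_network")
  expect_identical(mx$node_ids, c("a", "b", "c"))
  expect_equal(n_layers(mx), 2)
  expect_equal(mx$layers[[1]]["a", "b"], 1)
  expect_equal(mx$layers[[1]]["b", "a"], 1)
  expect_equal(mx$layers[[1]]["a", "c"], 0)
  expect_equal(mx$layers[[2]]["c", "b"], 2.5)
  # empty edge file -> valid edgeless layer
  f3 <- file.path(dir, "l3.tsv")
  writeLines(character(0), f3)
  mx3 <- read_multiplex(c(f1, f3), nodes)
  expect_equal(sum(mx3$layers[[2]]), 0)
})

test_that("malformed edge files fail loudly with file and line", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.txt")
  writeLines(c("a", "b", "c"), nodes)
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("a\tb\t1", "a\td\t1"), bad)
  expect_error(read_multiplex(bad, nodes), "line 2.*unknown node id 'd'")
  writeLines("a\tb\t-2", bad)
  expect_error(read_multiplex(bad, nodes), "negative weight")
  writeLines(c("a\tb\t1", "b\ta\t2"), bad)
  expect_error(read_multiplex(bad, nodes), "duplicate edge")
  writeLines("a\ta\t1", bad)
  expect_error(read_multiplex(bad, nodes), "self-loop")
})

test_that("header flag skips one line and line numbers stay correct", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.txt")
  writeLines(c("a", "b"), nodes)
  f <- file.path(dir, "h.tsv")
  writeLines(c("from\tto\tweight", "a\tb\t3"), f)
  mx <- read_multiplex(f, nodes, header = TRUE)
  expect_equal(mx$layers[[1]]["a", "b"], 3)
  writeLines(c("from\tto\tweight", "a\tz\t3"), f)
  expect_error(read_multiplex(f, nodes, header = TRUE), "line 2")
})

test_that("multiplex construction enforces the layer invariants", {
  W <- layer_from_edges(3, c(1, 2, 1))
  expect_error(multiplex_network(list(), c("a", "b", "c")), "nonempty")
  bad <- W; bad[1, 2] <- 5  # asymmetric
  expect_error(multiplex_network(list(bad), c("a", "b", "c")), "symmetric")
  bad <- W; diag(bad) <- 1
  expect_error(multiplex_network(list(bad), c("a", "b", "c")), "diagonal")
  expect_error(multiplex_network(list(-W), c("a", "b", "c")), "negative")
})

test_that("partitions canonicalize labels and expose disjoint covering modules", {
  p <- as_partition(c("x", "y", "x", "z"))
  expect_equal(p$assignment, c(1L, 2L, 1L, 3L))
  expect_equal(p$k, 3)
  expect_equal(sort(unlist(p$module_sets)), 1:4)
  expect_true(all(lengths(p$module_sets) >= 1))
  expect_error(as_partition(integer(0)), "empty")
  expect_error(as_partition(c(1, NA)), "NA")
})

test_that("write_modules emits node and summary tables that round-trip", {
  dir <- withr::local_tempdir()
  W1 <- layer_from_edges(3, c(1, 2, 1))
  W2 <- layer_from_edges(3, c(2, 3, 1))
  mx <- multiplex_network(list(W1, W2), c("a", "b", "c"))
  part <- as_partition(c(1, 1, 2))
  path <- file.path(dir, "modules.tsv")
  summ <- write_modules(part, mx, path)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "modules_summary.tsv")))
  got <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(got), 3)
  expect_equal(nrow(summ), 2)
  expect_equal(summ$size, c(2, 1))
  # density of module {a,b}: 1 in layer 1, 0 in layer 2; singleton 0
  expect_equal(summ$density_layer1, c(1, 0))
  expect_equal(summ$density_layer2[2], 0)
  # round trip reproduces the assignment vector and node order
  back <- read_modules(path)
  expect_identical(back$assignment, part$assignment)
  expect_identical(back$node_ids, mx$node_ids)
  # single all-covering module -> one summary row
  summ1 <- write_modules(as_partition(c(1, 1, 1)), mx,
                         file.path(dir, "one.tsv"))
  expect_equal(nrow(summ1), 1)
  expect_error(suppressWarnings(
    write_modules(part, mx, file.path(dir, "nope", "x.tsv"))),
    "cannot write")
})

test_that("read -> write -> read preserves weights and symmetry on random data", {
  dir <- withr::local_tempdir()
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    W <- random_layer(n, 0.4) * round(runif(n * n, 0.5, 3), 2)
    W <- (W + t(W)) / 2
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    mx <- multiplex_network(list(W), paste0("g", seq_len(n)))
    # write as an edge list and re-read
    ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    ef <- file.path(dir, "e.tsv")
    nf <- file.path(dir, "n.txt")
    writeLines(sprintf("%s\t%s\t%g", mx$node_ids[ut[, 1]],
                       mx$node_ids[ut[, 2]], W[ut]), ef)
    writeLines(mx$node_ids, nf)
    mx2 <- read_multiplex(ef, nf)
    expect_equal(mx2$layers[[1]], mx$layers[[1]])
    expect_identical(mx2$layers[[1]], t(mx2$layers[[1]]))
  }
})
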