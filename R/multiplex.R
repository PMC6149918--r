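#' Construct a multiplex network
#'
#' A multiplex network is a sequence of M weighted undirected networks
#' (layers), one per condition, over a single shared ordered vertex set.
#' Layers are stored as dense symmetric nonnegative weight matrices with zero
#' diagonal; a binary network is simply the special case w in \{0, 1\}.
#'
#' @param layers list of n x n numeric matrices, one per condition. Each must
#'   be symmetric, nonnegative, with zero diagonal.
#' @param node_ids character vector of n unique node identifiers.
#' @param layer_names optional character vector of condition labels; defaults
#'   to `layer1..layerM`.
#' @return an object of class `multiplex_network` with fields `node_ids`,
#'   `layers`, `layer_names`.
#' @export
multiplex_network <- function(layers, node_ids, layer_names = NULL) {
  if (!is.list(layers) || length(layers) < 1L)
    stop("`layers` must be a nonempty list of matrices (M >= 1)")
  node_ids <- as.character(node_ids)
  n <- length(node_ids)
  if (n < 1L) stop("empty vertex set")
  if (anyDuplicated(node_ids)) stop("duplicated node ids")
  if (is.null(layer_names))
    layer_names <- paste0("layer", seq_along(layers))
  if (length(layer_names) != length(layers))
    stop("`layer_names` must have one entry per layer")
  layers <- lapply(seq_along(layers), function(m) {
    W <- layers[[m]]
    if (!is.matrix(W) || !is.numeric(W))
      stop(sprintf("layer %d is not a numeric matrix", m))
    if (nrow(W) != n || ncol(W) != n)
      stop(sprintf("layer %d is %dx%d but there are %d nodes",
                   m, nrow(W), ncol(W), n))
    if (anyNA(W)) stop(sprintf("layer %d contains missing values", m))
    if (any(W < 0)) stop(sprintf("layer %d has negative weights", m))
    if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
      stop(sprintf("layer %d is not symmetric", m))
    if (any(diag(W) != 0))
      stop(sprintf("layer %d has nonzero diagonal (self-loops)", m))
    W <- (W + t(W)) / 2  # exact symmetry
    dimnames(W) <- list(node_ids, node_ids)
    W
  })
  structure(list(node_ids = node_ids, layers = layers,
                 layer_names = as.character(layer_names)),
            class = "multiplex_network")
}

#' Number of nodes / layers of a multiplex network
#' @param x a `multiplex_network`
#' @return integer count.
#' @export
n_nodes <- function(x) length(x$node_ids)

#' @rdname n_nodes
#' @export
n_layers <- function(x) length(x$layers)

#' @export
print.multiplex_network <- function(x, ...) {
  edges <- vapply(x$layers, function(W) sum(W[upper.tri(W)] > 0), numeric(1))
  cat(sprintf("multiplex_network: %d nodes, %d layer(s)\n",
              n_nodes(x), n_layers(x)))
  for (m in seq_along(x$layers))
    cat(sprintf("  [%d] %s: %d edges, total weight %.4g\n", m,
                x$layer_names[m], edges[m], sum(x$layers[[m]]) / 2))
  invisible(x)
}

#' Construct a partition of the vertex set
#'
#' A partition assigns every node to exactly one module; modules are nonempty
#' and jointly cover the vertex set (the hard-clustering constraints of the
#' index-matrix formulation). Labels are canonicalized to 1..k in order of
#' first appearance.
#'
#' @param assignment vector of module labels, one per node (any atomic type).
#' @param node_ids optional character vector of node identifiers.
#' @return an object of class `csm_partition` with fields `assignment`
#'   (integer labels 1..k), `node_ids`, `k`, and `module_sets` (list of k
#'   integer index vectors).
#' @export
as_partition <- function(assignment, node_ids = NULL) {
  if (length(assignment) < 1L) stop("empty assignment")
  if (anyNA(assignment)) stop("assignment contains NA")
  if (!is.null(node_ids)) {
    node_ids <- as.character(node_ids)
    if (length(node_ids) != length(assignment))
      stop("node_ids length does not match assignment")
  }
  memb <- match(assignment, unique(assignment))
  structure(list(assignment = as.integer(memb),
                 node_ids = node_ids,
                 k = max(memb),
                 module_sets = unname(split(seq_along(memb), memb))),
            class = "csm_partition")
}

#' @export
print.csm_partition <- function(x, ...) {
  sizes <- lengths(x$module_sets)
  cat(sprintf("partition of %d nodes into %d module(s); sizes: %s\n",
              length(x$assignment), x$k,
              paste(sizes, collapse = " ")))
  invisible(x)
}

# resolve a node set given as character ids or integer indices -> indices
resolve_nodes <- function(nodes, multiplex) {
  if (is.character(nodes)) {
    idx <- match(nodes, multiplex$node_ids)
    if (anyNA(idx))
      stop("unknown node id(s): ", paste(nodes[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1L | idx > n_nodes(multiplex)))
      stop("node index out of range")
    idx
  }
}

check_partition_on <- function(partition, multiplex) {
  if (!inherits(partition, "csm_partition")) stop("not a csm_partition")
  if (length(partition$assignment) != n_nodes(multiplex))
    stop("partition covers ", length(partition$assignment),
         " nodes but the multiplex has ", n_nodes(multiplex))
  invisible(TRUE)
}

#' Read a multiplex network from edge-list files
#'
#' Each layer is a tab-separated edge list with columns `node_a`, `node_b`,
#' `weight` (no header unless `header = TRUE`); the node list file holds one
#' identifier per line and fixes the shared vertex set and its order. Edges
#' may be written in either orientation and are stored symmetrically. A pair
#' listed twice within one file (in any orientation) is an error: silently
#' averaging conflicting weights would hide upstream data bugs.
#'
#' @param edge_list_paths character vector of edge-list file paths, one per
#'   condition; layer order follows this order.
#' @param node_list_path path of the node list file.
#' @param header logical; skip one header line in each edge file.
#' @param layer_names optional condition labels; default is the file base
#'   names.
#' @return a [multiplex_network()].
#' @export
read_multiplex <- function(edge_list_paths, node_list_path, header = FALSE,
                           layer_names = NULL) {
  node_ids <- readLines(node_list_path)
  node_ids <- trimws(node_ids)
  node_ids <- node_ids[nzchar(node_ids)]
  if (length(node_ids) == 0L) stop("empty node list: ", node_list_path)
  n <- length(node_ids)
  if (is.null(layer_names))
    layer_names <- tools::file_path_sans_ext(basename(edge_list_paths))
  layers <- lapply(edge_list_paths, function(path) {
    W <- matrix(0, n, n)
    lines <- readLines(path)
    offset <- 0L
    if (header && length(lines) >= 1L) {
      lines <- lines[-1L]
      offset <- 1L
    }
    keep <- nzchar(trimws(lines))
    lineno <- which(keep) + offset
    lines <- lines[keep]
    if (length(lines) == 0L) return(W)  # edgeless layer is valid
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad))
      stop(sprintf("%s line %d: expected 3 tab-separated fields",
                   path, lineno[which(bad)[1]]))
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    ia <- match(a, node_ids); ib <- match(b, node_ids)
    if (anyNA(ia)) {
      j <- which(is.na(ia))[1]
      stop(sprintf("%s line %d: unknown node id '%s'", path, lineno[j], a[j]))
    }
    if (anyNA(ib)) {
      j <- which(is.na(ib))[1]
      stop(sprintf("%s line %d: unknown node id '%s'", path, lineno[j], b[j]))
    }
    if (anyNA(w)) {
      j <- which(is.na(w))[1]
      stop(sprintf("%s line %d: non-numeric weight", path, lineno[j]))
    }
    if (any(w < 0)) {
      j <- which(w < 0)[1]
      stop(sprintf("%s line %d: negative weight %g", path, lineno[j], w[j]))
    }
    if (any(ia == ib)) {
      j <- which(ia == ib)[1]
      stop(sprintf("%s line %d: self-loop on '%s'", path, lineno[j], a[j]))
    }
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    if (anyDuplicated(key)) {
      j <- which(duplicated(key))[1]
      stop(sprintf(
        "%s line %d: duplicate edge %s-%s (listed more than once, possibly in both orientations)",
        path, lineno[j], a[j], b[j]))
    }
    W[cbind(ia, ib)] <- w
    W[cbind(ib, ia)] <- w
    W
  })
  multiplex_network(layers, node_ids, layer_names)
}

#' Write modules and a per-module summary to TSV files
#'
#' Writes a two-column TSV (`node_id`, `module_id`) plus a companion summary
#' with one row per module: size, per-layer module density, and per-layer
#' modularity contribution (the module's additive share of each layer's Q).
#'
#' @param partition a [as_partition()] over the multiplex vertex set.
#' @param multiplex a [multiplex_network()].
#' @param path output path for the node-to-module table.
#' @param summary_path output path for the summary; default replaces the
#'   extension of `path` with `_summary.tsv`.
#' @return invisibly, the summary data frame.
#' @export
write_modules <- function(partition, multiplex, path,
                          summary_path = NULL) {
  check_partition_on(partition, multiplex)
  if (is.null(summary_path))
    summary_path <- paste0(tools::file_path_sans_ext(path), "_summary.tsv")
  df <- data.frame(node_id = multiplex$node_ids,
                   module_id = partition$assignment,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  M <- n_layers(multiplex)
  summ <- data.frame(module_id = seq_len(partition$k),
                     size = lengths(partition$module_sets))
  for (m in seq_len(M)) {
    dens <- vapply(partition$module_sets, function(idx)
      module_density(idx, multiplex, m), numeric(1))
    summ[[paste0("density_", multiplex$layer_names[m])]] <- dens
    qc <- module_q_contributions(partition, multiplex, m)
    summ[[paste0("q_contrib_", multiplex$layer_names[m])]] <- qc
  }
  write.table(summ, summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(summ)
}

#' Read a node-to-module table written by [write_modules()]
#'
#' @param path TSV with header columns `node_id`, `module_id`.
#' @return a [as_partition()] with node ids taken from the file order.
#' @export
read_modules <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = c("character", NA))
  if (!all(c("node_id", "module_id") %in% names(df)))
    stop("'", path, "' lacks node_id/module_id columns")
  as_partition(df$module_id, node_ids = df$node_id)
}
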