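#' Construct a network topology
#'
#' A topology is a symmetric, unweighted graph: a node count plus a set of
#' unordered edges.  Every other object in the package (configurations,
#' ensembles, Potts parameters) is defined relative to one of these.
#' Node indices are 0-based everywhere in the package, including files.
#'
#' Edges may carry a class label (e.g. `"spatial"` vs `"temporal"` for
#' time-extended networks); each class gets its own coupling matrix and its
#' own couple-density block in the observable vector.
#'
#' @param n_nodes positive integer number of nodes.
#' @param edges two-column integer matrix of 0-based node pairs, one row per
#'   unordered edge.  Reversed duplicates are collapsed; self-loops are an
#'   error.
#' @param edge_class optional character vector, one label per edge row
#'   (default a single class `"spatial"`).
#' @param metadata free-form list of provenance (lattice shape, periodicity,
#'   ...) carried through round trips.
#' @return an object of class `potts_topology` with fields `n_nodes`,
#'   `edges` (canonicalised: first index < second, sorted), `edge_class`,
#'   `class_names`, `n_links`, `n_links_class`, `metadata`.
#' @seealso [lattice_topology()], [read_topology()]
#' @export
potts_topology <- function(n_nodes, edges, edge_class = NULL, metadata = list()) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 0L) || any(edges >= n_nodes))
      stop("edge endpoint out of range [0, n_nodes-1]")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed (row ",
           which(edges[, 1L] == edges[, 2L])[1L], ")")
  }
  if (is.null(edge_class)) edge_class <- rep("spatial", nrow(edges))
  edge_class <- as.character(edge_class)
  stopifnot(length(edge_class) == nrow(edges))

  # canonical unordered form: (min, max), dedupe keeping first class label
  if (nrow(edges) > 0L) {
    lo <- pmin(edges[, 1L], edges[, 2L])
    hi <- pmax(edges[, 1L], edges[, 2L])
    key <- lo * n_nodes + hi
    keep <- !duplicated(key)
    ord <- order(lo[keep], hi[keep])
    edges <- cbind(lo[keep], hi[keep])[ord, , drop = FALSE]
    edge_class <- edge_class[keep][ord]
  }
  class_names <- unique(edge_class)
  topo <- structure(list(
    n_nodes = n_nodes,
    edges = edges,
    edge_class = edge_class,
    class_names = class_names,
    n_links = nrow(edges),
    n_links_class = if (length(class_names))
      vapply(class_names, function(cl) sum(edge_class == cl), integer(1))
    else integer(0),
    metadata = metadata
  ), class = "potts_topology")
  topo
}

#' @export
print.potts_topology <- function(x, ...) {
  cat("<potts_topology> ", x$n_nodes, " nodes, ", x$n_links, " links",
      if (length(x$class_names) > 1L)
        paste0(" (", paste(x$class_names, x$n_links_class[x$class_names],
                           sep = ": ", collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Per-node degree of a topology
#' @param topology a `potts_topology`.
#' @return integer vector of length `n_nodes`.
#' @export
node_degree <- function(topology) {
  deg <- integer(topology$n_nodes)
  if (topology$n_links > 0L) {
    t1 <- tabulate(topology$edges[, 1L] + 1L, topology$n_nodes)
    t2 <- tabulate(topology$edges[, 2L] + 1L, topology$n_nodes)
    deg <- t1 + t2
  }
  deg
}

#' Adjacency (neighbour index) of a topology
#'
#' @param topology a `potts_topology`.
#' @return list with `ptr` (0-based CSR offsets, length n_nodes+1), `idx`
#'   (0-based neighbour indices) and `cls` (1-based edge-class index per
#'   neighbour entry), the format consumed by the compiled Metropolis kernel.
#' @keywords internal
neighbor_csr <- function(topology) {
  n <- topology$n_nodes
  m <- topology$n_links
  if (m == 0L) {
    return(list(ptr = integer(n + 1L), idx = integer(0), cls = integer(0)))
  }
  cls <- match(topology$edge_class, topology$class_names)
  from <- c(topology$edges[, 1L], topology$edges[, 2L])
  to <- c(topology$edges[, 2L], topology$edges[, 1L])
  ec <- c(cls, cls)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; ec <- ec[ord]
  ptr <- c(0L, cumsum(tabulate(from + 1L, n)))
  list(ptr = as.integer(ptr), idx = as.integer(to), cls = as.integer(ec))
}

#' Build a nearest-neighbour lattice topology
#'
#' Nodes are the cells of a rectangular lattice of arbitrary dimensionality,
#' flattened row-major (the last axis varies fastest), 0-based.  Edges join
#' nearest neighbours along each axis; `periodic = TRUE` wraps every axis.
#'
#' @param shape integer vector of axis lengths (each >= 1; >= 3 when
#'   periodic, because wrapping an axis of length 2 would duplicate edges).
#' @param periodic logical flag, default `TRUE` (typical lattice-model
#'   practice; image grids use `FALSE` since an image has borders).
#' @return a `potts_topology`; for a periodic lattice
#'   `n_links = n_nodes * length(shape)`.
#' @examples
#' lattice_topology(c(3, 3))                  # 9 nodes, 18 links
#' lattice_topology(4, periodic = FALSE)      # path graph, 3 links
#' @export
lattice_topology <- function(shape, periodic = TRUE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) >= 1L, all(shape >= 1L))
  if (periodic && any(shape == 2L))
    stop("periodic lattice with an axis of length 2 would create duplicate edges; ",
         "use periodic = FALSE or a longer axis")
  n <- prod(shape)
  d <- length(shape)
  # row-major strides: last axis stride 1
  strides <- rev(cumprod(rev(c(shape[-1L], 1L))))
  coords <- arrayInd(seq_len(n), .dim = rev(shape))[, rev(seq_len(d)), drop = FALSE] - 1L
  # arrayInd is column-major over rev(shape); after reversing columns,
  # coords[k, ] are the row-major coordinates of 0-based node k-1.
  edges_from <- integer(0); edges_to <- integer(0)
  node_of <- function(cc) as.integer(cc %*% strides)
  for (ax in seq_len(d)) {
    if (shape[ax] == 1L) next
    ok <- coords[, ax] < shape[ax] - 1L
    cc <- coords[ok, , drop = FALSE]
    cc2 <- cc; cc2[, ax] <- cc2[, ax] + 1L
    edges_from <- c(edges_from, node_of(cc))
    edges_to <- c(edges_to, node_of(cc2))
    if (periodic && shape[ax] > 2L) {
      wrap <- coords[, ax] == shape[ax] - 1L
      cc <- coords[wrap, , drop = FALSE]
      cc2 <- cc; cc2[, ax] <- 0L
      edges_from <- c(edges_from, node_of(cc))
      edges_to <- c(edges_to, node_of(cc2))
    }
  }
  potts_topology(n, cbind(edges_from, edges_to),
                 metadata = list(lattice_shape = shape, periodic = periodic))
}

#' Read a topology from an edge-list file
#'
#' The format is two integer columns (whitespace- or tab-delimited), one
#' unordered edge per line; lines starting with `#` are comments.  A comment
#' of the form `# n_nodes: K` declares the node count, otherwise it is
#' inferred as `max(index) + 1`.  Duplicate and reversed pairs collapse.
#' Disconnected inputs are accepted with a warning (nothing in the model
#' requires connectivity), never rejected.
#'
#' @param path file path.
#' @return a `potts_topology`.
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no edges in '", path, "'")
  declared <- NA_integer_
  m <- regmatches(comments, regexec("n_nodes:\\s*([0-9]+)", comments))
  for (mm in m) if (length(mm) == 2L) declared <- as.integer(mm[2L])
  toks <- strsplit(trimws(body), "[[:space:],]+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad)) stop("line ", bad[1L], ": expected two integer columns")
  vals <- suppressWarnings(vapply(toks, function(t) as.integer(t), integer(2)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1L]
    stop("line ", bad, ": non-integer token")
  }
  edges <- t(vals)
  sl <- which(edges[, 1L] == edges[, 2L])
  if (length(sl)) stop("line ", sl[1L], ": self-loop not allowed")
  n_nodes <- if (!is.na(declared)) declared else max(edges) + 1L
  topo <- potts_topology(n_nodes, edges, metadata = list(source = path))
  comp <- n_components(topo)
  if (comp > 1L)
    warning("topology has ", comp, " connected components")
  topo
}

#' Write a topology as an edge list
#' @param topology a `potts_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes: %d", topology$n_nodes), con)
  if (topology$n_links > 0L)
    writeLines(sprintf("%d\t%d", topology$edges[, 1L], topology$edges[, 2L]), con)
  invisible(path)
}

# number of connected components by traversal
n_components <- function(topology) {
  n <- topology$n_nodes
  if (n == 0L) return(0L)
  csr <- neighbor_csr(topology)
  seen <- logical(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      a <- csr$ptr[v] + 1L; b <- csr$ptr[v + 1L]
      if (b >= a) {
        nb <- csr$idx[a:b] + 1L
        new <- nb[!seen[nb]]
        seen[new] <- TRUE
        queue <- c(queue, new)
      }
    }
  }
  comp
}

#' Construct an ensemble of configurations
#'
#' A configuration is an integer state per node, values in
#' `0..n_states-1`.  An ensemble is a weighted collection of configurations
#' sharing one topology and one state alphabet.
#'
#' @param states integer matrix, one configuration per row
#'   (`n_conf x n_nodes`), or a single integer vector.
#' @param n_states size Q of the state alphabet.
#' @param topology the shared `potts_topology`.
#' @param weights nonnegative weights, one per configuration (default 1).
#' @return an object of class `potts_ensemble`.
#' @export
potts_ensemble <- function(states, n_states, topology, weights = NULL) {
  if (is.null(dim(states))) states <- matrix(as.integer(states), nrow = 1L)
  states <- matrix(as.integer(states), nrow = nrow(states))
  n_states <- as.integer(n_states)
  stopifnot(inherits(topology, "potts_topology"), n_states >= 1L)
  if (ncol(states) != topology$n_nodes)
    stop("configurations have ", ncol(states), " entries; topology has ",
         topology$n_nodes, " nodes")
  bad <- which(states < 0L | states >= n_states, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("state out of range [0, ", n_states - 1L, "] at row ", bad[1L, 1L],
         ", column ", bad[1L, 2L])
  if (is.null(weights)) weights <- rep(1, nrow(states))
  stopifnot(length(weights) == nrow(states), all(weights >= 0))
  if (sum(weights) <= 0) stop("ensemble weights must sum to a positive value")
  structure(list(states = states, n_states = n_states, topology = topology,
                 weights = as.numeric(weights), n_conf = nrow(states)),
            class = "potts_ensemble")
}

#' @export
print.potts_ensemble <- function(x, ...) {
  cat("<potts_ensemble> ", x$n_conf, " configurations, ",
      x$topology$n_nodes, " nodes, Q = ", x$n_states, "\n", sep = "")
  invisible(x)
}

#' Read an ensemble from a configuration-matrix file
#'
#' One configuration per line, whitespace- or comma-delimited integers,
#' `#` comments allowed.  Each row must have exactly `n_nodes` entries in
#' `0..n_states-1`.
#'
#' @param path file path.
#' @param topology the `potts_topology` the configurations live on.
#' @param n_states state-alphabet size Q.
#' @return a `potts_ensemble` with unit weights.
#' @export
read_ensemble <- function(path, topology, n_states) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no configurations in '", path, "'")
  toks <- strsplit(trimws(body), "[[:space:],]+")
  len <- vapply(toks, length, 1L)
  if (any(len != topology$n_nodes))
    stop("row ", which(len != topology$n_nodes)[1L], ": expected ",
         topology$n_nodes, " entries, found ", len[len != topology$n_nodes][1L])
  vals <- suppressWarnings(as.integer(unlist(toks)))
  if (anyNA(vals)) stop("non-integer token in configuration file")
  states <- matrix(vals, nrow = length(body), byrow = TRUE)
  potts_ensemble(states, n_states, topology)
}

#' Write an ensemble in the configuration-matrix format
#' @param ensemble a `potts_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  apply(ensemble$states, 1L, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
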