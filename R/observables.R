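#' Observable layout for a topology and state alphabet
#'
#' The constrained observables of the model are the per-state densities
#' s_1..s_Q followed by, for every edge class, the unordered near-neighbour
#' couple densities c_ij (upper triangle including the diagonal, row-major:
#' (1,1), (1,2), ..., (1,Q), (2,2), ...).  This frozen flat ordering is what
#' parameter vectors, covariance matrices and serialized files all use.
#'
#' @param n_states Q.
#' @param topology a `potts_topology` (supplies the edge classes and the
#'   normalisation counts).
#' @return a list with `n_states`, `classes`, `M` (flat length), `names`
#'   (flat labels), `pair_i`/`pair_j` (1-based state pairs of the c-block),
#'   `block` (factor: `"s"` or the class name per flat entry), and `D`
#'   (count-scaling vector: n_nodes for the s-block, the class link count
#'   for each c-block; the extensive observable is `D * flat`).
#' @export
observable_layout <- function(n_states, topology) {
  Q <- as.integer(n_states)
  classes <- topology$class_names[topology$n_links_class[topology$class_names] > 0L]
  pi_ <- integer(0); pj <- integer(0)
  for (i in seq_len(Q)) for (j in i:Q) { pi_ <- c(pi_, i); pj <- c(pj, j) }
  ntri <- length(pi_)
  nm <- paste0("s", seq_len(Q) - 1L)
  block <- rep("s", Q)
  D <- rep(as.numeric(topology$n_nodes), Q)
  for (cl in classes) {
    tag <- if (length(classes) == 1L && cl == "spatial") "c" else paste0("c_", cl)
    nm <- c(nm, paste0(tag, "[", pi_ - 1L, ",", pj - 1L, "]"))
    block <- c(block, rep(cl, ntri))
    D <- c(D, rep(as.numeric(topology$n_links_class[[cl]]), ntri))
  }
  list(n_states = Q, classes = classes, M = length(nm), names = nm,
       pair_i = pi_, pair_j = pj, block = block, D = D)
}

#' Per-state density of a single configuration
#'
#' `s_i = (1/n_nodes) * #\{k : state_k = i\}`; the densities sum to 1.
#'
#' @param states integer state vector (values in `0..n_states-1`).
#' @param n_states Q.
#' @return numeric vector of length Q.
#' @export
state_density <- function(states, n_states) {
  states <- as.integer(states)
  stopifnot(all(states >= 0L), all(states < n_states))
  tabulate(states + 1L, n_states) / length(states)
}

#' Near-neighbour couple density of a single configuration
#'
#' Each unordered edge contributes one count to the unordered state pair
#' \{i,j\} of its endpoints; counts are normalised by the number of links so
#' that the upper triangle (including the diagonal) sums to 1.  The returned
#' matrix is symmetric: for i != j the entries `[i,j]` and `[j,i]` both
#' report the shared unordered density.
#'
#' @param states integer state vector.
#' @param topology a `potts_topology`; if it has several edge classes, a
#'   named list of matrices is returned (one per class, each normalised by
#'   its own link count).
#' @param n_states Q.
#' @return Q x Q symmetric matrix, or a named list of them.
#' @export
pair_density <- function(states, topology, n_states) {
  states <- as.integer(states)
  stopifnot(length(states) == topology$n_nodes)
  classes <- topology$class_names[topology$n_links_class[topology$class_names] > 0L]
  out <- lapply(classes, function(cl) {
    sel <- topology$edge_class == cl
    a <- states[topology$edges[sel, 1L] + 1L]
    b <- states[topology$edges[sel, 2L] + 1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    m <- matrix(0, n_states, n_states)
    cnt <- tabulate(lo * n_states + hi + 1L, n_states * n_states)
    for (i in seq_len(n_states)) for (j in i:n_states) {
      v <- cnt[(i - 1L) * n_states + j]
      m[i, j] <- v; m[j, i] <- v
    }
    m / sum(sel)
  })
  names(out) <- classes
  if (length(out) == 1L) out[[1L]] else out
}

#' Count-space observable matrix of an ensemble
#'
#' Row r holds the extensive observables y of configuration r: the Q state
#' counts followed, per edge class, by the unordered pair counts in flat
#' layout order.  Densities are `y / layout$D`.  This matrix is the single
#' quantity the trainer needs from an ensemble: energies are `y %*% theta`,
#' model observables are weighted column means.
#'
#' @param ensemble a `potts_ensemble`.
#' @param layout optional precomputed [observable_layout()].
#' @return numeric matrix `n_conf x M`.
#' @export
observable_counts <- function(ensemble, layout = NULL) {
  topo <- ensemble$topology
  if (is.null(layout)) layout <- observable_layout(ensemble$n_states, topo)
  cls <- match(topo$edge_class, layout$classes)
  Y <- cpp_count_observables(ensemble$states, ensemble$n_states,
                             topo$edges, cls, length(layout$classes))
  colnames(Y) <- layout$names
  Y
}

#' Ensemble-average observables
#'
#' Weighted mean of the per-configuration densities; with unit weights this
#' is the plain arithmetic mean over the training set.
#'
#' @param ensemble a `potts_ensemble`.
#' @param layout optional precomputed layout.
#' @return an object of class `potts_observables`: list with `s`, `c`
#'   (named list of Q x Q matrices per edge class), `flat` (densities in
#'   layout order), `layout`.
#' @export
ensemble_observables <- function(ensemble, layout = NULL) {
  if (is.null(layout)) layout <- observable_layout(ensemble$n_states, ensemble$topology)
  w <- ensemble$weights
  if (sum(w) <= 0) stop("all-zero ensemble weights")
  w <- w / sum(w)
  Y <- observable_counts(ensemble, layout)
  flat <- as.numeric(crossprod(Y, w)) / layout$D
  flat_to_observables(flat, layout)
}

#' Assemble a `potts_observables` object from a flat density vector
#' @param flat densities in layout order.
#' @param layout an [observable_layout()].
#' @return a `potts_observables` object.
#' @export
flat_to_observables <- function(flat, layout) {
  Q <- layout$n_states
  s <- flat[seq_len(Q)]
  cmats <- list()
  off <- Q
  ntri <- length(layout$pair_i)
  for (cl in layout$classes) {
    v <- flat[off + seq_len(ntri)]
    m <- matrix(0, Q, Q)
    m[cbind(layout$pair_i, layout$pair_j)] <- v
    m[cbind(layout$pair_j, layout$pair_i)] <- v
    cmats[[cl]] <- m
    off <- off + ntri
  }
  structure(list(s = s, c = cmats, flat = flat, layout = layout),
            class = "potts_observables")
}

#' @export
print.potts_observables <- function(x, ...) {
  cat("<potts_observables> Q =", x$layout$n_states, "\n s:",
      signif(x$s, 4), "\n")
  for (cl in names(x$c)) {
    cat(" couple densities (", cl, "):\n", sep = "")
    print(signif(x$c[[cl]], 4))
  }
  invisible(x)
}

#' Weighted covariance of the ensemble observables
#'
#' The sample covariance of the per-configuration flat density vectors,
#' weighted by the ensemble weights.  Its kernel encodes the exact linear
#' dependencies among the observables (densities summing to one, couple sum
#' rules, lattice regularity relations) — the gauge freedom of the model.
#'
#' @param ensemble a `potts_ensemble` with at least two configurations.
#' @param layout optional precomputed layout.
#' @param count_scale if `TRUE`, return the covariance of the extensive
#'   (count-space) observables `D * x` instead; its kernel coincides with the
#'   gauge directions of the parameter vector.
#' @return symmetric `M x M` matrix.
#' @export
observable_covariance <- function(ensemble, layout = NULL, count_scale = FALSE) {
  if (ensemble$n_conf < 2L)
    stop("covariance requires at least 2 configurations")
  if (is.null(layout)) layout <- observable_layout(ensemble$n_states, ensemble$topology)
  w <- ensemble$weights / sum(ensemble$weights)
  X <- observable_counts(ensemble, layout)
  if (!count_scale) X <- sweep(X, 2L, layout$D, "/")
  mu <- as.numeric(crossprod(X, w))
  Xc <- sweep(X, 2L, mu, "-")
  S <- crossprod(Xc * w, Xc)
  (S + t(S)) / 2
}

#' Gauge projector from an observable covariance
#'
#' Diagonalises the covariance and flags eigen-directions whose eigenvalue
#' falls below `cutoff` times the largest eigenvalue as the kernel (gauge)
#' subspace.  The pseudo-inverse is built from the remaining spectrum only,
#' so residual components along the kernel never enter the chi-squared.
#'
#' Two thresholds are kept: `cutoff` (soft, default 1e-8 relative) guards
#' against near-singular sampling noise; directions below 1e-10 relative are
#' additionally marked `exact`.
#'
#' @param covariance symmetric matrix from [observable_covariance()].
#' @param cutoff relative eigenvalue threshold (default `1e-8`).
#' @param abs_floor absolute eigenvalue floor (default `1e-14`): directions
#'   whose variance is numerically indistinguishable from zero are kernel
#'   regardless of the spectrum scale (a fully degenerate covariance would
#'   otherwise keep its largest rounding-noise direction).
#' @return an object of class `gauge_projector`: `values`, `vectors`,
#'   `kernel` (logical per eigen-direction), `dof` (number of informative
#'   directions), `pseudo_inverse`, `projector` (idempotent symmetric P onto
#'   the informative subspace), `cutoff`.
#' @export
gauge_projector <- function(covariance, cutoff = 1e-8, abs_floor = 1e-14) {
  stopifnot(isSymmetric(unname(covariance), tol = 1e-8))
  eig <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  vmax <- max(eig$values, 0)
  kernel <- eig$values < max(cutoff * vmax, abs_floor) | eig$values <= 0
  if (all(kernel))
    stop("no informative directions: every eigenvalue falls below the cutoff ",
         "(degenerate training set)")
  keep <- !kernel
  V <- eig$vectors
  pinv <- V[, keep, drop = FALSE] %*%
    (t(V[, keep, drop = FALSE]) / eig$values[keep])
  P <- tcrossprod(V[, keep, drop = FALSE])
  structure(list(values = eig$values, vectors = V, kernel = kernel,
                 exact = eig$values < 1e-10 * vmax,
                 dof = sum(keep), pseudo_inverse = pinv, projector = P,
                 cutoff = cutoff),
            class = "gauge_projector")
}

#' @export
print.gauge_projector <- function(x, ...) {
  cat("<gauge_projector> dof =", x$dof, "| kernel dim =", sum(x$kernel),
      "| cutoff =", x$cutoff, "\n")
  invisible(x)
}

#' Serialize observables (or a covariance) to JSON
#'
#' The file records the flat layout alongside the numbers so that parameter
#' and observable files are portable across runs.
#'
#' @param obs a `potts_observables`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(obs, path) {
  jsonlite::write_json(list(
    layout = list(n_states = obs$layout$n_states, classes = obs$layout$classes,
                  names = obs$layout$names,
                  ordering = "s-block then upper-triangular c-block row-major"),
    flat = obs$flat), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
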