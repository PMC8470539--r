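#' Potts model parameters
#'
#' The model assigns each configuration the probability
#' `P(sigma) = exp(-E(sigma)) / Z` with the extensive energy
#' `E(sigma) = sum_k h[state_k] + sum_edges J_class[state_i, state_j]`,
#' i.e. one field term per node and one coupling term per unordered edge.
#' In density units this is the multi-state Ising (Potts) Hamiltonian
#' `H = sum_i h_i s_i + sum_{i<=j} J_ij c_ij` with s and c the state and
#' couple densities; the extensive exponent is the unique reading under
#' which the non-interacting start `h = -log(<s>)`, `J = 0` reproduces the
#' target densities exactly and has Shannon-Fano entropy (see the methods
#' vignette).  Positive J means repulsion between the two states.
#'
#' @param h numeric field vector of length Q.
#' @param J Q x Q symmetric coupling matrix, or a named list of such
#'   matrices (one per edge class, e.g. `spatial` and `temporal`).
#' @param n_states Q (inferred from `h` if missing).
#' @return an object of class `potts_parameters`.
#' @export
potts_parameters <- function(h, J = NULL, n_states = length(h)) {
  Q <- as.integer(n_states)
  h <- as.numeric(h)
  stopifnot(length(h) == Q, all(is.finite(h)))
  if (is.null(J)) J <- list(spatial = matrix(0, Q, Q))
  if (is.matrix(J)) J <- list(spatial = J)
  stopifnot(is.list(J), !is.null(names(J)))
  J <- lapply(J, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == Q, ncol(m) == Q, all(is.finite(m)))
    if (max(abs(m - t(m))) > 1e-9 * max(1, max(abs(m))))
      stop("coupling matrix must be symmetric")
    (m + t(m)) / 2
  })
  structure(list(h = h, J = J, n_states = Q), class = "potts_parameters")
}

#' @export
print.potts_parameters <- function(x, ...) {
  cat("<potts_parameters> Q =", x$n_states, "\n h:", signif(x$h, 4), "\n")
  for (cl in names(x$J)) {
    cat(" J (", cl, "):\n", sep = "")
    print(signif(x$J[[cl]], 4))
  }
  invisible(x)
}

#' Flatten parameters to the layout ordering (h-block then J upper triangles)
#' @param params a `potts_parameters`.
#' @param layout an [observable_layout()]; its edge classes select which J
#'   blocks enter (classes absent from the topology are dropped).
#' @return numeric vector of length `layout$M`.
#' @export
params_to_theta <- function(params, layout) {
  th <- params$h
  for (cl in layout$classes) {
    J <- params$J[[cl]]
    if (is.null(J)) J <- matrix(0, params$n_states, params$n_states)
    th <- c(th, J[cbind(layout$pair_i, layout$pair_j)])
  }
  th
}

#' Rebuild `potts_parameters` from a flat theta vector
#' @param theta flat parameter vector in layout order.
#' @param layout an [observable_layout()].
#' @return a `potts_parameters`.
#' @export
theta_to_params <- function(theta, layout) {
  Q <- layout$n_states
  h <- theta[seq_len(Q)]
  ntri <- length(layout$pair_i)
  J <- list()
  off <- Q
  for (cl in layout$classes) {
    v <- theta[off + seq_len(ntri)]
    m <- matrix(0, Q, Q)
    m[cbind(layout$pair_i, layout$pair_j)] <- v
    m[cbind(layout$pair_j, layout$pair_i)] <- v
    J[[cl]] <- m
    off <- off + ntri
  }
  potts_parameters(h, J, Q)
}

# J blocks as a Q*Q*nclass numeric vector for the compiled kernel
jcube <- function(params, layout) {
  Q <- params$n_states
  out <- numeric(0)
  for (cl in layout$classes) {
    J <- params$J[[cl]]
    if (is.null(J)) J <- matrix(0, Q, Q)
    out <- c(out, as.numeric(J))
  }
  out
}

#' Energy of configurations
#'
#' With `scale = "extensive"` (the Boltzmann exponent): one h term per node
#' plus one J term per edge.  With `scale = "density"`: the density-unit
#' Hamiltonian `sum_i h_i s_i + sum_{i<=j} J_ij c_ij`, useful for reporting.
#'
#' @param states a state vector, a configuration matrix (rows =
#'   configurations) or a `potts_ensemble`.
#' @param params a `potts_parameters`.
#' @param topology a `potts_topology` (taken from the ensemble if omitted).
#' @param scale `"extensive"` or `"density"`.
#' @return numeric vector of energies, one per configuration.
#' @export
potts_energy <- function(states, params, topology = NULL,
                         scale = c("extensive", "density")) {
  scale <- match.arg(scale)
  if (inherits(states, "potts_ensemble")) {
    topology <- states$topology
    states <- states$states
  }
  if (is.null(dim(states))) states <- matrix(as.integer(states), nrow = 1L)
  layout <- observable_layout(params$n_states, topology)
  ens <- potts_ensemble(states, params$n_states, topology)
  Y <- observable_counts(ens, layout)
  theta <- params_to_theta(params, layout)
  if (scale == "density") Y <- sweep(Y, 2L, layout$D, "/")
  as.numeric(Y %*% theta)
}

#' Energy change of a single-site update
#'
#' Extensive-energy difference of setting `node` to `new_state`, computed
#' from the local neighbourhood in O(degree); equals the difference of full
#' [potts_energy()] evaluations.
#'
#' @param states current state vector.
#' @param node 0-based node index.
#' @param new_state proposed state.
#' @param params,topology model and graph.
#' @return scalar energy difference.
#' @export
energy_delta <- function(states, node, new_state, params, topology) {
  a <- states[node + 1L]
  b <- as.integer(new_state)
  if (a == b) return(0)
  d <- params$h[b + 1L] - params$h[a + 1L]
  if (topology$n_links > 0L) {
    sel <- topology$edges[, 1L] == node | topology$edges[, 2L] == node
    if (any(sel)) {
      other <- ifelse(topology$edges[sel, 1L] == node,
                      topology$edges[sel, 2L], topology$edges[sel, 1L])
      cl <- topology$edge_class[sel]
      sn <- states[other + 1L]
      for (q in seq_along(other)) {
        J <- params$J[[cl[q]]]
        d <- d + J[b + 1L, sn[q] + 1L] - J[a + 1L, sn[q] + 1L]
      }
    }
  }
  d
}

#' Draw an equilibrium ensemble by Metropolis Monte Carlo
#'
#' Single-site proposals (uniform random free node, uniform random allowed
#' state different from the current one) accepted with probability
#' `min(1, exp(-dE))`.  One sweep is one proposal per free node.  Runs are
#' deterministic given `seed`.
#'
#' @param params a `potts_parameters`.
#' @param topology a `potts_topology`.
#' @param n_samples configurations to keep (default 1000).
#' @param burn_in discarded initial sweeps (default 1000).
#' @param stride sweeps between kept configurations (default 10).
#' @param init optional initial state vector (default: uniform random over
#'   the allowed states).
#' @param clamped optional integer vector of length `n_nodes` with `NA` for
#'   free nodes and a fixed state for clamped ones; clamped nodes are never
#'   proposed.
#' @param allowed_states optional integer vector of states free nodes may
#'   take (default: the full alphabet).
#' @param seed optional RNG seed.
#' @return a `potts_ensemble` of the kept configurations (unit weights).
#' @export
sample_potts <- function(params, topology, n_samples = 1000L,
                         burn_in = 1000L, stride = 10L, init = NULL,
                         clamped = NULL, allowed_states = NULL, seed = NULL) {
  stopifnot(n_samples >= 1L, burn_in >= 0L, stride >= 1L)
  if (!is.null(seed)) set.seed(seed)
  Q <- params$n_states
  n <- topology$n_nodes
  layout <- observable_layout(Q, topology)
  if (is.null(allowed_states)) allowed_states <- seq_len(Q) - 1L
  allowed_states <- sort(unique(as.integer(allowed_states)))
  stopifnot(all(allowed_states >= 0L), all(allowed_states < Q))
  if (is.null(clamped)) clamped <- rep(NA_integer_, n)
  stopifnot(length(clamped) == n)
  fixed <- !is.na(clamped)
  if (any(clamped[fixed] < 0L | clamped[fixed] >= Q))
    stop("clamped state out of range")
  free_nodes <- which(!fixed) - 1L
  if (length(free_nodes) == 0L) stop("all nodes are clamped")
  if (is.null(init)) {
    init <- sample(allowed_states, n, replace = TRUE)
  }
  init <- as.integer(init)
  init[fixed] <- as.integer(clamped[fixed])
  # per-node allowed-state CSR: clamped nodes get their single state
  allow_list <- vector("list", n)
  for (k in seq_len(n)) {
    allow_list[[k]] <- if (fixed[k]) as.integer(clamped[k]) else allowed_states
  }
  allow_len <- lengths(allow_list)
  allow_ptr <- c(0L, cumsum(allow_len))
  allow_val <- as.integer(unlist(allow_list))
  csr <- neighbor_csr(topology)
  kept <- cpp_metropolis(init, params$h, jcube(params, layout), Q,
                         length(layout$classes), csr$ptr, csr$idx, csr$cls,
                         as.integer(free_nodes), allow_ptr, allow_val,
                         as.integer(n_samples), as.integer(burn_in),
                         as.integer(stride))
  potts_ensemble(kept, Q, topology)
}

#' Exact enumeration of a small Potts system
#'
#' Enumerates all `Q^n_nodes` configurations, sums the partition function
#' directly and returns the exact Boltzmann table, observables and Shannon
#' entropy.  The reference oracle against which the Metropolis sampler and
#' the thermodynamic-integration entropy are validated.
#'
#' @param params a `potts_parameters`.
#' @param topology a `potts_topology`.
#' @param max_states guard on the state-space size (default 1e6).
#' @return an object of class `potts_enumeration`: `configs` (matrix, one
#'   configuration per row), `log_prob`, `prob`, `log_z`, `observables` (a
#'   `potts_observables` of exact means), `entropy` (exact -sum p log p),
#'   `layout`.
#' @export
enumerate_potts <- function(params, topology, max_states = 1e6) {
  Q <- params$n_states
  n <- topology$n_nodes
  n_tot <- Q^n
  if (n_tot > max_states)
    stop("state space has ", n_tot, " configurations (> ", max_states,
         "); use sample_potts() instead")
  layout <- observable_layout(Q, topology)
  idx <- 0:(n_tot - 1)
  configs <- matrix(0L, n_tot, n)
  rem <- idx
  for (k in n:1) {            # node k varies slowest for readability only
    configs[, k] <- as.integer(rem %% Q)
    rem <- rem %/% Q
  }
  ens <- potts_ensemble(configs, Q, topology)
  Y <- observable_counts(ens, layout)
  theta <- params_to_theta(params, layout)
  loge <- -as.numeric(Y %*% theta)
  mx <- max(loge)
  log_z <- mx + log(sum(exp(loge - mx)))
  log_prob <- loge - log_z
  prob <- exp(log_prob)
  flat <- as.numeric(crossprod(Y, prob)) / layout$D
  structure(list(configs = configs, log_prob = log_prob, prob = prob,
                 log_z = log_z,
                 observables = flat_to_observables(flat, layout),
                 entropy = -sum(prob * log_prob), layout = layout),
            class = "potts_enumeration")
}

#' Conditional per-node marginals by clamped Metropolis
#'
#' Fixes the clamped nodes, runs Metropolis over the free ones (optionally
#' restricted to a sub-alphabet) and reports, for every node and state, the
#' empirical probability across the stored ensemble.  Clamped nodes report
#' their fixed state with probability 1.
#'
#' @inheritParams sample_potts
#' @param clamped integer vector with `NA` marking free nodes.
#' @return numeric `n_nodes x Q` matrix of probabilities (rows sum to 1).
#' @export
conditional_marginals <- function(params, topology, clamped,
                                  allowed_states = NULL, n_samples = 1000L,
                                  burn_in = 1000L, stride = 10L, seed = NULL) {
  ens <- sample_potts(params, topology, n_samples = n_samples,
                      burn_in = burn_in, stride = stride, clamped = clamped,
                      allowed_states = allowed_states, seed = seed)
  Q <- params$n_states
  probs <- matrix(0, topology$n_nodes, Q,
                  dimnames = list(NULL, paste0("state", seq_len(Q) - 1L)))
  for (q in seq_len(Q) - 1L) probs[, q + 1L] <- colMeans(ens$states == q)
  probs
}

#' Write Potts parameters to JSON
#'
#' The file records the conventions (unordered pair counting, extensive
#' Boltzmann exponent) so that saved parameters are unambiguous.
#'
#' @param params a `potts_parameters`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(list(
    n_states = params$n_states,
    h = params$h,
    J = lapply(params$J, function(m) unname(apply(m, 1L, as.numeric,
                                                  simplify = FALSE))),
    convention = list(pair_counting = "unordered",
                      energy_scale = "extensive")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read Potts parameters from JSON written by [write_parameters()]
#' @param path file path.
#' @return a `potts_parameters`.
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  J <- obj$J
  if (is.matrix(J)) J <- list(spatial = J)
  J <- lapply(J, function(m) matrix(as.numeric(unlist(m)), obj$n_states,
                                    obj$n_states, byrow = TRUE))
  potts_parameters(as.numeric(obj$h), J, obj$n_states)
}
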