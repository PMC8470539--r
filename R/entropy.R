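#' Shannon-Fano (mean-field) entropy
#'
#' The entropy of the independent-node distribution with the given state
#' densities: `S_SF = -n_nodes * sum_i <s_i> log <s_i>` (natural log,
#' `0 log 0 := 0`).  It is the entropy of the non-interacting training
#' start, and an upper bound on the maximum-entropy result.
#'
#' @param densities per-state densities (sum to 1) or a `potts_observables`.
#' @param n_nodes number of nodes.
#' @return scalar entropy in nats.
#' @export
shannon_fano <- function(densities, n_nodes) {
  s <- if (inherits(densities, "potts_observables")) densities$s else as.numeric(densities)
  if (any(s < 0)) stop("negative density")
  stopifnot(abs(sum(s) - 1) < 1e-8)
  nz <- s > 0
  -n_nodes * sum(s[nz] * log(s[nz]))
}

#' Variational entropy by thermodynamic integration along a training path
#'
#' Starting from the non-interacting solution (whose entropy is the
#' Shannon-Fano term), the entropy of the fitted model is
#' `S = S_SF + <E>_final - <E>_initial - Int y . dtheta`,
#' where the line integral runs along the recorded parameter path and `y`
#' is the count-space (extensive) model observable vector, the conjugate of
#' the parameters: `d log Z / d theta_a = -<y_a>`.  The integral is
#' discretised by the trapezoidal rule over consecutive snapshots.  Because
#' every term is a model average already stored during training, the entropy
#' costs no extra sampling.
#'
#' @param x a `potts_fit`, or a raw path: a list of snapshots, each a list
#'   with `theta` (flat parameters) and `x` (flat model densities at those
#'   parameters).
#' @param target target observables (defaults to the fit's); supplies the
#'   densities entering `S_SF`.
#' @param topology,layout required when `x` is a raw path.
#' @return an object of class `entropy_report`: `s_sf`, `s_maxent`,
#'   `per_site` (both divided by `n_nodes`), `normalized` (per-site over
#'   `log Q`), `integral_term`, `boundary_term`, `n_snapshots`, `n_nodes`,
#'   `n_states`.
#' @export
path_entropy <- function(x, target = NULL, topology = NULL, layout = NULL) {
  if (inherits(x, "potts_fit")) {
    path <- x$path
    layout <- x$layout
    topology <- x$topology
    if (is.null(target)) target <- x$target
  } else {
    path <- x
    if (is.null(layout) || is.null(topology) || is.null(target))
      stop("raw paths need layout, topology and target")
  }
  if (length(path) < 1L) stop("empty training path")
  Q <- layout$n_states
  n_nodes <- topology$n_nodes
  D <- layout$D
  s_target <- if (inherits(target, "potts_observables")) target$s
              else as.numeric(target)[seq_len(Q)]
  s_sf <- shannon_fano(s_target, n_nodes)

  theta1 <- path[[1L]]$theta
  if (max(abs(theta1[-seq_len(Q)])) > 1e-9)
    stop("path must start at the non-interacting solution (J = 0): ",
         "the Shannon-Fano boundary term is only valid there")

  e_mean <- function(snap) {
    if (!is.null(snap$e_mean)) snap$e_mean else sum(snap$theta * (D * snap$x))
  }
  integral <- 0
  if (length(path) >= 2L) {
    for (k in seq_len(length(path) - 1L)) {
      dtheta <- path[[k + 1L]]$theta - path[[k]]$theta
      ymid <- D * (path[[k]]$x + path[[k + 1L]]$x) / 2
      integral <- integral + sum(ymid * dtheta)
    }
  }
  boundary <- e_mean(path[[length(path)]]) - e_mean(path[[1L]])
  s_maxent <- s_sf + boundary - integral
  structure(list(s_sf = s_sf, s_maxent = s_maxent,
                 per_site = c(s_sf = s_sf, s_maxent = s_maxent) / n_nodes,
                 normalized = c(s_sf = s_sf, s_maxent = s_maxent) /
                   (n_nodes * log(Q)),
                 integral_term = integral, boundary_term = boundary,
                 n_snapshots = length(path), n_nodes = n_nodes,
                 n_states = Q),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("<entropy_report> %d nodes, Q = %d, %d path snapshots\n",
              x$n_nodes, x$n_states, x$n_snapshots))
  cat(sprintf("  S_SF     = %.6g  (%.4f ln %d per site)\n", x$s_sf,
              x$normalized[["s_sf"]], x$n_states))
  cat(sprintf("  S_MaxEnt = %.6g  (%.4f ln %d per site)\n", x$s_maxent,
              x$normalized[["s_maxent"]], x$n_states))
  invisible(x)
}

#' Check the variational entropy ordering on an enumerable system
#'
#' For systems small enough to enumerate, asserts
#' `S_exact <= S_maxent <= S_SF` within `tol` (integration and sampling
#' tolerance) and returns all three entropies.  For larger systems the check
#' is skipped with a notice.
#'
#' @param params fitted `potts_parameters` (defines the exact reference).
#' @param topology the `potts_topology`.
#' @param report an `entropy_report` from [path_entropy()].
#' @param tol absolute tolerance per site.
#' @param max_states enumeration cap.
#' @return list with `s_exact`, `s_maxent`, `s_sf`, `ok` (logical, `NA` when
#'   skipped) and `message`.
#' @export
entropy_bounds <- function(params, topology, report, tol = 1e-2,
                           max_states = 1e6) {
  n_tot <- params$n_states^topology$n_nodes
  if (n_tot > max_states) {
    return(list(s_exact = NA_real_, s_maxent = report$s_maxent,
                s_sf = report$s_sf, ok = NA,
                message = "state space too large for exact enumeration; skipped"))
  }
  ex <- enumerate_potts(params, topology, max_states = max_states)
  n <- topology$n_nodes
  ok <- (ex$entropy <= report$s_maxent + tol * n) &&
    (report$s_maxent <= report$s_sf + tol * n)
  list(s_exact = ex$entropy, s_maxent = report$s_maxent, s_sf = report$s_sf,
       ok = ok, message = if (ok) "variational ordering holds"
       else "variational ordering violated beyond tolerance")
}

#' Refined thermodynamic-integration entropy along a straight parameter line
#'
#' Entropy is path-independent, so instead of the recorded training path --
#' whose detours through poorly-mixing parameter regions inject Monte Carlo
#' bias into the quick [path_entropy()] estimate -- this estimator
#' integrates along the straight line from the non-interacting solution
#' (fields `-log` of the target densities, zero couplings) to the given
#' parameters.  Chains are annealed: the Metropolis run at each step starts
#' from the final configuration of the previous step, so the walker stays
#' in the adiabatically connected basin instead of re-quenching at every
#' point.
#'
#' @param params the fitted `potts_parameters` (the line's endpoint).
#' @param target_s per-state densities anchoring the non-interacting start
#'   (use the training densities; a `potts_observables` is accepted).
#' @param topology the `potts_topology`.
#' @param n_steps number of integration intervals (default 20).
#' @param n_samples,burn_in,stride Metropolis settings per integration
#'   point.
#' @param seed optional RNG seed.
#' @return an `entropy_report` (see [path_entropy()]).
#' @export
ti_entropy <- function(params, target_s, topology, n_steps = 20L,
                       n_samples = 1000L, burn_in = 500L, stride = 5L,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(target_s, "potts_observables")) target_s <- target_s$s
  layout <- observable_layout(params$n_states, topology)
  th0 <- params_to_theta(init_noninteracting(target_s, classes = layout$classes),
                         layout)
  th1 <- params_to_theta(params, layout)
  init <- NULL
  path <- vector("list", n_steps + 1L)
  for (k in 0:n_steps) {
    th <- th0 + (k / n_steps) * (th1 - th0)
    ens <- sample_potts(theta_to_params(th, layout), topology,
                        n_samples = n_samples, burn_in = burn_in,
                        stride = stride, init = init)
    init <- ens$states[nrow(ens$states), ]
    xm <- as.numeric(crossprod(observable_counts(ens, layout),
                               rep(1 / nrow(ens$states), nrow(ens$states)))) /
      layout$D
    path[[k + 1L]] <- list(theta = th, x = xm)
  }
  target_flat <- c(target_s, rep(NA_real_, layout$M - layout$n_states))
  path_entropy(path, target = target_flat, topology = topology,
               layout = layout)
}
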