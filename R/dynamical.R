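#' Time-extended network for dynamical maximum entropy
#'
#' A time sequence of configurations on a base network is modelled as a
#' single configuration on an extended network with one copy of the base
#' graph per timestep.  Spatial edges are replicated in every frame (class
#' `"spatial"`); temporal edges (class `"temporal"`) join each node to its
#' own copy at the next timestep, so the temporal couple densities are the
#' self-time correlations -- their off-diagonal mass is the probability of a
#' node changing state between consecutive timesteps.  Node `(k, t)` of the
#' base network maps to extended index `t * n_base + k` (0-based).
#'
#' The extended link count is
#' `T * n_links_base + (T - 1) * n_nodes_base`.
#'
#' @param base a `potts_topology`.
#' @param n_time number of timesteps T (>= 2).
#' @return a `potts_topology` whose edges carry `spatial` / `temporal`
#'   class labels; `metadata` records the base topology and T.
#' @export
extend_topology <- function(base, n_time) {
  n_time <- as.integer(n_time)
  if (n_time < 2L) stop("a temporal network needs at least 2 timesteps")
  n <- base$n_nodes
  sp_from <- integer(0); sp_to <- integer(0)
  if (base$n_links > 0L) {
    offs <- rep((0:(n_time - 1L)) * n, each = base$n_links)
    sp_from <- rep(base$edges[, 1L], n_time) + offs
    sp_to <- rep(base$edges[, 2L], n_time) + offs
  }
  tm_from <- rep(0:(n_time - 2L) * n, each = n) + rep(0:(n - 1L), n_time - 1L)
  tm_to <- tm_from + n
  edges <- rbind(cbind(sp_from, sp_to), cbind(tm_from, tm_to))
  cls <- c(rep("spatial", length(sp_from)), rep("temporal", length(tm_from)))
  potts_topology(n_time * n, edges, edge_class = cls,
                 metadata = list(base = base, n_time = n_time))
}

#' Flatten a time series to a configuration on the extended network
#'
#' @param series integer matrix, T rows (timesteps) by `n_base` columns
#'   (nodes), states 0-based.
#' @return integer vector of length `T * n_base` in the extended indexing
#'   (frame t occupies positions `t*n_base + 1 .. (t+1)*n_base`).
#' @export
series_to_config <- function(series) {
  if (is.null(dim(series))) series <- matrix(as.integer(series), ncol = 1L)
  as.integer(as.vector(t(series)))
}

#' Reshape an extended-network configuration back into a T x n matrix
#' @param config flat configuration on the extended network.
#' @param n_base number of base nodes.
#' @return integer matrix with one timestep per row.
#' @export
config_to_series <- function(config, n_base) {
  matrix(as.integer(config), ncol = n_base, byrow = TRUE)
}

#' Fit a dynamical maximum-entropy model to time sequences
#'
#' Runs the static training loop on the time-extended network: one coupling
#' matrix per edge class (`J$spatial`, `J$temporal`), spatial couplings tied
#' across timesteps (stationarity), temporal couplings constraining the full
#' Q x Q self-time couple matrix.  A single time sequence is a legitimate
#' training set (the observable covariance is then estimated from a model
#' ensemble at the non-interacting start; see [fit_potts()]).
#'
#' @param series a T x n_base integer matrix, or a list of such matrices
#'   (one training sequence each, equal dimensions).
#' @param base the base `potts_topology`.
#' @param n_states state-alphabet size Q.
#' @param ... passed to [fit_potts()] (`eta`, `chi2_threshold`, sampler
#'   settings, `seed`, ...).
#' @return a `potts_fit` on the extended topology; `$params$J` has separate
#'   `spatial` and `temporal` blocks (spatial absent if the base graph has
#'   no links).
#' @export
fit_dynamical <- function(series, base, n_states, ...) {
  if (is.matrix(series)) series <- list(series)
  stopifnot(length(series) >= 1L)
  dims <- vapply(series, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != base$n_nodes))
    stop("all series must be T x n_base with the base node count")
  n_time <- dims[1L, 1L]
  ext <- extend_topology(base, n_time)
  states <- do.call(rbind, lapply(series, function(s) series_to_config(s)))
  ens <- potts_ensemble(states, n_states, ext)
  fit <- fit_potts(ens, ...)
  fit$base <- base
  fit$n_time <- n_time
  fit
}

#' Dynamical entropy of a fitted time-sequence model
#'
#' The Shannon entropy of the distribution over whole time sequences,
#' computed by thermodynamic integration along the training path on the
#' extended network.  `per_site` and `normalized` are per base-node per
#' timestep (the extended network has `T * n_base` nodes), so an i.i.d.
#' uniform process scores `log Q` per node-step and a frozen trajectory
#' scores 0.
#'
#' @param fit a fit from [fit_dynamical()].
#' @param ... passed to [path_entropy()].
#' @return an `entropy_report`.
#' @export
dynamical_entropy <- function(fit, ...) {
  path_entropy(fit, ...)
}
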