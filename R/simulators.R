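#' Random Hopfield connectivity matrix
#'
#' Builds the N x N coupling matrix `J = (1 - eps/2) S + (eps/2) A`, where
#' `S` is symmetric and `A` antisymmetric, both with off-diagonal entries
#' drawn uniformly from \[-1, 1\] and zero diagonal (no autapses).  `eps = 0`
#' gives a symmetric network, `eps = 2` a fully antisymmetric one.
#'
#' Dilution removes unordered neuron pairs (both `J_ij` and `J_ji`) with
#' probability `d`, so `d = 0` is fully connected; element-wise removal is
#' available with `pairwise_dilution = FALSE`.
#'
#' @param n_neurons N.
#' @param epsilon asymmetry in \[0, 2\].
#' @param dilution removal probability d in \[0, 1\].
#' @param eta per-neuron firing thresholds (scalar or length-N, default 0).
#' @param pairwise_dilution remove unordered pairs together (default) or
#'   individual matrix elements.
#' @param seed optional RNG seed.
#' @return an object of class `hopfield_network`: `n`, `J`, `epsilon`,
#'   `dilution`, `eta`, `seed`.
#' @export
hopfield_network <- function(n_neurons, epsilon = 0, dilution = 0, eta = 0,
                             pairwise_dilution = TRUE, seed = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 2, dilution >= 0, dilution <= 1,
            n_neurons >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_neurons)
  S <- matrix(0, n, n); A <- matrix(0, n, n)
  up <- upper.tri(S)
  S[up] <- stats::runif(sum(up), -1, 1)
  S <- S + t(S)
  A[up] <- stats::runif(sum(up), -1, 1)
  A <- A - t(A)
  J <- (1 - epsilon / 2) * S + (epsilon / 2) * A
  if (dilution > 0) {
    if (pairwise_dilution) {
      drop <- matrix(FALSE, n, n)
      drop[up] <- stats::runif(sum(up)) < dilution
      drop <- drop | t(drop)
    } else {
      drop <- matrix(stats::runif(n * n) < dilution, n, n)
      diag(drop) <- FALSE
    }
    J[drop] <- 0
  }
  if (length(eta) == 1L) eta <- rep(eta, n)
  stopifnot(length(eta) == n)
  structure(list(n = n, J = J, epsilon = epsilon, dilution = dilution,
                 eta = eta, seed = seed),
            class = "hopfield_network")
}

#' One synchronous Hopfield update
#'
#' `sigma_i(t+1) = theta(sum_j J_ij sigma_j(t) - eta_i)` with the sign
#' threshold `theta`; an input of exactly zero resolves to -1 or +1 with
#' equal probability (the RNG tie rule).
#'
#' @param sigma current +/-1 activation vector.
#' @param network a `hopfield_network`.
#' @return next +/-1 activation vector.
#' @export
hopfield_step <- function(sigma, network) {
  stopifnot(all(sigma %in% c(-1, 1)), length(sigma) == network$n)
  input <- as.numeric(network$J %*% sigma) - network$eta
  nxt <- sign(input)
  ties <- nxt == 0
  if (any(ties)) nxt[ties] <- sample(c(-1, 1), sum(ties), replace = TRUE)
  nxt
}

#' Simulate a Hopfield trajectory
#'
#' Runs `transient + n_time` synchronous updates from a random (or given)
#' initial profile and records the last `n_time` frames, mapped from
#' \{-1, +1\} to \{0, 1\} states (`-1 -> 0`) for maximum-entropy fitting.
#' For deterministic runs (no exact-zero inputs) the finite-state dynamics
#' is eventually periodic; recurrence within the recorded window is
#' detected and reported.
#'
#' @param network a `hopfield_network`.
#' @param n_time frames to record (>= 2).
#' @param sigma0 optional initial +/-1 profile (default random).
#' @param transient updates discarded before recording (default 0).
#' @param seed optional RNG seed.
#' @return an integer `n_time x N` matrix in \{0, 1\} with attributes
#'   `mapping` (`"-1->0, +1->1"`) and `cycle` (list: `detected`, `length`,
#'   `first_return`; `length` 1 means a fixed point).
#' @export
hopfield_trajectory <- function(network, n_time, sigma0 = NULL, transient = 0,
                                seed = NULL) {
  stopifnot(n_time >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- network$n
  sigma <- if (is.null(sigma0)) sample(c(-1, 1), n, replace = TRUE)
           else { stopifnot(all(sigma0 %in% c(-1, 1)), length(sigma0) == n); sigma0 }
  for (t in seq_len(transient)) sigma <- hopfield_step(sigma, network)
  out <- matrix(0L, n_time, n)
  keys <- character(n_time)
  cycle <- list(detected = FALSE, length = NA_integer_, first_return = NA_integer_)
  for (t in seq_len(n_time)) {
    out[t, ] <- as.integer((sigma + 1) / 2)
    keys[t] <- paste(out[t, ], collapse = "")
    if (!cycle$detected && t > 1L) {
      prev <- match(keys[t], keys[seq_len(t - 1L)])
      if (!is.na(prev)) {
        cycle <- list(detected = TRUE, length = t - prev, first_return = t)
      }
    }
    sigma <- hopfield_step(sigma, network)
  }
  attr(out, "mapping") <- "-1->0, +1->1"
  attr(out, "cycle") <- cycle
  out
}

#' Parameters of the predator-prey lattice ecosystem
#'
#' A minimal two-species agent model on a periodic L x L lattice with three
#' site states: 0 environment, 1 prey (fish), 2 predator (shark).  The rule
#' set (this package's own choice of a Wa-Tor-class dynamics): each step
#' visits all agents in random order; a fish moves to a uniformly random
#' empty neighbour with probability `p_fish_move` and breeds into its
#' vacated site with probability `p_fish_breed`; a shark eats a uniformly
#' random neighbouring fish when one exists (resetting its starvation
#' clock), otherwise moves to an empty neighbour with probability
#' `p_shark_move` (the predator mobility), breeds into its vacated site with
#' probability `p_shark_breed`, and dies after `shark_starve` consecutive
#' steps without eating.
#'
#' @param L lattice edge.
#' @param p_fish_move,p_fish_breed,p_shark_move,p_shark_breed per-step
#'   probabilities in \[0, 1\].
#' @param shark_starve starvation horizon in steps.
#' @param init_fish,init_shark initial occupation densities.
#' @param n_steps simulated steps after burn-in.
#' @param burn_in discarded initial steps.
#' @param record_stride steps between recorded snapshots.
#' @param seed optional RNG seed.
#' @return a list of validated parameters, class `ecolat_params`.
#' @export
ecolat_params <- function(L = 20L, p_fish_move = 0.9, p_fish_breed = 0.6,
                          p_shark_move = 0.7, p_shark_breed = 0.1,
                          shark_starve = 3L, init_fish = 0.35,
                          init_shark = 0.05, n_steps = 200L, burn_in = 100L,
                          record_stride = 5L, seed = NULL) {
  p <- list(L = as.integer(L), p_fish_move = p_fish_move,
            p_fish_breed = p_fish_breed, p_shark_move = p_shark_move,
            p_shark_breed = p_shark_breed, shark_starve = as.integer(shark_starve),
            init_fish = init_fish, init_shark = init_shark,
            n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
            record_stride = as.integer(record_stride), seed = seed)
  probs <- unlist(p[c("p_fish_move", "p_fish_breed", "p_shark_move",
                      "p_shark_breed", "init_fish", "init_shark")])
  stopifnot(all(probs >= 0), all(probs <= 1), init_fish + init_shark <= 1,
            p$L >= 3L, p$shark_starve >= 1L)
  structure(p, class = "ecolat_params")
}

#' Simulate the predator-prey lattice ecosystem
#'
#' Runs the agent dynamics of [ecolat_params()] and records snapshots of the
#' lattice in the non-equilibrium steady state.  Absorbing outcomes are
#' detected and flagged instead of being passed off as a steady state:
#' `"fish_saturation"` when the sharks die out, `"extinction"` when the prey
#' do (the remaining sharks then starve deterministically).
#'
#' @param params an `ecolat_params`.
#' @return list with `ensemble` (a `potts_ensemble` of snapshots on the
#'   periodic L x L lattice; `NULL` if absorbed before any snapshot),
#'   `absorbing` (`NULL` or the flag), `absorbed_at` (step index or `NA`),
#'   `densities` (per-step fish/shark density trace), `params`.
#' @export
ecolat_simulate <- function(params) {
  stopifnot(inherits(params, "ecolat_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  L <- params$L
  n <- L * L
  topo <- lattice_topology(c(L, L), periodic = TRUE)
  grid <- rep(0L, n)
  occ <- sample(n, round((params$init_fish + params$init_shark) * n))
  n_fish0 <- round(params$init_fish * n)
  grid[occ[seq_len(min(n_fish0, length(occ)))]] <- 1L
  if (length(occ) > n_fish0) grid[occ[(n_fish0 + 1L):length(occ)]] <- 2L
  hunger <- integer(n)                       # starvation clock per shark site

  # periodic 4-neighbourhood lookup (1-based site indices)
  row <- (seq_len(n) - 1L) %/% L
  col <- (seq_len(n) - 1L) %% L
  nb <- cbind(((row + 1L) %% L) * L + col, ((row - 1L) %% L) * L + col,
              row * L + (col + 1L) %% L, row * L + (col - 1L) %% L) + 1L

  total_steps <- params$burn_in + params$n_steps
  snapshots <- list()
  dens <- matrix(NA_real_, total_steps, 2L,
                 dimnames = list(NULL, c("fish", "shark")))
  absorbing <- NULL; absorbed_at <- NA_integer_

  for (step in seq_len(total_steps)) {
    agents <- which(grid != 0L)
    if (length(agents) > 1L) agents <- sample(agents)
    for (site in agents) {
      state <- grid[site]
      if (state == 0L) next                  # already moved/eaten this step
      nbs <- nb[site, ]
      if (state == 1L) {                     # fish
        empty <- nbs[grid[nbs] == 0L]
        if (length(empty) && stats::runif(1) < params$p_fish_move) {
          dest <- if (length(empty) == 1L) empty else sample(empty, 1L)
          grid[dest] <- 1L
          grid[site] <- if (stats::runif(1) < params$p_fish_breed) 1L else 0L
        }
      } else {                               # shark
        hunger[site] <- hunger[site] + 1L
        fish <- nbs[grid[nbs] == 1L]
        moved <- FALSE; dest <- site
        if (length(fish)) {
          dest <- if (length(fish) == 1L) fish else sample(fish, 1L)
          grid[dest] <- 2L
          hunger[dest] <- 0L
          moved <- TRUE
        } else {
          if (hunger[site] >= params$shark_starve) { grid[site] <- 0L; hunger[site] <- 0L; next }
          empty <- nbs[grid[nbs] == 0L]
          if (length(empty) && stats::runif(1) < params$p_shark_move) {
            dest <- if (length(empty) == 1L) empty else sample(empty, 1L)
            grid[dest] <- 2L
            hunger[dest] <- hunger[site]
            moved <- TRUE
          }
        }
        if (moved) {
          # vacated site: newborn shark (hunger 0) or empty
          grid[site] <- if (stats::runif(1) < params$p_shark_breed) 2L else 0L
          hunger[site] <- 0L
        }
      }
    }
    dens[step, ] <- c(mean(grid == 1L), mean(grid == 2L))
    if (!any(grid == 2L)) { absorbing <- "fish_saturation"; absorbed_at <- step; break }
    if (!any(grid == 1L)) { absorbing <- "extinction"; absorbed_at <- step; break }
    if (step > params$burn_in &&
        (step - params$burn_in) %% params$record_stride == 0L) {
      snapshots[[length(snapshots) + 1L]] <- grid
    }
  }

  ensemble <- if (length(snapshots))
    potts_ensemble(do.call(rbind, snapshots), 3L, topo) else NULL
  list(ensemble = ensemble, absorbing = absorbing, absorbed_at = absorbed_at,
       densities = dens[seq_len(min(which(is.na(dens[, 1L]))[1L] - 1L,
                                    total_steps, na.rm = TRUE)), , drop = FALSE],
       params = params)
}

#' Draw a ground-truth ensemble from known Potts parameters
#'
#' Test-fixture generator for parameter-recovery experiments: i.i.d. draws
#' from the exact Boltzmann table (`method = "exact"`, enumerable systems
#' only) or thinned Metropolis draws (`method = "metropolis"`).
#'
#' @param params a `potts_parameters`.
#' @param topology a `potts_topology`.
#' @param n_conf configurations to draw.
#' @param method `"exact"` or `"metropolis"`.
#' @param seed optional RNG seed.
#' @param ... passed to [sample_potts()] for the Metropolis method.
#' @return a `potts_ensemble`; `attr(, "generator")` records how it was made.
#' @export
generate_potts_ensemble <- function(params, topology, n_conf,
                                    method = c("exact", "metropolis"),
                                    seed = NULL, ...) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "exact") {
    ex <- enumerate_potts(params, topology)
    idx <- sample.int(nrow(ex$configs), n_conf, replace = TRUE, prob = ex$prob)
    ens <- potts_ensemble(ex$configs[idx, , drop = FALSE], params$n_states, topology)
  } else {
    ens <- sample_potts(params, topology, n_samples = n_conf, ...)
  }
  attr(ens, "generator") <- list(method = method, seed = seed)
  ens
}

#' Dynamical-entropy scan over Hopfield network asymmetry
#'
#' The recurrent-network experiment: for each asymmetry value epsilon,
#' generate random connectivity matrices, run synchronous trajectories from
#' random initial profiles, fit the dynamical maximum-entropy model to every
#' single-neuron trajectory, and average the normalized dynamical entropy
#' (per node-step, in units of ln 2).  Fully connected symmetric networks
#' relax into fixed points or short cycles (entropy near 0); strongly
#' asymmetric ones are chaotic (entropy near 1); the mean entropy rises
#' abruptly along the asymmetry axis.
#'
#' @param eps_grid asymmetry values to scan.
#' @param n_real random network realizations per grid point.
#' @param n_neurons network size N (default 20).
#' @param dilution connection-removal probability (default 0, fully
#'   connected).
#' @param n_time recorded trajectory length per realization (default 200).
#' @param transient discarded initial updates (default 100).
#' @param seed base RNG seed; realization seeds are derived from it.
#' @param n_samples,burn_in,stride Metropolis settings for the per-neuron
#'   fits (defaults sized for the single-neuron chain problems).
#' @return matrix `length(eps_grid) x n_real` of mean normalized entropies
#'   (rows named by epsilon); `attr(, "per_neuron")` keeps the full
#'   epsilon x realization x neuron array.
#' @export
hopfield_entropy_scan <- function(eps_grid, n_real = 3L, n_neurons = 20L,
                                  dilution = 0, n_time = 200L,
                                  transient = 100L, seed = 1L,
                                  n_samples = 800L, burn_in = 200L,
                                  stride = 2L) {
  base <- potts_topology(1L, matrix(integer(0), 0, 2))
  out <- matrix(NA_real_, length(eps_grid), n_real,
                dimnames = list(paste0("eps", eps_grid), NULL))
  per_neuron <- array(NA_real_, c(length(eps_grid), n_real, n_neurons))
  for (e in seq_along(eps_grid)) {
    for (r in seq_len(n_real)) {
      sd_er <- (seed * 1000L + e * 100L + r) %% .Machine$integer.max
      net <- hopfield_network(n_neurons, epsilon = eps_grid[e],
                              dilution = dilution, seed = sd_er)
      traj <- hopfield_trajectory(net, n_time, transient = transient,
                                  seed = sd_er + 1L)
      for (k in seq_len(n_neurons)) {
        fit <- fit_dynamical(traj[, k, drop = FALSE], base, 2L,
                             n_samples = n_samples, burn_in = burn_in,
                             stride = stride, seed = sd_er + 10L + k)
        per_neuron[e, r, k] <- dynamical_entropy(fit)$normalized[["s_maxent"]]
      }
      out[e, r] <- mean(per_neuron[e, r, ])
    }
  }
  attr(out, "per_neuron") <- per_neuron
  out
}

#' Locate the steepest rise along a scanned curve
#'
#' Returns the grid value at which the increment to the next grid point is
#' largest -- the onset of the abrupt change along the scan.
#'
#' @param grid ordered grid values.
#' @param values curve values at the grid points.
#' @return the grid value where the largest increment begins.
#' @export
steepest_rise <- function(grid, values) {
  stopifnot(length(grid) == length(values), length(grid) >= 2L)
  grid[which.max(diff(values))]
}
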