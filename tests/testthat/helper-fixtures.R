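# Shared fixtures: tiny systems small enough for exact enumeration.

path_topology <- function(n) lattice_topology(n, periodic = FALSE)

one_node_topology <- function() potts_topology(1, matrix(integer(0), 0, 2))

# reference parameters on Q = 2 used across trainer/entropy tests
toy_params_q2 <- function() {
  potts_parameters(c(0, 0.4), matrix(c(-0.6, 0.3, 0.3, -0.2), 2, 2))
}

# the published four-state interaction example (states black, green, red,
# blue); used as a report-format fixture
tissue_example_params <- function() {
  h <- c(0.64, 1.54, 4.30, 2.23)
  J <- rbind(c(-0.112, 0.320, -0.036, 0.532),
             c(0.320, -0.442, 0.318, 0.247),
             c(-0.036, 0.318, 0.047, 0.060),
             c(0.532, 0.247, 0.060, -0.927))
  potts_parameters(h, J, 4L)
}

# clustered-tissue interaction structure: blue mildly self-attracting,
# strongly attracted to green and repelled by the background, and the
# background anchored to red (qualitatively the published pattern).  The
# couplings to *visible* classes carry the spatial information used by
# missing-state inference: they survive conditioning, whereas hidden-class
# self-clustering is largely exchangeable across the free region.
tissue_couplings <- function() {
  J <- matrix(0, 4, 4)
  J[4, 4] <- -0.3
  J[2, 4] <- J[4, 2] <- -0.9
  J[1, 4] <- J[4, 1] <- 0.6
  J[1, 3] <- J[3, 1] <- -0.6
  J
}

tissue_densities <- function() c(0.3, 0.3, 0.25, 0.15)

# two-state single-node Markov chain with flip probability p
markov_chain_series <- function(n_time, p_flip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- integer(n_time)
  s[1] <- stats::rbinom(1, 1, 0.5)
  for (t in 2:n_time) {
    s[t] <- if (stats::runif(1) < p_flip) 1L - s[t - 1L] else s[t - 1L]
  }
  matrix(s, ncol = 1)
}

# total variation distance between an empirical ensemble and an exact table
tv_distance <- function(ensemble, enumeration) {
  Q <- ensemble$n_states
  n <- ncol(ensemble$states)
  code <- as.numeric(ensemble$states %*% Q^(seq_len(n) - 1L))
  emp <- tabulate(code + 1L, Q^n) / nrow(ensemble$states)
  # enumeration configs are built with node n varying slowest; recompute its
  # codes the same way to align the two tables
  ecode <- as.numeric(enumeration$configs %*% Q^(seq_len(n) - 1L)) + 1L
  exact <- numeric(Q^n)
  exact[ecode] <- enumeration$prob
  0.5 * sum(abs(emp - exact))
}
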