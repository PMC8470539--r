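test_that("energies follow the density-unit Hamiltonian and its extensive form", {
  topo <- lattice_topology(c(3, 3), periodic = TRUE)
  set.seed(7)
  states <- sample(0:2, 9, replace = TRUE)

  zero <- potts_parameters(rep(0, 3), matrix(0, 3, 3))
  expect_equal(potts_energy(states, zero, topo), 0)
  expect_equal(potts_energy(states, zero, topo, scale = "density"), 0)

  h <- c(0.3, -1, 2)
  field_only <- potts_parameters(h, matrix(0, 3, 3))
  expect_equal(potts_energy(states, field_only, topo, scale = "density"),
               sum(h * state_density(states, 3)))
  expect_equal(potts_energy(states, field_only, topo),
               sum(h[states + 1]))
})

test_that("the published four-state example evaluates term by term", {
  params <- tissue_example_params()
  topo <- lattice_topology(c(3, 3), periodic = FALSE)
  set.seed(8)
  states <- sample(0:3, 9, replace = TRUE)
  s <- state_density(states, 4)
  cm <- pair_density(states, topo, 4)
  ref <- sum(params$h * s)
  for (i in 1:4) for (j in i:4) ref <- ref + params$J$spatial[i, j] * cm[i, j] *
    (if (i == j) 1 else 1)          # upper-triangle convention: each pair once
  expect_equal(potts_energy(states, params, topo, scale = "density"), ref)
})

test_that("local energy deltas match global re-evaluation", {
  topo <- lattice_topology(c(3, 3), periodic = TRUE)
  params <- potts_parameters(c(0.2, -0.4, 0.1),
                             matrix(c(-1, 0.5, 0, 0.5, 0.3, -0.2, 0, -0.2, 0.8), 3, 3))
  set.seed(9)
  states <- sample(0:2, 9, replace = TRUE)

  expect_equal(energy_delta(states, 0L, states[1], params, topo), 0)

  single <- one_node_topology()
  p1 <- potts_parameters(c(0, 2), matrix(0, 2, 2))
  expect_equal(energy_delta(0L, 0L, 1L, p1, single), 2)

  for (r in 1:10) {
    node <- sample(0:8, 1)
    new <- sample(setdiff(0:2, states[node + 1]), 1)
    s2 <- states; s2[node + 1] <- new
    expect_equal(energy_delta(states, node, new, params, topo),
                 potts_energy(s2, params, topo) - potts_energy(states, params, topo),
                 tolerance = 1e-12)
  }
})

test_that("Metropolis sampling is uniform when the Hamiltonian vanishes", {
  topo <- lattice_topology(c(2, 2), periodic = FALSE)
  params <- potts_parameters(c(0, 0), matrix(0, 2, 2))
  ens <- sample_potts(params, topo, n_samples = 4000, burn_in = 100,
                      stride = 1, seed = 12)
  freq <- mean(ens$states == 0)
  n <- length(ens$states)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / n) * 5)  # generous: samples correlate
})

test_that("Metropolis matches exact enumeration on an antiferromagnetic pair", {
  # moderate coupling: strong enough to order the pair, weak enough that
  # single-site dynamics still crosses the barrier and mixes
  topo <- path_topology(2)
  params <- potts_parameters(c(0, 0), matrix(c(1.5, -1.5, -1.5, 1.5), 2, 2))
  ex <- enumerate_potts(params, topo)
  ens <- sample_potts(params, topo, n_samples = 20000, burn_in = 200,
                      stride = 2, seed = 13)
  expect_lt(tv_distance(ens, ex), 0.02)
})

test_that("sampling is deterministic given a seed", {
  topo <- lattice_topology(c(3, 3), periodic = TRUE)
  params <- toy_params_q2()
  e1 <- sample_potts(params, topo, n_samples = 50, burn_in = 50, seed = 99)
  e2 <- sample_potts(params, topo, n_samples = 50, burn_in = 50, seed = 99)
  expect_identical(e1$states, e2$states)
})

test_that("exact enumeration reproduces closed forms and the sampler", {
  topo <- lattice_topology(c(2, 2), periodic = FALSE)
  zero <- potts_parameters(c(0, 0), matrix(0, 2, 2))
  ex0 <- enumerate_potts(zero, topo)
  expect_equal(sum(ex0$prob), 1)
  expect_equal(ex0$entropy, 4 * log(2))
  expect_equal(max(ex0$prob) - min(ex0$prob), 0, tolerance = 1e-14)

  set.seed(14)
  params <- potts_parameters(stats::rnorm(3, 0, 0.5),
                             { m <- matrix(stats::rnorm(9, 0, 0.5), 3, 3); (m + t(m)) / 2 })
  ex <- enumerate_potts(params, topo)
  expect_equal(sum(ex$prob), 1)
  ens <- sample_potts(params, topo, n_samples = 30000, burn_in = 200,
                      stride = 1, seed = 15)
  emp <- ensemble_observables(ens)
  expect_lt(max(abs(emp$flat - ex$observables$flat)), 0.015)

  expect_error(enumerate_potts(params, lattice_topology(c(20, 20)), max_states = 1e4),
               "use sample_potts")
})

test_that("field gauge shifts leave exact probabilities unchanged", {
  topo <- path_topology(3)
  params <- toy_params_q2()
  shifted <- potts_parameters(params$h + 1.7, params$J)
  expect_equal(enumerate_potts(params, topo)$prob,
               enumerate_potts(shifted, topo)$prob, tolerance = 1e-12)
})

test_that("single-site proposals satisfy detailed balance numerically", {
  topo <- lattice_topology(c(2, 2), periodic = FALSE)
  params <- toy_params_q2()
  ex <- enumerate_potts(params, topo)
  set.seed(16)
  for (r in 1:20) {
    i <- sample(nrow(ex$configs), 1)
    sa <- ex$configs[i, ]
    node <- sample(0:3, 1)
    sb <- sa; sb[node + 1] <- 1L - sb[node + 1]
    d <- energy_delta(sa, node, sb[node + 1], params, topo)
    lhs <- exp(ex$log_prob[i]) * min(1, exp(-d))
    j <- which(colSums(abs(t(ex$configs) - sb)) == 0)
    rhs <- exp(ex$log_prob[j]) * min(1, exp(d))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("clamped marginals reduce to closed forms and conditional enumeration", {
  # all nodes clamped but one, J = 0: free marginal is the single-site weight
  topo <- path_topology(3)
  h <- c(0.5, -0.3)
  params <- potts_parameters(h, matrix(0, 2, 2))
  clamped <- c(0L, NA, 1L)
  marg <- conditional_marginals(params, topo, clamped, n_samples = 4000,
                                burn_in = 100, stride = 1, seed = 17)
  boltz <- exp(-h) / sum(exp(-h))
  expect_equal(marg[1, ], c(1, 0), ignore_attr = TRUE)
  expect_equal(marg[3, ], c(0, 1), ignore_attr = TRUE)
  expect_lt(max(abs(marg[2, ] - boltz)), 0.03)

  # 2x3 open lattice, 2 clamped nodes: compare to conditional probabilities
  # from the enumeration oracle
  topo2 <- lattice_topology(c(2, 3), periodic = FALSE)
  params2 <- toy_params_q2()
  clamp2 <- c(0L, NA, NA, NA, 1L, NA)
  ex <- enumerate_potts(params2, topo2)
  keep <- ex$configs[, 1] == 0L & ex$configs[, 5] == 1L
  condp <- ex$prob[keep] / sum(ex$prob[keep])
  cond_marg <- t(vapply(1:6, function(k)
    vapply(0:1, function(q) sum(condp[ex$configs[keep, k] == q]), 0), c(0, 0)))
  marg2 <- conditional_marginals(params2, topo2, clamp2, n_samples = 20000,
                                 burn_in = 200, stride = 1, seed = 18)
  expect_lt(max(abs(marg2 - cond_marg)), 0.02)
})

test_that("attraction to a clamped cluster decays with graph distance", {
  # strongly attractive state-1/state-1 coupling on a path; one end clamped
  topo <- path_topology(6)
  J <- matrix(c(0, 0, 0, -2.5), 2, 2)
  params <- potts_parameters(c(0, 0), J)
  clamped <- c(1L, NA, NA, NA, NA, NA)
  ex <- enumerate_potts(params, topo)
  keep <- ex$configs[, 1] == 1L
  condp <- ex$prob[keep] / sum(ex$prob[keep])
  p1 <- vapply(2:6, function(k) sum(condp[ex$configs[keep, k] == 1L]), 0)
  expect_true(all(diff(p1) < 0))

  marg <- conditional_marginals(params, topo, clamped, n_samples = 20000,
                                burn_in = 200, stride = 1, seed = 19)
  expect_lt(max(abs(marg[2:6, 2] - p1)), 0.02)
})
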