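test_that("the non-interacting start reproduces target densities", {
  expect_equal(init_noninteracting(c(0.5, 0.5))$h, c(log(2), log(2)))
  expect_equal(init_noninteracting(rep(0.25, 4))$h, rep(log(4), 4))

  # one-node oracle: marginals equal the target densities exactly
  p <- init_noninteracting(c(0.7, 0.2, 0.1))
  ex <- enumerate_potts(p, one_node_topology())
  expect_equal(ex$observables$s, c(0.7, 0.2, 0.1), tolerance = 1e-12)

  # on any graph the init is the product distribution with those marginals
  topo <- path_topology(3)
  ex3 <- enumerate_potts(init_noninteracting(c(0.7, 0.3)), topo)
  expect_equal(ex3$observables$s, c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(ex3$entropy, shannon_fano(c(0.7, 0.3), 3), tolerance = 1e-12)

  pinned <- init_noninteracting(c(0.5, 0.5, 0))
  expect_equal(pinned$h[3], 30)
  expect_error(init_noninteracting(c(0, 0)), "all target densities")
})

test_that("reweighting reduces to uniform at the anchor and is gauge invariant", {
  topo <- lattice_topology(c(2, 3), periodic = FALSE)
  params <- toy_params_q2()
  ens <- sample_potts(params, topo, n_samples = 200, burn_in = 100, seed = 23)

  expect_equal(reweight_ensemble(ens, params, params), rep(1 / 200, 200))

  shifted <- potts_parameters(params$h + 0.9, params$J)
  pert <- potts_parameters(params$h, lapply(params$J, function(m) m + 0.05))
  expect_equal(reweight_ensemble(ens, pert, params),
               reweight_ensemble(ens, potts_parameters(pert$h + 0.9, pert$J),
                                 params), tolerance = 1e-12)
  expect_equal(reweight_ensemble(ens, shifted, params), rep(1 / 200, 200))
})

test_that("reweighted observables track a fresh run at perturbed parameters", {
  topo <- lattice_topology(c(2, 3), periodic = FALSE)
  params <- toy_params_q2()
  ens <- sample_potts(params, topo, n_samples = 4000, burn_in = 300,
                      stride = 2, seed = 24)
  pert <- potts_parameters(params$h,
                           lapply(params$J, function(m) m + matrix(c(0.1, -0.05, -0.05, 0.08), 2, 2)))
  rho <- reweight_ensemble(ens, pert, params)
  layout <- observable_layout(2, topo)
  Y <- observable_counts(ens, layout)
  rew <- as.numeric(crossprod(Y, rho)) / layout$D
  exact <- enumerate_potts(pert, topo)$observables$flat
  expect_lt(max(abs(rew - exact)), 0.02)
})

test_that("effective sample ratio matches its closed forms", {
  expect_equal(effective_sample_ratio(rep(0.1, 10)), 1)
  expect_equal(effective_sample_ratio(c(1, rep(0, 9))), 0.1)
  expect_equal(effective_sample_ratio(c(2, 1, 1)), 16 / 18)
  expect_error(effective_sample_ratio(rep(0, 4)), "zero")
})

test_that("chi-squared respects the gauge projection", {
  pr <- gauge_projector(diag(4))
  x <- c(0.3, 0.3, 0.2, 0.2)
  expect_equal(chi_square(x, x, pr)$chi2, 0)
  expect_equal(chi_square(c(0.1, -0.1, 0, 0) + x, x, pr)$chi2, 0.02)
  expect_equal(chi_square(x, x, pr)$dof, 4L)

  # residual entirely in the kernel scores zero
  S <- matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2)
  pk <- gauge_projector(S)
  expect_equal(chi_square(c(0.6, 0.6), c(0.5, 0.5), pk)$chi2, 0,
               tolerance = 1e-12)
  expect_error(chi_square(c(1, 2, 3), c(1, 2), pr), "mismatch")
})

test_that("the analytic gradient agrees with finite differences", {
  topo <- lattice_topology(c(2, 2), periodic = FALSE)
  layout <- observable_layout(2, topo)
  gen <- toy_params_q2()
  ens <- generate_potts_ensemble(gen, topo, 400, method = "exact", seed = 25)
  target <- ensemble_observables(ens)
  proj <- gauge_projector(observable_covariance(ens) / 400)
  anchor <- potts_parameters(c(0.25, 0), matrix(c(0.1, 0, 0, 0), 2, 2))
  aens <- sample_potts(anchor, topo, n_samples = 1500, burn_in = 300, seed = 26)

  chi2_at <- function(th) {
    p <- theta_to_params(th, layout)
    rho <- reweight_ensemble(aens, p, anchor)
    Y <- observable_counts(aens, layout)
    xm <- as.numeric(crossprod(Y, rho)) / layout$D
    chi_square(target$flat, xm, proj)$chi2
  }
  th <- params_to_theta(potts_parameters(c(0.21, 0.02),
                                         matrix(c(0.12, 0.01, 0.01, -0.02), 2, 2)),
                        layout)
  g <- chi_square_gradient(theta_to_params(th, layout), target, aens, proj,
                           anchor)
  gfd <- vapply(seq_along(th), function(k) {
    e <- rep(0, length(th)); e[k] <- 1e-5
    (chi2_at(th + e) - chi2_at(th - e)) / 2e-5
  }, 0)
  gfd <- as.numeric(proj$projector %*% gfd)
  expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-4)

  # at the exact solution the gradient vanishes
  ex <- enumerate_potts(gen, topo)
  g0 <- chi_square_gradient(gen, ex$observables,
                            generate_potts_ensemble(gen, topo, 2000,
                                                    method = "exact", seed = 27),
                            proj)
  # stochastic zero: compare against the gradient scale away from optimum
  expect_lt(max(abs(g0)), 0.05 * max(abs(g)))

  # no gradient component along kernel eigen-directions
  for (k in which(proj$kernel)) {
    expect_lt(abs(sum(g * proj$vectors[, k])), 1e-10)
  }
})

test_that("fitting a non-interacting target converges at once with J = 0", {
  topo <- lattice_topology(c(2, 3), periodic = FALSE)
  gen <- init_noninteracting(c(0.65, 0.35))
  ens <- generate_potts_ensemble(gen, topo, 400, method = "exact", seed = 28)
  fit <- fit_potts(ens, seed = 29)
  expect_true(fit$converged)
  expect_lt(fit$chi2_per_dof, 1)
  # the fitted model's exact observables match the generator's
  ex_fit <- enumerate_potts(fit$params, topo)
  ex_gen <- enumerate_potts(gen, topo)
  expect_lt(max(abs(ex_fit$observables$flat - ex_gen$observables$flat)),
            4 * max(fit$target_se))
})

test_that("parameters of a known model are recovered from exact draws", {
  topo <- lattice_topology(c(2, 3), periodic = FALSE)
  gen <- toy_params_q2()
  ens <- generate_potts_ensemble(gen, topo, 500, method = "exact", seed = 3)
  fit <- fit_potts(ens, seed = 11)
  expect_true(fit$converged)
  expect_lt(fit$chi2_per_dof, 1)

  ex_gen <- enumerate_potts(gen, topo)
  ex_fit <- enumerate_potts(fit$params, topo)
  expect_lt(max(abs(ex_fit$observables$flat - ex_gen$observables$flat) /
                  pmax(fit$target_se, 1e-12)), 3)

  covy <- observable_covariance(ens, count_scale = TRUE)
  py <- gauge_projector(covy)
  dth <- params_to_theta(fit$params, fit$layout) - params_to_theta(gen, fit$layout)
  expect_lt(max(abs(as.numeric(py$projector %*% dth))), 0.6)
})

test_that("states with zero target density never appear after convergence", {
  topo <- lattice_topology(c(2, 3), periodic = FALSE)
  set.seed(31)
  states <- matrix(sample(0:1, 6 * 200, replace = TRUE), 200, 6)
  ens <- potts_ensemble(states, 3, topo)       # state 2 never observed
  fit <- fit_potts(ens, seed = 32)
  expect_true(fit$converged)
  expect_equal(fit$params$h[3], 30)
  post <- sample_potts(fit$params, topo, n_samples = 500, burn_in = 200,
                       seed = 33)
  expect_false(any(post$states == 2L))
})

test_that("identical seeds give identical fits", {
  topo <- lattice_topology(c(2, 3), periodic = FALSE)
  ens <- generate_potts_ensemble(toy_params_q2(), topo, 300,
                                 method = "exact", seed = 34)
  f1 <- fit_potts(ens, seed = 35)
  f2 <- fit_potts(ens, seed = 35)
  expect_identical(params_to_theta(f1$params, f1$layout),
                   params_to_theta(f2$params, f2$layout))
  expect_identical(f1$log, f2$log)
})

test_that("accepted steps never increase the reweighted chi-squared", {
  topo <- lattice_topology(c(2, 3), periodic = FALSE)
  ens <- generate_potts_ensemble(toy_params_q2(), topo, 500,
                                 method = "exact", seed = 36)
  fit <- fit_potts(ens, seed = 37)
  lg <- fit$log
  # within each stretch between refreshes, chi2 is non-increasing
  refresh_at <- which(lg$event == "refresh")
  bounds <- c(refresh_at, nrow(lg) + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    seg <- lg$chi2[bounds[b]:(bounds[b + 1L] - 1L)]
    if (length(seg) > 1L) expect_true(all(diff(seg) <= 1e-9))
  }
})
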