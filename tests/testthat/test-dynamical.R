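test_that("extended topologies have the predicted structure", {
  iso <- one_node_topology()
  e1 <- extend_topology(iso, 3)
  expect_equal(e1$n_nodes, 3L)
  expect_equal(e1$n_links, 2L)
  expect_equal(unname(e1$n_links_class["temporal"]), 2L)
  expect_false("spatial" %in% e1$class_names)

  base <- lattice_topology(c(3, 3), periodic = TRUE)   # 18 links
  e2 <- extend_topology(base, 2)
  expect_equal(e2$n_nodes, 18L)
  expect_equal(e2$n_links, 2L * 18L + 9L)
  expect_equal(unname(e2$n_links_class["spatial"]), 36L)
  expect_equal(unname(e2$n_links_class["temporal"]), 9L)

  # link-count formula for assorted (base, T)
  for (Tn in c(2, 4)) for (shape in list(c(2, 3), 5)) {
    b <- lattice_topology(shape, periodic = FALSE)
    ee <- extend_topology(b, Tn)
    expect_equal(ee$n_links, Tn * b$n_links + (Tn - 1) * b$n_nodes)
  }
  expect_error(extend_topology(base, 1), "at least 2")
})

test_that("slicing the extended network at fixed t recovers the base edges", {
  base <- lattice_topology(c(2, 3), periodic = FALSE)
  Tn <- 3
  ext <- extend_topology(base, Tn)
  n <- base$n_nodes
  for (t in 0:(Tn - 1)) {
    sel <- ext$edge_class == "spatial" &
      ext$edges[, 1] >= t * n & ext$edges[, 1] < (t + 1) * n
    slice <- ext$edges[sel, , drop = FALSE] - t * n
    expect_equal(slice[order(slice[, 1], slice[, 2]), ], base$edges)
  }
  tempo <- ext$edges[ext$edge_class == "temporal", , drop = FALSE]
  expect_true(all(tempo[, 2] - tempo[, 1] == n))
  expect_true(all((tempo[, 1] %% n) == (tempo[, 2] %% n)))
})

test_that("series flattening matches the extended indexing", {
  series <- rbind(c(0L, 1L, 0L), c(1L, 1L, 0L))
  expect_equal(series_to_config(series), c(0L, 1L, 0L, 1L, 1L, 0L))
  expect_equal(config_to_series(series_to_config(series), 3), series)

  # constant series: every temporal edge carries an identical state pair
  base <- path_topology(3)
  ext <- extend_topology(base, 4)
  cfg <- series_to_config(matrix(rep(c(0L, 1L, 0L), 4), 4, 3, byrow = TRUE))
  cm <- pair_density(cfg, ext, 2)
  expect_equal(cm$temporal[1, 2], 0)

  # alternating single-node series concentrates on the off-diagonal
  alt <- matrix(c(0L, 1L, 0L, 1L), 4, 1)
  exta <- extend_topology(one_node_topology(), 4)
  cma <- pair_density(series_to_config(alt), exta, 2)
  expect_equal(cma[1, 2], 1)

  # spatial observables equal the time-average of per-frame pair densities
  set.seed(52)
  rnd <- matrix(sample(0:1, 12, replace = TRUE), 4, 3)
  cmr <- pair_density(series_to_config(rnd), ext, 2)
  frames <- lapply(1:4, function(t) pair_density(rnd[t, ], base, 2))
  expect_equal(cmr$spatial, Reduce(`+`, frames) / 4)
})

test_that("i.i.d. frames fit with vanishing temporal coupling", {
  set.seed(53)
  base <- one_node_topology()
  series <- lapply(1:150, function(i)
    matrix(stats::rbinom(10, 1, 0.35), ncol = 1))
  fit <- fit_dynamical(series, base, 2, seed = 54)
  expect_true(fit$converged)
  # model temporal couples match the independence product of the marginals
  ext <- extend_topology(base, 10)
  ex <- enumerate_potts(fit$params, ext)
  s <- ex$observables$s
  indep <- c(s[1]^2, 2 * s[1] * s[2], s[2]^2)
  ct <- ex$observables$c$temporal
  got <- c(ct[1, 1], ct[1, 2], ct[2, 2])
  expect_lt(max(abs(got - indep)), 0.03)
})

test_that("a Markov chain's flip probability is recovered", {
  p_flip <- 0.3
  base <- one_node_topology()
  set.seed(55)
  series <- lapply(1:200, function(i) markov_chain_series(12, p_flip))
  fit <- fit_dynamical(series, base, 2, seed = 56)
  expect_true(fit$converged)
  ext <- extend_topology(base, 12)
  ex <- enumerate_potts(fit$params, ext)
  offdiag <- ex$observables$c$temporal[1, 2]
  # 3 SE of the training mean for the flip density
  se <- fit$target_se[fit$layout$names == "c_temporal[0,1]"]
  expect_lt(abs(offdiag - p_flip), 3 * se + 0.01)
})

test_that("dynamical entropy brackets the i.i.d. and frozen limits", {
  base <- one_node_topology()
  # i.i.d. uniform frames: entropy near ln 2 per node-step
  set.seed(57)
  series <- lapply(1:100, function(i)
    matrix(stats::rbinom(8, 1, 0.5), ncol = 1))
  fit <- fit_dynamical(series, base, 2, seed = 58)
  rep <- dynamical_entropy(fit)
  expect_gt(rep$normalized[["s_maxent"]], 0.9)
  expect_lte(rep$normalized[["s_maxent"]],
             rep$normalized[["s_sf"]] + 1e-9)

  # frozen trajectory: entropy 0
  frozen <- fit_dynamical(matrix(1L, 40, 1), base, 2, seed = 59)
  expect_equal(path_entropy(frozen)$s_maxent, 0)

  # deterministic period-2 trajectory: near-zero entropy per node-step.
  # The fit reproduces the observed flip density only to the single-sequence
  # stochastic accuracy (a few flips in T-1 = 199 links), so the residual is
  # of order H(eps)/ln2 with eps ~ 1e-2, i.e. about 0.1 -- an order of
  # magnitude below the i.i.d. value of 1
  per2 <- fit_dynamical(matrix(rep(c(0L, 1L), 100), 200, 1), base, 2, seed = 60)
  rep2 <- dynamical_entropy(per2)
  expect_lt(rep2$normalized[["s_maxent"]], 0.12)
})

test_that("a known Markov chain's entropy matches the exact value", {
  # 10-step chains: exact dynamical entropy is ln2 + 9 * H(p)
  p_flip <- 0.25
  base <- one_node_topology()
  set.seed(61)
  series <- lapply(1:300, function(i) markov_chain_series(10, p_flip))
  fit <- fit_dynamical(series, base, 2, seed = 62)
  rep <- dynamical_entropy(fit)
  hp <- -(p_flip * log(p_flip) + (1 - p_flip) * log(1 - p_flip))
  s_exact <- log(2) + 9 * hp
  expect_lt(abs(rep$s_maxent - s_exact) / 10, 5e-2)  # per node-step
  # variational up to the finite-training fluctuation of the fitted flip
  # rate (dH/dp * SE * (T-1) ~ 0.1 here)
  expect_gte(rep$s_maxent + 0.2, s_exact)
})

test_that("time-independent constraints reduce to the static fit", {
  # i.i.d. frames on a 2x2 lattice: the dynamical fit's spatial couple
  # densities agree with a static fit on the pooled frames
  set.seed(63)
  base <- lattice_topology(c(2, 2), periodic = FALSE)
  gen <- potts_parameters(c(0, 0.3), matrix(c(-0.8, 0.4, 0.4, 0), 2, 2))
  frames <- generate_potts_ensemble(gen, base, 300, method = "exact", seed = 64)
  series <- lapply(seq(1, 300, by = 3), function(i)
    frames$states[i:(i + 2), , drop = FALSE])
  dyn <- fit_dynamical(series, base, 2, seed = 65)
  sta <- fit_potts(frames, seed = 66)
  expect_true(dyn$converged && sta$converged)
  exd <- enumerate_potts(dyn$params, extend_topology(base, 3))
  exs <- enumerate_potts(sta$params, base)
  expect_lt(max(abs(exd$observables$c$spatial - exs$observables$c$spatial)), 0.05)
  expect_lt(max(abs(exd$observables$s - exs$observables$s)), 0.03)
})
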