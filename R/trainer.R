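#' Non-interacting starting parameters
#'
#' The training loop starts from the independent-node solution that
#' reproduces the target state densities exactly: `h_i = -log(<s_i>)`,
#' `J = 0`.  Under the extensive Boltzmann exponent this start is the
#' product distribution with marginals `<s_i>` on every node; its entropy is
#' the Shannon-Fano entropy, which anchors the thermodynamic-integration
#' entropy formula.
#'
#' States with target density exactly 0 get their field pinned to a large
#' finite value (`h_pin`, default 30) instead of `+Inf`: the state's
#' probability is numerically negligible (about `exp(-30)`) while all
#' arithmetic stays finite.  Such states are excluded from the optimisation.
#'
#' @param target a `potts_observables` (or a plain density vector).
#' @param classes edge classes that need a (zero) coupling block.
#' @param h_pin field value for never-observed states.
#' @return a `potts_parameters` with `J = 0`.
#' @export
init_noninteracting <- function(target, classes = "spatial", h_pin = 30) {
  s <- if (inherits(target, "potts_observables")) target$s else as.numeric(target)
  if (all(s == 0)) stop("all target densities are zero")
  stopifnot(all(s >= 0), abs(sum(s) - 1) < 1e-8)
  h <- ifelse(s > 0, -log(pmax(s, .Machine$double.xmin)), h_pin)
  Q <- length(s)
  J <- stats::setNames(replicate(length(classes), matrix(0, Q, Q),
                                 simplify = FALSE), classes)
  potts_parameters(h, J, Q)
}

#' Importance-sampling weights for ensemble reuse
#'
#' An ensemble drawn at anchor parameters is reused at new parameters by
#' assigning each configuration the normalised weight
#' `rho_i = exp(-E_new(sigma_i) + E_anchor(sigma_i)) / sum_j(...)`,
#' computed in log space with max subtraction.  Shifting all fields by a
#' constant leaves the weights unchanged (gauge invariance).
#'
#' @param ensemble a `potts_ensemble` drawn under `anchor_params`.
#' @param new_params,anchor_params `potts_parameters`.
#' @return numeric weight vector summing to 1.
#' @export
reweight_ensemble <- function(ensemble, new_params, anchor_params) {
  layout <- observable_layout(new_params$n_states, ensemble$topology)
  Y <- observable_counts(ensemble, layout)
  dtheta <- params_to_theta(new_params, layout) -
    params_to_theta(anchor_params, layout)
  logw <- -as.numeric(Y %*% dtheta)
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

#' Effective sample size ratio of a weight vector
#'
#' `(sum rho)^2 / (n * sum rho^2)`: equals 1 iff the weights are uniform and
#' `1/n` when a single configuration carries all the weight.  The trainer
#' refreshes its Metropolis ensemble whenever this ratio falls below the
#' user threshold eta (default 0.5).
#'
#' @param weights nonnegative weights, not all zero.
#' @return a number in (0, 1].
#' @export
effective_sample_ratio <- function(weights) {
  stopifnot(all(weights >= 0))
  s <- sum(weights)
  if (s <= 0) stop("all weights are zero")
  s^2 / (length(weights) * sum(weights^2))
}

as_flat <- function(x) {
  if (inherits(x, "potts_observables")) x$flat else as.numeric(x)
}

#' Gauge-projected chi-squared between target and model observables
#'
#' The residual `target - model` (flat densities) is measured in the
#' metric of the kernel-projected pseudo-inverse of the training covariance:
#' `chi2 = r' Sigma^+ r`.  Residual components along the gauge kernel are
#' annihilated and never counted; `dof` is the informative dimension.
#'
#' @param target,model `potts_observables` or flat density vectors of equal
#'   layout.
#' @param projector a [gauge_projector()].
#' @return list with `chi2`, `dof` and `chi2_per_dof`.
#' @export
chi_square <- function(target, model, projector) {
  rt <- as_flat(target); rm_ <- as_flat(model)
  if (length(rt) != length(rm_) || length(rt) != nrow(projector$pseudo_inverse))
    stop("layout mismatch between target, model and projector")
  r <- rt - rm_
  chi2 <- as.numeric(r %*% projector$pseudo_inverse %*% r)
  list(chi2 = chi2, dof = projector$dof, chi2_per_dof = chi2 / max(projector$dof, 1L))
}

# gradient of chi2 wrt theta from a reweighted count matrix.
# d<x_a>/dtheta_b = -Cov_rho(x_a, y_b)  (Boltzmann family), so
# grad_b = 2 * sum_a [Sigma^+ r]_a Cov_rho(y_a, y_b) / D_a.
chi2_gradient_core <- function(Y, rho, D, target_flat, projector) {
  ybar <- as.numeric(crossprod(Y, rho))
  xm <- ybar / D
  r <- target_flat - xm
  u <- as.numeric(projector$pseudo_inverse %*% r)
  Yc <- sweep(Y, 2L, ybar, "-")
  Cyy <- crossprod(Yc * rho, Yc)
  g <- 2 * as.numeric(Cyy %*% (u / D))
  # no component along the gauge kernel
  as.numeric(projector$projector %*% g)
}

#' Gradient of the chi-squared with respect to the flat parameters
#'
#' Uses the Boltzmann-family identity (the derivative of a model average is
#' minus the covariance with the conjugate count observable), evaluated on
#' the reweighted anchor ensemble, and projects the result onto the
#' informative (non-kernel) subspace.  Verified against central finite
#' differences in the test suite.
#'
#' @param params parameters at which to evaluate.
#' @param target `potts_observables` (or flat densities).
#' @param ensemble anchor `potts_ensemble`.
#' @param projector a [gauge_projector()].
#' @param anchor_params parameters the ensemble was drawn at (default
#'   `params`, i.e. uniform weights).
#' @return numeric gradient in layout order.
#' @export
chi_square_gradient <- function(params, target, ensemble, projector,
                                anchor_params = params) {
  layout <- observable_layout(params$n_states, ensemble$topology)
  Y <- observable_counts(ensemble, layout)
  rho <- reweight_ensemble(ensemble, params, anchor_params)
  chi2_gradient_core(Y, rho, layout$D, as_flat(target), projector)
}

snapshot_row <- function(theta, xm, D, ess = 1) {
  list(theta = theta, x = xm, e_mean = sum(theta * (D * xm)), ess = ess)
}

#' Fit a maximum-entropy Potts model
#'
#' The training loop: starting from the non-interacting solution, draw a
#' Metropolis ensemble at the current (anchor) parameters, take conjugate
#' gradient steps on the gauge-projected chi-squared using importance
#' reweighting of the anchor ensemble, refresh the ensemble whenever the
#' effective-sample-size ratio drops below `eta`, and stop when
#' `chi2 / dof` falls below `chi2_threshold`.  The full path of parameters
#' and reweighted model observables is recorded at every accepted step; the
#' thermodynamic-integration entropy is computed from exactly this path by
#' [path_entropy()].
#'
#' @param x the training data: a `potts_ensemble`, or a `potts_observables`
#'   target (then `topology` and either `target_covariance` or a model-based
#'   covariance are used).
#' @param topology required when `x` is not an ensemble.
#' @param eta ESS refresh threshold in (0, 1], default 0.5.
#' @param chi2_threshold convergence level for chi2 per degree of freedom
#'   (default 1).
#' @param max_steps maximum accepted CG steps (default 200).
#' @param max_refresh maximum Metropolis refreshes (default 100).
#' @param max_cg_per_refresh forced-refresh cap on CG steps taken from one
#'   anchor ensemble (default 20): importance reweighting is only trusted
#'   for limited excursions even at high ESS, because an anchor ensemble
#'   cannot represent configurations it never sampled.  Convergence is only
#'   declared on a freshly sampled ensemble, never on a reweighted one.
#' @param step_max trust-region cap on the largest single-parameter move per
#'   accepted step (default 1, in extensive energy units): larger moves are
#'   overshoots driven by reweighting bias.
#' @param n_samples,burn_in,stride Metropolis settings per refresh.
#' @param kernel_cutoff relative eigenvalue cutoff for the gauge kernel.
#' @param target_covariance optional covariance matrix of the *target
#'   estimate* (used as-is in the chi-squared metric).  By default the
#'   per-configuration sample covariance of the training ensemble divided by
#'   `n_train` -- the stochastic accuracy of the target means -- or, when
#'   the training set has fewer than `min_cov_conf` configurations (e.g. a
#'   single time sequence), the per-configuration covariance of a model
#'   ensemble sampled at the non-interacting start, divided by `n_train`.
#' @param min_cov_conf smallest training set whose empirical covariance is
#'   trusted (default 10).
#' @param h_pin field value pinning never-observed states.
#' @param seed optional RNG seed (the whole fit is deterministic given it).
#' @param verbose print per-iteration diagnostics.
#' @return an object of class `potts_fit`: `params`, `converged`, `chi2`,
#'   `dof`, `path` (list of snapshots with `theta`, `x`, `e_mean`), `log`
#'   (per-event data frame: step, chi2, ess, event), `target`, `target_se`,
#'   `projector`, `layout`, `n_refresh`, `n_steps`.
#' @export
fit_potts <- function(x, topology = NULL, eta = 0.5, chi2_threshold = 1,
                      max_steps = 200L, max_refresh = 100L,
                      max_cg_per_refresh = 20L, step_max = 1,
                      n_samples = 1000L, burn_in = 1000L, stride = 10L,
                      kernel_cutoff = 1e-8, target_covariance = NULL,
                      min_cov_conf = 10L, h_pin = 30, seed = NULL,
                      verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(eta > 0, eta <= 1, chi2_threshold > 0)

  n_train <- 1L
  if (inherits(x, "potts_ensemble")) {
    topology <- x$topology
    layout <- observable_layout(x$n_states, topology)
    target <- ensemble_observables(x, layout)
    n_train <- x$n_conf
    if (is.null(target_covariance) && x$n_conf >= min_cov_conf)
      target_covariance <- observable_covariance(x, layout) / n_train
  } else if (inherits(x, "potts_observables")) {
    if (is.null(topology)) stop("topology required when fitting a target vector")
    layout <- x$layout
    target <- x
  } else stop("x must be a potts_ensemble or potts_observables")
  Q <- layout$n_states

  params0 <- init_noninteracting(target, classes = layout$classes, h_pin = h_pin)
  theta0 <- params_to_theta(params0, layout)
  D <- layout$D

  # frozen directions: fields and couplings touching never-observed states
  missing_state <- target$s == 0
  frozen <- c(missing_state,
              rep(missing_state[layout$pair_i] | missing_state[layout$pair_j],
                  length(layout$classes)))

  # Metropolis chains are seeded from a training configuration when one is
  # available: at strong couplings a randomly initialised chain quenches
  # into frozen defects it cannot anneal away, the model observables then
  # miss the target no matter how far the couplings grow, and the
  # optimisation runs away.  Starting in the data mode removes the quench;
  # at moderate couplings the burn-in re-equilibrates the chain anyway.
  train_states <- if (inherits(x, "potts_ensemble")) x$states else NULL
  sample_at <- function(theta) {
    init <- if (!is.null(train_states))
      train_states[sample.int(nrow(train_states), 1L), ] else NULL
    sample_potts(theta_to_params(theta, layout), topology,
                 n_samples = n_samples, burn_in = burn_in, stride = stride,
                 init = init)
  }

  cov_model_based <- FALSE
  if (is.null(target_covariance)) {
    # model-based covariance at the non-interacting start (single-sequence
    # training sets carry no between-configuration variance to estimate);
    # divided by n_train it is the stochastic accuracy of the target means.
    # It is re-estimated at every Metropolis refresh so the metric reflects
    # the stochastic accuracy under the model as it approaches the data.
    cov_model_based <- TRUE
    target_covariance <- observable_covariance(sample_at(theta0), layout) / n_train
  }
  target_se <- sqrt(pmax(diag(target_covariance), 0))

  projector <- tryCatch(gauge_projector(target_covariance, kernel_cutoff),
                        error = function(e) e)
  log_rows <- list()
  add_log <- function(step, chi2, ess, event) {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(step = step, chi2 = chi2, ess = ess, event = event)
  }

  if (inherits(projector, "error")) {
    # fully degenerate training set (e.g. a frozen trajectory): the
    # non-interacting start already reproduces everything measurable
    add_log(0L, 0, 1, "degenerate")
    path <- list(snapshot_row(theta0, target$flat, D))
    return(structure(list(params = params0, converged = TRUE, chi2 = 0,
                          dof = 0L, chi2_per_dof = 0, path = path,
                          log = do.call(rbind, log_rows), target = target,
                          target_se = target_se, covariance = target_covariance,
                          projector = NULL, layout = layout,
                          topology = topology, n_refresh = 0L, n_steps = 0L),
                     class = "potts_fit"))
  }

  dof <- projector$dof
  theta <- theta0
  path <- list()
  seg_start <- 1L
  n_refresh <- 0L; n_steps <- 0L
  converged <- FALSE
  chi2_cur <- Inf
  tflat <- target$flat

  repeat {
    if (n_refresh >= max_refresh) break
    anchor <- theta
    ens <- sample_at(theta)
    Y <- observable_counts(ens, layout)
    n_refresh <- n_refresh + 1L

    # bridge correction of the segment recorded since the last refresh:
    # forward-reweighted observables are biased near the end of a long
    # excursion (the old anchor lacks support there, which the ESS ratio
    # cannot detect), while the fresh ensemble reweights backward with good
    # support exactly there.  Each snapshot keeps the ESS-weighted average
    # of the two estimates; the entropy line integral uses these.
    if (seg_start <= length(path)) {
      for (i in seg_start:length(path)) {
        snap <- path[[i]]
        logw <- -as.numeric(Y %*% (snap$theta - anchor))
        w <- exp(logw - max(logw)); w <- w / sum(w)
        ess_new <- effective_sample_ratio(w)
        x_new <- as.numeric(crossprod(Y, w)) / D
        # inverse-MSE weights: both the variance and the squared
        # support-deficiency bias of a self-normalised importance estimate
        # scale like 1 / (n * ess)^2 at low ess, so quadratic ESS weights
        # down-weight the failing side much harder than linear ones
        w_old <- snap$ess^2; w_new <- ess_new^2
        x_comb <- (w_old * snap$x + w_new * x_new) / (w_old + w_new)
        path[[i]] <- snapshot_row(snap$theta, x_comb, D,
                                  ess = max(snap$ess, ess_new))
      }
    }

    if (cov_model_based && n_refresh > 1L) {
      tc <- observable_covariance(ens, layout) / n_train
      pr <- tryCatch(gauge_projector(tc, kernel_cutoff), error = function(e) NULL)
      if (!is.null(pr)) {       # keep the old metric if the model froze
        target_covariance <- tc
        projector <- pr
        dof <- pr$dof
        target_se <- sqrt(pmax(diag(tc), 0))
      }
    }

    rho_of <- function(th) {
      logw <- -as.numeric(Y %*% (th - anchor))
      w <- exp(logw - max(logw))
      w / sum(w)
    }
    chi2_of <- function(th) {
      rho <- rho_of(th)
      xm <- as.numeric(crossprod(Y, rho)) / D
      r <- tflat - xm
      list(chi2 = as.numeric(r %*% projector$pseudo_inverse %*% r),
           xm = xm, rho = rho)
    }
    # reweighted covariance of the count observables at the current theta;
    # supplies both the analytic gradient and the Gauss-Newton curvature
    # used to scale the line search
    cov_at <- function(ev) {
      Yc <- sweep(Y, 2L, D * ev$xm, "-")
      crossprod(Yc * ev$rho, Yc)
    }

    ev <- chi2_of(theta)
    chi2_cur <- ev$chi2
    path[[length(path) + 1L]] <- snapshot_row(theta, ev$xm, D)
    seg_start <- length(path) + 1L
    add_log(n_steps, chi2_cur, 1, "refresh")
    if (verbose)
      message(sprintf("refresh %d: chi2/dof = %.4g", n_refresh, chi2_cur / dof))
    if (chi2_cur / dof < chi2_threshold) { converged <- TRUE; break }

    g_prev <- NULL; dir_prev <- NULL
    cg_iter <- 0L
    need_refresh <- FALSE

    repeat {
      Cyy <- cov_at(ev)
      u <- as.numeric(projector$pseudo_inverse %*% (tflat - ev$xm))
      g <- 2 * as.numeric(Cyy %*% (u / D))
      g <- as.numeric(projector$projector %*% g)
      g[frozen] <- 0
      if (sqrt(sum(g^2)) < 1e-12) break      # stationary on this ensemble
      if (is.null(g_prev) || cg_iter %% dof == 0L) {
        dir <- -g
      } else {
        beta <- max(0, sum(g * (g - g_prev)) / sum(g_prev^2))
        dir <- -g + beta * dir_prev
        if (sum(dir * g) >= 0) dir <- -g     # ensure descent
      }
      # line search along dir: start from the Gauss-Newton step for the
      # quadratic model of chi2 (A = d<x>/dtheta = -Cov(x, y)), then Armijo
      # backtracking.  A trial step must also keep the effective sample
      # ratio above half the refresh threshold: a step that collapses the
      # importance weights makes the reweighted chi2 (and the recorded path
      # observables) untrustworthy, so it is shortened instead of trusted.
      slope <- sum(dir * g)
      Ad <- as.numeric(Cyy %*% dir) / D
      curv <- 2 * as.numeric(Ad %*% projector$pseudo_inverse %*% Ad)
      alpha <- if (curv > 1e-300) -slope / curv else 1 / max(1, sqrt(sum(g^2)))
      # trust region: fields and couplings are order-1 quantities under the
      # extensive energy; a single step moving any of them by more than
      # step_max is an overshoot driven by reweighting bias, and lands the
      # path in regions neither the anchor nor a fresh chain samples well
      alpha <- min(alpha, step_max / max(abs(dir)))
      ess_floor <- eta / 2
      accepted <- FALSE
      for (bt in 1:40) {
        evn <- chi2_of(theta + alpha * dir)
        if (evn$chi2 <= chi2_cur + 1e-4 * alpha * slope &&
            effective_sample_ratio(evn$rho) >= ess_floor) { accepted <- TRUE; break }
        alpha <- alpha / 2
      }
      if (!accepted) break                   # stalled on this ensemble
      # record the segment at sub-step resolution: the entropy line
      # integral needs the model observables along the move, and reweighted
      # averages at interior points of an accepted (ESS-guarded) step cost
      # only a matrix-vector product each.  Without this, large well-scaled
      # steps make the trapezoidal integral too coarse.
      for (f in seq_len(4L) / 4L) {
        th_sub <- theta + f * alpha * dir
        ev_sub <- if (f == 1) evn else chi2_of(th_sub)
        path[[length(path) + 1L]] <- snapshot_row(
          th_sub, ev_sub$xm, D, ess = effective_sample_ratio(ev_sub$rho))
      }
      theta <- theta + alpha * dir
      ev <- evn
      chi2_cur <- evn$chi2
      n_steps <- n_steps + 1L
      cg_iter <- cg_iter + 1L
      g_prev <- g; dir_prev <- dir
      ess <- effective_sample_ratio(evn$rho)
      add_log(n_steps, chi2_cur, ess, "cg")
      if (verbose)
        message(sprintf("  step %d: chi2/dof = %.4g, ess = %.3f",
                        n_steps, chi2_cur / dof, ess))
      # apparent convergence on a reweighted ensemble must be confirmed by
      # a fresh Metropolis run (the check at the top of the outer loop)
      if (chi2_cur / dof < chi2_threshold) { need_refresh <- TRUE; break }
      if (n_steps >= max_steps) break
      if (ess < eta || cg_iter >= max_cg_per_refresh) { need_refresh <- TRUE; break }
    }

    if (converged || n_steps >= max_steps) break
    if (!need_refresh) {
      # CG stalled with a still-trusted ensemble: one refresh may unlock it
      # (fresh samples move the reweighted averages); stop if even a fresh
      # ensemble cannot improve.
      if (effective_sample_ratio(ev$rho) > 0.999) break
    }
  }

  structure(list(params = theta_to_params(theta, layout), converged = converged,
                 chi2 = chi2_cur, dof = dof, chi2_per_dof = chi2_cur / dof,
                 path = path, log = do.call(rbind, log_rows), target = target,
                 target_se = target_se, covariance = target_covariance,
                 projector = projector, layout = layout, topology = topology,
                 n_refresh = n_refresh, n_steps = n_steps),
            class = "potts_fit")
}

#' @export
print.potts_fit <- function(x, ...) {
  cat("<potts_fit> ", if (x$converged) "converged" else "NOT converged",
      sprintf(": chi2/dof = %.4g (dof = %d), %d CG steps, %d Metropolis refreshes\n",
              x$chi2_per_dof, x$dof, x$n_steps, x$n_refresh), sep = "")
  invisible(x)
}
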