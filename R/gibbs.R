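# Conjugate full-conditional updates and the Gibbs sampler driver.
#
# Every block of the hierarchical MFA model has a closed-form full
# conditional (complete conditional conjugacy). Each update below first
# computes the conditional's parameters via a cond_* helper — these helpers
# are what the test suite compares against grid-normalized densities — and
# then draws from it. The sweep order is fixed (gamma/omega, t, c/k,
# theta/chi, eta, tau) so runs are reproducible.

#' Gibbs sampler settings
#'
#' @param iterations Total number of full sweeps (positive integer).
#' @param burnin Number of initial sweeps discarded (non-negative,
#'   < iterations). Default: half the iterations.
#' @param thin Keep every `thin`-th post-burn-in sweep. Default keeps at
#'   most ~1000 states.
#' @param seed Integer seed controlling the whole run (initialization and
#'   sampling).
#' @return A `bmfa_settings` object.
#' @export
gibbs_settings <- function(iterations, burnin = NULL, thin = NULL, seed = 1L) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop_invalid("iterations must be a positive integer")
  if (is.null(burnin)) burnin <- iterations %/% 2L
  burnin <- as.integer(burnin)
  if (is.na(burnin) || burnin < 0L || burnin >= iterations)
    stop_invalid("burnin must satisfy 0 <= burnin < iterations")
  if (is.null(thin)) thin <- max(1L, (iterations - burnin) %/% 1000L)
  thin <- as.integer(thin)
  if (is.na(thin) || thin < 1L) stop_invalid("thin must be a positive integer")
  kept <- (iterations - burnin) %/% thin
  if (kept < 1L) stop_invalid("settings keep no samples: increase iterations or lower thin")
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 seed = as.integer(seed), kept = kept),
            class = "bmfa_settings")
}

## ---- conditional parameters (closed forms) ----

# t_i | rest: Normal. prec_i = 1 + sum_g tau_g k_{gamma_i g}^2,
# mean_i = prec_i^-1 sum_g tau_g k_{gamma_i g} (y_ig - c_{gamma_i g}).
cond_pseudotime <- function(state, Y) {
  Kg <- state$k[state$gamma, , drop = FALSE]
  prec <- as.numeric(1 + (Kg * Kg) %*% state$tau)
  mean <- as.numeric(((Y - state$c[state$gamma, , drop = FALSE]) * Kg) %*%
                       state$tau) / prec
  list(mean = mean, prec = prec)
}

# c_bg | rest (given current k_bg): Normal with precision tau_c + tau_g N_b.
cond_intercept <- function(state, Y, hyper, b) {
  idx <- which(state$gamma == b)
  nb <- length(idx)
  tb <- state$t[idx]
  Yb <- Y[idx, , drop = FALSE]
  prec <- hyper$tau_c + state$tau * nb
  mean <- (hyper$tau_c * state$eta +
             state$tau * (.colSums(Yb, nb, ncol(Y)) - state$k[b, ] * sum(tb))) / prec
  list(mean = mean, prec = prec)
}

# k_bg | rest (given current c_bg): Normal with precision
# chi_g + tau_g sum_{i in b} t_i^2.
cond_gradient <- function(state, Y, hyper, b) {
  idx <- which(state$gamma == b)
  tb <- state$t[idx]
  Yb <- Y[idx, , drop = FALSE]
  prec <- state$chi + state$tau * sum(tb * tb)
  yt <- if (length(idx)) as.numeric(crossprod(Yb, tb)) else numeric(ncol(Y))
  mean <- (state$chi * state$theta +
             state$tau * (yt - state$c[b, ] * sum(tb))) / prec
  list(mean = mean, prec = prec)
}

# theta_g | rest: Normal with precision tau_theta + B chi_g.
cond_theta <- function(state, hyper) {
  B <- hyper$B
  prec <- hyper$tau_theta + B * state$chi
  mean <- (hyper$tau_theta * hyper$theta_tilde +
             state$chi * .colSums(state$k, B, length(state$chi))) / prec
  list(mean = mean, prec = prec)
}

# chi_g | rest: Gamma(alpha_chi + B/2, beta_chi + 1/2 sum_b (k_bg - theta_g)^2).
cond_chi <- function(state, hyper) {
  B <- hyper$B
  dev <- state$k - rep(state$theta, each = B)
  list(shape = hyper$alpha_chi + B / 2,
       rate = hyper$beta_chi + 0.5 * .colSums(dev * dev, B, length(state$theta)))
}

# eta_g | rest: Normal with precision tau_eta + B tau_c.
cond_eta <- function(state, hyper) {
  B <- hyper$B
  prec <- hyper$tau_eta + B * hyper$tau_c
  mean <- (hyper$tau_eta * hyper$eta_tilde +
             hyper$tau_c * .colSums(state$c, B, length(state$eta))) / prec
  list(mean = mean, prec = rep(prec, length(state$eta)))
}

# tau_g | rest: Gamma(alpha + N/2, beta + 1/2 sum_i r_ig^2).
cond_tau <- function(state, Y, hyper) {
  R <- Y - state$c[state$gamma, , drop = FALSE] -
    state$k[state$gamma, , drop = FALSE] * state$t
  list(shape = hyper$alpha + nrow(Y) / 2,
       rate = hyper$beta + 0.5 * .colSums(R * R, nrow(Y), ncol(Y)))
}

# log P(gamma_i = b) up to a per-cell constant: log omega_b plus the
# Gaussian log likelihood of cell i under branch b.
cond_branch_logprob <- function(state, Y) {
  N <- nrow(Y); B <- length(state$omega)
  ll <- matrix(0, N, B)
  half_logtau <- 0.5 * sum(log(state$tau)) - 0.5 * ncol(Y) * log(2 * pi)
  for (b in seq_len(B)) {
    R <- Y - rep(state$c[b, ], each = N) - tcrossprod(state$t, state$k[b, ])
    ll[, b] <- as.numeric((R * R) %*% (-0.5 * state$tau)) + half_logtau +
      log(state$omega[b])
  }
  ll
}

## ---- block updates ----

#' Gibbs update of the pseudotimes
#'
#' Draws each \eqn{t_i} from its Normal full conditional (standard Normal
#' prior combined with the branch-specific linear likelihood). When all
#' gradients are zero the conditional is the prior N(0, 1).
#'
#' @param state A `bmfa_state`.
#' @param Y Expression matrix.
#' @return The state with `t` resampled.
#' @export
update_pseudotimes <- function(state, Y) {
  cp <- cond_pseudotime(state, Y)
  state$t <- stats::rnorm(length(cp$mean), cp$mean, 1 / sqrt(cp$prec))
  state
}

#' Gibbs update of the factor loadings
#'
#' For each branch and gene, draws the intercept `c_bg` and then the
#' gradient `k_bg` from their Normal full conditionals (sequentially, so the
#' gradient update sees the fresh intercept). An empty branch falls back to
#' the prior: `c_bg ~ N(eta_g, tau_c^-1)`, `k_bg ~ N(theta_g, chi_g^-1)`.
#'
#' @inheritParams update_pseudotimes
#' @param hyper A `bmfa_hyper`.
#' @return The state with `c` and `k` resampled.
#' @export
update_factor_loadings <- function(state, Y, hyper) {
  G <- ncol(Y)
  for (b in seq_len(hyper$B)) {
    cc <- cond_intercept(state, Y, hyper, b)
    state$c[b, ] <- stats::rnorm(G, cc$mean, 1 / sqrt(cc$prec))
    ck <- cond_gradient(state, Y, hyper, b)
    state$k[b, ] <- stats::rnorm(G, ck$mean, 1 / sqrt(ck$prec))
  }
  state
}

#' Gibbs update of the shared gradient and shrinkage precisions
#'
#' Draws `theta_g` from its Normal conditional and then `chi_g` from
#' Gamma(alpha_chi + B/2, beta_chi + 1/2 sum_b (k_bg - theta_g)^2). Small
#' sampled `chi_g` (large 1/chi_g) indicates branch gradients that the data
#' keep far apart, i.e. a gene involved in the bifurcation.
#'
#' @inheritParams update_factor_loadings
#' @return The state with `theta` and `chi` resampled.
#' @export
update_shrinkage <- function(state, hyper) {
  ct <- cond_theta(state, hyper)
  state$theta <- stats::rnorm(length(ct$mean), ct$mean, 1 / sqrt(ct$prec))
  cx <- cond_chi(state, hyper)
  state$chi <- stats::rgamma(length(cx$rate), cx$shape, rate = cx$rate)
  state
}

#' Gibbs update of the shared intercept prior mean
#'
#' @inheritParams update_factor_loadings
#' @return The state with `eta` resampled.
#' @export
update_eta <- function(state, hyper) {
  ce <- cond_eta(state, hyper)
  state$eta <- stats::rnorm(length(ce$mean), ce$mean, 1 / sqrt(ce$prec))
  state
}

#' Gibbs update of the per-gene noise precisions
#'
#' @inheritParams update_factor_loadings
#' @return The state with `tau` resampled.
#' @export
update_noise_precision <- function(state, Y, hyper) {
  ct <- cond_tau(state, Y, hyper)
  state$tau <- stats::rgamma(length(ct$rate), ct$shape, rate = ct$rate)
  state
}

#' Gibbs update of branch assignments and mixture weights
#'
#' Branch labels are drawn from the categorical conditional
#' \eqn{P(\gamma_i = b) \propto \omega_b \prod_g N(y_{ig}; c_{bg} + k_{bg} t_i, \tau_g^{-1})},
#' computed in log space with per-cell max subtraction so that a hopeless
#' branch underflows to exact zero probability rather than NaN. The weights
#' are then drawn from Dirichlet(1/B + N_1, ..., 1/B + N_B).
#'
#' @inheritParams update_factor_loadings
#' @return The state with `gamma` and `omega` resampled.
#' @export
update_branch_assignments <- function(state, Y, hyper) {
  B <- hyper$B; N <- nrow(Y)
  ll <- cond_branch_logprob(state, Y)
  mx <- ll[cbind(seq_len(N), max.col(ll))]
  p <- exp(ll - mx)
  cum <- p %*% upper.tri(diag(B), diag = TRUE)   # row-wise cumulative sums
  u <- stats::runif(N) * cum[, B]
  state$gamma <- as.integer(B + 1L - as.numeric((u <= cum) %*% rep(1, B)))
  nb <- tabulate(state$gamma, B)
  g <- stats::rgamma(B, 1 / B + nb, rate = 1)
  state$omega <- g / sum(g)
  state
}

## ---- driver ----

check_block <- function(x, block) {
  if (!all(is.finite(x)))
    stop("non-finite values produced by Gibbs block '", block,
         "'; the sampler was aborted", call. = FALSE)
}

# Shared driver for the standard and zero-inflated samplers. When
# `zero_inflation` is TRUE the data matrix seen by all conditionals is the
# latent X, and each sweep ends by re-imputing the zero entries; with an
# empty zero mask both paths make identical RNG draws, so the traces are
# bit-identical.
run_gibbs <- function(Y, hyper, settings, pc_index, zero_inflation = FALSE,
                      lambda = NULL, verbose = FALSE) {
  Y <- expression_matrix(Y)
  if (!inherits(hyper, "bmfa_hyper")) stop_invalid("hyper must be a bmfa_hyper")
  if (!inherits(settings, "bmfa_settings"))
    stop_invalid("settings must come from gibbs_settings()")
  N <- nrow(Y); G <- ncol(Y); B <- hyper$B

  zero_mask <- NULL; z_per_gene <- NULL; n_zero <- 0L
  if (zero_inflation) {
    zero_mask <- Y == 0
    n_zero <- sum(zero_mask)
    if (n_zero > 0L) {
      if (is.null(lambda)) lambda <- estimate_lambda(Y)
      if (!is.finite(lambda) || lambda <= 0)
        stop_invalid("zero-inflated sampling with observed zeros requires a finite lambda > 0")
      z_per_gene <- .colSums(zero_mask, N, G)
    } else {
      lambda <- Inf   # no zeros: dropout model is vacuous
    }
  }

  state <- init_state(Y, hyper, pc_index, seed = settings$seed)
  X <- Y  # latent expression; equals Y outside the zero mask

  kept <- settings$kept
  tr <- list(
    t = matrix(NA_real_, kept, N), gamma = matrix(NA_integer_, kept, N),
    c = array(NA_real_, c(kept, B, G)), k = array(NA_real_, c(kept, B, G)),
    eta = matrix(NA_real_, kept, G), theta = matrix(NA_real_, kept, G),
    chi = matrix(NA_real_, kept, G), tau = matrix(NA_real_, kept, G),
    omega = matrix(NA_real_, kept, B), log_joint = rep(NA_real_, kept))
  imputed_mean <- if (zero_inflation) rep(NA_real_, settings$iterations) else NULL

  j <- 0L
  for (s in seq_len(settings$iterations)) {
    state <- update_branch_assignments(state, X, hyper)
    state <- update_pseudotimes(state, X)
    check_block(state$t, "pseudotimes")
    state <- update_factor_loadings(state, X, hyper)
    check_block(state$c, "factor loadings (c)")
    check_block(state$k, "factor loadings (k)")
    state <- update_shrinkage(state, hyper)
    check_block(state$theta, "shrinkage (theta)")
    check_block(state$chi, "shrinkage (chi)")
    state <- update_eta(state, hyper)
    check_block(state$eta, "eta")
    state <- update_noise_precision(state, X, hyper)
    check_block(state$tau, "noise precision")
    if (zero_inflation && n_zero > 0L) {
      zst <- impute_zeros(new_zi_state(state, X, zero_mask, lambda,
                                       z_per_gene), Y)
      X <- zst$X
      check_block(X[zero_mask], "zero imputation")
      imputed_mean[s] <- mean(X[zero_mask])
    }
    if (s > settings$burnin && (s - settings$burnin) %% settings$thin == 0L) {
      j <- j + 1L
      tr$t[j, ] <- state$t; tr$gamma[j, ] <- state$gamma
      tr$c[j, , ] <- state$c; tr$k[j, , ] <- state$k
      tr$eta[j, ] <- state$eta; tr$theta[j, ] <- state$theta
      tr$chi[j, ] <- state$chi; tr$tau[j, ] <- state$tau
      tr$omega[j, ] <- state$omega
      lj <- log_likelihood(state, X) + log_prior(state, hyper)
      if (!is.finite(lj))
        stop("non-finite log joint at iteration ", s,
             "; the sampler was aborted", call. = FALSE)
      tr$log_joint[j] <- lj
    }
    if (verbose && s %% 1000L == 0L) {
      message(sprintf("iteration %d / %d, log joint %.2f", s,
                      settings$iterations,
                      log_likelihood(state, X) + log_prior(state, hyper)))
    }
  }

  structure(list(
    t = tr$t, gamma = tr$gamma, c = tr$c, k = tr$k, eta = tr$eta,
    theta = tr$theta, chi = tr$chi, tau = tr$tau, omega = tr$omega,
    log_joint = tr$log_joint,
    imputed_mean = imputed_mean,
    meta = list(iterations = settings$iterations, burnin = settings$burnin,
                thin = settings$thin, seed = settings$seed,
                pc_index = as.integer(pc_index), B = B, N = N, G = G,
                cell_ids = rownames(Y), gene_ids = colnames(Y),
                zero_inflated = zero_inflation,
                lambda = if (zero_inflation) lambda else NULL)),
    class = "bmfa_trace")
}

#' Fit the mixture of factor analyzers by Gibbs sampling
#'
#' Runs PCA initialization followed by full Gibbs sweeps in the fixed block
#' order gamma/omega, t, c/k, theta/chi, eta, tau, keeping thinned
#' post-burn-in states together with the joint log density. The run is
#' fully reproducible given `settings$seed`.
#'
#' @param Y Expression matrix (cells x genes), see [expression_matrix()].
#' @param hyper A `bmfa_hyper`; defaults to
#'   `default_hyperparameters(2, Y)`.
#' @param settings A `bmfa_settings` from [gibbs_settings()].
#' @param pc_index Principal component used to initialize pseudotimes.
#' @param verbose Log progress (current log joint) every 1000 sweeps.
#' @return A `bmfa_trace`: thinned arrays for every parameter block (first
#'   axis = kept iteration), the per-kept-iteration log joint, and run
#'   metadata.
#' @seealso [zi_gibbs_sample()] for the zero-inflated variant,
#'   [map_pseudotime()], [map_branch()], [chi_relevance()] for summaries.
#' @export
gibbs_sample <- function(Y, hyper = NULL, settings = gibbs_settings(2000L),
                         pc_index = 1L, verbose = FALSE) {
  if (is.null(hyper)) hyper <- default_hyperparameters(2L, Y)
  run_gibbs(Y, hyper, settings, pc_index, zero_inflation = FALSE,
            verbose = verbose)
}

#' Number of kept states in a trace
#' @param trace A `bmfa_trace`.
#' @return Integer count of kept (post burn-in, thinned) states.
#' @export
n_states <- function(trace) nrow(trace$t)

#' Extract one kept state from a trace
#' @param trace A `bmfa_trace`.
#' @param j Kept-iteration index (1-based).
#' @return A `bmfa_state`.
#' @export
trace_state <- function(trace, j) {
  j <- as.integer(j)
  if (is.na(j) || j < 1L || j > n_states(trace))
    stop_invalid("state index out of range")
  new_state(omega = trace$omega[j, ], gamma = trace$gamma[j, ],
            eta = trace$eta[j, ], theta = trace$theta[j, ],
            chi = trace$chi[j, ], c = trace$c[j, , , drop = TRUE],
            k = trace$k[j, , , drop = TRUE], t = trace$t[j, ],
            tau = trace$tau[j, ])
}
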