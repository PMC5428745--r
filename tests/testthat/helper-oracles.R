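# Shared test fixtures and independent numeric oracles.
#
# grid_moments() is the independent oracle for every conjugate update: it
# normalizes an arbitrary unnormalized log density on a fine grid by the
# trapezoid rule and returns its mean and variance. The closed forms in the
# package are never used inside the oracle.

grid_moments <- function(logf, lower, upper, n = 40001L) {
  x <- seq(lower, upper, length.out = n)
  lf <- vapply(x, logf, numeric(1))
  w <- exp(lf - max(lf))
  dx <- x[2L] - x[1L]
  z <- sum(w) * dx
  m <- sum(x * w) * dx / z
  v <- sum((x - m)^2 * w) * dx / z
  list(mean = m, var = v)
}

# A small arbitrary-but-valid model configuration for conditional checks.
tiny_problem <- function(N = 3L, G = 2L, B = 2L, seed = 42L) {
  set.seed(seed)
  Y <- expression_matrix(matrix(rnorm(N * G, 1, 2), N, G))
  hyper <- mfa_hyperparameters(B = B, eta_tilde = 0.4, theta_tilde = -0.2,
                               tau_eta = 1.3, tau_theta = 0.8, tau_c = 1.7,
                               alpha_chi = 1.2, beta_chi = 0.9,
                               alpha = 2.5, beta = 1.4)
  state <- bmfa:::new_state(
    omega = c(0.3, 0.7)[seq_len(B)] / sum(c(0.3, 0.7)[seq_len(B)]),
    gamma = rep_len(seq_len(B), N),
    eta = rnorm(G), theta = rnorm(G), chi = rgamma(G, 2, 1) + 0.2,
    c = matrix(rnorm(B * G), B, G), k = matrix(rnorm(B * G), B, G),
    t = rnorm(N), tau = rgamma(G, 3, 2) + 0.2)
  list(Y = Y, hyper = hyper, state = state)
}

# Compare every closed-form full conditional against the grid oracle on
# scalar instances. Returns the worst absolute error in mean and variance
# over all checked blocks (used by both the gibbs unit tests and the
# acceptance criterion).
conditional_oracle_errors <- function(seed = 42L) {
  p <- tiny_problem(seed = seed)
  Y <- p$Y; hyper <- p$hyper; st <- p$state
  N <- nrow(Y); G <- ncol(Y); B <- hyper$B
  errs <- c()
  add <- function(errs, tag, closed_mean, closed_var, logf, center, spread) {
    o <- grid_moments(logf, center - 12 * spread, center + 12 * spread)
    c(errs, stats::setNames(c(abs(o$mean - closed_mean),
                              abs(o$var - closed_var)),
                            paste0(tag, c("_mean", "_var"))))
  }

  # pseudotime t_1
  cp <- bmfa:::cond_pseudotime(st, Y)
  i <- 1L; b <- st$gamma[i]
  logf <- function(v) {
    dnorm(v, 0, 1, log = TRUE) +
      sum(dnorm(Y[i, ], st$c[b, ] + st$k[b, ] * v, 1 / sqrt(st$tau), log = TRUE))
  }
  errs <- add(errs, "t", cp$mean[i], 1 / cp$prec[i], logf,
              cp$mean[i], 1 / sqrt(cp$prec[i]))

  # intercept c_{1,1} and gradient k_{1,1}
  b <- 1L; g <- 1L
  idx <- which(st$gamma == b)
  cc <- bmfa:::cond_intercept(st, Y, hyper, b)
  logf <- function(v) {
    dnorm(v, st$eta[g], 1 / sqrt(hyper$tau_c), log = TRUE) +
      sum(dnorm(Y[idx, g], v + st$k[b, g] * st$t[idx],
                1 / sqrt(st$tau[g]), log = TRUE))
  }
  errs <- add(errs, "c", cc$mean[g], 1 / cc$prec[g], logf,
              cc$mean[g], 1 / sqrt(cc$prec[g]))

  ck <- bmfa:::cond_gradient(st, Y, hyper, b)
  logf <- function(v) {
    dnorm(v, st$theta[g], 1 / sqrt(st$chi[g]), log = TRUE) +
      sum(dnorm(Y[idx, g], st$c[b, g] + v * st$t[idx],
                1 / sqrt(st$tau[g]), log = TRUE))
  }
  errs <- add(errs, "k", ck$mean[g], 1 / ck$prec[g], logf,
              ck$mean[g], 1 / sqrt(ck$prec[g]))

  # shared gradient theta_1
  ct <- bmfa:::cond_theta(st, hyper)
  logf <- function(v) {
    dnorm(v, hyper$theta_tilde, 1 / sqrt(hyper$tau_theta), log = TRUE) +
      sum(dnorm(st$k[, g], v, 1 / sqrt(st$chi[g]), log = TRUE))
  }
  errs <- add(errs, "theta", ct$mean[g], 1 / ct$prec[g], logf,
              ct$mean[g], 1 / sqrt(ct$prec[g]))

  # shrinkage chi_1 (positive support: grid over (~0, far tail])
  cx <- bmfa:::cond_chi(st, hyper)
  m_cl <- cx$shape / cx$rate[g]; v_cl <- cx$shape / cx$rate[g]^2
  logf <- function(v) {
    dgamma(v, hyper$alpha_chi, rate = hyper$beta_chi, log = TRUE) +
      sum(dnorm(st$k[, g], st$theta[g], 1 / sqrt(v), log = TRUE))
  }
  o <- grid_moments(logf, 1e-9, qgamma(1 - 1e-14, cx$shape, rate = cx$rate[g]))
  errs <- c(errs, chi_mean = abs(o$mean - m_cl), chi_var = abs(o$var - v_cl))

  # eta_1
  ce <- bmfa:::cond_eta(st, hyper)
  logf <- function(v) {
    dnorm(v, hyper$eta_tilde, 1 / sqrt(hyper$tau_eta), log = TRUE) +
      sum(dnorm(st$c[, g], v, 1 / sqrt(hyper$tau_c), log = TRUE))
  }
  errs <- add(errs, "eta", ce$mean[g], 1 / ce$prec[g], logf,
              ce$mean[g], 1 / sqrt(ce$prec[g]))

  # noise precision tau_1
  ctau <- bmfa:::cond_tau(st, Y, hyper)
  m_cl <- ctau$shape / ctau$rate[g]; v_cl <- ctau$shape / ctau$rate[g]^2
  mu_g <- st$c[st$gamma, g] + st$k[st$gamma, g] * st$t
  logf <- function(v) {
    dgamma(v, hyper$alpha, rate = hyper$beta, log = TRUE) +
      sum(dnorm(Y[, g], mu_g, 1 / sqrt(v), log = TRUE))
  }
  o <- grid_moments(logf, 1e-9, qgamma(1 - 1e-14, ctau$shape, rate = ctau$rate[g]))
  errs <- c(errs, tau_mean = abs(o$mean - m_cl), tau_var = abs(o$var - v_cl))

  # ZI imputation: tilted Normal for a zero entry
  Yz <- Y; Yz[1L, 1L] <- 0
  zst <- bmfa:::new_zi_state(st, Yz, Yz == 0, lambda = 2.5)
  b <- st$gamma[1L]
  mu <- st$c[b, 1L] + st$k[b, 1L] * st$t[1L]
  s2 <- 1 / st$tau[1L]
  m_cl <- mu - 2.5 * s2 / N
  logf <- function(v) dnorm(v, mu, sqrt(s2), log = TRUE) - 2.5 * v / N
  errs <- add(errs, "impute", m_cl, s2, logf, m_cl, sqrt(s2))

  errs
}

# Minimal hand-built trace for summary-level tests.
make_trace <- function(t, gamma, chi = NULL, log_joint = NULL, B = 2L,
                       omega = NULL) {
  S <- nrow(t); N <- ncol(t); G <- if (is.null(chi)) 2L else ncol(chi)
  if (is.null(chi)) chi <- matrix(1, S, G)
  if (is.null(log_joint)) log_joint <- rep(0, S)
  if (is.null(omega)) omega <- matrix(1 / B, S, B)
  structure(list(
    t = t, gamma = gamma, c = array(0, c(S, B, G)), k = array(0, c(S, B, G)),
    eta = matrix(0, S, G), theta = matrix(0, S, G), chi = chi,
    tau = matrix(1, S, G), omega = omega, log_joint = log_joint,
    imputed_mean = NULL,
    meta = list(iterations = S, burnin = 0L, thin = 1L, seed = 1L,
                pc_index = 1L, B = B, N = N, G = G,
                cell_ids = paste0("cell_", seq_len(N)),
                gene_ids = paste0("gene_", seq_len(G)),
                zero_inflated = FALSE, lambda = NULL)),
    class = "bmfa_trace")
}

abs_cor <- function(a, b) abs(stats::cor(a, b))

pc_scores <- function(Y, pc = 1L) {
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(Yc, nu = pc, nv = 0)
  sv$u[, pc] * sv$d[pc]
}
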