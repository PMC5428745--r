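# Core model types: expression matrices, hyperparameters, model states,
# the joint log density and PCA-based initialization.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("bmfa_invalid_argument", "bmfa_error")))
}
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("bmfa_degenerate_input", "bmfa_error")))
}
stop_estimation <- function(...) {
  stop(errorCondition(paste0(...), class = c("bmfa_estimation_error", "bmfa_error")))
}

#' Construct and validate an expression matrix
#'
#' Wraps an \eqn{N \times G} numeric matrix of normalized log-scale
#' expression (cells in rows, genes in columns) and enforces the model's
#' input contract: at least two cells and two genes, all entries finite,
#' unique cell and gene identifiers.
#'
#' @param values Numeric matrix, cells x genes.
#' @param cell_ids Character vector of length N. Defaults to existing
#'   rownames, or `cell_1 ... cell_N`.
#' @param gene_ids Character vector of length G. Defaults to existing
#'   colnames, or `gene_1 ... gene_G`.
#' @return A numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("'values' must be a numeric matrix")
  N <- nrow(values); G <- ncol(values)
  if (N < 2L || G < 2L)
    stop_invalid("expression matrix needs N >= 2 cells and G >= 2 genes, got ",
                 N, " x ", G)
  if (anyNA(values) || !all(is.finite(values)))
    stop_invalid("expression matrix contains missing or non-finite entries")
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(N))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(G))
  if (length(cell_ids) != N || length(gene_ids) != G)
    stop_invalid("id lengths do not match matrix dimensions")
  if (anyDuplicated(cell_ids)) stop_invalid("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop_invalid("duplicate gene ids")
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  values
}

#' Model hyperparameters
#'
#' All user-fixed quantities of the hierarchical MFA prior: the number of
#' branches B, the prior means and precisions of the shared intercept
#' (`eta_tilde`, `tau_eta`) and shared gradient (`theta_tilde`,
#' `tau_theta`), the intercept precision `tau_c`, the Gamma shape/rate of
#' the per-gene shrinkage precisions chi (`alpha_chi`, `beta_chi`) and of
#' the per-gene noise precisions tau (`alpha`, `beta`).
#'
#' @param B Integer number of branches, at least 2.
#' @param eta_tilde,theta_tilde Prior means (real).
#' @param tau_eta,tau_theta,tau_c Prior precisions (positive).
#' @param alpha_chi,beta_chi Gamma shape/rate for the shrinkage precisions.
#' @param alpha,beta Gamma shape/rate for the noise precisions.
#' @return An object of class `bmfa_hyper`.
#' @export
mfa_hyperparameters <- function(B = 2L, eta_tilde = 0, theta_tilde = 0,
                                tau_eta = 1, tau_theta = 1, tau_c = 1,
                                alpha_chi = 1e-2, beta_chi = 1e-2,
                                alpha = 2, beta = 1) {
  B <- as.integer(B)
  if (is.na(B) || B < 2L) stop_invalid("B must be an integer >= 2")
  pos <- c(tau_eta = tau_eta, tau_theta = tau_theta, tau_c = tau_c,
           alpha_chi = alpha_chi, beta_chi = beta_chi, alpha = alpha,
           beta = beta)
  if (anyNA(pos) || any(pos <= 0))
    stop_invalid("precisions, shapes and rates must all be strictly positive")
  if (!is.finite(eta_tilde) || !is.finite(theta_tilde))
    stop_invalid("prior means must be finite")
  structure(list(B = B, eta_tilde = eta_tilde, theta_tilde = theta_tilde,
                 tau_eta = tau_eta, tau_theta = tau_theta, tau_c = tau_c,
                 alpha_chi = alpha_chi, beta_chi = beta_chi,
                 alpha = alpha, beta = beta),
            class = "bmfa_hyper")
}

#' Default hyperparameters for a dataset
#'
#' The shrinkage prior is the non-informative `alpha_chi = beta_chi = 1e-2`,
#' chosen to make the posterior of chi maximally informative about which
#' genes behave differently across branches. The remaining defaults are
#' data-scale neutral: the intercept prior mean is the grand mean of the
#' data, the gradient prior mean is 0, all structural precisions are 1, and
#' the noise precisions get a proper weakly informative Gamma(2, 1) prior.
#'
#' @param B Number of branches (>= 2).
#' @param Y Expression matrix (cells x genes), see [expression_matrix()].
#' @return A `bmfa_hyper` object.
#' @export
default_hyperparameters <- function(B = 2L, Y) {
  Y <- expression_matrix(Y)
  mfa_hyperparameters(B = B, eta_tilde = mean(Y), theta_tilde = 0,
                      tau_eta = 1, tau_theta = 1, tau_c = 1,
                      alpha_chi = 1e-2, beta_chi = 1e-2,
                      alpha = 2, beta = 1)
}

# Build a model state; internal constructor, no validation beyond shapes.
new_state <- function(omega, gamma, eta, theta, chi, c, k, t, tau) {
  structure(list(omega = omega, gamma = as.integer(gamma), eta = eta,
                 theta = theta, chi = chi, c = c, k = k, t = t, tau = tau),
            class = "bmfa_state")
}

validate_state <- function(state, Y, hyper) {
  N <- nrow(Y); G <- ncol(Y); B <- hyper$B
  if (length(state$t) != N || length(state$gamma) != N)
    stop_invalid("state/cell dimension mismatch")
  if (length(state$eta) != G || length(state$theta) != G ||
      length(state$chi) != G || length(state$tau) != G)
    stop_invalid("state/gene dimension mismatch")
  if (!identical(dim(state$c), c(B, G)) || !identical(dim(state$k), c(B, G)))
    stop_invalid("loading matrices must be B x G")
  if (length(state$omega) != B || any(state$omega < 0) ||
      abs(sum(state$omega) - 1) > 1e-8)
    stop_invalid("omega must be a length-B simplex vector")
  if (any(state$gamma < 1L) || any(state$gamma > B))
    stop_invalid("branch labels out of range 1..B")
  if (any(state$chi <= 0) || any(state$tau <= 0))
    stop_invalid("precisions chi and tau must be strictly positive")
  invisible(state)
}

# Gaussian log likelihood of Y under the per-branch linear factor model.
log_likelihood <- function(state, Y) {
  mu <- state$c[state$gamma, , drop = FALSE] +
    state$k[state$gamma, , drop = FALSE] * state$t
  sdm <- rep(1 / sqrt(state$tau), each = nrow(Y))
  sum(stats::dnorm(Y, mu, sdm, log = TRUE))
}

log_prior <- function(state, hyper) {
  B <- hyper$B
  a <- rep(1 / B, B)
  lp <- lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(state$omega))
  lp <- lp + sum(log(state$omega[state$gamma]))
  lp <- lp + sum(stats::dnorm(state$t, 0, 1, log = TRUE))
  lp <- lp + sum(stats::dnorm(state$eta, hyper$eta_tilde,
                              1 / sqrt(hyper$tau_eta), log = TRUE))
  lp <- lp + sum(stats::dnorm(state$theta, hyper$theta_tilde,
                              1 / sqrt(hyper$tau_theta), log = TRUE))
  lp <- lp + sum(stats::dgamma(state$chi, hyper$alpha_chi,
                               rate = hyper$beta_chi, log = TRUE))
  lp <- lp + sum(stats::dgamma(state$tau, hyper$alpha,
                               rate = hyper$beta, log = TRUE))
  for (b in seq_len(B)) {
    lp <- lp + sum(stats::dnorm(state$c[b, ], state$eta,
                                1 / sqrt(hyper$tau_c), log = TRUE))
    lp <- lp + sum(stats::dnorm(state$k[b, ], state$theta,
                                1 / sqrt(state$chi), log = TRUE))
  }
  lp
}

#' Joint log density of a model state
#'
#' Sum of all prior log densities of the hierarchical MFA specification plus
#' the Gaussian log likelihood
#' \eqn{\sum_i \sum_g \log N(y_{ig}; c_{\gamma_i g} + k_{\gamma_i g} t_i, \tau_g^{-1})}.
#'
#' @param state A `bmfa_state`.
#' @param Y Expression matrix (cells x genes).
#' @param hyper A `bmfa_hyper` object whose dimensions match `state`.
#' @return A finite scalar for any valid state.
#' @export
log_joint <- function(state, Y, hyper) {
  Y <- expression_matrix(Y)
  validate_state(state, Y, hyper)
  log_likelihood(state, Y) + log_prior(state, hyper)
}

#' Initialize a model state from PCA
#'
#' Pseudotimes are initialized to the scores of a chosen principal
#' component, standardized to zero mean and unit variance; this picks the
#' posterior mode the sampler will explore, since the direction of
#' pseudotime is not identifiable from expression alone. Branch labels are
#' drawn uniformly at random under `seed`. Intercepts start at the gene
#' means, gradients at the per-gene least-squares slope of expression on
#' the initial pseudotime (shared across branches), `eta` at the gene
#' means, `theta` at the shared slope, `chi` at its prior mean
#' `alpha_chi / beta_chi`, `tau` at 1 and `omega` uniform.
#'
#' @param Y Expression matrix (cells x genes).
#' @param hyper A `bmfa_hyper`.
#' @param pc_index Which principal component initializes pseudotime
#'   (1-based; the default 1 suits most data, component 2 was useful for
#'   hematopoietic scRNA-seq).
#' @param seed Integer seed for the random branch labels.
#' @return A `bmfa_state`.
#' @export
init_state <- function(Y, hyper, pc_index = 1L, seed = 1L) {
  Y <- expression_matrix(Y)
  N <- nrow(Y); G <- ncol(Y); B <- hyper$B
  pc_index <- as.integer(pc_index)
  if (is.na(pc_index) || pc_index < 1L || pc_index > min(N, G))
    stop_invalid("pc_index must lie in 1..min(N, G) = 1..", min(N, G))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sv <- svd(Yc, nu = pc_index, nv = 0)
  scores <- sv$u[, pc_index] * sv$d[pc_index]
  s <- stats::sd(scores)
  if (!is.finite(s) || s < 1e-12)
    stop_degenerate("principal component ", pc_index,
                    " has (near-)zero variance; PCA initialization is degenerate")
  t0 <- as.numeric(scale(scores))
  set.seed(seed)
  gamma <- sample.int(B, N, replace = TRUE)
  gmean <- unname(colMeans(Y))
  slope <- as.numeric(crossprod(Yc, t0 - mean(t0))) / sum((t0 - mean(t0))^2)
  new_state(omega = rep(1 / B, B),
            gamma = gamma,
            eta = gmean,
            theta = slope,
            chi = rep(hyper$alpha_chi / hyper$beta_chi, G),
            c = matrix(rep(gmean, each = B), B, G),
            k = matrix(rep(slope, each = B), B, G),
            t = t0,
            tau = rep(1, G))
}
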