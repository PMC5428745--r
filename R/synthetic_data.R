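# Synthetic data generators: an exact-model generator for parameter
# recovery, a sigmoidal bifurcating toy generator (deliberately mildly
# mis-specified with respect to the linear model), and exponential
# per-gene dropout.

new_truth <- function(Y, t_true, gamma_true, bifurcating, transient,
                      lambda_used, seed, params = NULL) {
  structure(list(Y = Y, t_true = t_true, gamma_true = as.integer(gamma_true),
                 bifurcating = bifurcating, transient = transient,
                 lambda_used = lambda_used, seed = as.integer(seed),
                 params = params),
            class = "bmfa_truth")
}

#' Simulate data from the model's own generative process
#'
#' Draws every parameter from the hierarchical prior and emits Y from the
#' Gaussian likelihood. For the non-bifurcating fraction of genes the
#' gradient is drawn once and copied across branches; for the bifurcating
#' fraction it is drawn independently per branch from
#' `Normal(theta_g, chi_g^-1)`. Used to validate the sampler (parameter
#' recovery on well-specified data).
#'
#' @param n_cells,n_genes Dimensions of the output matrix.
#' @param B Number of branches.
#' @param frac_bifurcating Fraction of genes (in `[0, 1]`) whose gradients
#'   differ across branches; the first `round(frac * n_genes)` genes.
#' @param hyper A `bmfa_hyper` providing all prior parameters.
#' @param seed Integer seed.
#' @return A `bmfa_truth` with fields `Y`, `t_true`, `gamma_true`,
#'   `bifurcating`, `transient` (all FALSE here), `lambda_used` (Inf) and
#'   the drawn parameters in `$params`.
#' @export
generate_exact_model <- function(n_cells, n_genes, B = 2L,
                                 frac_bifurcating = 0.5, hyper, seed = 1L) {
  if (!is.numeric(frac_bifurcating) || is.na(frac_bifurcating) ||
      frac_bifurcating < 0 || frac_bifurcating > 1)
    stop_invalid("frac_bifurcating must lie in [0, 1]")
  if (!inherits(hyper, "bmfa_hyper")) stop_invalid("hyper must be a bmfa_hyper")
  if (hyper$B != B) stop_invalid("hyper$B must equal B")
  N <- as.integer(n_cells); G <- as.integer(n_genes)
  set.seed(seed)
  gdir <- stats::rgamma(B, 1 / B, rate = 1)
  omega <- gdir / sum(gdir)
  gamma <- sample.int(B, N, replace = TRUE, prob = omega)
  t <- stats::rnorm(N)
  eta <- stats::rnorm(G, hyper$eta_tilde, 1 / sqrt(hyper$tau_eta))
  theta <- stats::rnorm(G, hyper$theta_tilde, 1 / sqrt(hyper$tau_theta))
  chi <- stats::rgamma(G, hyper$alpha_chi, rate = hyper$beta_chi)
  tau <- stats::rgamma(G, hyper$alpha, rate = hyper$beta)
  cmat <- matrix(stats::rnorm(B * G, rep(eta, each = B), 1 / sqrt(hyper$tau_c)),
                 B, G)
  n_bif <- round(frac_bifurcating * G)
  bif <- seq_len(G) <= n_bif
  kmat <- matrix(0, B, G)
  shared <- stats::rnorm(G, theta, 1 / sqrt(chi))
  for (b in seq_len(B)) {
    kb <- shared
    if (n_bif > 0)
      kb[bif] <- stats::rnorm(n_bif, theta[bif], 1 / sqrt(chi[bif]))
    kmat[b, ] <- kb
  }
  mu <- cmat[gamma, , drop = FALSE] + kmat[gamma, , drop = FALSE] * t
  Y <- mu + matrix(stats::rnorm(N * G, 0, rep(1 / sqrt(tau), each = N)), N, G)
  Y <- expression_matrix(Y)
  new_truth(Y, t_true = t, gamma_true = gamma, bifurcating = bif,
            transient = rep(FALSE, G), lambda_used = Inf, seed = seed,
            params = list(omega = omega, eta = eta, theta = theta, chi = chi,
                          tau = tau, c = cmat, k = kmat))
}

# Sigmoidal / transient mean functions used by the toy generator.
sigmoid_mean <- function(t, mu0, k, t0) 2 * mu0 / (1 + exp(-k * (t - t0)))
transient_mean <- function(t, mu0, w, p) 2 * mu0 * exp(-w * (t - p)^2)

#' Simulate the sigmoidal bifurcating toy dataset
#'
#' 300 cells x 60 genes by default. Pseudotimes are Uniform(0, 1) and each
#' cell carries one of two branch labels, independent of pseudotime
#' (pre-bifurcation cells can equally be said to lie on either branch).
#' Genes are partitioned into a transient fraction, then half of the
#' remainder bifurcating and half common:
#' \itemize{
#'   \item common: mean `2 mu0 / (1 + exp(-k (t - t0)))`, identical on
#'     both branches, switching early (`t0 ~ U(0, 0.5)`) so the
#'     pre-bifurcation stem has dynamics;
#'   \item bifurcating: the same sigmoid with `t0 ~ U(0.5, 1)` on one
#'     randomly chosen branch, while the other branch stays flat at the
#'     shared pre-bifurcation baseline (0 for a rising gene, `2 mu0` for a
#'     falling one), so the two branch means agree before the bifurcation
#'     at t = 0.5 and diverge after it;
#'   \item transient: mean `2 mu0 exp(-w (t - p)^2)`, identical on both
#'     branches (briefly up-regulated and back).
#' }
#' Per-gene shape parameters: `mu0 ~ U(5, 10)`, `|k| ~ U(5, 10)` with random
#' sign, transient peak `p ~ U(0.3, 0.7)` and width `w ~ U(30, 50)`.
#' Observation noise is Gaussian with sd 0.5 and simulated values are not
#' clipped. In PCA space the data show the characteristic Y shape of a
#' bifurcation, and the leading principal component tracks pseudotime.
#'
#' @param n_cells,n_genes Dimensions (defaults 300 x 60).
#' @param prop_transient Proportion of genes (in `[0, 0.8]`) with transient
#'   behavior.
#' @param seed Integer seed.
#' @return A `bmfa_truth`; `$params` keeps the per-gene shape parameters
#'   and branch mean functions used.
#' @export
generate_sigmoidal_toy <- function(n_cells = 300L, n_genes = 60L,
                                   prop_transient = 0, seed = 1L) {
  if (!is.numeric(prop_transient) || is.na(prop_transient) ||
      prop_transient < 0 || prop_transient > 0.8)
    stop_invalid("prop_transient must lie in [0, 0.8]")
  N <- as.integer(n_cells); G <- as.integer(n_genes)
  set.seed(seed)
  n_trans <- round(prop_transient * G)
  n_bif <- (G - n_trans) %/% 2L
  n_common <- G - n_trans - n_bif
  kind <- rep(c("bifurcating", "common", "transient"),
              c(n_bif, n_common, n_trans))
  t <- stats::runif(N)
  gamma <- sample.int(2L, N, replace = TRUE)
  mu0 <- stats::runif(G, 5, 10)
  kmag <- stats::runif(G, 5, 10)
  ksign <- sample(c(-1, 1), G, replace = TRUE)
  kg <- kmag * ksign
  t0 <- ifelse(kind == "bifurcating", stats::runif(G, 0.5, 1),
               stats::runif(G, 0, 0.5))
  pk <- stats::runif(G, 0.3, 0.7)
  wd <- stats::runif(G, 30, 50)
  active_branch <- sample.int(2L, G, replace = TRUE)  # used by bifurcating genes
  branch_means <- function(t, branch) {
    M <- matrix(0, length(t), G)
    for (g in seq_len(G)) {
      M[, g] <- switch(kind[g],
        transient = transient_mean(t, mu0[g], wd[g], pk[g]),
        common = sigmoid_mean(t, mu0[g], kg[g], t0[g]),
        bifurcating = if (branch == active_branch[g])
          sigmoid_mean(t, mu0[g], kg[g], t0[g])
        else  # flat at the shared pre-bifurcation baseline
          rep(if (kg[g] > 0) 0 else 2 * mu0[g], length(t)))
    }
    M
  }
  M <- matrix(0, N, G)
  for (b in 1:2) {
    idx <- gamma == b
    if (any(idx)) M[idx, ] <- branch_means(t[idx], b)
  }
  Y <- M + matrix(stats::rnorm(N * G, 0, 0.5), N, G)
  Y <- expression_matrix(Y)
  new_truth(Y, t_true = t, gamma_true = gamma,
            bifurcating = kind == "bifurcating",
            transient = kind == "transient",
            lambda_used = Inf, seed = seed,
            params = list(kind = kind, mu0 = mu0, k = kg, t0 = t0,
                          peak = pk, width = wd,
                          active_branch = active_branch, sigma_obs = 0.5,
                          branch_means = branch_means))
}

#' Apply exponential dropout to a synthetic dataset
#'
#' With `method = "gene"` (the fitted model's own dropout form) each gene's
#' dropout probability `p_g = exp(-(lambda/N) sum_i x_ig)` is computed on
#' the pre-dropout matrix (clipped into `[0, 1]`) and every entry of gene g
#' is independently zeroed with probability `p_g`. With
#' `method = "entry"` each entry is zeroed with its own probability
#' `exp(-lambda x_ig)` (clipped), so lowly expressed measurements drop out
#' preferentially — the more realistic mechanism used for the
#' dropout-robustness experiments. `lambda = Inf` leaves the matrix
#' unchanged (no dropout, only true zeros); smaller lambda means more
#' dropout.
#'
#' @param truth A `bmfa_truth` whose `$Y` is the pre-dropout matrix.
#' @param lambda Positive dropout rate, `Inf` allowed.
#' @param seed Integer seed for the Bernoulli mask.
#' @param method `"gene"` (default) or `"entry"`, see above.
#' @return The `bmfa_truth` with zeros introduced and `lambda_used` set.
#' @export
apply_dropout <- function(truth, lambda, seed = 1L,
                          method = c("gene", "entry")) {
  if (!inherits(truth, "bmfa_truth")) stop_invalid("truth must be a bmfa_truth")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    stop_invalid("lambda must be > 0 (Inf allowed)")
  method <- match.arg(method)
  truth$lambda_used <- lambda
  truth$seed <- as.integer(seed)
  if (is.infinite(lambda)) return(truth)
  Y <- truth$Y
  N <- nrow(Y)
  p <- if (method == "gene")
    matrix(pmin(pmax(exp(-(lambda / N) * colSums(Y)), 0), 1),
           N, ncol(Y), byrow = TRUE)
  else pmin(pmax(exp(-lambda * Y), 0), 1)
  set.seed(seed)
  drop_mask <- matrix(stats::runif(length(Y)), N, ncol(Y)) < p
  Y[drop_mask] <- 0
  truth$Y <- Y
  truth
}
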