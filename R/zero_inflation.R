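# Zero-inflated variant: Empirical-Bayes dropout rate estimation and Gibbs
# imputation of latent expression for observed zeros.
#
# Dropout is modeled per gene: P(dropout in gene g) = exp(-(lambda/N) sum_i
# x_ig), with x the latent (pre-dropout) expression and lambda a single
# global rate. Because a zero can also be a genuine absence of transcript
# and the two are indistinguishable, every observed zero is treated as a
# dropout and its latent value is imputed during sampling.

new_zi_state <- function(base, X, zero_mask, lambda, z_per_gene = NULL) {
  if (is.null(z_per_gene))
    z_per_gene <- .colSums(zero_mask, nrow(zero_mask), ncol(zero_mask))
  structure(list(base = base, X = X, zero_mask = zero_mask, lambda = lambda,
                 z_per_gene = z_per_gene),
            class = "bmfa_zi_state")
}

#' Per-gene dropout probability
#'
#' Evaluates `exp(-(lambda/N) * sum_i x_ig)` for one gene of a latent
#' expression matrix, clipped into `[0, 1]` (the clip only matters when a
#' gene's latent sum is negative, which the Gaussian model permits).
#'
#' @param X Latent expression matrix (cells x genes).
#' @param g Gene (column) index.
#' @param lambda Positive dropout rate; larger values mean less dropout and
#'   `lambda = Inf` means none.
#' @return A probability in `[0, 1]`.
#' @export
dropout_probability <- function(X, g, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    stop_invalid("lambda must be a positive scalar (Inf allowed)")
  g <- as.integer(g)
  if (is.na(g) || g < 1L || g > ncol(X)) stop_invalid("gene index out of range")
  if (is.infinite(lambda)) return(0)
  p <- exp(-(lambda / nrow(X)) * sum(X[, g]))
  min(max(p, 0), 1)
}

#' Empirical-Bayes estimate of the global dropout rate
#'
#' Under the exponential dropout model the observed zero proportion of gene
#' g satisfies `p0_g = exp(-lambda * m_g)` with `m_g` the gene's mean
#' expression, i.e. `-log(p0_g)` is proportional to `m_g` through the
#' origin. The estimate is therefore the no-intercept least-squares slope
#' of `-log(p0_g)` on `m_g`, restricted to genes with a zero proportion
#' strictly between 0 and 1. Gene means are taken over all cells, zeros
#' included.
#'
#' @param Y Expression matrix (cells x genes) with observed zeros.
#' @return A positive scalar estimate of lambda.
#' @export
estimate_lambda <- function(Y) {
  Y <- expression_matrix(Y)
  N <- nrow(Y)
  p0 <- .colSums(Y == 0, N, ncol(Y)) / N
  m <- colMeans(Y)
  ok <- p0 > 0 & p0 < 1
  if (!any(ok))
    stop_estimation("no gene has a zero proportion strictly between 0 and 1; ",
                    "lambda cannot be estimated")
  y <- -log(p0[ok]); x <- m[ok]
  lambda <- sum(x * y) / sum(x * x)
  if (!is.finite(lambda) || lambda <= 0)
    stop_estimation("dropout rate estimate is not positive; ",
                    "the exponential dropout model does not fit these genes")
  lambda
}

#' Gibbs imputation of observed zeros
#'
#' Redraws the latent expression of every zero entry from its (approximate)
#' full conditional, an exponentially tilted Normal: with predictive mean
#' `mu_ig = c_{gamma_i g} + k_{gamma_i g} t_i` and variance
#' `sigma_g^2 = 1/tau_g`, the entry's own dropout factor contributes
#' `exp(-lambda x / N)`, giving
#' `x_ig ~ Normal(mu_ig - lambda sigma_g^2 / N, sigma_g^2)`. Nonzero
#' observed entries are never touched. The dependence of the other dropout
#' factors of the gene and of the retained `(1 - p_g)` factors of nonzero
#' entries on `x` is deliberately ignored (tilt-only approximation);
#' scaling the tilt by the gene's full zero count makes the chain diverge
#' at high dropout.
#'
#' @param state A `bmfa_zi_state`.
#' @param Y The observed expression matrix (used only to assert which
#'   entries are imputable).
#' @return The `bmfa_zi_state` with `X` redrawn at the zero mask.
#' @export
impute_zeros <- function(state, Y) {
  if (!inherits(state, "bmfa_zi_state")) stop_invalid("state must be a bmfa_zi_state")
  mask <- state$zero_mask
  if (!any(mask)) return(state)
  st <- state$base
  N <- nrow(mask)
  mu <- st$c[st$gamma, , drop = FALSE] + st$k[st$gamma, , drop = FALSE] * st$t
  sig2 <- rep(1 / st$tau, each = N)
  mean_mat <- mu - (state$lambda / N) * sig2
  idx <- which(mask)
  state$X[idx] <- stats::rnorm(length(idx), mean_mat[idx], sqrt(sig2[idx]))
  state
}

#' Fit the zero-inflated mixture of factor analyzers
#'
#' Identical to [gibbs_sample()] except that every conditional sees the
#' latent matrix X in place of Y, and each sweep ends by re-imputing the
#' zero entries via [impute_zeros()]. The dropout rate lambda is estimated
#' once up front by [estimate_lambda()] (Empirical Bayes) and held fixed;
#' pass `lambda` to override. If Y contains no zeros the run is
#' bit-identical to the standard sampler under the same seed.
#'
#' @inheritParams gibbs_sample
#' @param lambda Optional positive dropout rate overriding the
#'   Empirical-Bayes estimate.
#' @return A `bmfa_trace` whose metadata records `lambda` and which
#'   additionally carries the per-sweep mean of imputed values
#'   (`imputed_mean`).
#' @export
zi_gibbs_sample <- function(Y, hyper = NULL, settings = gibbs_settings(2000L),
                            pc_index = 1L, lambda = NULL, verbose = FALSE) {
  if (is.null(hyper)) hyper <- default_hyperparameters(2L, Y)
  run_gibbs(Y, hyper, settings, pc_index, zero_inflation = TRUE,
            lambda = lambda, verbose = verbose)
}
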