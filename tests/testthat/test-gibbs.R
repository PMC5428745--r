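test_that("every closed-form conditional matches the grid oracle", {
  for (seed in c(42L, 7L, 99L)) {
    errs <- conditional_oracle_errors(seed)
    expect_lt(max(errs), 1e-6)
  }
})

test_that("pseudotime conditional reduces to the prior when gradients vanish", {
  p <- tiny_problem()
  st <- p$state
  st$k[] <- 0
  cp <- bmfa:::cond_pseudotime(st, p$Y)
  expect_equal(cp$mean, rep(0, nrow(p$Y)))
  expect_equal(cp$prec, rep(1, nrow(p$Y)))
})

test_that("scalar pseudotime case and precision monotonicity behave", {
  # G = 2 but the second gene carries no information (k = 0); effective
  # scalar instance y = 2, k = 1, c = 0, tau = 1 -> Normal(1, 1/2)
  Y <- expression_matrix(matrix(c(2, 0, 0, 0), 2, 2))
  st <- bmfa:::new_state(omega = c(0.5, 0.5), gamma = c(1L, 1L),
                         eta = c(0, 0), theta = c(0, 0), chi = c(1, 1),
                         c = matrix(0, 2, 2), k = matrix(c(1, 1, 0, 0), 2, 2),
                         t = c(0, 0), tau = c(1, 1))
  cp <- bmfa:::cond_pseudotime(st, Y)
  expect_equal(cp$mean[1], 1)
  expect_equal(1 / cp$prec[1], 0.5)
  # doubling tau shrinks the conditional variance and moves the mean
  # toward the least-squares value (y/k = 2)
  st2 <- st; st2$tau <- c(2, 2)
  cp2 <- bmfa:::cond_pseudotime(st2, Y)
  expect_lt(1 / cp2$prec[1], 1 / cp$prec[1])
  expect_gt(cp2$mean[1], cp$mean[1])
  expect_lt(cp2$mean[1], 2)
})

test_that("empty branches fall back to the prior", {
  p <- tiny_problem()
  st <- p$state
  st$gamma <- rep(1L, nrow(p$Y))  # branch 2 empty
  cc <- bmfa:::cond_intercept(st, p$Y, p$hyper, 2L)
  expect_equal(cc$mean, st$eta)
  expect_equal(cc$prec, rep(p$hyper$tau_c, ncol(p$Y)))
  ck <- bmfa:::cond_gradient(st, p$Y, p$hyper, 2L)
  expect_equal(ck$mean, st$theta)
  expect_equal(ck$prec, st$chi)
  # a full sweep with an empty branch must not error
  expect_no_error(update_factor_loadings(st, p$Y, p$hyper))
})

test_that("shrinkage conditional flags genes with divergent gradients", {
  p <- tiny_problem()
  h <- mfa_hyperparameters(B = 2, alpha_chi = 0.01, beta_chi = 0.01)
  st <- p$state
  # zero deviation: chi | rest ~ Gamma(alpha_chi + B/2, beta_chi),
  # mean 1.01/0.01 = 101
  st$k[1, ] <- st$k[2, ] <- st$theta
  cx <- bmfa:::cond_chi(st, h)
  expect_equal(cx$shape, 1.01)
  expect_equal(cx$rate, rep(0.01, 2))
  expect_equal(cx$shape / cx$rate[1], 101)
  # large gradient gap: conditional mean of chi collapses, 1/chi blows up
  st2 <- st; st2$k[1, 1] <- st2$theta[1] + 50; st2$k[2, 1] <- st2$theta[1] - 50
  cx2 <- bmfa:::cond_chi(st2, h)
  expect_lt(cx2$shape / cx2$rate[1], 0.01 * (cx$shape / cx$rate[1]))
})

test_that("noise-precision conditional matches the perfect-fit case", {
  p <- tiny_problem()
  st <- p$state
  Yfit <- st$c[st$gamma, ] + st$k[st$gamma, ] * st$t
  ct <- bmfa:::cond_tau(st, expression_matrix(Yfit), p$hyper)
  expect_equal(ct$shape, p$hyper$alpha + nrow(p$Y) / 2)
  expect_equal(ct$rate, rep(p$hyper$beta, ncol(p$Y)))
  # doubling all residuals quadruples the data part of the rate
  r1 <- bmfa:::cond_tau(st, expression_matrix(Yfit + 1), p$hyper)$rate
  r2 <- bmfa:::cond_tau(st, expression_matrix(Yfit + 2), p$hyper)$rate
  expect_equal(r2 - p$hyper$beta, 4 * (r1 - p$hyper$beta))
})

test_that("branch conditional is the prior under identical loadings and is
          underflow-safe", {
  p <- tiny_problem(N = 4L)
  st <- p$state
  st$c[2, ] <- st$c[1, ]; st$k[2, ] <- st$k[1, ]
  ll <- bmfa:::cond_branch_logprob(st, p$Y)
  pr <- exp(ll - apply(ll, 1, max))
  pr <- pr / rowSums(pr)
  expect_equal(pr, matrix(st$omega, 4, 2, byrow = TRUE), tolerance = 1e-12)

  # one branch 20+ sd away per gene: probability underflows to exact zero
  # without NaN/Inf
  st2 <- p$state
  st2$c[2, ] <- st2$c[1, ] + 40 / sqrt(st2$tau)
  st2$k[2, ] <- st2$k[1, ]
  Yb <- expression_matrix(st2$c[1, ][col(matrix(0, 4, 2))] +
                            outer(st2$t, st2$k[1, ]))
  ll2 <- bmfa:::cond_branch_logprob(st2, Yb)
  pr2 <- exp(ll2 - apply(ll2, 1, max)); pr2 <- pr2 / rowSums(pr2)
  expect_true(all(is.finite(pr2)))
  expect_equal(unname(pr2[, 2]), rep(0, 4))
  # log-space agreement with a direct high-precision computation
  direct <- sapply(1:2, function(b) {
    sapply(1:4, function(i) {
      log(st2$omega[b]) + sum(dnorm(Yb[i, ], st2$c[b, ] + st2$k[b, ] * st2$t[i],
                                    1 / sqrt(st2$tau), log = TRUE))
    })
  })
  expect_equal(ll2, direct, tolerance = 1e-9)
})

test_that("omega posterior is symmetric Dirichlet under balanced branches", {
  set.seed(1)
  p <- tiny_problem(N = 4L)
  st <- p$state
  # fully exchangeable branches: identical loadings and equal weights
  st$c[2, ] <- st$c[1, ]; st$k[2, ] <- st$k[1, ]
  st$omega <- c(0.5, 0.5)
  draws <- replicate(4000, update_branch_assignments(st, p$Y, p$hyper)$omega[1])
  # marginalizing the balanced categorical draw, E[omega_1] = 1/2
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  # and directly: with N_1 = N_2 fixed, the Dirichlet update is symmetric
  st$gamma <- c(1L, 1L, 2L, 2L)
  nb <- tabulate(st$gamma, 2)
  expect_identical(nb[1], nb[2])
})

test_that("gibbs_sample is reproducible and records what it promises", {
  set.seed(3)
  Y <- generate_sigmoidal_toy(n_cells = 40, n_genes = 8, seed = 3)$Y
  s <- gibbs_settings(60, 20, 4, seed = 9)
  tr1 <- gibbs_sample(Y, settings = s)
  tr2 <- gibbs_sample(Y, settings = s)
  expect_identical(tr1, tr2)
  expect_identical(n_states(tr1), 10L)       # floor((60-20)/4)
  expect_identical(dim(tr1$c), c(10L, 2L, 8L))
  expect_true(all(is.finite(tr1$log_joint)))
  st5 <- trace_state(tr1, 5)
  expect_s3_class(st5, "bmfa_state")
  expect_identical(st5$t, tr1$t[5, ])
  tr3 <- gibbs_sample(Y, settings = gibbs_settings(60, 20, 4, seed = 10))
  expect_false(identical(tr1$t, tr3$t))
  expect_error(gibbs_settings(100, 120), class = "bmfa_invalid_argument")
  expect_error(gibbs_settings(0), class = "bmfa_invalid_argument")
})

test_that("sign flips and branch permutations are likelihood symmetries", {
  p <- tiny_problem(N = 5L, G = 3L)
  st <- p$state
  # negating t and all gradients leaves the likelihood unchanged
  st_neg <- st; st_neg$t <- -st$t; st_neg$k <- -st$k
  expect_equal(bmfa:::log_likelihood(st_neg, p$Y),
               bmfa:::log_likelihood(st, p$Y))
  # permuting branch indices consistently leaves the joint unchanged
  perm <- c(2L, 1L)
  st_p <- st
  st_p$omega <- st$omega[perm]
  st_p$c <- st$c[perm, ]; st_p$k <- st$k[perm, ]
  st_p$gamma <- match(st$gamma, perm)
  expect_equal(log_joint(st_p, p$Y, p$hyper), log_joint(st, p$Y, p$hyper))
})

test_that("log joint is trend-free after burn-in on well-specified data", {
  hyper <- mfa_hyperparameters(B = 2, alpha_chi = 1, beta_chi = 4,
                               alpha = 10, beta = 1)
  truth <- generate_exact_model(60, 10, 2, 0.25, hyper, seed = 4)
  tr <- gibbs_sample(truth$Y, hyper, gibbs_settings(8000, 4000, 4, seed = 4))
  # the kept series is autocorrelated, so the slope is assessed on batch
  # means (20 batches), which are approximately independent
  lj <- tr$log_joint
  nb <- 20L; bs <- length(lj) %/% nb
  bm <- tapply(lj[seq_len(nb * bs)], rep(seq_len(nb), each = bs), mean)
  bi <- seq_len(nb)
  ci <- confint(lm(bm ~ bi))["bi", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})
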