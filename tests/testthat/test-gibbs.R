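test_that("stored draws are bit-identical given the seed and invariant to row order", {
  sf <- small_fit()
  design <- derive_design(sf$obs)    # fix strain indexing across row orders
  cfg <- mcmc_config(n_iter = 1000, burn_in = 200, thin = 10, seed = 11)
  d1 <- fit_gibbs(sf$obs, design, cfg)
  d2 <- fit_gibbs(sf$obs, design, cfg)
  expect_identical(d1$H, d2$H)
  expect_identical(d1$U, d2$U)
  expect_identical(d1$beta, d2$beta)
  # permuting rows leaves the sufficient statistics (hence the chain) unchanged
  set.seed(5)
  d3 <- fit_gibbs(sf$obs[sample(nrow(sf$obs)), ], design, cfg)
  expect_identical(d1$H, d3$H)
  expect_identical(d1$U, d3$U)
  # draw count invariant: n_iter / thin per chain
  expect_equal(n_draws(d1), 100)
})

test_that("every stored H draw is symmetric positive definite", {
  dr <- small_fit()$draws
  for (j in seq_len(n_draws(dr))) {
    H <- dr$H[j, , ]
    expect_lt(max(abs(H - t(H))), 1e-12)
    expect_gt(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("with all random variances at zero the fixed effects are pinned", {
  truth <- default_truth(H = matrix(0, 4, 4), sigma2_v = 0, sigma2_vS = 0,
                         residual = c(iF = 1e-6, oF = 1e-6, iM = 1e-6, oM = 1e-6))
  sim <- simulate_diallel(truth, scale_design(default_design(), 0.3), seed = 31)
  obs <- sim$observations
  obs$relative_fitness <- obs$count / 40     # keep the generating scale
  dr <- fit_gibbs(obs, config = mcmc_config(n_iter = 2000, burn_in = 500,
                                            thin = 10, seed = 32))
  post_mean <- colMeans(dr$beta)
  post_sd <- apply(dr$beta, 2, sd)
  expected <- c(1, 0.02, 0, -0.294, 0, 0)    # mu, S, B, I, SxI, BxI
  expect_lt(max(abs(post_mean - expected)), 0.01)
  expect_lt(max(post_sd), 0.01)
})

test_that("the 4x4 sampler restricted to one class matches a univariate oracle", {
  # theory: the diagonal marginal of IW(nu = 4, V_h*I4) is IG(1/2, V_h/2), so
  # single-class data reduce the model to the univariate PX one-way layout
  set.seed(11)
  k <- 12; m <- 8
  u <- rnorm(k, 0, sqrt(0.5))
  strains <- sprintf("S%02d", 1:k)
  y <- 2 + u[rep(1:k, each = m)] + rnorm(k * m, 0, 0.5)
  obs <- data.frame(sire = rep(strains, each = m), dam = rep(strains, each = m),
                    sex = "F", state = "i", block = 1L, count = y,
                    relative_fitness = y)
  design <- derive_design(obs)
  dr <- suppressMessages(fit_gibbs(obs, design, mcmc_config(
    n_iter = 27000, burn_in = 3000, thin = 30, seed = 21)))
  h11 <- dr$H[, 1, 1]
  oracle <- oneway_px_gibbs(y, rep(1:k, each = m),
                            n_iter = 33000, burn_in = 3000, thin = 30, seed = 22)
  expect_gt(stats::ks.test(h11, oracle)$p.value, 0.01)
  # classes without data are reported as NA, not prior garbage
  expect_true(all(is.na(dr$sigma2_e[, c("oF", "iM", "oM")])))
  expect_true(all(is.na(dr$sigma2_v)))
})

test_that("with zero-length data the sampler draws from the H prior", {
  obs0 <- data.frame(sire = character(0), dam = character(0),
                     sex = character(0), state = character(0),
                     block = integer(0), count = numeric(0))
  design <- default_design()
  dr <- fit_gibbs(obs0, design, mcmc_config(n_iter = 20000, burn_in = 0,
                                            thin = 20, seed = 41))
  h11 <- dr$H[, 1, 1]
  # direct prior sample: H11 = alpha^2 * psi, alpha ~ N(0, 625),
  # psi ~ IG(1/2, V_h/2) with the default V_h = 0.002
  set.seed(42)
  ref <- rnorm(5000, 0, 25)^2 / rgamma(5000, 0.5, rate = 0.001)
  expect_gt(stats::ks.test(log(h11), log(ref))$p.value, 0.001)
})

test_that("central 95% intervals for H diagonals cover truth at the nominal rate", {
  truth <- default_truth()
  design <- scale_design(default_design(), 0.25)
  nrep <- 50
  covered <- matrix(NA, nrep, 4)
  for (r in seq_len(nrep)) {
    sim <- simulate_diallel(truth, design, seed = 500 + r)
    obs <- standardize_relative_fitness(sim$observations)
    dr <- fit_gibbs(obs, config = mcmc_config(n_iter = 4000, burn_in = 1000,
                                              thin = 20, seed = 600 + r))
    for (k in 1:4) {
      ci <- stats::quantile(dr$H[, k, k], c(0.025, 0.975))
      covered[r, k] <- ci[1] <= truth$H[k, k] && truth$H[k, k] <= ci[2]
    }
  }
  cover <- colMeans(covered)
  expect_true(all(cover >= 0.85 & cover <= 1.0))
})
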