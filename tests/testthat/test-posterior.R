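test_that("heterosis is the outbred minus inbred effect, per draw and strain", {
  U <- array(0, c(12, 2, 4))
  U[, 1, ] <- matrix(rep(c(-0.2, 0.1, 0.3, 0.1), each = 12), 12, 4)  # iF oF iM oM
  U[, 2, ] <- matrix(rep(c(0.3, 0.3, 0.0, 0.4), each = 12), 12, 4)
  dr <- new_diallel_draws(U, array(rep(diag(4), 12), c(4, 4, 12)) |> aperm(c(3, 1, 2)))
  hF <- heterosis_per_draw(dr, "F")
  expect_equal(unname(hF[1, ]), c(0.3, 0.0))
  # o-column equal to i-column gives identically zero heterosis
  U2 <- U; U2[, , 2] <- U2[, , 1]; U2[, , 4] <- U2[, , 3]
  dr2 <- new_diallel_draws(U2, dr$H)
  expect_true(all(heterosis_per_draw(dr2, "F") == 0))
  expect_true(all(heterosis_per_draw(dr2, "M") == 0))
  # sex-averaged identity
  expect_equal(heterosis_per_draw(dr, "averaged"),
               ((U[, , 4] + U[, , 2]) / 2 - (U[, , 3] + U[, , 1]) / 2),
               ignore_attr = TRUE)
})

test_that("per-draw covariance and correlation match the brute-force oracle", {
  set.seed(91)
  x <- matrix(rnorm(200 * 16), 200, 16)
  y <- matrix(rnorm(200 * 16), 200, 16)
  cc <- per_draw_cov_corr(x, y)
  for (j in c(1, 57, 200)) {
    expect_equal(cc$cov[j], brute_cov(x[j, ], y[j, ]), tolerance = 1e-12)
    expect_equal(cc$cor[j], brute_corr(x[j, ], y[j, ]), tolerance = 1e-12)
  }
  expect_true(all(abs(cc$cor) <= 1))
  # exact anti-correlation and zero-variance handling
  cc2 <- per_draw_cov_corr(x, -x)
  expect_true(all(abs(cc2$cor + 1) < 1e-12))
  xconst <- x; xconst[3, ] <- 7
  cc3 <- per_draw_cov_corr(xconst, y)
  expect_equal(cc3$cov[3], 0)
  expect_true(is.na(cc3$cor[3]))
  expect_equal(cc3$n_excluded, 1)
  expect_error(per_draw_cov_corr(x[, 1:2], y[, 1:2]), "3 strains")
})

test_that("the KDE posterior mode behaves on symmetric, constant and skewed samples", {
  x <- 3 + stats::qnorm(stats::ppoints(200))   # symmetric unimodal around 3
  expect_equal(posterior_mode(x), 3, tolerance = 0.05)
  expect_equal(posterior_mode(rep(2.5, 50)), 2.5)
  set.seed(12)
  g <- rgamma(1e5, shape = 3, scale = 1)
  expect_equal(posterior_mode(g), 2, tolerance = 0.05)   # analytic (shape-1)*scale
  expect_error(posterior_mode(1:5), "at least 10")
})

test_that("HPD intervals are the shortest windows, ties to the lowest endpoint", {
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  x <- c(runif(99), 1000)
  hp <- hpd_interval(x, 0.95)
  expect_true(hp[2] <= 1)                               # outlier excluded
  set.seed(13)
  z <- rnorm(1e5)
  expect_equal(hpd_interval(z, 0.95), c(-1.96, 1.96), tolerance = 0.03)
  expect_error(hpd_interval(z, 1.2), "prob")
  # random cases against the exhaustive scan
  for (s in 1:5) {
    set.seed(100 + s)
    y <- rgamma(200, 2)
    expect_equal(hpd_interval(y, 0.9), brute_hpd(y, 0.9))
  }
})

test_that("MCMC p-values count draws on the opposite side of zero, twice", {
  set.seed(14)
  x <- abs(rnorm(1000)) + 0.5
  x[1:4] <- -x[1:4]
  expect_equal(as.numeric(mcmc_pvalue(x)), 0.008)
  # half the draws on each side, posterior mode positive -> p capped at 1
  half <- c(rnorm(500, 3, 0.1), rnorm(500, -3, 0.5))
  expect_gt(posterior_mode(half), 0)
  expect_equal(as.numeric(mcmc_pvalue(half)), 1)
  allpos <- abs(rnorm(1000)) + 0.1
  p <- mcmc_pvalue(allpos)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "below_resolution"))              # report as "< 2/n"
  pz <- mcmc_pvalue(c(rep(0, 11), 1e-9), mode = 0)
  expect_equal(as.numeric(pz), 1)                       # mode at zero convention
})

test_that("cross-iteration pairing is a seeded derangement", {
  for (s in 1:10) {
    perm <- cross_pairing(50, seed = s)
    expect_setequal(perm, 1:50)
    expect_false(any(perm == 1:50))
  }
  expect_identical(cross_pairing(1000, 3), cross_pairing(1000, 3))
})

test_that("selection intensity reduces to its algebraic identities", {
  set.seed(15)
  n <- 200; ns <- 16
  U <- array(rnorm(n * ns * 4, 0, 0.1), c(n, ns, 4))
  # constant outbred male vector in every draw -> beta = 0, p = 1
  U0 <- U; U0[, , 4] <- 0.3
  dr0 <- new_diallel_draws(U0, array(rep(diag(4), n), c(4, 4, n)) |> aperm(c(3, 1, 2)))
  s0 <- selection_intensity(dr0, "M", "opposite_sex")
  expect_true(all(s0$per_draw == 0))
  expect_equal(s0$p_value, 1)
  # heterosis exactly minus the outbred vector -> beta = -SD(outbred) per draw
  U1 <- U
  U1[, , 2] <- 0                      # oF = 0
  U1[, , 1] <- U1[, , 4]              # iF = oM  =>  hetF = -oM
  dr1 <- new_diallel_draws(U1, dr0$H)
  s1 <- selection_intensity(dr1, "M", "opposite_sex")
  sd_o <- apply(U1[, , 4], 1, sd)
  expect_equal(s1$per_draw, -sd_o, tolerance = 1e-12)
  # beta scales linearly with the outbred-fitness scale
  U3 <- U; U3[, , 4] <- 3 * U3[, , 4]
  dr3 <- new_diallel_draws(U3, dr0$H)
  drb <- new_diallel_draws(U, dr0$H)
  expect_equal(selection_intensity(dr3, "M", "opposite_sex")$per_draw,
               3 * selection_intensity(drb, "M", "opposite_sex")$per_draw)
  # sex-averaged variant requires a pairing seed
  expect_error(selection_intensity(drb, "M", "sex_averaged"), "pairing_seed")
})

test_that("genetic correlations hit their trivial anchors and scale invariance", {
  set.seed(16)
  n <- 400; ns <- 16
  U <- array(rnorm(n * ns * 4, 0, 0.1), c(n, ns, 4))
  H <- array(rep(diag(4), n), c(4, 4, n)) |> aperm(c(3, 1, 2))
  # identical male and female heterosis vectors -> r_het_MF = 1 every draw
  U1 <- U
  U1[, , 2] <- U1[, , 4]   # oF = oM
  U1[, , 1] <- U1[, , 3]   # iF = iM
  r1 <- genetic_correlation(new_diallel_draws(U1, H), "r_het_MF")
  expect_true(all(abs(r1$per_draw - 1) < 1e-12))
  # independent random vectors -> mode near zero at 16 strains
  r0 <- genetic_correlation(new_diallel_draws(U, H), "r_oM_hetF")
  expect_lt(abs(r0$posterior_mode), 0.3)
  # invariance to positive rescaling of all strain effects
  r2 <- genetic_correlation(new_diallel_draws(U * 4.2, H), "r_oM_hetF")
  expect_equal(r2$per_draw, r0$per_draw, tolerance = 1e-12)
})

test_that("sex-difference tests use the point-estimate direction with ties at half", {
  set.seed(17)
  m <- rnorm(1000)
  expect_equal(as.numeric(sex_difference_test(m, m)), 1)
  f <- m + abs(rnorm(1000)) + 0.1     # female statistic always larger
  p <- sex_difference_test(m, f)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "below_resolution"))
  expect_error(sex_difference_test(m, f[1:10]), "equal length")
  # null: centers jitter with spread equal to the posterior spread
  set.seed(18)
  ps <- replicate(200, as.numeric(sex_difference_test(
    rnorm(1) + rnorm(400), rnorm(1) + rnorm(400))))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("cross-iteration pairing removes shared-error bias in covariances", {
  set.seed(19)
  ns <- 16; nd <- 400; nrep <- 100
  same <- cross <- numeric(nrep)
  for (r in seq_len(nrep)) {
    u <- matrix(rnorm(ns * 4, 0, 0.1), ns, 4)   # truth: COV(oM, hetF) = 0
    U <- array(0, c(nd, ns, 4))
    for (j in seq_len(nd)) {
      d <- u
      e <- rnorm(ns, 0, 0.1)                    # shared sampling error
      d[, 4] <- d[, 4] + e
      d[, 2] <- d[, 2] + e
      d[, 1] <- d[, 1] + rnorm(ns, 0, 0.1)
      d[, 3] <- d[, 3] + rnorm(ns, 0, 0.1)
      U[j, , ] <- d
    }
    dr <- new_diallel_draws(U, array(rep(diag(4), nd), c(4, 4, nd)) |> aperm(c(3, 1, 2)))
    oM <- dr$U[, , "oM"]
    het <- heterosis_per_draw(dr, "F")
    same[r] <- mean(per_draw_cov_corr(oM, het)$cov)
    cross[r] <- mean(per_draw_cov_corr(oM[cross_pairing(nd, r), ], het)$cov)
  }
  # same-iteration pairing inherits var(shared error) ~ 0.01; cross does not
  expect_lt(t.test(same, mu = 0, alternative = "greater")$p.value, 1e-6)
  expect_gt(mean(same), 0.005)
  expect_lt(abs(mean(cross)), 0.002)
})

test_that("mcmc p-values are at worst super-uniform under a symmetric null", {
  set.seed(20)
  ps <- replicate(300, as.numeric(mcmc_pvalue(rnorm(1) + rnorm(300))))
  grid <- seq(0.05, 1, by = 0.05)
  ecdf_p <- stats::ecdf(ps)
  expect_true(all(ecdf_p(grid) <= grid + 0.07))
})

test_that("summarize_H lays out variances, covariances and per-draw correlations", {
  dI <- const_H_draws(diag(4), n = 500)
  sI <- summarize_H(dI)
  expect_equal(unname(diag(sI$matrix)), rep(1, 4))
  expect_equal(unname(sI$matrix[lower.tri(sI$matrix)]), rep(0, 6))
  expect_equal(unname(sI$matrix[upper.tri(sI$matrix)]), rep(0, 6))
  expect_false(any(sI$significant))
})
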