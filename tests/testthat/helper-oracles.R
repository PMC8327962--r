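# Independent oracles used to freeze expected values. These deliberately do
# not share code paths with the package implementation.

# Monte Carlo gene-dropping of identity-by-descent at a neutral locus under
# repeated full-sibling mating: pair_0 are unrelated founders; pair_g are two
# children of pair_{g-1}; F_t is the IBD probability in a child of pair_t.
gene_drop_fullsib <- function(t, nrep) {
  pick <- function(a1, a2) ifelse(stats::runif(length(a1)) < 0.5, a1, a2)
  p1a <- rep(1L, nrep); p1b <- rep(2L, nrep)
  p2a <- rep(3L, nrep); p2b <- rep(4L, nrep)
  for (g in seq_len(t)) {
    c1a <- pick(p1a, p1b); c1b <- pick(p2a, p2b)
    c2a <- pick(p1a, p1b); c2b <- pick(p2a, p2b)
    p1a <- c1a; p1b <- c1b; p2a <- c2a; p2b <- c2b
  }
  mean(pick(p1a, p1b) == pick(p2a, p2b))
}

# pairwise-sum covariance/correlation, explicit loops
brute_cov <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - xb) * (y[i] - yb)
  s / (n - 1)
}
brute_corr <- function(x, y) brute_cov(x, y) / sqrt(brute_cov(x, x) * brute_cov(y, y))

# exhaustive shortest-window HPD: O(n^2) scan over all candidate windows
brute_hpd <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(prob * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    j <- i + m - 1
    if (j > n) break
    if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
  }
  best
}

# Independent univariate parameter-expanded Gibbs sampler for the one-way
# model y_ij = mu + a*eta_i + e_ij; eta_i ~ N(0, psi).
# Priors mirror the reduction of the 4x4 model to one observed class:
# psi ~ IG(1/2, V_h/2) (diagonal marginal of IW(nu = 4, V_h * I4)),
# a ~ N(0, 625), s2e ~ IG(0.001, 0.001), mu flat. Reports H11 = a^2 * psi.
oneway_px_gibbs <- function(y, grp, n_iter, burn_in, thin, seed, V_h = 0.002) {
  set.seed(seed)
  ni <- as.numeric(table(grp))
  k <- length(ni)
  sy_i <- as.numeric(tapply(y, grp, sum))
  n <- length(y)
  mu <- mean(y); a <- 1; eta <- rep(0, k); psi <- 0.1; s2e <- stats::var(y)
  out <- numeric((n_iter - burn_in) %/% thin)
  r <- 0L
  for (it in seq_len(n_iter)) {
    prec <- n / s2e
    mu <- (sum(y) - a * sum(ni * eta)) / s2e / prec + stats::rnorm(1) / sqrt(prec)
    prec_i <- a^2 * ni / s2e + 1 / psi
    eta <- a * (sy_i - ni * mu) / s2e / prec_i + stats::rnorm(k) / sqrt(prec_i)
    pr <- sum(ni * eta^2) / s2e + 1 / 625
    a <- sum(eta * (sy_i - ni * mu)) / s2e / pr + stats::rnorm(1) / sqrt(pr)
    psi <- 1 / stats::rgamma(1, 0.5 + k / 2, rate = V_h / 2 + sum(eta^2) / 2)
    ssr <- sum((y - mu - a * eta[grp])^2)
    s2e <- 1 / stats::rgamma(1, 0.001 + n / 2, rate = 0.001 + ssr / 2)
    if (it > burn_in && (it - burn_in) %% thin == 0) out[r <- r + 1L] <- a^2 * psi
  }
  out
}
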