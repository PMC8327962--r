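# In-code fixtures shared across test files.

toy_obs <- function() {
  data.frame(
    sire = c("A", "A", "A", "B"),
    dam  = c("A", "A", "B", "A"),
    sex  = c("F", "M", "F", "M"),
    state = c("i", "i", "o", "o"),
    block = c(1L, 1L, 2L, 2L),
    count = c(5, 7, 12, 20),
    stringsAsFactors = FALSE
  )
}

write_toy_csv <- function(obs = toy_obs()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  path
}

# draws object with every H slice equal to a fixed matrix and optional fixed
# residual variances; U filled with independent noise unless supplied
const_H_draws <- function(H, n = 1000, resid = NULL, U = NULL, seed = 1) {
  set.seed(seed)
  ns <- 16
  if (is.null(U)) U <- array(stats::rnorm(n * ns * 4, 0, 0.1), c(n, ns, 4))
  Ha <- array(0, c(n, 4, 4))
  for (j in seq_len(n)) Ha[j, , ] <- H
  se <- if (is.null(resid)) NULL else
    matrix(rep(resid, each = n), n, 4)
  new_diallel_draws(U, Ha, sigma2_e = se)
}

# draws whose strain effects are truth + iid posterior noise per draw
noisy_draws <- function(u_truth, n = 500, tau = 0.05, seed = 1) {
  set.seed(seed)
  ns <- nrow(u_truth)
  U <- array(0, c(n, ns, 4))
  for (j in seq_len(n))
    U[j, , ] <- u_truth + matrix(stats::rnorm(ns * 4, 0, tau), ns, 4)
  new_diallel_draws(U, H = array(rep(diag(4), n), c(4, 4, n)) |> aperm(c(3, 1, 2)))
}

table1_H <- function() default_truth()$H

table1_resid <- function() c(iF = 0.0256, oF = 0.0150, iM = 0.0863, oM = 0.0837)

# small standardized dataset + short fit, memoised per session
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- scale_design(default_design(), 0.3)
      sim <- simulate_diallel(default_truth(), d, seed = 42)
      obs <- standardize_relative_fitness(sim$observations)
      cache <<- list(
        sim = sim, obs = obs,
        draws = fit_gibbs(obs, config = mcmc_config(
          n_iter = 4000, burn_in = 1000, thin = 10, seed = 7)))
    }
    cache
  }
})
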