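#' Prior specification for the diallel mixed model
#'
#' Minimally informative parameter-expanded priors. The strain-effect
#' covariance uses the non-central scaled-F family: the working covariance
#' has an inverse-Wishart prior with scale `V_h * I4` and `nu_h` degrees of
#' freedom, and the working scale parameters (one per observation class)
#' have independent Gaussian priors `N(alpha_mu, alpha_V)`. Scalar variance
#' components (epistasis and residual) use weak inverse-gamma priors
#' parameterized MCMC-style as `IW(nu, V)` in one dimension, i.e.
#' `IG(nu/2, nu*V/2)`. Fixed effects have improper flat priors.
#'
#' @param V_h,nu_h Inverse-Wishart scale multiplier and degrees of freedom
#'   for the 4x4 working covariance (defaults 0.002, 4). The scale must sit
#'   well below the genetic variances to be estimated: the posterior mean of
#'   each H diagonal inherits a floor of about `alpha^2 * V_h / (nu_h +
#'   n_strains - 5)` from the prior, which at scale 0.02 is the same order
#'   as fitness genetic variances (~0.001-0.02 on the relative scale) and
#'   visibly inflates small variances in parameter-recovery experiments.
#' @param alpha_mu,alpha_V Gaussian prior mean and variance of the working
#'   scale parameters (defaults 0, 625).
#' @param nu_resid,V_resid Residual-variance prior (defaults 0.002, 1).
#' @param nu_pair,V_pair Epistasis-variance prior (defaults 0.002, 1).
#' @return A named list of hyperparameters.
#' @export
prior_spec <- function(V_h = 0.002, nu_h = 4, alpha_mu = 0, alpha_V = 625,
                       nu_resid = 0.002, V_resid = 1,
                       nu_pair = 0.002, V_pair = 1) {
  stopifnot(V_h > 0, nu_h >= 4, alpha_V > 0, nu_resid > 0, nu_pair > 0)
  list(V_h = V_h, nu_h = nu_h, alpha_mu = alpha_mu, alpha_V = alpha_V,
       nu_resid = nu_resid, V_resid = V_resid,
       nu_pair = nu_pair, V_pair = V_pair)
}

#' MCMC run configuration
#'
#' Defaults encode the full estimation schedule of the original analysis:
#' 2,000,000 iterations after a 200,000-iteration burn-in with a thinning
#' interval of 2,000, storing 1,000 approximately uncorrelated draws from a
#' single chain. Diagnostics runs use several shorter chains.
#'
#' @param n_iter Post-burn-in iterations.
#' @param burn_in Burn-in iterations.
#' @param thin Thinning interval; must divide `n_iter` exactly.
#' @param n_chains Number of chains (1 for estimation; >= 2 for
#'   [gelman_rubin()] diagnostics).
#' @param seed Integer seed (chain k uses `seed + k - 1`).
#' @param w_self Loading of selfs on their inbred strain-effect column
#'   (1 = whole-genotype state effect, 2 = additive-dose alternative).
#' @param jitter,max_jitter Diagonal jitter added on Cholesky failure and
#'   the number of consecutive failures tolerated before a hard error.
#' @param priors A [prior_spec()].
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 2e6, burn_in = 2e5, thin = 2000,
                        n_chains = 1, seed = 1L, w_self = 1,
                        jitter = 1e-10, max_jitter = 10,
                        priors = prior_spec()) {
  stopifnot(n_iter > 0, burn_in >= 0, thin > 0, n_chains >= 1)
  if (n_iter %% thin != 0)
    stop("thin must divide the post-burn-in iteration count exactly")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, seed = as.integer(seed),
                 w_self = w_self, jitter = jitter, max_jitter = max_jitter,
                 priors = priors),
            class = "mcmc_config")
}

#' Fit the diallel mixed model by parameter-expanded Gibbs sampling
#'
#' Samples the posterior of the model
#' `y = mu + S + B + I + SxI + BxI + u + v + vxS + eps`, where `u` are
#' strain-by-class genetic effects with 4x4 covariance H (classes
#' `iF, oF, iM, oM`), `v` and `vxS` are symmetric-epistasis effects of
#' unordered outbred pairs, and `eps` has a separate variance per
#' observation class. Location effects are drawn from their Gaussian full
#' conditionals in blocks; H uses the parameter-expanded inverse-Wishart
#' update (working covariance + per-class scale parameters); scalar
#' variances use inverse-gamma full conditionals. Given the seed, stored
#' draws are bit-identical across runs.
#'
#' With zero-row observations (and a design supplying the strains) the
#' sampler draws from the prior of H, which is useful for prior-predictive
#' checks. Residual variances of classes with no observations, and
#' epistasis variances when no outbred pairs exist, are not updated and are
#' stored as `NA`.
#'
#' @param obs Standardized observations (must carry `relative_fitness`).
#' @param design Optional `diallel_design`; derived from `obs` if omitted.
#' @param config An [mcmc_config()].
#' @return A `diallel_draws` object (single chain), or a `diallel_chains`
#'   list of them when `config$n_chains > 1`.
#' @export
fit_gibbs <- function(obs, design = NULL, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  if (is.null(design)) design <- derive_design(obs)
  if (length(design$strains) < 2) stop("need at least 2 strains")
  if (config$n_chains > 1) {
    chains <- lapply(seq_len(config$n_chains), function(k) {
      cfg <- config
      cfg$n_chains <- 1L
      cfg$seed <- config$seed + k - 1L
      ch <- fit_gibbs(obs, design, cfg)
      ch$chain <- k
      ch
    })
    return(structure(chains, class = "diallel_chains"))
  }
  inc <- build_incidence(obs, design, w_self = config$w_self)
  # Observations sharing a design row (cross, sex, state, block) enter the
  # full conditionals only through their count, sum and sum of squares:
  # aggregate to group-level sufficient statistics in a canonical order, so
  # runtime is independent of replication and row order.
  n <- length(inc$y)
  if (n > 0) {
    key <- paste(match(obs$sire, inc$strains), match(obs$dam, inc$strains),
                 obs$sex, obs$state, obs$block)
    ukey <- sort(unique(key))
    gi <- match(key, ukey)
    rep_row <- match(ukey, key)          # representative observation per group
    agg <- list(
      ng = as.numeric(tabulate(gi, length(ukey))),
      sy = as.numeric(rowsum(inc$y, gi)),
      syy = as.numeric(rowsum(inc$y^2, gi)),
      X = inc$X[rep_row, , drop = FALSE],
      cls = inc$cls[rep_row], load1 = inc$load1[rep_row],
      load2 = inc$load2[rep_row], w1 = inc$w1[rep_row], w2 = inc$w2[rep_row],
      pair = inc$pair[rep_row], pairsex = inc$pairsex[rep_row])
  } else {
    agg <- list(ng = numeric(0), sy = numeric(0), syy = numeric(0),
                X = inc$X, cls = integer(0), load1 = integer(0),
                load2 = integer(0), w1 = numeric(0), w2 = numeric(0),
                pair = integer(0), pairsex = integer(0))
  }
  pr <- config$priors
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  fit <- gibbs_diallel_cpp(
    ng = agg$ng, sy = agg$sy, syy = agg$syy,
    X = agg$X, cls = as.integer(agg$cls - 1L),
    load1 = as.integer(agg$load1 - 1L),
    load2 = as.integer(ifelse(is.na(agg$load2), -1L, agg$load2 - 1L)),
    w1 = agg$w1, w2 = agg$w2,
    pair = as.integer(ifelse(is.na(agg$pair), -1L, agg$pair - 1L)),
    pairsex = as.integer(ifelse(is.na(agg$pairsex), -1L, agg$pairsex - 1L)),
    n_strain = length(inc$strains),
    n_pair = length(inc$pair_labels),
    n_pairsex = length(inc$pairsex_labels),
    n_iter = config$burn_in + config$n_iter,   # total; n_iter counts post-burn-in
    burn_in = config$burn_in, thin = config$thin,
    V_h = pr$V_h, nu_h = pr$nu_h,
    alpha_mu = pr$alpha_mu, alpha_V = pr$alpha_V,
    nu_resid = pr$nu_resid, V_resid = pr$V_resid,
    nu_pair = pr$nu_pair, V_pair = pr$V_pair,
    jitter = config$jitter, max_jitter = config$max_jitter)
  ns <- length(inc$strains)
  nst <- fit$n_store
  beta <- fit$beta
  if (ncol(inc$X)) colnames(beta) <- colnames(inc$X) else beta <- NULL
  dr <- new_diallel_draws(
    U = array(fit$U, c(nst, ns, 4)),
    H = array(fit$H, c(nst, 4, 4)),
    beta = beta,
    sigma2_e = fit$sigma2_e,
    sigma2_v = as.numeric(fit$sigma2_v),
    sigma2_vS = as.numeric(fit$sigma2_vS),
    strains = inc$strains, chain = 1L, config = config)
  dr$jitter_count <- fit$jitter_count
  if (fit$jitter_count > 0)
    message("Cholesky jitter applied ", fit$jitter_count, " time(s)")
  dr
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Plain (non rank-normalized) PSRF per scalar parameter from two or more
#' chains of equal length: `sqrt(((n-1)/n * W + (1 + 1/m) * B/n) / W)`,
#' with `W` the mean within-chain variance and `B/n` the variance of the
#' chain means. Values near 1 indicate convergence; > 1.1 is the
#' conventional alarm threshold. Parameters monitored: fixed effects, the
#' 10 unique H entries, and the variance components present in the data.
#'
#' @param chains A `diallel_chains` object or list of `diallel_draws` with
#'   equal draw counts.
#' @return Named numeric vector of PSRFs.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "diallel_draws"))
    stop("gelman_rubin needs >= 2 chains; rerun with n_chains >= 2")
  stopifnot(is.list(chains), length(chains) >= 2)
  nd <- vapply(chains, function(ch) ch$n_draws, 0L)
  if (length(unique(nd)) != 1) stop("chains must have equal draw counts")
  flat <- lapply(chains, flatten_scalars)
  params <- colnames(flat[[1]])
  m <- length(flat)
  n <- nrow(flat[[1]])
  psrf <- vapply(params, function(pn) {
    xs <- vapply(flat, function(f) f[, pn], numeric(n))
    if (anyNA(xs)) return(NA_real_)
    W <- mean(apply(xs, 2, stats::var))
    if (W == 0) return(NA_real_)
    B_over_n <- stats::var(colMeans(xs))
    sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
  }, 0)
  psrf
}

flatten_scalars <- function(ch) {
  H <- ch$H
  hn <- outer(OBSERVATION_CLASSES, OBSERVATION_CLASSES, paste, sep = ".")
  keep <- which(lower.tri(matrix(0, 4, 4), diag = TRUE))
  Hm <- matrix(H, dim(H)[1], 16)[, keep, drop = FALSE]
  colnames(Hm) <- paste0("H.", hn[keep])
  out <- cbind(ch$beta, Hm)
  if (!is.null(ch$sigma2_v) && !all(is.na(ch$sigma2_v)))
    out <- cbind(out, sigma2_v = ch$sigma2_v)
  if (!is.null(ch$sigma2_vS) && !all(is.na(ch$sigma2_vS)))
    out <- cbind(out, sigma2_vS = ch$sigma2_vS)
  if (!is.null(ch$sigma2_e)) {
    se <- ch$sigma2_e[, colSums(is.na(ch$sigma2_e)) == 0, drop = FALSE]
    if (ncol(se)) {
      colnames(se) <- paste0("sigma2_e.", colnames(se))
      out <- cbind(out, se)
    }
  }
  out
}
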