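#' Kernel-density posterior mode
#'
#' Point estimate used for all derived statistics: the argmax of a Gaussian
#' kernel density estimate over a 512-point grid spanning the sample range,
#' with Silverman's rule-of-thumb bandwidth times `adjust`.
#'
#' @param x Numeric samples (at least 10).
#' @param adjust Bandwidth multiplier (default 1).
#' @return The mode (numeric scalar).
#' @export
posterior_mode <- function(x, adjust = 1) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("posterior_mode needs at least 10 samples")
  if (diff(range(x)) == 0) return(x[1])
  d <- stats::density(x, bw = "nrd0", adjust = adjust, n = 512,
                      from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' The shortest contiguous window of sorted samples containing
#' `ceiling(prob * n)` of them; ties in width are broken towards the lowest
#' lower endpoint.
#'
#' @param x Numeric samples.
#' @param prob Target probability mass (in (0, 1); default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)")
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < ceiling(1 / (1 - prob)))
    stop("too few samples for an HPD interval at prob = ", prob)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # which.min returns the first (lowest) minimizer
  c(x[i], x[i + m - 1])
}

#' Two-sided MCMC p-value against zero
#'
#' Twice the fraction of draws falling on the opposite side of zero from the
#' posterior mode, capped at 1. The resolution is `2/n`: when no draw falls
#' on the opposite side the value 0 is returned with attribute
#' `below_resolution = TRUE`, to be reported as "< 2/n". A posterior mode
#' exactly at zero yields p = 1 by convention.
#'
#' @param x Numeric draws of the statistic (at least 10).
#' @param mode Optional precomputed posterior mode.
#' @return Numeric p-value with attributes `below_resolution` and `n`.
#' @export
mcmc_pvalue <- function(x, mode = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("mcmc_pvalue needs at least 10 samples")
  if (is.null(mode)) mode <- posterior_mode(x)
  n <- length(x)
  if (mode == 0) {
    p <- 1
    attr(p, "below_resolution") <- FALSE
    attr(p, "n") <- n
    return(p)
  }
  opp <- sum(sign(x) == -sign(mode))
  p <- min(1, 2 * opp / n)
  attr(p, "below_resolution") <- opp == 0
  attr(p, "n") <- n
  p
}

#' Per-draw covariance and correlation across strains
#'
#' For matched `draw x strain` matrices, computes within each draw the
#' covariance and Pearson correlation across strains (denominator n - 1).
#' Draws in which either vector has zero variance are recorded as missing
#' and excluded from downstream summaries.
#'
#' @param x,y Numeric matrices `n_draws x n_strains`.
#' @return List with numeric vectors `cov` and `cor` (NA where undefined)
#'   and the count `n_excluded`.
#' @export
per_draw_cov_corr <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  if (ncol(x) < 3) stop("need at least 3 strains")
  ns <- ncol(x)
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  cv <- rowSums(xc * yc) / (ns - 1)
  vx <- rowSums(xc * xc) / (ns - 1)
  vy <- rowSums(yc * yc) / (ns - 1)
  bad <- vx <= 0 | vy <= 0
  cr <- ifelse(bad, NA_real_, cv / sqrt(vx * vy))
  list(cov = cv, cor = cr, n_excluded = sum(bad))
}

#' Per-draw heterosis vectors
#'
#' Heterosis of a strain is its outbred minus its inbred genetic effect:
#' `oF - iF` (female), `oM - iM` (male), or the sex-averaged
#' `(oM + oF)/2 - (iM + iF)/2`.
#'
#' @param draws A `diallel_draws` object.
#' @param sex `"F"`, `"M"`, or `"averaged"`.
#' @return Matrix `n_draws x n_strains`.
#' @export
heterosis_per_draw <- function(draws, sex = c("F", "M", "averaged")) {
  sex <- match.arg(sex)
  U <- draws$U
  switch(sex,
    F = U[, , "oF"] - U[, , "iF"],
    M = U[, , "oM"] - U[, , "iM"],
    averaged = (U[, , "oM"] + U[, , "oF"]) / 2 - (U[, , "iM"] + U[, , "iF"]) / 2
  )
}

#' Seeded cross-iteration pairing of draws
#'
#' Returns a random permutation of draw indices with no fixed points, used
#' to take outbred fitness vectors from different posterior iterations than
#' those supplying sex-averaged heterosis, removing shared MCMC sampling
#' error from the resampled statistics.
#'
#' @param n Number of draws.
#' @param seed Integer seed (required for reproducibility).
#' @return Integer permutation of `1:n` with `perm[i] != i` for all i.
#' @export
cross_pairing <- function(n, seed) {
  if (n < 2) stop("need at least 2 draws to cross-pair")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  repeat {
    fixed <- which(perm == seq_len(n))
    if (!length(fixed)) break
    for (j in fixed) {            # swap each identity mapping with a random partner
      k <- sample(setdiff(seq_len(n), j), 1)
      tmp <- perm[j]; perm[j] <- perm[k]; perm[k] <- tmp
    }
  }
  perm
}

summarize_derived <- function(name, per_draw, prob = 0.95, adjust = 1,
                              n_excluded = 0) {
  keep <- is.finite(per_draw)
  vals <- per_draw[keep]
  mode <- posterior_mode(vals, adjust = adjust)
  hpd <- hpd_interval(vals, prob = prob)
  p <- mcmc_pvalue(vals, mode = mode)
  structure(list(name = name, per_draw = per_draw, posterior_mode = mode,
                 hpd_low = hpd[1], hpd_high = hpd[2],
                 p_value = as.numeric(p),
                 below_resolution = attr(p, "below_resolution"),
                 n_draws = length(vals),
                 n_excluded = n_excluded + sum(!keep)),
            class = "derived_statistic")
}

#' @export
print.derived_statistic <- function(x, digits = 4, ...) {
  pflag <- if (isTRUE(x$below_resolution))
    paste0("< ", format(2 / x$n_draws)) else format(round(x$p_value, digits))
  cat(sprintf("%s: mode %s [95%% HPD %s, %s], P = %s (n = %d, excluded %d)\n",
              x$name, format(round(x$posterior_mode, digits)),
              format(round(x$hpd_low, digits)),
              format(round(x$hpd_high, digits)),
              pflag, x$n_draws, x$n_excluded))
  invisible(x)
}

#' Standardized selection intensity against mutation-load alleles
#'
#' The per-draw statistic `beta_a' = COV(o_sex, het) / SD(het)` across
#' strains: the genetic change in outbred relative fitness of the target sex
#' per genetic standard deviation of heterosis. With
#' `heterosis_source = "opposite_sex"` the heterosis vector comes from the
#' opposite sex (avoiding shared measurement error), giving the primed
#' estimators; with `"sex_averaged"` heterosis is the sex-averaged `o - i`
#' and the outbred vectors are taken from cross-paired draw indices
#' (see [cross_pairing()]), giving the double-primed estimators used for
#' sex-difference tests.
#'
#' @param draws A `diallel_draws` object.
#' @param target_sex `"M"` or `"F"`: the sex whose outbred fitness is related
#'   to heterosis.
#' @param heterosis_source `"opposite_sex"` or `"sex_averaged"`.
#' @param pairing_seed Integer seed for the cross-iteration pairing
#'   (required when `heterosis_source = "sex_averaged"`).
#' @param prob HPD probability mass.
#' @param adjust KDE bandwidth multiplier for the posterior mode.
#' @return A `derived_statistic`.
#' @export
selection_intensity <- function(draws, target_sex = c("M", "F"),
                                heterosis_source = c("opposite_sex", "sex_averaged"),
                                pairing_seed = NULL, prob = 0.95, adjust = 1) {
  target_sex <- match.arg(target_sex)
  heterosis_source <- match.arg(heterosis_source)
  o <- draws$U[, , paste0("o", target_sex)]
  if (heterosis_source == "opposite_sex") {
    het <- heterosis_per_draw(draws, if (target_sex == "M") "F" else "M")
    name <- paste0("beta_a", target_sex, "_prime")
  } else {
    if (is.null(pairing_seed))
      stop("pairing_seed is required for sex-averaged heterosis")
    het <- heterosis_per_draw(draws, "averaged")
    o <- o[cross_pairing(nrow(o), pairing_seed + match(target_sex, c("M", "F"))), ,
           drop = FALSE]
    name <- paste0("beta_a", target_sex, "_dblprime")
  }
  cc <- per_draw_cov_corr(o, het)
  sd_het <- sqrt(rowSums((het - rowMeans(het))^2) / (ncol(het) - 1))
  beta <- ifelse(sd_het > 0, cc$cov / sd_het, NA_real_)
  summarize_derived(name, beta, prob = prob, adjust = adjust)
}

#' Resampled genetic correlations among strain effects
#'
#' Per-draw Pearson correlations across strains between named pairs of
#' genetic vectors:
#' * `r_iM_iF`, `r_oM_oF` - intersexual correlations of inbred / outbred
#'   fitness;
#' * `r_het_MF` - correlation of male and female heterosis;
#' * `r_oM_hetF`, `r_oF_hetM` - outbred fitness of one sex against the
#'   opposite sex's heterosis;
#' * `r_oM_het_avg`, `r_oF_het_avg` - outbred fitness against sex-averaged
#'   heterosis, with the outbred vector taken from cross-paired draws.
#'
#' @inheritParams selection_intensity
#' @param pair Statistic name (see Details).
#' @return A `derived_statistic`.
#' @export
genetic_correlation <- function(draws,
                                pair = c("r_iM_iF", "r_oM_oF", "r_het_MF",
                                         "r_oM_hetF", "r_oF_hetM",
                                         "r_oM_het_avg", "r_oF_het_avg"),
                                pairing_seed = NULL, prob = 0.95, adjust = 1) {
  pair <- match.arg(pair)
  U <- draws$U
  xy <- switch(pair,
    r_iM_iF   = list(U[, , "iM"], U[, , "iF"]),
    r_oM_oF   = list(U[, , "oM"], U[, , "oF"]),
    r_het_MF  = list(heterosis_per_draw(draws, "M"),
                     heterosis_per_draw(draws, "F")),
    r_oM_hetF = list(U[, , "oM"], heterosis_per_draw(draws, "F")),
    r_oF_hetM = list(U[, , "oF"], heterosis_per_draw(draws, "M")),
    r_oM_het_avg = ,
    r_oF_het_avg = {
      if (is.null(pairing_seed))
        stop("pairing_seed is required for sex-averaged statistics")
      sex <- if (pair == "r_oM_het_avg") "M" else "F"
      o <- U[, , paste0("o", sex)]
      perm <- cross_pairing(nrow(o), pairing_seed + match(sex, c("M", "F")))
      list(o[perm, , drop = FALSE], heterosis_per_draw(draws, "averaged"))
    })
  cc <- per_draw_cov_corr(xy[[1]], xy[[2]])
  summarize_derived(pair, cc$cor, prob = prob, adjust = adjust,
                    n_excluded = 0)
}

#' Two-sided MCMC test for a sex difference in a derived statistic
#'
#' Given matched per-draw sequences of the male and female versions of a
#' statistic, returns twice the fraction of draws whose ordering contradicts
#' the point-estimate (posterior mode) ordering, capped at 1. Ties count as
#' half an exceedance, so identical sequences give p = 1 (no evidence of a
#' difference).
#'
#' @param draws_stat_M,draws_stat_F Per-draw numeric vectors (equal length,
#'   matched draw indices) or `derived_statistic` objects.
#' @return Numeric p-value with attributes `below_resolution` and `n`.
#' @export
sex_difference_test <- function(draws_stat_M, draws_stat_F) {
  m <- if (inherits(draws_stat_M, "derived_statistic")) draws_stat_M$per_draw else draws_stat_M
  f <- if (inherits(draws_stat_F, "derived_statistic")) draws_stat_F$per_draw else draws_stat_F
  if (length(m) != length(f)) stop("per-draw sequences must have equal length")
  keep <- is.finite(m) & is.finite(f)
  m <- m[keep]; f <- f[keep]
  n <- length(m)
  if (n < 10) stop("too few matched draws")
  dir <- sign(posterior_mode(f) - posterior_mode(m))
  if (dir == 0) dir <- 1
  d <- f - m
  opp <- sum(sign(d) == -dir) + 0.5 * sum(d == 0)
  p <- min(1, 2 * opp / n)
  attr(p, "below_resolution") <- opp == 0
  attr(p, "n") <- n
  p
}

#' Compute the full set of derived posterior statistics
#'
#' Runs every named selection intensity and genetic correlation on a set of
#' posterior draws, plus the sex-difference tests based on the sex-averaged
#' (double-primed) estimators, and returns a tidy report.
#'
#' @param draws A `diallel_draws` object.
#' @param pairing_seed Seed for the cross-iteration pairing of sex-averaged
#'   statistics.
#' @param prob HPD probability mass.
#' @param adjust KDE bandwidth multiplier.
#' @return A list with `statistics` (named list of `derived_statistic`),
#'   `report` (data frame: name, posterior_mode, hpd_low, hpd_high, p_value,
#'   p_display, n_draws, n_excluded) and `sex_differences` (named numeric
#'   p-values for the selection-intensity and correlation contrasts).
#' @export
derive_statistics <- function(draws, pairing_seed = 1L, prob = 0.95, adjust = 1) {
  stats_list <- list(
    selection_intensity(draws, "M", "opposite_sex", prob = prob, adjust = adjust),
    selection_intensity(draws, "F", "opposite_sex", prob = prob, adjust = adjust),
    selection_intensity(draws, "M", "sex_averaged", pairing_seed, prob, adjust),
    selection_intensity(draws, "F", "sex_averaged", pairing_seed, prob, adjust),
    genetic_correlation(draws, "r_het_MF", prob = prob, adjust = adjust),
    genetic_correlation(draws, "r_iM_iF", prob = prob, adjust = adjust),
    genetic_correlation(draws, "r_oM_oF", prob = prob, adjust = adjust),
    genetic_correlation(draws, "r_oM_hetF", prob = prob, adjust = adjust),
    genetic_correlation(draws, "r_oF_hetM", prob = prob, adjust = adjust),
    genetic_correlation(draws, "r_oM_het_avg", pairing_seed, prob, adjust),
    genetic_correlation(draws, "r_oF_het_avg", pairing_seed, prob, adjust)
  )
  names(stats_list) <- vapply(stats_list, `[[`, "", "name")
  report <- do.call(rbind, lapply(stats_list, function(s)
    data.frame(name = s$name, posterior_mode = s$posterior_mode,
               hpd_low = s$hpd_low, hpd_high = s$hpd_high,
               p_value = s$p_value,
               p_display = if (isTRUE(s$below_resolution))
                 paste0("< ", format(2 / s$n_draws)) else format(s$p_value),
               n_draws = s$n_draws, n_excluded = s$n_excluded,
               stringsAsFactors = FALSE)))
  rownames(report) <- NULL
  sex_diff <- c(
    beta_dblprime = as.numeric(
      sex_difference_test(stats_list$beta_aM_dblprime,
                          stats_list$beta_aF_dblprime)),
    r_het_avg = as.numeric(
      sex_difference_test(stats_list$r_oM_het_avg,
                          stats_list$r_oF_het_avg))
  )
  list(statistics = stats_list, report = report, sex_differences = sex_diff)
}

#' Summarize posterior H-matrix draws in tabular form
#'
#' Builds the conventional display of a genetic covariance matrix: posterior
#' modes of the variances on the diagonal (with HPD intervals and, when
#' available, the class residual variances), posterior modes of the
#' covariances in the lower triangle, and posterior modes of the per-draw
#' correlations in the upper triangle. Correlations are computed within each
#' draw from that draw's H sample and then summarized (mode of ratios, not
#' ratio of modes). A significance flag marks off-diagonal entries whose
#' covariance HPD excludes zero.
#'
#' @param draws A `diallel_draws` object.
#' @param prob HPD probability mass.
#' @param adjust KDE bandwidth multiplier.
#' @return An `h_summary` list with components `matrix` (4x4 display
#'   matrix), `hpd` (4x4x2 array for variances/covariances),
#'   `correlation_hpd` (4x4x2, upper triangle), `significant` (logical 4x4),
#'   `residual` (modes of residual variances, NA when unavailable).
#' @export
summarize_H <- function(draws, prob = 0.95, adjust = 1) {
  H <- draws$H
  disp <- matrix(NA_real_, 4, 4, dimnames = list(OBSERVATION_CLASSES,
                                                 OBSERVATION_CLASSES))
  hpd <- array(NA_real_, c(4, 4, 2))
  cor_hpd <- array(NA_real_, c(4, 4, 2))
  sig <- matrix(FALSE, 4, 4)
  for (i in 1:4) {
    vi <- H[, i, i]
    disp[i, i] <- posterior_mode(vi, adjust)
    hpd[i, i, ] <- hpd_interval(vi, prob)
  }
  for (i in 1:4) for (j in 1:4) {
    if (i <= j) next
    cv <- H[, i, j]
    disp[i, j] <- posterior_mode(cv, adjust)           # lower: covariance
    hpd[i, j, ] <- hpd_interval(cv, prob)
    sig[i, j] <- prod(hpd[i, j, ]) > 0
    r <- cv / sqrt(H[, i, i] * H[, j, j])              # per-draw correlation
    r <- r[is.finite(r)]
    disp[j, i] <- posterior_mode(r, adjust)            # upper: correlation
    cor_hpd[j, i, ] <- hpd_interval(r, prob)
    sig[j, i] <- prod(cor_hpd[j, i, ]) > 0
  }
  resid <- rep(NA_real_, 4)
  names(resid) <- OBSERVATION_CLASSES
  if (!is.null(draws$sigma2_e)) {
    for (k in 1:4) {
      v <- draws$sigma2_e[, k]
      v <- v[is.finite(v)]
      if (length(v) >= 10)
        resid[k] <- if (diff(range(v)) == 0) v[1] else posterior_mode(v, adjust)
    }
  }
  structure(list(matrix = disp, hpd = hpd, correlation_hpd = cor_hpd,
                 significant = sig, residual = resid, prob = prob),
            class = "h_summary")
}

#' @export
print.h_summary <- function(x, digits = 4, ...) {
  cat("H matrix summary (diag: variance modes; lower: covariance modes;",
      "upper: per-draw correlation modes)\n")
  m <- round(x$matrix, digits)
  print(m)
  cat("Residual variance modes by class:\n")
  print(round(x$residual, digits))
  cat("Off-diagonal entries with", x$prob, "HPD excluding zero:",
      paste(which(x$significant), collapse = " "), "\n")
  invisible(x)
}
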