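#' Reference generative truth for the seed-beetle diallel
#'
#' Default parameter set for the synthetic-data generator, on the relative
#' fitness scale: the published 4x4 strain-effect covariance matrix (order
#' `iF, oF, iM, oM`) and class-specific residual variances for this
#' experiment, an inbreeding fixed effect of -0.294 (the mean reduction in
#' relative fitness of inbred selfs versus outbred crosses), intercept 1
#' (the outbred female mean after standardization), a small sex effect, and
#' symmetric-epistasis variances of 0.001 (not published; chosen at the
#' order of the smaller genetic variances).
#'
#' @param H Strain-effect covariance matrix (4x4, order `iF, oF, iM, oM`).
#' @param sigma2_v Variance of the unordered-pair (symmetric epistasis)
#'   effect among outbred families.
#' @param sigma2_vS Variance of the pair-by-sex effect.
#' @param residual Residual variances per observation class (length 4).
#' @param fixed Named fixed effects `mu, S, B, I, SI, BI` under treatment
#'   coding (reference: female, outbred, block 1).
#' @return A `generative_truth` object.
#' @export
default_truth <- function(H = matrix(c(0.0108, 0.0010, 0.0106, 0.0016,
                                       0.0010, 0.0015, 0.0002, -2.5e-5,
                                       0.0106, 0.0002, 0.0199, 0.0030,
                                       0.0016, -2.5e-5, 0.0030, 0.0018),
                                     4, 4),
                          sigma2_v = 0.001, sigma2_vS = 0.001,
                          residual = c(iF = 0.0256, oF = 0.0150,
                                       iM = 0.0863, oM = 0.0837),
                          fixed = c(mu = 1, S = 0.02, B = 0, I = -0.294,
                                    SI = 0, BI = 0)) {
  dimnames(H) <- list(OBSERVATION_CLASSES, OBSERVATION_CLASSES)
  truth <- structure(list(H = H, sigma2_v = sigma2_v, sigma2_vS = sigma2_vS,
                          residual = residual, fixed = fixed),
                     class = "generative_truth")
  validate_truth(truth)
}

validate_truth <- function(truth) {
  H <- truth$H
  stopifnot(is.matrix(H), all(dim(H) == 4))
  if (max(abs(H - t(H))) > 1e-10) stop("H must be symmetric")
  if (min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("H must be positive semi-definite")
  if (truth$sigma2_v < 0 || truth$sigma2_vS < 0 || any(truth$residual < 0))
    stop("variances must be non-negative")
  stopifnot(length(truth$residual) == 4, length(truth$fixed) == 6)
  truth
}

#' The default realized diallel design
#'
#' A 16-strain full diallel with all 16 parental selfs and 237 of the 240
#' possible ordered outbred crosses (3 ordered cells removed by seeded
#' choice, since which cells failed in the real experiment is not recorded),
#' two experimental blocks, and per-class totals of 1616 outbred male, 1450
#' outbred female, 115 inbred male and 97 inbred female observations
#' (3278 in total). Replicates are allocated as evenly as possible across
#' realized cell-by-block units, the remainder assigned by seeded choice.
#'
#' @param seed Integer seed controlling the removed cells and remainder
#'   allocation.
#' @return A `diallel_design` object.
#' @export
default_design <- function(seed = 1L) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  strains <- sprintf("L%02d", 1:16)
  all_pairs <- expand.grid(sire = strains, dam = strains,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$sire != all_pairs$dam, ]
  drop <- sample(nrow(all_pairs), 3)
  crosses <- all_pairs[-drop, , drop = FALSE]
  rownames(crosses) <- NULL

  alloc <- function(cells, sex, total) {
    units <- rbind(cbind(cells, block = 1L), cbind(cells, block = 2L))
    k <- nrow(units)
    n <- rep(total %/% k, k)
    extra <- total - sum(n)
    if (extra > 0) {
      idx <- sample(k, extra)
      n[idx] <- n[idx] + 1L
    }
    cbind(units, data.frame(sex = sex, n = n, stringsAsFactors = FALSE))
  }
  selfs <- data.frame(sire = strains, dam = strains, stringsAsFactors = FALSE)
  reps <- rbind(
    alloc(crosses, "M", 1616L),
    alloc(crosses, "F", 1450L),
    alloc(selfs,  "M", 115L),
    alloc(selfs,  "F", 97L)
  )
  reps <- reps[reps$n > 0, c("sire", "dam", "sex", "block", "n")]
  rownames(reps) <- NULL
  new_diallel_design(strains = strains, crosses = crosses,
                     selfs = strains, replicates = reps)
}

#' Rescale the replicate counts of a design
#'
#' Multiplies every per-unit replicate count by `factor` (rounded, floored
#' at 1), e.g. for parameter-recovery experiments at inflated sample sizes
#' or reduced-scale calibration runs.
#'
#' @param design A `diallel_design`.
#' @param factor Positive multiplier.
#' @return The rescaled design.
#' @export
scale_design <- function(design, factor) {
  stopifnot(factor > 0)
  design$replicates$n <- pmax(1L, as.integer(round(design$replicates$n * factor)))
  design
}

#' Simulate a diallel fitness dataset from a stated truth
#'
#' Generative mirror of the fitted model: strain-effect rows are drawn
#' independently from a 4-dimensional zero-mean Gaussian with covariance
#' `truth$H`; one symmetric-epistasis effect per realized unordered outbred
#' pair (variance `sigma2_v`) plus one per pair-by-sex (variance
#' `sigma2_vS`); relative fitness is the fixed-effect sum plus
#' incidence-weighted random effects plus class-specific Gaussian noise.
#' Offspring counts are the relative values scaled by a sex-specific target
#' outbred mean and truncated at zero (the truncation rate is recorded and
#' is below 1\% at the defaults).
#'
#' @param truth A `generative_truth` (default [default_truth()]).
#' @param design A `diallel_design` (default [default_design()]).
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param target_mean Named vector `c(F=, M=)` of target outbred mean
#'   offspring counts.
#' @return A `diallel_sim` list: `observations` (schema of
#'   [read_fitness_table()]), `truth`, realized `U` (strain effects),
#'   `pair_effects`, and `truncation_rate`.
#' @export
simulate_diallel <- function(truth = default_truth(), design = default_design(),
                             seed = 1L, target_mean = c(F = 40, M = 40)) {
  validate_truth(truth)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  strains <- design$strains
  ns <- length(strains)

  U <- rmvn_chol(ns, truth$H)                      # ns x 4, class cols
  dimnames(U) <- list(strains, OBSERVATION_CLASSES)

  cr <- design$crosses
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = ":")
  pairs <- unique(pair_key(cr$sire, cr$dam))
  v <- stats::rnorm(length(pairs), 0, sqrt(truth$sigma2_v))
  names(v) <- pairs
  ps <- c(paste0(pairs, ":F"), paste0(pairs, ":M"))
  vs <- stats::rnorm(length(ps), 0, sqrt(truth$sigma2_vS))
  names(vs) <- ps

  reps <- design$replicates
  idx <- rep(seq_len(nrow(reps)), reps$n)
  obs <- data.frame(sire = reps$sire[idx], dam = reps$dam[idx],
                    sex = reps$sex[idx],
                    state = ifelse(reps$sire[idx] == reps$dam[idx], "i", "o"),
                    block = reps$block[idx], count = NA_real_,
                    stringsAsFactors = FALSE)
  fx <- truth$fixed
  male <- obs$sex == "M"
  inb <- obs$state == "i"
  blk2 <- obs$block == 2L
  y <- fx["mu"] + fx["S"] * male + fx["B"] * blk2 + fx["I"] * inb +
    fx["SI"] * (male & inb) + fx["BI"] * (blk2 & inb)
  cls_col <- match(paste0(ifelse(inb, "i", "o"), obs$sex), OBSERVATION_CLASSES)
  si <- match(obs$sire, strains)
  di <- match(obs$dam, strains)
  u_contrib <- ifelse(inb,
                      U[cbind(si, cls_col)],
                      U[cbind(si, cls_col)] + U[cbind(di, cls_col)])
  pk <- pair_key(obs$sire, obs$dam)
  v_contrib <- ifelse(inb, 0, v[pk])
  vs_contrib <- ifelse(inb, 0, vs[paste0(pk, ":", obs$sex)])
  eps <- stats::rnorm(nrow(obs), 0, sqrt(truth$residual[cls_col]))
  y <- as.numeric(y + u_contrib + v_contrib + vs_contrib + eps)
  counts <- as.numeric(y * target_mean[obs$sex])
  trunc_rate <- mean(counts < 0)
  obs$count <- pmax(0, counts)
  structure(list(observations = obs, truth = truth, U = U,
                 pair_effects = list(v = v, vS = vs),
                 truncation_rate = trunc_rate, seed = seed),
            class = "diallel_sim")
}

#' @export
print.diallel_sim <- function(x, ...) {
  cat("Simulated diallel dataset:", nrow(x$observations), "observations,",
      length(unique(c(x$observations$sire, x$observations$dam))), "strains,",
      sprintf("truncation rate %.3f%%", 100 * x$truncation_rate), "\n")
  invisible(x)
}

#' Write a simulated dataset with its ground-truth sidecar
#'
#' @param sim A `diallel_sim`.
#' @param stem Path stem; writes `<stem>.csv` (observations) and
#'   `<stem>_truth.json`.
#' @return The CSV path, invisibly.
#' @export
write_sim <- function(sim, stem) {
  write_fitness_table(sim$observations, paste0(stem, ".csv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(H = truth$H, sigma2_v = truth$sigma2_v, sigma2_vS = truth$sigma2_vS,
         residual = as.list(truth$residual), fixed = as.list(truth$fixed),
         seed = sim$seed, U = sim$U,
         truncation_rate = sim$truncation_rate),
    paste0(stem, "_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".csv"))
}

rmvn_chol <- function(n, sigma) {
  p <- ncol(sigma)
  ev <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% (t(ev$vectors) * sqrt(lam))
}

null_constraint_matrix <- function(constraint) {
  C <- matrix(0, 4, 4)
  if (is.matrix(constraint)) {
    stopifnot(all(dim(constraint) == 4))
    C <- (constraint + t(constraint)) / 2
  } else {
    switch(constraint,
      # COV(oM, oF - iF) = H[oF,oM] - H[iF,oM] = 0
      cov_oM_hetF_zero = {
        C[2, 4] <- C[4, 2] <- 0.5
        C[1, 4] <- C[4, 1] <- -0.5
      },
      # COV(oF, oM - iM) = H[oF,oM] - H[oF,iM] = 0
      cov_oF_hetM_zero = {
        C[2, 4] <- C[4, 2] <- 0.5
        C[2, 3] <- C[3, 2] <- -0.5
      },
      # COV(oM, (oM+oF)/2 - (iM+iF)/2) = 0
      cov_oM_het_avg_zero = {
        C[4, 4] <- 0.5
        C[2, 4] <- C[4, 2] <- 0.25
        C[3, 4] <- C[4, 3] <- -0.25
        C[1, 4] <- C[4, 1] <- -0.25
      },
      stop("unknown named constraint: ", constraint)
    )
  }
  if (all(C == 0)) stop("constraint matrix is identically zero")
  C
}

#' Project a generative truth onto a null hypothesis
#'
#' Replaces `truth$H` by the nearest (Frobenius) positive semi-definite
#' matrix satisfying a linear constraint `sum(C * H) = 0`, via Dykstra's
#' alternating projections between the constraint hyperplane and the PSD
#' cone. Used by type-I-error calibration harnesses. Named constraints:
#' `"cov_oM_hetF_zero"` (COV(oM, oF-iF) = 0), `"cov_oF_hetM_zero"`,
#' `"cov_oM_het_avg_zero"`; alternatively pass the symmetric coefficient
#' matrix `C` directly.
#'
#' @param truth A `generative_truth`.
#' @param constraint Name or 4x4 coefficient matrix.
#' @param tol Convergence tolerance on the constraint and eigenvalues.
#' @return The modified `generative_truth`.
#' @export
make_null_truth <- function(truth, constraint = "cov_oM_hetF_zero",
                            tol = 1e-12) {
  C <- null_constraint_matrix(constraint)
  cc <- sum(C * C)
  H <- truth$H
  proj_lin <- function(M) M - (sum(C * M) / cc) * C
  proj_psd <- function(M) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
    ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  }
  P <- matrix(0, 4, 4)   # Dykstra correction for the PSD projection
  X <- H
  for (iter in seq_len(10000)) {
    Y <- proj_lin(X)
    Xp <- proj_psd(Y + P)
    P <- Y + P - Xp
    X <- Xp
    if (abs(sum(C * X)) < tol &&
        min(eigen(X, symmetric = TRUE, only.values = TRUE)$values) > -tol)
      break
  }
  if (abs(sum(C * X)) >= max(tol, 1e-10))
    stop("constraint projection did not converge; constraint may be infeasible")
  X <- proj_lin(X)   # land exactly on the hyperplane
  dimnames(X) <- dimnames(truth$H)
  truth$H <- (X + t(X)) / 2
  truth
}
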