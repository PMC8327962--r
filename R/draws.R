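#' Construct a posterior-draws object
#'
#' Container for stored MCMC draws of the diallel mixed model. Normally
#' produced by [fit_gibbs()], but exposed so that draws can be rebuilt from
#' persisted tables or constructed directly in resampling experiments.
#'
#' @param U Strain-effect draws: array `n_draws x n_strains x 4`, class
#'   columns ordered `iF, oF, iM, oM`.
#' @param H H-matrix draws: array `n_draws x 4 x 4` (each slice symmetric
#'   positive definite).
#' @param beta Fixed-effect draws: matrix `n_draws x p` with column names.
#' @param sigma2_e Residual-variance draws: matrix `n_draws x 4` (NA for
#'   observation classes absent from the data).
#' @param sigma2_v,sigma2_vS Epistasis variance draws (length `n_draws`;
#'   NA when no outbred pairs exist).
#' @param strains Strain labels.
#' @param chain Chain id (integer scalar).
#' @param config The [mcmc_config()] used, if any.
#' @return A `diallel_draws` object.
#' @export
new_diallel_draws <- function(U, H, beta = NULL, sigma2_e = NULL,
                              sigma2_v = NULL, sigma2_vS = NULL,
                              strains = NULL, chain = 1L, config = NULL) {
  stopifnot(length(dim(U)) == 3, dim(U)[3] == 4,
            length(dim(H)) == 3, dim(H)[2] == 4, dim(H)[3] == 4,
            dim(U)[1] == dim(H)[1])
  n <- dim(U)[1]
  if (is.null(strains)) strains <- paste0("S", seq_len(dim(U)[2]))
  dimnames(U) <- list(NULL, strains, OBSERVATION_CLASSES)
  dimnames(H) <- list(NULL, OBSERVATION_CLASSES, OBSERVATION_CLASSES)
  if (!is.null(sigma2_e)) colnames(sigma2_e) <- OBSERVATION_CLASSES
  structure(list(U = U, H = H, beta = beta, sigma2_e = sigma2_e,
                 sigma2_v = sigma2_v, sigma2_vS = sigma2_vS,
                 strains = strains, n_draws = n, chain = as.integer(chain),
                 config = config),
            class = "diallel_draws")
}

#' @export
print.diallel_draws <- function(x, ...) {
  cat("Diallel posterior draws: ", x$n_draws, " draws, ",
      length(x$strains), " strains (chain ", x$chain, ")\n", sep = "")
  invisible(x)
}

#' Number of stored draws
#' @param draws A `diallel_draws` object.
#' @return Integer draw count.
#' @export
n_draws <- function(draws) draws$n_draws

#' Persist posterior draws as plain-text tables
#'
#' Writes a columnar CSV of all stored scalar parameters (one row per draw)
#' plus a JSON sidecar holding the strain labels, chain id and sampler
#' configuration, from which [read_draws()] can rebuild the object.
#'
#' @param draws A `diallel_draws` object.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return The CSV path, invisibly.
#' @export
write_draws <- function(draws, stem) {
  ns <- length(draws$strains)
  flat <- cbind(
    draws$beta,
    matrix(draws$U, draws$n_draws, ns * 4,
           dimnames = list(NULL, paste0("U.", rep(draws$strains, 4), ".",
                                        rep(OBSERVATION_CLASSES, each = ns)))),
    matrix(draws$H, draws$n_draws, 16,
           dimnames = list(NULL, paste0("H.", rep(OBSERVATION_CLASSES, 4), ".",
                                        rep(OBSERVATION_CLASSES, each = 4)))),
    sigma2_v = draws$sigma2_v, sigma2_vS = draws$sigma2_vS,
    matrix(draws$sigma2_e, draws$n_draws, 4,
           dimnames = list(NULL, paste0("sigma2_e.", OBSERVATION_CLASSES)))
  )
  utils::write.csv(as.data.frame(flat), paste0(stem, ".csv"), row.names = FALSE)
  side <- list(strains = draws$strains, chain = draws$chain,
               beta_names = colnames(draws$beta),
               config = draws$config[setdiff(names(draws$config), "priors")],
               priors = draws$config$priors)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(stem, ".csv"))
}

#' Rebuild posterior draws from persisted tables
#' @param stem Path stem previously passed to [write_draws()].
#' @return A `diallel_draws` object.
#' @export
read_draws <- function(stem) {
  flat <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  strains <- side$strains
  ns <- length(strains)
  n <- nrow(flat)
  pick <- function(prefix) as.matrix(flat[, startsWith(names(flat), prefix), drop = FALSE])
  U <- array(pick("U."), c(n, ns, 4))
  H <- array(pick("H."), c(n, 4, 4))
  beta <- if (length(side$beta_names)) {
    b <- as.matrix(flat[, side$beta_names, drop = FALSE])
    colnames(b) <- side$beta_names
    b
  } else NULL
  new_diallel_draws(U, H, beta = beta,
                    sigma2_e = pick("sigma2_e."),
                    sigma2_v = flat$sigma2_v, sigma2_vS = flat$sigma2_vS,
                    strains = strains, chain = side$chain %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
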