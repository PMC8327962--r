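#' Build model matrices for the diallel mixed model
#'
#' Constructs the fixed-effect design matrix (treatment coding, reference
#' levels: female, outbred, block 1 — so the `inbred` coefficient is
#' directly the inbred-versus-outbred mean shift) and the random-effect
#' incidence mappings. An outbred observation of sex s loads weight 1 on
#' the sire's and the dam's (outbred, s) strain-effect columns, plus its
#' unordered-pair effect and pair-by-sex effect; an inbred observation
#' loads weight `w_self` (default 1, treating the inbred effect as a
#' whole-genotype effect; 2 for the additive-dose alternative) on its
#' strain's (inbred, s) column and no pair effects. Aliased fixed-effect
#' columns (e.g. in single-class data) are dropped with a message.
#'
#' @param obs Standardized observations ([standardize_relative_fitness()]).
#' @param design A `diallel_design` covering every strain in `obs`.
#' @param w_self Loading of selfs on their strain's inbred column.
#' @return List with `y`, `X` (full column rank), `cls` (1-based class
#'   index), `load1`, `load2` (strain indices; `NA` for absent second
#'   loading), `w1`, `w2` (loading weights), `pair`, `pairsex` (effect
#'   indices; `NA` for inbreds), `pair_labels`, `pairsex_labels`,
#'   `strains`.
#' @export
build_incidence <- function(obs, design = NULL, w_self = 1) {
  if (nrow(obs) > 0 && !"relative_fitness" %in% names(obs))
    stop("observations must be standardized first (standardize_relative_fitness)")
  if (is.null(design)) design <- derive_design(obs)
  strains <- design$strains
  if (nrow(obs)) {
    unknown <- setdiff(unique(c(obs$sire, obs$dam)), strains)
    if (length(unknown))
      stop("observation references strain(s) absent from design: ",
           paste(unknown, collapse = ", "))
  }
  n <- nrow(obs)
  male <- obs$sex == "M"
  inb <- obs$state == "i"
  blk2 <- obs$block == 2L
  X <- cbind("(Intercept)" = rep(1, n), sexM = as.numeric(male),
             block2 = as.numeric(blk2), inbred = as.numeric(inb),
             "sexM:inbred" = as.numeric(male & inb),
             "block2:inbred" = as.numeric(blk2 & inb))
  dropped <- character()
  if (n) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      keep <- qx$pivot[seq_len(qx$rank)]
      dropped <- colnames(X)[-keep]
      message("dropping aliased fixed-effect column(s): ",
              paste(dropped, collapse = ", "))
      X <- X[, sort(keep), drop = FALSE]
    }
  }
  cls <- match(paste0(ifelse(inb, "i", "o"), obs$sex), OBSERVATION_CLASSES)
  si <- match(obs$sire, strains)
  di <- match(obs$dam, strains)
  load1 <- si
  load2 <- ifelse(inb, NA_integer_, di)
  w1 <- ifelse(inb, w_self, 1)
  w2 <- ifelse(inb, 0, 1)
  pk <- ifelse(inb, NA_character_,
               paste(pmin(obs$sire, obs$dam), pmax(obs$sire, obs$dam), sep = ":"))
  pair_labels <- sort(unique(pk[!is.na(pk)]))
  pair <- match(pk, pair_labels)
  psk <- ifelse(inb, NA_character_, paste0(pk, ":", obs$sex))
  pairsex_labels <- sort(unique(psk[!is.na(psk)]))
  pairsex <- match(psk, pairsex_labels)
  list(y = if (n) obs$relative_fitness else numeric(0),
       X = X, cls = cls, load1 = load1, load2 = load2, w1 = w1, w2 = w2,
       pair = pair, pairsex = pairsex,
       pair_labels = pair_labels, pairsex_labels = pairsex_labels,
       strains = strains, dropped = dropped)
}
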