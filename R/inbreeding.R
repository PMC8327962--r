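#' Inbreeding coefficient under repeated full-sibling mating
#'
#' Classical recursion for the inbreeding coefficient F after `t`
#' generations of brother-sister mating starting from unrelated,
#' non-inbred parents:
#' \deqn{F_t = (1 + 2 F_{t-1} + F_{t-2})/4, \quad F_0 = F_{-1} = 0.}
#' One generation gives F = 0.25 (the level of an isofemale line founded by
#' a single pair); twelve generations give F = 0.9255..., which displays as
#' 0.926 at three decimals. Values are returned at full precision; round
#' only for display.
#'
#' @param t Number of generations (positive integer).
#' @param trajectory If `TRUE`, return the whole sequence `F_1 .. F_t`.
#' @return `F_t` as a numeric scalar, or the trajectory vector.
#' @examples
#' fullsib_inbreeding(1)            # 0.25
#' round(fullsib_inbreeding(12), 3) # 0.926
#' @export
fullsib_inbreeding <- function(t, trajectory = FALSE) {
  if (length(t) != 1 || is.na(t) || t < 1 || t != as.integer(t))
    stop("t must be a positive integer")
  t <- as.integer(t)
  f <- numeric(t)
  fm1 <- 0; fm2 <- 0   # F_0 and F_{-1}
  for (g in seq_len(t)) {
    f[g] <- (1 + 2 * fm1 + fm2) / 4
    fm2 <- fm1
    fm1 <- f[g]
  }
  if (trajectory) f else f[t]
}
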