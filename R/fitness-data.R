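#' Observation classes of the diallel fitness assay
#'
#' Every fitness observation belongs to exactly one of four classes defined
#' by its sex and inbred/outbred state: inbred female (`iF`), outbred female
#' (`oF`), inbred male (`iM`), outbred male (`oM`). This ordering is used
#' throughout the package, in particular for the rows/columns of the H
#' matrix and the columns of strain-effect draws.
#'
#' @format A character vector of length 4.
#' @export
OBSERVATION_CLASSES <- c("iF", "oF", "iM", "oM")

#' Map observations to their class label
#'
#' @param obs A fitness observation data frame (see [read_fitness_table()]).
#' @return A factor with levels `iF, oF, iM, oM`.
#' @export
observation_class <- function(obs) {
  lab <- paste0(ifelse(obs$state == "i", "i", "o"), obs$sex)
  factor(lab, levels = OBSERVATION_CLASSES)
}

req_cols <- c("sire", "dam", "sex", "block", "count")

#' Read a diallel fitness observation table
#'
#' Reads a tidy CSV of individual competitive lifetime reproductive success
#' measurements from a sex-specific diallel cross. The fixed schema has one
#' row per assay dish with columns `sire`, `dam`, `sex` (`F`/`M`), `state`
#' (`i`/`o`, derived from `sire == dam` when absent), `block` (`1`/`2`) and
#' `count` (non-negative offspring count). An optional `relative_fitness`
#' column (as written by [write_fitness_table()]) is preserved.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param col_map Optional named character vector mapping schema names to
#'   the file's column names, e.g. `c(sire = "male_line")`, to accommodate
#'   archives using different headers.
#' @return A `data.frame` of validated observations in file row order.
#' @export
read_fitness_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw))
        stop("column mapping names absent column '", col_map[[nm]], "'")
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(req_cols, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  obs <- data.frame(
    sire  = as.character(raw$sire),
    dam   = as.character(raw$dam),
    sex   = as.character(raw$sex),
    state = if ("state" %in% names(raw)) as.character(raw$state)
            else ifelse(raw$sire == raw$dam, "i", "o"),
    block = raw$block,
    count = raw$count,
    stringsAsFactors = FALSE
  )
  if ("relative_fitness" %in% names(raw))
    obs$relative_fitness <- as.numeric(raw$relative_fitness)
  validate_observations(obs)
}

#' Validate a fitness observation table
#'
#' Checks the schema invariants: sex in `F`/`M`, state in `i`/`o` and
#' consistent with `sire == dam`, block in `1`/`2`, counts non-negative.
#' Row-level problems are reported with their row numbers.
#'
#' @param obs A data frame with the schema of [read_fitness_table()].
#' @return `obs`, invisibly coerced to canonical types.
#' @export
validate_observations <- function(obs) {
  stopifnot(is.data.frame(obs))
  missing <- setdiff(req_cols, names(obs))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!"state" %in% names(obs))
    obs$state <- ifelse(obs$sire == obs$dam, "i", "o")
  bad <- which(!obs$sex %in% c("F", "M"))
  if (length(bad))
    stop("unparseable sex at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!obs$state %in% c("i", "o"))
  if (length(bad))
    stop("unparseable state at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  blk <- suppressWarnings(as.integer(obs$block))
  bad <- which(is.na(blk) | !blk %in% c(1L, 2L))
  if (length(bad))
    stop("unparseable block at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  obs$block <- blk
  cnt <- suppressWarnings(as.numeric(obs$count))
  bad <- which(is.na(cnt) | cnt < 0)
  if (length(bad))
    stop("negative or unparseable count at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  obs$count <- cnt
  selfed <- obs$sire == obs$dam
  bad <- which(selfed != (obs$state == "i"))
  if (length(bad))
    stop("state inconsistent with sire/dam equality at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  obs
}

#' Write a fitness observation table
#'
#' Inverse of [read_fitness_table()]: numeric fields are written with full
#' double precision so that a write/read round-trip reproduces every field
#' exactly.
#'
#' @param obs Observation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(obs, path) {
  out <- obs
  out$count <- vapply(obs$count, function(x) sprintf("%.17g", x), "")
  if ("relative_fitness" %in% names(out))
    out$relative_fitness <- vapply(out$relative_fitness, function(x)
      if (is.na(x)) "" else sprintf("%.17g", x), "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize fitness by the sex-specific outbred mean
#'
#' Converts raw offspring counts to relative fitness by dividing each count
#' by the mean count of outbred observations of the same sex, so that the
#' outbred mean relative fitness is exactly 1 within each sex. This is the
#' scale on which the H matrix and all derived statistics are estimated.
#'
#' @param obs Observation data frame.
#' @param per_block If `TRUE`, standardize within sex-by-block cells instead
#'   of globally per sex. The default (global per sex) matches the usual
#'   definition of relative fitness for a jointly assayed population.
#' @return `obs` with a `relative_fitness` column.
#' @export
standardize_relative_fitness <- function(obs, per_block = FALSE) {
  obs <- validate_observations(obs)
  key <- if (per_block) paste(obs$sex, obs$block) else obs$sex
  rel <- numeric(nrow(obs))
  for (k in unique(key)) {
    in_k <- key == k
    o <- in_k & obs$state == "o"
    if (!any(o))
      stop("cannot standardize: no outbred observations for group '", k, "'")
    m <- mean(obs$count[o])
    if (m <= 0)
      stop("cannot standardize: outbred mean count is not positive for '", k, "'")
    rel[in_k] <- obs$count[in_k] / m
  }
  obs$relative_fitness <- rel
  obs
}

#' Summarize the realized diallel design of a dataset
#'
#' Extracts which cells of the strain-by-strain cross table are realized,
#' the selfed strains, and per cell-by-sex-by-block replicate counts.
#' Strain indexing is by first appearance in the data (sires before dams,
#' row order).
#'
#' @param obs Observation data frame.
#' @return A `diallel_design` object: list with `strains` (ordered labels),
#'   `crosses` (data frame of ordered sire/dam pairs), `selfs` (labels), and
#'   `replicates` (data frame `sire, dam, sex, block, n`).
#' @export
derive_design <- function(obs) {
  obs <- validate_observations(obs)
  if (!nrow(obs)) stop("empty observation list")
  strains <- unique(c(rbind(obs$sire, obs$dam)))
  cell <- paste(obs$sire, obs$dam, obs$sex, obs$block, sep = "\r")
  tab <- table(cell)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  reps <- data.frame(sire = parts[, 1], dam = parts[, 2], sex = parts[, 3],
                     block = as.integer(parts[, 4]), n = as.integer(tab),
                     stringsAsFactors = FALSE)
  reps <- reps[order(match(reps$sire, strains), match(reps$dam, strains),
                     reps$sex, reps$block), , drop = FALSE]
  rownames(reps) <- NULL
  cross_cells <- unique(reps[reps$sire != reps$dam, c("sire", "dam")])
  rownames(cross_cells) <- NULL
  new_diallel_design(
    strains = strains,
    crosses = cross_cells,
    selfs = unique(reps$sire[reps$sire == reps$dam]),
    replicates = reps
  )
}

new_diallel_design <- function(strains, crosses, selfs, replicates) {
  stopifnot(all(selfs %in% strains),
            all(crosses$sire %in% strains), all(crosses$dam %in% strains),
            all(crosses$sire != crosses$dam))
  structure(list(strains = strains, crosses = crosses, selfs = selfs,
                 replicates = replicates),
            class = "diallel_design")
}

#' @export
print.diallel_design <- function(x, ...) {
  cat("Diallel design:", length(x$strains), "strains,",
      nrow(x$crosses), "ordered outbred crosses,",
      length(x$selfs), "selfs,",
      sum(x$replicates$n), "observations\n")
  invisible(x)
}
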