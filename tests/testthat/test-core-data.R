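test_that("a toy CSV parses into one observation per class", {
  path <- write_toy_csv()
  obs <- read_fitness_table(path)
  expect_equal(nrow(obs), 4)
  expect_setequal(as.character(observation_class(obs)),
                  c("iF", "iM", "oF", "oM"))
  # row order preserved
  expect_equal(obs$count, c(5, 7, 12, 20))
  # state is derivable when the column is absent
  raw <- toy_obs()
  raw$state <- NULL
  path2 <- write_toy_csv(raw)
  expect_equal(read_fitness_table(path2)$state, c("i", "i", "o", "o"))
})

test_that("schema and row-level validation errors are informative", {
  bad <- toy_obs()
  bad$state[1] <- "o"          # self marked outbred
  expect_error(validate_observations(bad), "inconsistent")
  raw <- toy_obs()
  raw$count <- NULL
  path <- write_toy_csv(raw)
  expect_error(read_fitness_table(path), "count")
  raw2 <- toy_obs()
  raw2$sex[3] <- "X"
  expect_error(validate_observations(raw2), "sex at row\\(s\\): 3")
  raw3 <- toy_obs()
  raw3$count[2] <- -1
  expect_error(validate_observations(raw3), "count")
  # column mapping handles renamed headers
  renamed <- toy_obs()
  names(renamed)[names(renamed) == "sire"] <- "male_line"
  path3 <- write_toy_csv(renamed)
  expect_error(read_fitness_table(path3), "sire")
  obs <- read_fitness_table(path3, col_map = c(sire = "male_line"))
  expect_equal(obs$sire, toy_obs()$sire)
})

test_that("relative fitness is the count over the sex-specific outbred mean", {
  obs <- data.frame(
    sire = c("A", "A", "B", "B", "A", "B", "A"),
    dam  = c("B", "B", "A", "A", "B", "A", "A"),
    sex  = c("M", "M", "F", "F", "F", "F", "F"),
    state = c("o", "o", "o", "o", "o", "o", "i"),
    block = 1L,
    count = c(10, 20, 30, 30, 30, 30, 15))
  std <- standardize_relative_fitness(obs)
  expect_equal(std$relative_fitness[1:2], c(2 / 3, 4 / 3))
  expect_equal(mean(std$relative_fitness[std$sex == "M" & std$state == "o"]), 1)
  expect_equal(mean(std$relative_fitness[std$sex == "F" & std$state == "o"]), 1)
  # inbred female at half the (constant) female outbred count
  expect_equal(std$relative_fitness[7], 0.5)
  # idempotence
  expect_equal(standardize_relative_fitness(std)$relative_fitness,
               std$relative_fitness)
  # order invariance
  set.seed(1)
  perm <- sample(nrow(obs))
  std2 <- standardize_relative_fitness(obs[perm, ])
  expect_equal(std2$relative_fitness, std$relative_fitness[perm])
})

test_that("standardization fails cleanly without outbred observations", {
  inb <- data.frame(sire = "A", dam = "A", sex = "F", state = "i",
                    block = 1L, count = 4)
  expect_error(standardize_relative_fitness(inb), "no outbred")
})

test_that("write/read round-trip preserves all fields exactly", {
  obs <- toy_obs()
  obs$count <- c(1 / 3, 2 / 7, 12.000000001, 20)
  std <- standardize_relative_fitness(obs)
  path <- tempfile(fileext = ".csv")
  write_fitness_table(std, path)
  back <- read_fitness_table(path)
  expect_identical(back$count, std$count)
  expect_identical(back$relative_fitness, std$relative_fitness)
  expect_identical(back[c("sire", "dam", "sex", "state", "block")],
                   std[c("sire", "dam", "sex", "state", "block")])
})

test_that("derive_design summarizes realized cells and replicates", {
  obs <- toy_obs()
  des <- derive_design(obs)
  expect_equal(length(des$selfs), 1)
  expect_equal(nrow(des$crosses), 2)    # A x B and B x A are distinct cells
  expect_equal(sum(des$replicates$n), nrow(obs))
  # duplicating rows doubles every replicate count
  des2 <- derive_design(rbind(obs, obs))
  expect_equal(des2$replicates$n, des$replicates$n * 2)
  expect_error(derive_design(obs[0, ]), "empty")
})

test_that("every observation maps to exactly one class", {
  set.seed(3)
  sires <- sample(LETTERS[1:5], 60, replace = TRUE)
  dams <- sample(LETTERS[1:5], 60, replace = TRUE)
  obs <- data.frame(sire = sires, dam = dams,
                    sex = sample(c("F", "M"), 60, TRUE),
                    state = ifelse(sires == dams, "i", "o"),
                    block = sample(1:2, 60, TRUE),
                    count = rpois(60, 20))
  cl <- observation_class(obs)
  expect_false(anyNA(cl))
  expect_true(all(levels(cl) == OBSERVATION_CLASSES))
  agree <- (obs$state == "i") == (substr(as.character(cl), 1, 1) == "i") &
    obs$sex == substr(as.character(cl), 2, 2)
  expect_true(all(agree))
})
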