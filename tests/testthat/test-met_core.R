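test_that("read_met parses long CSVs, flags missing cells, rejects duplicates", {
  path <- tmp_csv(c(
    "environment,variety,replicate,trait,value",
    "E1,A,1,yield,5.0",
    "E1,A,2,yield,6.0",
    "E1,B,1,yield,7.0",
    "E1,B,2,yield,8.0"
  ))
  met <- read_met(path)
  expect_s3_class(met, "met_table")
  expect_identical(nrow(met), 4L)
  expect_false(anyNA(met$value))

  # blank value -> missing, count preserved
  path2 <- tmp_csv(c(
    "environment,variety,replicate,trait,value",
    "E1,A,1,yield,5.0",
    "E1,A,2,yield,",
    "E1,B,1,yield,7.0",
    "E1,B,2,yield,8.0"
  ))
  met2 <- read_met(path2)
  expect_identical(nrow(met2), 4L)
  expect_identical(sum(is.na(met2$value)), 1L)

  # unparseable value -> missing with warning
  path3 <- tmp_csv(c(
    "environment,variety,replicate,trait,value",
    "E1,A,1,yield,5.0",
    "E1,A,2,yield,oops"
  ))
  expect_warning(met3 <- read_met(path3), "1 value cell")
  expect_identical(sum(is.na(met3$value)), 1L)

  # duplicated key -> integrity error naming the key
  path4 <- tmp_csv(c(
    "environment,variety,replicate,trait,value",
    "E1,A,1,yield,5.0",
    "E1,A,1,yield,6.0"
  ))
  expect_error(read_met(path4), class = "oatmet_integrity_error")
  expect_error(read_met(path4), "E1")

  # missing mandatory column -> schema error
  path5 <- tmp_csv(c("environment,variety,trait,value", "E1,A,yield,5"))
  expect_error(read_met(path5), class = "oatmet_schema_error")
})

test_that("read_met honours a column-name schema and na strings", {
  path <- tmp_csv(c(
    "env,gen,rep,char,val",
    "E1,A,1,yield,5.0",
    "E1,A,2,yield,na",
    "E1,B,1,yield,7.0",
    "E1,B,2,yield,8.0"
  ))
  met <- read_met(path, schema = c(environment = "env", variety = "gen",
                                   replicate = "rep", trait = "char",
                                   value = "val"))
  expect_identical(nrow(met), 4L)
  expect_identical(sum(is.na(met$value)), 1L)
})

test_that("cell_means averages replicates and masks empty cells", {
  met <- met_table(data.frame(
    environment = rep(c("E1", "E2", "E3"), each = 4),
    variety = rep(c("A", "A", "B", "B"), times = 3),
    replicate = rep(1:2, times = 6),
    trait = "yield",
    value = c(2, 4, 5, 7, 3, 5, 6, 8, 4, 6, 7, NA)
  ))
  cm <- cell_means(met, "yield")
  expect_equal(cm$values["A", "E1"], 3) # mean of (2, 4)
  expect_equal(cm$values["B", "E3"], 7) # available-case: single replicate
  expect_equal(cm$n["B", "E3"], 1)

  # a fully-missing cell is masked, the others unaffected
  met2 <- met_table(data.frame(
    environment = rep(c("E1", "E2", "E3"), each = 6),
    variety = rep(c("A", "A", "B", "B", "C", "C"), times = 3),
    replicate = rep(1:2, times = 9),
    trait = "yield",
    value = c(2, 4, 5, 7, 1, 3, 3, 5, 6, 8, 2, 4, 4, 6, NA, NA, 3, 5)
  ))
  cm2 <- cell_means(met2, "yield")
  expect_true(is.na(cm2$values["B", "E3"]))
  expect_equal(cm2$values["A", "E3"], 5)
  expect_equal(cm2$values["C", "E3"], 4)

  expect_error(cell_means(met, "nope"), class = "oatmet_not_found_error")
})

test_that("cell_means is invariant to record order and replicate numbering", {
  sim <- simulate_met(synthetic_truth(seed = 11, g = 3, e = 5, r = 3))
  met <- sim$met
  cm <- cell_means(met, "yield")

  set.seed(1)
  shuffled <- met_table(met[sample(nrow(met)), ])
  cm_shuffled <- cell_means(shuffled, "yield")
  expect_equal(cm_shuffled$values, cm$values)

  renumbered <- met
  renumbered$replicate <- ((renumbered$replicate + 1L) %% 3L) + 1L
  cm_renum <- cell_means(met_table(renumbered), "yield")
  expect_equal(cm_renum$values, cm$values)
})

test_that("zero-noise generator round-trip reproduces cell values exactly", {
  truth <- synthetic_truth(seed = 3, g = 4, e = 22, r = 3, sigma_noise = 0)
  sim <- simulate_met(truth)
  cm <- cell_means(sim$met, "yield")
  expected <- truth$mu + matrix(truth$variety_effects, 4, 22) +
    outer(truth$sensitivities, truth$env_index)
  expect_equal(unname(cm$values), unname(expected), tolerance = 1e-12)
  expect_equal(variety_means(cm), truth$mu + truth$variety_effects,
               tolerance = 1e-12, ignore_attr = "names")
})

test_that("environment and variety means are unweighted available-case means", {
  cm <- as_cell_means(rbind(c(6, 2, 1), c(8, 4, 2), c(8, 6, 3),
                            c(10, 8, 4)))
  expect_equal(unname(environment_means(cm)[1]), 8)
  expect_equal(unname(variety_means(cm)[1]), 3)

  vals <- rbind(c(6, 2, 1), c(NA, 4, 2), c(8, 6, 3), c(10, 8, 4))
  cm2 <- as_cell_means(vals)
  expect_equal(unname(environment_means(cm2)[1]), 8) # over 3 values

  # all-masked row violates the >= 2 observed cells invariant
  vals3 <- rbind(c(NA, NA, NA), c(8, 6, 3), c(10, 8, 4))
  expect_error(as_cell_means(vals3), class = "oatmet_input_error")
})

test_that("grand means from environments and varieties agree for balanced tables", {
  for (seed in 1:5) {
    sim <- simulate_met(synthetic_truth(seed = seed, g = 4, e = 6, r = 2))
    cm <- cell_means(sim$met, "yield")
    expect_equal(mean(environment_means(cm)), mean(variety_means(cm)),
                 tolerance = 1e-12)
  }
})

test_that("environment metadata validation catches impossible records", {
  path <- tmp_csv(c(
    "environment,site,latitude,longitude,sowing_date,harvest_date",
    "1,Here,52.4,-4.0,2011-09-28,2012-08-09"
  ))
  meta <- read_env_metadata(path)
  expect_identical(meta$spring_sown, FALSE)

  bad_dates <- tmp_csv(c(
    "environment,site,latitude,longitude,sowing_date,harvest_date",
    "1,Here,52.4,-4.0,2012-09-28,2012-08-09"
  ))
  expect_error(read_env_metadata(bad_dates), class = "oatmet_integrity_error")

  bad_lat <- tmp_csv(c(
    "environment,site,latitude,longitude,sowing_date,harvest_date",
    "1,Here,952.4,-4.0,2011-09-28,2012-08-09"
  ))
  expect_error(read_env_metadata(bad_lat), class = "oatmet_integrity_error")
})
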