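test_that("windowed aggregation: sums for rain, means for temperature", {
  wx <- flat_weather("2012-11-01", "2013-09-30", rain = 2)
  harvest <- as.Date("2013-08-15")

  # Dec 1 - Apr 30 over a non-leap February: 151 days at 2 mm/day
  rain_win <- weather_window("rain_dec_apr", "rain", 12, 4)
  expect_equal(aggregate_weather(wx, harvest, rain_win), 302)

  # July mean of (tmin + tmax) / 2 with tmin 4, tmax 12
  temp_win <- weather_window("temp_jul", "temperature", 7, 7)
  expect_equal(aggregate_weather(wx, harvest, temp_win), 8)

  # autumn months anchor to the pre-harvest year
  autumn <- weather_window("rain_nov", "rain", 11, 11)
  expect_equal(aggregate_weather(wx, harvest, autumn), 60) # Nov 2012

  # leap February changes the window length
  wx_leap <- flat_weather("2011-11-01", "2012-09-30", rain = 2)
  expect_equal(aggregate_weather(wx_leap, as.Date("2012-08-15"), rain_win),
               304)
})

test_that("aggregation reports missing when the window is too sparse", {
  wx <- flat_weather("2013-06-01", "2013-06-10")
  win <- weather_window("rain_jun_jul", "rain", 6, 7)
  # only 10 of 61 days present
  expect_warning(v <- aggregate_weather(wx, as.Date("2013-08-15"), win),
                 "missing")
  expect_true(is.na(v))

  # empty overlap -> missing too
  win_dec <- weather_window("rain_dec", "rain", 12, 12)
  expect_warning(v2 <- aggregate_weather(wx, as.Date("2013-08-15"), win_dec))
  expect_true(is.na(v2))

  # a few missing days within tolerance are fine
  wx_most <- flat_weather("2013-06-01", "2013-07-28", rain = 1)
  expect_equal(aggregate_weather(wx_most, as.Date("2013-08-15"), win), 58)
})

test_that("daily weather validation enforces physical invariants", {
  bad_t <- tibble::tibble(date = as.Date("2013-06-01"), rain = 0,
                          tmin = 15, tmax = 10)
  expect_error(validate_daily_weather <- oatmet:::validate_daily_weather(bad_t),
               class = "oatmet_integrity_error")
  bad_rain <- flat_weather("2013-06-01", "2013-06-03", rain = -1)
  expect_error(oatmet:::validate_daily_weather(bad_rain),
               class = "oatmet_integrity_error")
  dup <- rbind(flat_weather("2013-06-01", "2013-06-02"),
               flat_weather("2013-06-01", "2013-06-01"))
  expect_error(oatmet:::validate_daily_weather(dup),
               class = "oatmet_integrity_error")
})

test_that("pearson_cor matches the closed form and flags degenerate input", {
  x <- c(1, 2, 3, 5, 8)
  y <- 2 * x + 1
  res <- pearson_cor(x, y)
  expect_equal(res$r, 1)
  expect_identical(res$df, 3L)

  set.seed(2)
  a <- rnorm(12)
  b <- a + rnorm(12)
  res2 <- pearson_cor(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_hand <- r_hand * sqrt(10 / (1 - r_hand^2))
  expect_equal(res2$r, r_hand)
  expect_equal(res2$p_value, 2 * pt(-abs(t_hand), df = 10))

  # symmetry and shift/scale invariance
  expect_equal(pearson_cor(b, a)$r, res2$r)
  expect_equal(pearson_cor(3 * a - 7, b / 2 + 1)$r, res2$r)

  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)),
               class = "oatmet_domain_error")
  expect_error(pearson_cor(c(1, 2), c(1, 2)), class = "oatmet_input_error")
})

test_that("significance stars follow the conventional thresholds", {
  expect_identical(oatmet:::star_code(c(0.0005, 0.005, 0.04, 0.2)),
                   c("***", "**", "*", ""))
})

test_that("correlation grid uses pairwise deletion and exclusions", {
  trial <- oat_trial()
  covs <- trial$environments[, c("environment", "rain_dec_apr",
                                 "rain_jun_jul", "temp_mar", "temp_jul")]
  spring <- trial$environments$environment[trial$environments$spring_sown]
  grid <- correlation_table(trial$env_means, covs, exclude = spring)

  cell <- function(tr, cv) grid[grid$trait == tr & grid$covariate == cv, ]

  # hectoliter weight is unavailable in two environments: df drops to 17
  expect_identical(cell("hectoliter_weight", "rain_jun_jul")$df, 17L)
  # fully observed traits keep 21 environments: df 19
  expect_identical(cell("yield", "rain_jun_jul")$df, 19L)
  # December-April rainfall is itself missing for the spring-sown trial,
  # but that environment is excluded anyway
  expect_identical(cell("yield", "rain_dec_apr")$df, 19L)

  # determinism: identical trait vectors give identical correlations
  dup <- trial$env_means[, c("environment", "yield")]
  dup$yield_copy <- dup$yield
  g2 <- correlation_table(dup, covs, exclude = spring)
  expect_equal(g2$r[g2$trait == "yield"], g2$r[g2$trait == "yield_copy"])

  expect_error(correlation_table(trial$env_means, covs,
                                 exclude = trial$env_means$environment),
               class = "oatmet_input_error")
})

test_that("stars in the grid are consistent with the p-values", {
  trial <- oat_trial()
  covs <- trial$environments[, c("environment", "rain_jun_jul")]
  grid <- correlation_table(trial$env_means, covs, exclude = "8")
  expect_true(all(grid$stars == oatmet:::star_code(grid$p_value)))
  expect_true(all(abs(grid$r) <= 1))
  expect_true(all(grid$df == grid$n - 2L))
})
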