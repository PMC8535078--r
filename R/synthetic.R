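#' Ground truth for a synthetic multi-environment trial
#'
#' Defines the parameters of the bilinear generating model
#' \eqn{y_{ijk} = \mu + V_i + b_i E_j + \epsilon_{ijk}} for a g-variety x
#' e-environment x r-replicate randomized-block trial. Defaults emulate a
#' yield-like trait in a 4-variety x 22-environment x 3-replicate UK winter
#' oat series: grand mean 8.16 t/ha, environment spread `sigma_env` 1.5
#' t/ha (the spread of published per-environment yields), nearly equal
#' variety means (`sigma_variety` 0.12), slope spread `sigma_b` 0.15
#' (the spread of published yield sensitivities) and plot noise
#' `sigma_noise` 0.5 t/ha.
#'
#' Effects may be supplied explicitly or drawn (Normal); drawn or supplied,
#' they are re-identified exactly: `mean(b) = 1`, `sum(V) = 0`,
#' `sum(E) = 0`, and drawn `E` is rescaled so `sd(E)` equals `sigma_env`
#' exactly.
#'
#' Reproducibility uses fixed stream-splitting from the single root seed:
#' effect draws use `seed`, replicate noise `seed + 1`, cell missingness
#' `seed + 2`, weather `seed + 3`.
#'
#' @param seed Root seed (non-negative integer).
#' @param g,e,r Numbers of varieties, environments, replicates.
#' @param mu Grand mean, trait units.
#' @param variety_effects,sensitivities,env_index Optional explicit
#'   \eqn{V_i} (length g), \eqn{b_i} (length g), \eqn{E_j} (length e);
#'   drawn if `NULL`.
#' @param sigma_variety,sigma_b SDs for drawing \eqn{V_i} and \eqn{b_i}.
#' @param sigma_env Spread (SD) of the environmental index \eqn{E_j}.
#' @param sigma_noise Replicate (plot) noise SD \eqn{\sigma_\epsilon}.
#' @param missing_prob Probability that a variety-environment cell is
#'   dropped entirely, in \[0, 1).
#' @param rho Target correlation between a simulated windowed weather
#'   covariate and \eqn{E_j}, in \[-1, 1\].
#' @param weather_mean,weather_sd Location/scale of the simulated windowed
#'   weather aggregate (defaults emulate summer rainfall totals, mm).
#' @param trait Trait label for the generated records.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1L, g = 4L, e = 22L, r = 3L, mu = 8.16,
                            variety_effects = NULL, sensitivities = NULL,
                            env_index = NULL,
                            sigma_variety = 0.12, sigma_env = 1.5,
                            sigma_b = 0.15, sigma_noise = 0.5,
                            missing_prob = 0, rho = 0,
                            weather_mean = 180, weather_sd = 60,
                            trait = "yield") {
  if (g < 2L || e < 3L || r < 1L) {
    stop_oatmet("need g >= 2, e >= 3, r >= 1", "oatmet_config_error")
  }
  for (nm in c("sigma_variety", "sigma_env", "sigma_b", "sigma_noise")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  assert_scalar_number(missing_prob, "missing_prob", lower = 0, upper = 1)
  if (missing_prob >= 1) {
    stop_oatmet("missing_prob must be < 1", "oatmet_config_error")
  }
  assert_scalar_number(rho, "rho", lower = -1, upper = 1)
  assert_scalar_number(seed, "seed", lower = 0)

  set.seed(seed)
  V <- variety_effects %||% rnorm(g, 0, sigma_variety)
  b <- sensitivities %||% (1 + rnorm(g, 0, sigma_b))
  E <- env_index
  if (is.null(E)) {
    E <- rnorm(e)
    E <- E - mean(E)
    E <- if (sd(E) > 0) E * sigma_env / sd(E) else E
  } else {
    E <- E - mean(E)
  }
  if (length(V) != g || length(b) != g || length(E) != e) {
    stop_oatmet("effect vectors have wrong length", "oatmet_config_error")
  }
  # exact re-identification
  V <- V - mean(V)
  b <- b - mean(b) + 1

  structure(list(seed = as.integer(seed), g = as.integer(g),
                 e = as.integer(e), r = as.integer(r), mu = mu,
                 variety_effects = stats::setNames(V, paste0("V", seq_len(g))),
                 sensitivities = stats::setNames(b, paste0("V", seq_len(g))),
                 env_index = stats::setNames(E, sprintf("E%02d", seq_len(e))),
                 sigma_noise = sigma_noise, missing_prob = missing_prob,
                 rho = rho, weather_mean = weather_mean,
                 weather_sd = weather_sd, trait = trait),
            class = "synthetic_truth")
}

#' Simulate replicate-level multi-environment trial data
#'
#' Draws `y_ijk = mu + V_i + b_i E_j + eps_ijk` with
#' `eps ~ Normal(0, sigma_noise)`, then deletes whole variety-environment
#' cells with probability `missing_prob`. Deletion is repaired where needed
#' so the generated table always satisfies the downstream invariants (every
#' environment keeps >= 2 observed varieties, every variety >= 3
#' environments). Identical seeds give identical output.
#'
#' @param truth A [synthetic_truth()].
#' @return A list with elements `met` (a [met_table()]) and `truth`.
#' @examples
#' sim <- simulate_met(synthetic_truth(seed = 7, sigma_noise = 0))
#' fit <- fit_joint_regression(cell_means(sim$met, "yield"))
#' max(abs(fit$sensitivity - sim$truth$sensitivities)) # ~1e-16
#' @export
simulate_met <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  g <- truth$g
  e <- truth$e
  r <- truth$r
  envs <- names(truth$env_index)
  vars <- names(truth$variety_effects)

  mu_cell <- truth$mu + matrix(truth$variety_effects, g, e) +
    outer(truth$sensitivities, truth$env_index)

  set.seed(truth$seed + 1L)
  eps <- array(rnorm(g * e * r, 0, truth$sigma_noise), dim = c(g, e, r))

  set.seed(truth$seed + 2L)
  drop <- matrix(runif(g * e) < truth$missing_prob, g, e)
  drop <- repair_missingness(drop)

  rec <- expand.grid(variety = seq_len(g), environment = seq_len(e),
                     replicate = seq_len(r))
  value <- mu_cell[cbind(rec$variety, rec$environment)] +
    eps[cbind(rec$variety, rec$environment, rec$replicate)]
  value[drop[cbind(rec$variety, rec$environment)]] <- NA_real_

  met <- met_table(data.frame(
    environment = envs[rec$environment],
    variety = vars[rec$variety],
    replicate = rec$replicate,
    trait = truth$trait,
    value = value
  ))
  list(met = met, truth = truth)
}

# undo just enough random cell deletion to keep every column with >= 2
# observed cells and every row with >= 3 (fitter preconditions)
repair_missingness <- function(drop) {
  for (j in seq_len(ncol(drop))) {
    while (sum(!drop[, j]) < 2L) {
      drop[which(drop[, j])[1L], j] <- FALSE
    }
  }
  for (i in seq_len(nrow(drop))) {
    while (sum(!drop[i, ]) < 3L) {
      drop[i, which(drop[i, ])[1L]] <- FALSE
    }
  }
  drop
}

#' Simulate daily weather linked to the environmental index
#'
#' Constructs, for each synthetic environment, a daily series over the
#' given window whose windowed aggregate \eqn{A_j} satisfies
#' \eqn{A_j = m + s\,(\rho\, z(E_j) + \sqrt{1 - \rho^2}\, \zeta_j)} with
#' \eqn{\zeta_j \sim N(0,1)} and \eqn{z(E)} the standardised environmental
#' index, so the sample correlation between the aggregate and \eqn{E_j}
#' converges to `rho` as the number of environments grows (and is exactly
#' affine in \eqn{E_j} when `|rho| = 1`). The aggregate is spread uniformly
#' over the window's days; rainfall is clamped at zero (aggregates are
#' `pmax(A, 0)`), and `tmin <= tmax` holds by construction.
#'
#' @param truth A [synthetic_truth()] (uses its `rho`, `weather_mean`,
#'   `weather_sd` and weather seed stream).
#' @param window A [weather_window()].
#' @param harvest_year Calendar year all synthetic environments are
#'   harvested in (default 2012); every environment gets harvest date
#'   15 August.
#' @return A list: `weather` (named list of daily tibbles per environment),
#'   `env_meta` (metadata tibble), `covariate` (tibble of the windowed
#'   aggregates), `truth`.
#' @export
simulate_weather <- function(truth, window, harvest_year = 2012L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(window, "weather_window"))
  e <- truth$e
  envs <- names(truth$env_index)
  harvest <- as.Date(sprintf("%04d-08-15", harvest_year))
  sowing <- as.Date(sprintf("%04d-10-01", harvest_year - 1L))

  z <- truth$env_index
  z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
  set.seed(truth$seed + 3L)
  zeta <- rnorm(e)
  agg <- truth$weather_mean +
    truth$weather_sd * (truth$rho * z + sqrt(1 - truth$rho^2) * zeta)
  if (window$variable %in% c("rain", "radiation")) agg <- pmax(agg, 0)

  span <- resolve_window(window, harvest)
  days <- seq(span[["start"]], span[["end"]], by = "day")
  nd <- length(days)

  weather <- lapply(seq_len(e), function(j) {
    daily <- agg[j] / if (window$statistic == "sum") nd else 1
    tibble::tibble(
      date = days,
      rain = if (window$variable == "rain") rep(daily, nd) else 0,
      tmin = if (window$variable == "temperature") daily - 4 else 6,
      tmax = if (window$variable == "temperature") daily + 4 else 14,
      radiation = if (window$variable == "radiation") rep(daily, nd) else 15
    )
  })
  names(weather) <- envs

  env_meta <- tibble::tibble(
    environment = envs, site = "synthetic",
    latitude = 52, longitude = -4,
    sowing_date = sowing, harvest_date = harvest,
    spring_sown = FALSE
  )
  covariate <- tibble::tibble(environment = envs,
                              value = stats::setNames(agg, NULL))
  names(covariate)[2] <- window$name
  list(weather = weather, env_meta = env_meta, covariate = covariate,
       truth = truth)
}
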