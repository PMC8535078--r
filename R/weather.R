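#' Read a daily weather series for one site
#'
#' @param path CSV with columns `date` (ISO-8601), `rain` (mm/day),
#'   `tmin`, `tmax` (deg C), and optionally `rh` (%) and `radiation`
#'   (MJ/m2/day).
#' @return A tibble, validated: unique dates, `rain >= 0`, `tmin <= tmax`,
#'   `rh` in \[0, 100\] where present.
#' @export
read_daily_weather <- function(path) {
  if (!file.exists(path)) {
    stop_oatmet(sprintf("file not found: %s", path), "oatmet_io_error")
  }
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("date", "rain", "tmin", "tmax")
  missing_cols <- setdiff(needed, names(w))
  if (length(missing_cols)) {
    stop_oatmet(paste0("missing weather column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "oatmet_schema_error")
  }
  w$date <- as.Date(w$date)
  validate_daily_weather(w)
}

validate_daily_weather <- function(w) {
  if (anyDuplicated(w$date)) {
    stop_oatmet("duplicate dates in weather series", "oatmet_integrity_error")
  }
  if (any(w$rain < 0, na.rm = TRUE)) {
    stop_oatmet("negative rainfall", "oatmet_integrity_error")
  }
  if (any(w$tmin > w$tmax, na.rm = TRUE)) {
    stop_oatmet("tmin > tmax", "oatmet_integrity_error")
  }
  if ("rh" %in% names(w) && any(w$rh < 0 | w$rh > 100, na.rm = TRUE)) {
    stop_oatmet("relative humidity outside [0, 100]",
                "oatmet_integrity_error")
  }
  if ("radiation" %in% names(w) && any(w$radiation < 0, na.rm = TRUE)) {
    stop_oatmet("negative radiation", "oatmet_integrity_error")
  }
  tibble::as_tibble(w)
}

#' Define a seasonal weather window
#'
#' A window is a start month/day and end month/day anchored to an
#' environment's harvest year. By default months from September onwards are
#' taken from the calendar year *before* harvest (an autumn-sown crop's
#' season starts the previous autumn), months January-August from the
#' harvest year itself; explicit `start_offset` / `end_offset` (in years,
#' relative to the harvest year) override this rule.
#'
#' @param name Covariate name used in output tables.
#' @param variable One of `"rain"`, `"temperature"`, `"radiation"`.
#' @param start_month,start_day Window start (day defaults to 1).
#' @param end_month,end_day Window end (day defaults to the last day of
#'   `end_month`).
#' @param statistic `"sum"` or `"mean"`; defaults to `"sum"` for rain and
#'   radiation, `"mean"` (of daily `(tmin + tmax) / 2`) for temperature.
#' @param start_offset,end_offset Optional explicit year offsets relative
#'   to the harvest year.
#' @return An object of class `weather_window`.
#' @examples
#' weather_window("rain_dec_apr", "rain", 12, end_month = 4)
#' @export
weather_window <- function(name, variable = c("rain", "temperature",
                                              "radiation"),
                           start_month, end_month,
                           start_day = 1L, end_day = NULL,
                           statistic = NULL,
                           start_offset = NULL, end_offset = NULL) {
  variable <- match.arg(variable)
  statistic <- statistic %||%
    if (variable == "temperature") "mean" else "sum"
  if (!statistic %in% c("sum", "mean")) {
    stop_oatmet("statistic must be 'sum' or 'mean'", "oatmet_config_error")
  }
  for (m in c(start_month, end_month)) {
    if (!m %in% 1:12) stop_oatmet("months must be in 1..12",
                                  "oatmet_config_error")
  }
  structure(list(name = name, variable = variable, statistic = statistic,
                 start_month = as.integer(start_month),
                 start_day = as.integer(start_day),
                 end_month = as.integer(end_month), end_day = end_day,
                 start_offset = start_offset, end_offset = end_offset),
            class = "weather_window")
}

# default year anchoring: autumn months belong to the pre-harvest year
default_offset <- function(month) if (month >= 9L) -1L else 0L

resolve_window <- function(window, harvest_date) {
  harvest_year <- as.integer(format(as.Date(harvest_date), "%Y"))
  so <- window$start_offset %||% default_offset(window$start_month)
  eo <- window$end_offset %||% default_offset(window$end_month)
  start <- as.Date(sprintf("%04d-%02d-%02d", harvest_year + so,
                           window$start_month, window$start_day))
  end_day <- window$end_day
  if (is.null(end_day)) {
    first_next <- as.Date(sprintf("%04d-%02d-01",
                                  harvest_year + eo + (window$end_month == 12L),
                                  window$end_month %% 12L + 1L))
    end <- first_next - 1L
  } else {
    end <- as.Date(sprintf("%04d-%02d-%02d", harvest_year + eo,
                           window$end_month, end_day))
  }
  if (is.na(start) || is.na(end) || end < start) {
    stop_oatmet(sprintf("window '%s' is empty or unresolvable", window$name),
                "oatmet_config_error")
  }
  c(start = start, end = end)
}

#' Aggregate a daily weather series over a seasonal window
#'
#' Cumulative sum for rainfall and radiation, mean of the daily midpoint
#' `(tmin + tmax) / 2` for temperature. If more than `max_missing` of the
#' window's days are absent from the series (or have a missing value for
#' the needed variable) the aggregate is reported missing, with a warning.
#'
#' @param weather A daily weather tibble (see [read_daily_weather()]).
#' @param harvest_date Harvest date of the environment; anchors the window.
#' @param window A [weather_window()].
#' @param max_missing Maximum tolerated fraction of missing days
#'   (default 0.1).
#' @return A single numeric value, or `NA` if too many days are missing.
#' @export
aggregate_weather <- function(weather, harvest_date, window,
                              max_missing = 0.1) {
  span <- resolve_window(window, harvest_date)
  days <- seq(span[["start"]], span[["end"]], by = "day")
  idx <- match(days, weather$date)
  x <- switch(window$variable,
    rain = weather$rain[idx],
    radiation = {
      if (!"radiation" %in% names(weather)) {
        stop_oatmet("weather series has no radiation column",
                    "oatmet_schema_error")
      }
      weather$radiation[idx]
    },
    temperature = (weather$tmin[idx] + weather$tmax[idx]) / 2
  )
  frac_missing <- mean(is.na(x))
  if (frac_missing > max_missing) {
    rlang::warn(sprintf(
      "window '%s': %.0f%% of %d days missing; aggregate set to NA",
      window$name, 100 * frac_missing, length(days)))
    return(NA_real_)
  }
  if (window$statistic == "sum") sum(x, na.rm = TRUE) else mean(x, na.rm = TRUE)
}

#' Per-environment weather covariates
#'
#' Applies a set of windows to each environment's daily weather series.
#'
#' @param weather Named list of daily weather tibbles, one per environment
#'   (names are environment ids).
#' @param env_meta Environment metadata tibble with `environment` and
#'   `harvest_date` columns.
#' @param windows A list of [weather_window()] objects.
#' @inheritParams aggregate_weather
#' @return A tibble with `environment` and one column per window name.
#' @export
weather_covariates <- function(weather, env_meta, windows,
                               max_missing = 0.1) {
  out <- tibble::tibble(environment = as.character(env_meta$environment))
  for (w in windows) {
    out[[w$name]] <- vapply(seq_len(nrow(env_meta)), function(k) {
      env <- as.character(env_meta$environment[k])
      series <- weather[[env]]
      if (is.null(series)) {
        stop_oatmet(sprintf("no weather series for environment '%s'", env),
                    "oatmet_input_error")
      }
      aggregate_weather(series, env_meta$harvest_date[k], w,
                        max_missing = max_missing)
    }, numeric(1))
  }
  out
}

#' Pearson product-moment correlation with significance
#'
#' Pairwise-complete Pearson correlation with the two-sided t test
#' \eqn{t = r \sqrt{df / (1 - r^2)}} on `df = n - 2` degrees of freedom,
#' and the conventional star code (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   in either are dropped.
#' @return A one-row tibble: `r`, `n`, `df`, `p_value`, `stars`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop_oatmet("fewer than 3 complete pairs", "oatmet_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_oatmet("correlation undefined: zero variance", "oatmet_domain_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- ct$p.value
  tibble::tibble(r = r, n = n, df = n - 2L, p_value = p,
                 stars = star_code(p))
}

#' Trait-by-covariate Pearson correlation grid
#'
#' Computes the correlation between every trait column and every covariate
#' column across environments, with pairwise deletion (a trait missing in
#' some environments loses only those rows, so different cells can have
#' different degrees of freedom) and optional environment exclusions (e.g.
#' a spring-sown trial in an autumn-sown series).
#'
#' @param traits A tibble with an `environment` column and one numeric
#'   column per trait (per-environment trait means).
#' @param covariates A tibble with an `environment` column and one numeric
#'   column per covariate.
#' @param exclude Character vector of environment ids to drop before
#'   correlating (default none).
#' @param min_pairs Minimum complete pairs per cell (default 3); cells with
#'   fewer are reported as missing with a note.
#' @return A tibble with one row per trait x covariate pair: `trait`,
#'   `covariate`, `r`, `n`, `df`, `p_value`, `stars`, `note`.
#' @export
correlation_table <- function(traits, covariates, exclude = NULL,
                              min_pairs = 3L) {
  traits$environment <- as.character(traits$environment)
  covariates$environment <- as.character(covariates$environment)
  keep <- !traits$environment %in% as.character(exclude)
  if (!any(keep)) {
    stop_oatmet("all environments excluded", "oatmet_input_error")
  }
  tr <- traits[keep, , drop = FALSE]
  cv <- covariates[match(tr$environment, covariates$environment), ,
                   drop = FALSE]
  trait_cols <- setdiff(names(tr), "environment")
  cov_cols <- setdiff(names(cv), "environment")
  if (!length(trait_cols) || !length(cov_cols)) {
    stop_oatmet("need at least one trait and one covariate column",
                "oatmet_input_error")
  }

  grid <- expand.grid(trait = trait_cols, covariate = cov_cols,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    x <- tr[[grid$trait[k]]]
    y <- cv[[grid$covariate[k]]]
    n_ok <- sum(stats::complete.cases(x, y))
    res <- tryCatch({
      if (n_ok < min_pairs) {
        stop_oatmet(sprintf("only %d complete pairs", n_ok),
                    "oatmet_input_error")
      }
      cbind(pearson_cor(x, y), note = NA_character_)
    }, oatmet_error = function(e) {
      tibble::tibble(r = NA_real_, n = n_ok, df = NA_integer_,
                     p_value = NA_real_, stars = NA_character_,
                     note = conditionMessage(e))
    })
    cbind(grid[k, , drop = FALSE], res)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
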