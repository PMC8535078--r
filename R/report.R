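#' Range of per-environment values with the extreme environments
#'
#' @param x Numeric vector of per-environment values (missing values
#'   ignored).
#' @param labels Labels for the entries (defaults to `names(x)`, then to
#'   positional indices).
#' @return A one-row tibble: `min`, `min_label`, `max`, `max_label`, `n`.
#' @examples
#' summarize_ranges(c(E1 = 6.0, E2 = 4.8, E3 = 10.5))
#' @export
summarize_ranges <- function(x, labels = NULL) {
  labels <- labels %||% names(x) %||% as.character(seq_along(x))
  keep <- !is.na(x)
  x <- x[keep]
  labels <- labels[keep]
  if (!length(x)) {
    stop_oatmet("no non-missing values", "oatmet_input_error")
  }
  tibble::tibble(min = min(x), min_label = labels[which.min(x)],
                 max = max(x), max_label = labels[which.max(x)],
                 n = length(x))
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates the package end to end and writes CSV report tables plus a
#' JSON run manifest to `config$output_dir`. Two modes:
#'
#' * **Bundled-summary mode** (default): uses the packaged trial tables.
#'   Writes the merged per-environment means with ranges, the published
#'   variety stability table with its slope-mean consistency check, the
#'   recomputed trait-weather correlation grid (spring-sown environment
#'   excluded) side by side with the published values, and an
#'   environment-level trait biplot.
#' * **Synthetic mode** (`config$synthetic` is a list of
#'   [synthetic_truth()] arguments): simulates a multi-trait trial sharing
#'   one environmental index, refits the joint regression per trait,
#'   scores parameter recovery against the truth, simulates linked
#'   weather, recomputes the correlation grid, and builds the
#'   variety-by-environment biplot with per-variety convex hulls.
#'
#' Any stage failure aborts with the stage name; files already written by
#' the failed run are removed.
#'
#' @param config A list: `output_dir` (required), `seed` (default 1),
#'   optional `synthetic` (list passed to [synthetic_truth()]),
#'   `n_traits` (synthetic mode, default 4), `exclude_spring_sown`
#'   (default `TRUE`).
#' @return Invisibly, a named list of the objects computed, with the
#'   written file paths in `files`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$output_dir)) {
    stop_oatmet("config$output_dir is required", "oatmet_config_error")
  }
  seed <- config$seed %||% 1L
  assert_scalar_number(seed, "seed", lower = 0)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  written <- character(0)
  emit <- function(df, file) {
    p <- file.path(config$output_dir, file)
    readr::write_csv(df, p, na = "")
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      unlink(written)
      stop_oatmet(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)),
                  "oatmet_pipeline_error")
    })
  }

  out <- if (is.null(config$synthetic)) {
    run_pipeline_bundled(config, emit, stage)
  } else {
    run_pipeline_synthetic(config, seed, emit, stage)
  }

  manifest <- list(
    package = "oatmet",
    package_version = as.character(utils::packageVersion("oatmet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = rlang::hash(config[sort(names(config))]),
    files = basename(written)
  )
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  out$files <- c(written, mp)
  invisible(out)
}

run_pipeline_bundled <- function(config, emit, stage) {
  trial <- stage("load bundled tables", oat_trial())

  stage("environment means", {
    emit(trial$env_means, "environment_means.csv")
    trait_cols <- setdiff(names(trial$env_means), "environment")
    ranges <- do.call(rbind, lapply(trait_cols, function(tr) {
      cbind(trait = tr,
            summarize_ranges(trial$env_means[[tr]],
                             labels = trial$env_means$environment))
    }))
    emit(tibble::as_tibble(ranges), "trait_ranges.csv")
  })

  stage("variety stability", {
    emit(trial$variety_stability, "variety_stability.csv")
    b_means <- stats::aggregate(sensitivity ~ trait,
                                data = trial$variety_stability, FUN = mean)
    names(b_means)[2] <- "mean_sensitivity"
    emit(tibble::as_tibble(b_means), "sensitivity_consistency.csv")
  })

  corr <- stage("trait-weather correlations", {
    exclude <- if (isTRUE(config$exclude_spring_sown %||% TRUE)) {
      trial$environments$environment[trial$environments$spring_sown]
    }
    covs <- trial$environments[, c("environment", "rain_dec_apr",
                                   "rain_jun_jul", "temp_mar", "temp_jul")]
    grid <- correlation_table(trial$env_means, covs, exclude = exclude)
    cmp <- merge(grid, trial$published_correlations,
                 by = c("trait", "covariate"),
                 suffixes = c("_recomputed", "_published"), all.x = TRUE)
    names(cmp)[names(cmp) == "r"] <- "r_published"
    emit(grid, "correlation_grid.csv")
    emit(tibble::as_tibble(cmp), "correlation_comparison.csv")
    grid
  })

  bp <- stage("biplot", {
    m <- as.matrix(trial$env_means[, setdiff(names(trial$env_means),
                                             "environment")])
    rownames(m) <- trial$env_means$environment
    bp <- suppressMessages(trait_biplot(m))
    emit(tibble::as_tibble(bp$scores, rownames = "environment"),
         "biplot_scores.csv")
    emit(tibble::as_tibble(bp$loadings, rownames = "trait"),
         "biplot_loadings.csv")
    bp
  })

  list(trial = trial, correlations = corr, biplot = bp)
}

run_pipeline_synthetic <- function(config, seed, emit, stage) {
  n_traits <- config$n_traits %||% 4L

  sims <- stage("simulate", {
    base <- do.call(synthetic_truth,
                    c(list(seed = seed), config$synthetic))
    # extra traits share the base environmental index (rescaled), which is
    # what makes the simulated traits correlated across environments
    scales <- rep_len(c(1, 0.8, -0.6, 0.4, -0.3, 0.7), n_traits)
    lapply(seq_len(n_traits), function(t) {
      args <- c(list(seed = seed + 10L * t,
                     env_index = unname(base$env_index) * scales[t],
                     trait = if (t == 1L) base$trait
                             else paste0("trait_", t)),
                config$synthetic[setdiff(names(config$synthetic),
                                         c("env_index", "trait"))])
      simulate_met(do.call(synthetic_truth, args))
    })
  })

  fits <- stage("joint regression", {
    lapply(sims, function(s) {
      fit <- fit_joint_regression(cell_means(s$met, s$truth$trait))
      list(fit = fit, truth = s$truth)
    })
  })

  stage("recovery scores", {
    recovery <- do.call(rbind, lapply(fits, function(f) {
      tibble::tibble(
        trait = f$fit$trait,
        rmse_sensitivity = sqrt(mean((f$fit$sensitivity -
                                        f$truth$sensitivities)^2)),
        rmse_variety_mean = sqrt(mean((f$fit$variety_means -
                                         (f$truth$mu +
                                            f$truth$variety_effects))^2)),
        rmse_env_index = sqrt(mean((f$fit$env_index -
                                      f$truth$env_index)^2)),
        heterogeneity_p = slope_heterogeneity_test(f$fit)$p_value
      )
    }))
    emit(recovery, "recovery_scores.csv")
    stab <- do.call(rbind, lapply(fits, function(f) {
      cbind(trait = f$fit$trait, stability_table(f$fit))
    }))
    emit(tibble::as_tibble(stab), "stability_tables.csv")
  })

  corr <- stage("weather correlations", {
    window <- weather_window("rain_jun_jul", "rain", 6, 7)
    wx <- simulate_weather(fits[[1L]]$truth, window)
    covs <- weather_covariates(wx$weather, wx$env_meta, list(window))
    env_tab <- tibble::tibble(environment = names(fits[[1L]]$fit$env_index))
    for (f in fits) {
      env_tab[[f$fit$trait]] <-
        unname(environment_means(as_cell_means(f$fit$fitted +
                                                 f$fit$residuals)))
    }
    grid <- correlation_table(env_tab, covs)
    emit(grid, "correlation_grid.csv")
    grid
  })

  bp <- stage("biplot", {
    cells <- lapply(sims, function(s) cell_means(s$met, s$truth$trait))
    m <- do.call(cbind, lapply(cells, function(cc) as.vector(cc$values)))
    colnames(m) <- vapply(cells, `[[`, character(1), "trait")
    grp <- rep(cells[[1L]]$varieties, times = length(cells[[1L]]$environments))
    rownames(m) <- paste(grp,
                         rep(cells[[1L]]$environments,
                             each = length(cells[[1L]]$varieties)),
                         sep = ":")
    bp <- suppressMessages(trait_biplot(m, groups = grp))
    emit(tibble::as_tibble(bp$scores, rownames = "row"), "biplot_scores.csv")
    emit(tibble::as_tibble(bp$loadings, rownames = "trait"),
         "biplot_loadings.csv")
    hulls <- tibble::tibble(
      variety = names(bp$hulls),
      area = vapply(bp$hulls, `[[`, numeric(1), "area"),
      n_vertices = vapply(bp$hulls, function(h) nrow(h$vertices),
                          integer(1))
    )
    emit(hulls, "hull_areas.csv")
    bp
  })

  list(sims = sims, fits = fits, correlations = corr, biplot = bp)
}
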