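#' Modified joint regression (bilinear stability model)
#'
#' Fits the Finlay-Wilkinson-type stability model
#' \deqn{y_{ij} = V_i + b_i E_j + \epsilon_{ij}}
#' to variety-by-environment cell means, where \eqn{V_i} is the variety
#' mean, \eqn{b_i} the sensitivity of variety \eqn{i} to the environment,
#' and \eqn{E_j} a latent environmental index. "Modified" means the indices
#' \eqn{E_j} are estimated jointly with the slopes by alternating least
#' squares rather than being fixed at the observed environment means, which
#' removes the regression-on-own-mean bias of classical joint regression.
#'
#' The alternating scheme is: (a) initialise \eqn{E_j} as centred observed
#' environment means and \eqn{b_i = 1}; (b) given \eqn{E}, per-variety least
#' squares of the cell means on \eqn{E} gives \eqn{V_i, b_i}; (c) given
#' \eqn{V, b}, update
#' \eqn{E_j = \sum_i b_i (y_{ij} - V_i) / \sum_i b_i^2} over observed
#' cells; (d) re-identify by absorbing the mean of \eqn{E} into \eqn{V} and
#' rescaling so that \eqn{\mathrm{mean}(b) = 1}; iterate until the relative
#' change in the residual sum of squares falls below `tol`. Each half-step
#' is an exact least-squares solve, so the RSS is non-increasing. For
#' complete data the solution coincides with the rank-1 truncated SVD of the
#' row-centred matrix (rescaled to mean-1 slopes).
#'
#' A slope \eqn{b_i > 1} marks a variety with above-average sensitivity to
#' the environment; \eqn{b_i < 1} marks a stable variety.
#'
#' Standard errors are conditional on the final \eqn{E} (classical
#' joint-regression reporting, from the pooled residual mean square); they
#' ignore the uncertainty in the estimated indices. The error degrees of
#' freedom are `n_obs - (2g + e - 2)`.
#'
#' @param cells A [cell_means()] object, or a numeric matrix of cell means
#'   (varieties x environments, `NA` for unobserved cells).
#' @param tol Convergence tolerance (default 1e-10): iteration stops once
#'   the relative RSS change drops below `tol` *and* the largest change in
#'   any fitted cell is below `tol / 100` times the data scale. The second
#'   condition matters because the RSS flattens quadratically near the
#'   optimum, so an RSS-only rule can stop while the parameters are still
#'   several orders of magnitude from the least-squares solution.
#' @param max_iter Maximum number of alternating iterations (default 2000;
#'   the alternating scheme converges linearly at a rate set by the gap
#'   between the two leading singular values, so near-degenerate spectra
#'   need a generous cap). Non-convergence is flagged on the result (with a
#'   warning), not an error.
#' @return An object of class `joint_regression` with components
#'   `variety_means` (\eqn{V_i}), `sensitivity` (\eqn{b_i}), `env_index`
#'   (\eqn{E_j}), `se_variety`, `se_sensitivity`, `fitted`, `residuals`,
#'   `rss`, `rss_trace`, `df_error`, `sigma2` (pooled residual mean
#'   square), `n_obs`, `iterations`, `converged`, `exact_fit`.
#' @examples
#' y <- matrix(c(9, 17, 11, 23), nrow = 2) # V=(10,20), b=(0.5,1.5), E=(-2,2)
#' fit <- fit_joint_regression(cbind(y, c(10, 20), c(12, 26)))
#' fit$sensitivity
#' @export
fit_joint_regression <- function(cells, tol = 1e-10, max_iter = 2000L) {
  if (inherits(cells, "cell_means")) {
    y <- cells$values
    trait <- cells$trait
    unit <- cells$unit
  } else {
    y <- as.matrix(cells)
    trait <- "trait"
    unit <- "unspecified"
  }
  g <- nrow(y)
  e <- ncol(y)
  if (g < 2L) stop_oatmet("need at least 2 varieties", "oatmet_input_error")
  if (e < 3L) stop_oatmet("need at least 3 environments", "oatmet_input_error")
  obs <- !is.na(y)
  if (any(rowSums(obs) < 3L)) {
    stop_oatmet("every variety must be observed in at least 3 environments",
                "oatmet_input_error")
  }
  varieties <- rownames(y) %||% paste0("V", seq_len(g))
  environments <- colnames(y) %||% paste0("E", seq_len(e))
  n_obs <- sum(obs)

  # (a) initialise: centred observed environment means, unit slopes
  E <- colMeans(y, na.rm = TRUE)
  E <- E - mean(E)
  if (max(abs(E)) < 1e-12) {
    stop_oatmet(paste0("no spread in environment means: environmental index",
                       " degenerate, slopes undefined; fit an additive model",
                       " instead"),
                "oatmet_degenerate_error")
  }
  b <- rep(1, g)
  V <- numeric(g)

  rss <- Inf
  rss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  scale2 <- mean(y[obs]^2) + 1
  yscale <- 1 + max(abs(y[obs]))
  fitted_prev <- NULL

  while (iter < max_iter) {
    iter <- iter + 1L

    # (b) per-variety least squares of cell means on E
    for (i in seq_len(g)) {
      oi <- obs[i, ]
      xi <- E[oi]
      yi <- y[i, oi]
      xc <- xi - mean(xi)
      den <- sum(xc^2)
      b[i] <- if (den > 0) sum(xc * yi) / den else 1
      V[i] <- mean(yi) - b[i] * mean(xi)
    }

    # (c) least-squares update of the environmental indices
    for (j in seq_len(e)) {
      oj <- obs[, j]
      E[j] <- sum(b[oj] * (y[oj, j] - V[oj])) / sum(b[oj]^2)
    }

    # (d) re-identification: sum(E) = 0, mean(b) = 1; leaves fit unchanged
    m <- mean(E)
    V <- V + b * m
    E <- E - m
    cb <- mean(b)
    if (abs(cb) < 1e-12) {
      stop_oatmet("mean slope collapsed to zero; model degenerate",
                  "oatmet_degenerate_error")
    }
    b <- b / cb
    E <- E * cb

    fitted <- V + outer(b, E)
    res <- y - fitted
    rss_new <- sum(res[obs]^2)
    rss_trace <- c(rss_trace, rss_new)
    delta_fit <- if (is.null(fitted_prev)) Inf else
      max(abs(fitted - fitted_prev))
    fitted_prev <- fitted
    if (is.finite(rss) &&
        (rss - rss_new) <= tol * max(rss, scale2 * 1e-8) &&
        delta_fit <= 0.01 * tol * yscale) {
      rss <- rss_new
      converged <- TRUE
      break
    }
    rss <- rss_new
  }
  if (!converged) {
    rlang::warn(sprintf("joint regression did not converge in %d iterations",
                        max_iter))
  }

  df_error <- n_obs - (2L * g + e - 2L)
  sigma2 <- if (df_error > 0) rss / df_error else NA_real_
  exact_fit <- is.finite(sigma2) && sigma2 <= 1e-10 * scale2

  # conditional-on-E standard errors from the pooled residual mean square
  se_b <- se_V <- rep(NA_real_, g)
  if (is.finite(sigma2)) {
    for (i in seq_len(g)) {
      oi <- obs[i, ]
      xi <- E[oi]
      sxx <- sum((xi - mean(xi))^2)
      se_b[i] <- sqrt(sigma2 / sxx)
      se_V[i] <- sqrt(sigma2 * (1 / sum(oi) + mean(xi)^2 / sxx))
    }
  }

  dimnames(fitted) <- dimnames(res) <- list(varieties, environments)
  structure(list(
    trait = trait, unit = unit,
    variety_means = stats::setNames(V, varieties),
    sensitivity = stats::setNames(b, varieties),
    env_index = stats::setNames(E, environments),
    se_variety = stats::setNames(se_V, varieties),
    se_sensitivity = stats::setNames(se_b, varieties),
    fitted = fitted, residuals = res, observed = obs,
    rss = rss, rss_trace = rss_trace,
    df_error = df_error, sigma2 = sigma2, n_obs = n_obs,
    iterations = iter, converged = converged, exact_fit = exact_fit
  ), class = "joint_regression")
}

#' @export
print.joint_regression <- function(x, digits = 4, ...) {
  cat(sprintf("Modified joint regression: trait '%s' (%s)\n", x$trait, x$unit))
  cat(sprintf("  %d varieties x %d environments, %d observed cells\n",
              length(x$variety_means), length(x$env_index), x$n_obs))
  cat(sprintf("  RSS %.6g on %d error df (%d iterations%s%s)\n",
              x$rss, x$df_error, x$iterations,
              if (x$converged) ", converged" else ", NOT converged",
              if (x$exact_fit) ", exact fit" else ""))
  print(stability_table(x), n = Inf)
  invisible(x)
}

#' Variety-level summary of a joint-regression fit
#'
#' One row per variety: mean, sensitivity slope, their conditional standard
#' errors, and the stability classification.
#'
#' @param fit A [fit_joint_regression()] result.
#' @param alpha Significance level passed to [classify_stability()].
#' @return A tibble with columns `variety`, `mean`, `se_mean`,
#'   `sensitivity`, `se_sensitivity`, `stability`.
#' @export
stability_table <- function(fit, alpha = 0.05) {
  tibble::tibble(
    variety = names(fit$variety_means),
    mean = unname(fit$variety_means),
    se_mean = unname(fit$se_variety),
    sensitivity = unname(fit$sensitivity),
    se_sensitivity = unname(fit$se_sensitivity),
    stability = unname(classify_stability(fit, alpha = alpha))
  )
}

#' Test for heterogeneity of sensitivity slopes
#'
#' F test of the null hypothesis that all varieties respond identically to
#' the environment (all \eqn{b_i = 1}), against the pooled residual mean
#' square:
#' \deqn{F = \frac{\sum_i (b_i - 1)^2 \sum_{j \in obs(i)} E_j^2 / (g-1)}{s^2}}
#' on \eqn{(g - 1, \mathrm{df}_{error})} degrees of freedom. A significant
#' result is the formal evidence of genotype-by-environment interaction of
#' the regression type.
#'
#' @param fit A converged [fit_joint_regression()] result with positive
#'   error df.
#' @return An object of class `stability_test`: list with `label`,
#'   `statistic`, `df1`, `df2`, `p_value`, `exact_fit`.
#' @export
slope_heterogeneity_test <- function(fit) {
  check_testable(fit)
  g <- length(fit$sensitivity)
  ss <- sum(vapply(seq_len(g), function(i) {
    (fit$sensitivity[i] - 1)^2 * sum(fit$env_index[fit$observed[i, ]]^2)
  }, numeric(1)))
  make_stability_test("slope heterogeneity (all b_i equal)", ss, g - 1L, fit)
}

#' Test for differences between variety means
#'
#' F test of equality of the \eqn{V_i} against the pooled residual mean
#' square, with between-variety sum of squares weighted by the number of
#' observed cells per variety (reduces to `e * sum((V - mean(V))^2)` for
#' complete data).
#'
#' @inheritParams slope_heterogeneity_test
#' @return An object of class `stability_test`.
#' @export
variety_effect_test <- function(fit) {
  check_testable(fit)
  n_i <- rowSums(fit$observed)
  V <- fit$variety_means
  vbar <- sum(n_i * V) / sum(n_i)
  ss <- sum(n_i * (V - vbar)^2)
  make_stability_test("variety mean differences", ss,
                      length(V) - 1L, fit)
}

check_testable <- function(fit) {
  if (!inherits(fit, "joint_regression")) {
    stop_oatmet("`fit` must be a joint_regression object",
                "oatmet_input_error")
  }
  if (!isTRUE(fit$converged)) {
    stop_oatmet("fit did not converge; tests unavailable",
                "oatmet_input_error")
  }
  if (fit$df_error < 1L) {
    stop_oatmet("no error degrees of freedom", "oatmet_input_error")
  }
  invisible(fit)
}

make_stability_test <- function(label, ss, df1, fit) {
  if (fit$exact_fit) {
    # zero residual mean square: the bilinear part fits exactly
    stat <- if (ss > 1e-12) Inf else 0
    p <- if (ss > 1e-12) 0 else 1
    out <- list(label = label, statistic = stat, df1 = df1,
                df2 = fit$df_error, p_value = p, exact_fit = TRUE)
  } else {
    stat <- (ss / df1) / fit$sigma2
    out <- list(label = label, statistic = stat, df1 = df1,
                df2 = fit$df_error,
                p_value = stats::pf(stat, df1, fit$df_error,
                                    lower.tail = FALSE),
                exact_fit = FALSE)
  }
  structure(out, class = "stability_test")
}

#' @export
print.stability_test <- function(x, ...) {
  cat(sprintf("F test: %s\n  F(%d, %d) = %.4g, p = %.4g%s\n",
              x$label, x$df1, x$df2, x$statistic, x$p_value,
              if (x$exact_fit) " (exact fit)" else ""))
  invisible(x)
}

#' Classify varieties as environmentally sensitive, stable or average
#'
#' A variety whose sensitivity slope is significantly above 1 (two-sided t
#' test at level `alpha`, on the fit's error df) is labelled `"sensitive"`;
#' significantly below 1, `"stable"`; otherwise `"average"`.
#'
#' @inheritParams slope_heterogeneity_test
#' @param alpha Two-sided significance level (default 0.05).
#' @return Named character vector of labels, one per variety.
#' @export
classify_stability <- function(fit, alpha = 0.05) {
  b <- fit$sensitivity
  se <- fit$se_sensitivity
  labels <- rep("average", length(b))
  signif <- if (isTRUE(fit$exact_fit)) {
    abs(b - 1) > 1e-12
  } else if (all(is.finite(se)) && fit$df_error >= 1L) {
    p <- 2 * stats::pt(-abs((b - 1) / se), df = fit$df_error)
    p < alpha
  } else {
    rep(FALSE, length(b))
  }
  labels[signif & b > 1] <- "sensitive"
  labels[signif & b < 1] <- "stable"
  stats::setNames(labels, names(b))
}
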