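#' Principal-component trait biplot
#'
#' Correlation-matrix PCA of a rows-by-traits matrix of means (rows are
#' typically variety-environment combinations): columns are centred and
#' scaled to unit variance, decomposed by SVD, and displayed through the
#' first two components. With scaling exponent `alpha`,
#' `scores = U d^alpha` and `loadings = V d^(1 - alpha)`, so
#' `alpha = 0.5` gives the symmetric biplot, `alpha = 1` a row-metric
#' (principal-coordinates) biplot and `alpha = 0` a column-metric
#' (covariance) biplot. Variance fractions come from the squared singular
#' values. The angle between two trait loading vectors reflects their
#' correlation: acute for positive, obtuse for negative.
#'
#' Missing entries are mean-imputed per trait (count reported via a
#' message) unless `drop_incomplete = TRUE`, in which case incomplete rows
#' are dropped. Constant trait columns are dropped with a warning. The sign
#' of each axis is fixed by making the largest-magnitude loading positive,
#' so output is deterministic across linear-algebra back-ends.
#'
#' @param x Numeric matrix or data frame, rows = observations (e.g.
#'   variety-environment means), columns = traits; >= 3 rows and >= 2
#'   non-constant traits required.
#' @param groups Optional vector (length `nrow(x)`) of group labels, e.g.
#'   varieties; per-group convex hulls of the scores are then computed.
#' @param scaling `"symmetric"` (alpha = 0.5, default), `"row"`
#'   (alpha = 1) or `"column"` (alpha = 0); alternatively pass a numeric
#'   `alpha` in \[0, 1\].
#' @param alpha Numeric scaling exponent overriding `scaling` if given.
#' @param drop_incomplete Drop rows with missing values instead of
#'   mean-imputing (default `FALSE`).
#' @return An object of class `trait_biplot`: list with `scores`
#'   (rows x 2), `loadings` (traits x 2), `var_fractions` (all
#'   components), `singular_values`, `alpha`, `n_imputed`,
#'   `dropped_traits`, `groups`, `hulls` (see [convex_hulls()]).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' bp <- trait_biplot(cbind(a = x[, 1], b = x[, 1] + 0.1 * x[, 2]))
#' bp$var_fractions
#' @export
trait_biplot <- function(x, groups = NULL,
                         scaling = c("symmetric", "row", "column"),
                         alpha = NULL, drop_incomplete = FALSE) {
  if (is.null(alpha)) {
    scaling <- match.arg(scaling)
    alpha <- c(symmetric = 0.5, row = 1, column = 0)[[scaling]]
  }
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("trait", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))

  n_imputed <- 0L
  if (anyNA(x)) {
    if (drop_incomplete) {
      keep <- stats::complete.cases(x)
      x <- x[keep, , drop = FALSE]
      if (!is.null(groups)) groups <- groups[keep]
    } else {
      n_imputed <- sum(is.na(x))
      for (k in seq_len(ncol(x))) {
        miss <- is.na(x[, k])
        x[miss, k] <- mean(x[, k], na.rm = TRUE)
      }
      rlang::inform(sprintf("mean-imputed %d missing trait value(s)",
                            n_imputed))
    }
  }
  if (nrow(x) < 3L) {
    stop_oatmet("need at least 3 rows", "oatmet_input_error")
  }

  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds < 1e-12]
  if (length(dropped)) {
    rlang::warn(paste0("dropping constant trait column(s): ",
                       paste(dropped, collapse = ", ")))
    x <- x[, sds >= 1e-12, drop = FALSE]
  }
  if (ncol(x) < 2L) {
    stop_oatmet("need at least 2 non-constant traits", "oatmet_input_error")
  }

  z <- scale(x, center = TRUE, scale = TRUE)
  sv <- svd(z)
  var_fractions <- sv$d^2 / sum(sv$d^2)
  d2 <- sv$d[1:2]

  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(d2^alpha, 2)
  loadings <- sv$v[, 1:2, drop = FALSE] %*% diag(d2^(1 - alpha), 2)
  # deterministic sign: largest-magnitude loading on each axis positive
  for (a in 1:2) {
    k <- which.max(abs(loadings[, a]))
    if (loadings[k, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(rownames(z), c("PC1", "PC2"))
  dimnames(loadings) <- list(colnames(z), c("PC1", "PC2"))

  hulls <- if (!is.null(groups)) convex_hulls(scores, groups) else NULL
  structure(list(scores = scores, loadings = loadings,
                 var_fractions = var_fractions, singular_values = sv$d,
                 alpha = alpha, n_imputed = n_imputed,
                 dropped_traits = dropped, groups = groups, hulls = hulls),
            class = "trait_biplot")
}

#' @export
print.trait_biplot <- function(x, ...) {
  cat(sprintf("Trait biplot (alpha = %g): %d rows, %d traits\n",
              x$alpha, nrow(x$scores), nrow(x$loadings)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_fractions[1], 100 * x$var_fractions[2]))
  if (!is.null(x$hulls)) {
    areas <- vapply(x$hulls, `[[`, numeric(1), "area")
    cat("  hull areas:",
        paste(sprintf("%s %.3g", names(areas), areas), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
plot.trait_biplot <- function(x, expand = 1, hull_col = NULL, ...) {
  s <- x$scores
  l <- x$loadings
  sc <- expand * max(abs(s)) / max(abs(l))
  lim <- range(s, l * sc)
  grp <- x$groups %||% rep(1, nrow(s))
  cols <- as.integer(factor(grp))
  plot(s, col = cols, pch = 16, xlim = lim, ylim = lim,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$var_fractions[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$var_fractions[2]), ...)
  if (!is.null(x$hulls)) {
    for (k in seq_along(x$hulls)) {
      v <- x$hulls[[k]]$vertices
      if (nrow(v) >= 2) {
        graphics::polygon(v, border = hull_col %||% k, lty = 2)
      }
    }
  }
  graphics::arrows(0, 0, l[, 1] * sc, l[, 2] * sc, length = 0.08,
                   col = "grey30")
  graphics::text(l * sc * 1.05, labels = rownames(l), col = "grey30")
  invisible(x)
}

#' Per-group convex hulls of 2-D scores
#'
#' Minimal convex polygon per group, vertices in counter-clockwise order,
#' with the enclosed area (shoelace formula). Groups of 1 or 2 points
#' degrade to a point or segment with zero area. In a biplot of
#' variety-environment scores, a variety's hull area summarises how much
#' its trait profile moves across environments.
#'
#' @param points Two-column numeric matrix of coordinates.
#' @param groups Vector of group labels, length `nrow(points)`.
#' @return Named list (one element per group) of lists with `indices`
#'   (row indices of the hull vertices within the group's points, in
#'   counter-clockwise order), `vertices` (coordinate matrix) and `area`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' convex_hulls(sq, rep("a", 4))$a$area # 1
#' @export
convex_hulls <- function(points, groups) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) {
    stop_oatmet("`points` must have exactly 2 columns", "oatmet_input_error")
  }
  if (length(groups) != nrow(points)) {
    stop_oatmet("`groups` must match the number of points",
                "oatmet_input_error")
  }
  out <- lapply(split(seq_len(nrow(points)), groups), function(idx) {
    p <- points[idx, , drop = FALSE]
    if (nrow(p) == 1L) {
      hull <- 1L
    } else {
      hull <- grDevices::chull(p[, 1], p[, 2])
      # chull returns clockwise order; normalise to counter-clockwise
      if (shoelace(p[hull, , drop = FALSE]) < 0) hull <- rev(hull)
    }
    v <- p[hull, , drop = FALSE]
    list(indices = hull, vertices = v, area = abs(shoelace(v)))
  })
  out
}

# signed polygon area; positive for counter-clockwise vertex order
shoelace <- function(v) {
  if (nrow(v) < 3L) return(0)
  x <- v[, 1]
  y <- v[, 2]
  nxt <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[nxt] - x[nxt] * y) / 2
}
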