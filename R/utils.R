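#' @importFrom rlang %||% abort warn inform
#' @importFrom stats coef complete.cases cor.test pf pt quantile rnorm runif sd var
NULL

# internal assertion helpers ---------------------------------------------

stop_oatmet <- function(msg, class) {
  rlang::abort(msg, class = c(class, "oatmet_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_oatmet(sprintf("`%s` must be a single finite number", name),
                "oatmet_domain_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper) {
    stop_oatmet(sprintf("`%s` = %s is outside its valid range", name,
                        format(x)), "oatmet_domain_error")
  }
  invisible(x)
}

# significance stars used throughout the correlation tables:
# p < 0.05 "*", p < 0.01 "**", p < 0.001 "***"
star_code <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

# case/whitespace normalisation for trait labels
normalize_trait <- function(x) tolower(trimws(as.character(x)))
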