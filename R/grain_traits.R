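#' Groat content from a dehulling run
#'
#' Groat content (kernel content) is the mass fraction of groat recovered
#' from the grain that was actually dehulled:
#' `100 * groat / (initial - residual)`, where `residual` is the whole
#' (un-dehulled) grain remaining after the huller pass.
#'
#' @param initial Initial grain mass (g), > 0.
#' @param residual Residual whole-grain mass (g), >= 0 and < `initial`.
#' @param groat Recovered groat mass (g), >= 0.
#' @return Groat content in percent, in \[0, 100\]. Vectorised.
#' @examples
#' groat_content(25, 2, 17.02) # 74
#' @export
groat_content <- function(initial, residual, groat) {
  check_masses(initial, residual, groat)
  if (any(residual >= initial)) {
    stop_oatmet("residual mass >= initial mass: nothing was dehulled",
                "oatmet_domain_error")
  }
  if (any(residual + groat > initial * (1 + 1e-8))) {
    rlang::warn("residual + groat mass exceeds initial mass")
  }
  100 * groat / (initial - residual)
}

#' Hullability from a dehulling run
#'
#' The percentage of grains successfully dehulled in one standard huller
#' pass: `100 - 100 * residual / initial`.
#'
#' @inheritParams groat_content
#' @return Hullability in percent, in \[0, 100\]. Vectorised.
#' @examples
#' hullability(25, 0.365) # 98.54
#' @export
hullability <- function(initial, residual) {
  check_masses(initial, residual)
  100 - 100 * residual / initial
}

check_masses <- function(initial, ...) {
  extras <- list(...)
  if (!all(is.finite(initial)) || any(initial <= 0)) {
    stop_oatmet("initial mass must be finite and > 0", "oatmet_domain_error")
  }
  for (m in extras) {
    if (!all(is.finite(m)) || any(m < 0)) {
      stop_oatmet("masses must be finite and non-negative",
                  "oatmet_domain_error")
    }
  }
  invisible(NULL)
}

#' Grain roundness
#'
#' Ratio of grain width to grain length: 0 is very elongated, 1 perfectly
#' round. Width greater than length usually indicates swapped dimensions and
#' triggers a warning, not an error.
#'
#' @param width Grain width (mm), > 0.
#' @param length Grain length (mm), > 0.
#' @return Width/length ratio. Vectorised.
#' @examples
#' roundness(3.34, 10.69) # 0.312 at 3 d.p.
#' @export
roundness <- function(width, length) {
  if (!all(is.finite(length)) || any(length <= 0)) {
    stop_oatmet("grain length must be finite and > 0", "oatmet_domain_error")
  }
  if (!all(is.finite(width)) || any(width <= 0)) {
    stop_oatmet("grain width must be finite and > 0", "oatmet_domain_error")
  }
  if (any(width > length)) {
    rlang::warn("width > length: grain dimensions may be swapped")
  }
  width / length
}

#' Protein content from nitrogen content
#'
#' Converts groat nitrogen to protein using the oat-specific Jones factor
#' 5.36 (lower than the generic 6.25 because oat protein is rich in
#' glutamine-poor globulins).
#'
#' @param n Nitrogen content in percent, >= 0.
#' @return Protein content in percent. Vectorised.
#' @examples
#' protein_from_nitrogen(2) # 10.72
#' @export
protein_from_nitrogen <- function(n) {
  if (!all(is.finite(n)) || any(n < 0)) {
    stop_oatmet("nitrogen content must be finite and >= 0",
                "oatmet_domain_error")
  }
  n * 5.36
}

#' Grain number per unit field area
#'
#' Derived from grain yield and thousand grain weight (TGW):
#' `yield * 100 / tgw`, in thousand grains per square metre
#' (1 t/ha = 100 g/m2, so yield in g/m2 divided by TGW in g per 1000 grains
#' gives thousands of grains per m2).
#'
#' @param yield Grain yield (t/ha).
#' @param tgw Thousand grain weight (g per 1000 grains), > 0.
#' @return Grain number in thousand grains per m2. Vectorised.
#' @examples
#' grain_number(6.03, 37.65) # 16.02
#' @export
grain_number <- function(yield, tgw) {
  if (!all(is.finite(tgw)) || any(tgw <= 0)) {
    stop_oatmet("TGW must be finite and > 0", "oatmet_domain_error")
  }
  yield * 100 / tgw
}

#' Adjust grain yield to a standard moisture content
#'
#' Conserves dry matter: `fresh_yield * (100 - measured_moisture) /
#' (100 - target)`. The 15% default is the standard reporting basis for
#' combinable crops in the UK.
#'
#' @param fresh_yield Harvested yield (t/ha) at `measured_moisture`.
#' @param measured_moisture Measured grain moisture, percent in \[0, 100).
#' @param target Target moisture, percent in \[0, 100); default 15.
#' @return Yield (t/ha) at the target moisture content. Vectorised.
#' @examples
#' adjust_yield_moisture(8.5, 20) # 8.0
#' @export
adjust_yield_moisture <- function(fresh_yield, measured_moisture,
                                  target = 15) {
  if (!all(is.finite(measured_moisture)) || any(measured_moisture < 0) ||
      any(measured_moisture >= 100)) {
    stop_oatmet("measured moisture must be in [0, 100)", "oatmet_domain_error")
  }
  if (!all(is.finite(target)) || any(target < 0) || any(target >= 100)) {
    stop_oatmet("target moisture must be in [0, 100)", "oatmet_domain_error")
  }
  fresh_yield * (100 - measured_moisture) / (100 - target)
}
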