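#' Bundled winter oat multi-environment trial summary tables
#'
#' Summary tables from a published UK winter oat variety trial network:
#' four varieties (Balado, Gerald, Mascani, Tardis) grown in 22
#' environments (site x harvest-year combinations, harvests 2011-2014).
#' Plot-level raw data were not published; what is bundled are the printed
#' per-environment means (averaged over the four varieties), per-variety
#' means and joint-regression sensitivities, environment metadata with
#' seasonal weather covariates, and the published trait-weather
#' correlations for the covariates whose per-environment values were
#' themselves printed.
#'
#' @return A list of tibbles:
#' \describe{
#'   \item{environments}{22 rows: site, coordinates, sowing/harvest dates,
#'     seasonal covariates (`rain_dec_apr`, `rain_jun_jul` in mm;
#'     `temp_mar`, `temp_jul` in deg C) and the `spring_sown` flag
#'     (environment 8 only). December-April rainfall is unavailable for
#'     the spring-sown environment.}
#'   \item{env_means}{22 rows: per-environment means of yield (t/ha),
#'     grain number (1000/m2), groat content, hullability (%), hectoliter
#'     weight (kg/hL; unavailable in environments 15 and 18), TGW (g),
#'     grain width/length (mm), roundness, oil, protein and beta-glucan
#'     (%).}
#'   \item{variety_stability}{48 rows (12 traits x 4 varieties): published
#'     variety mean and joint-regression sensitivity `b_i`.}
#'   \item{published_correlations}{Published Pearson correlations between
#'     trait site-means and the four bundled covariates, with significance
#'     stars, for cross-checking recomputation.}
#' }
#' @examples
#' trial <- oat_trial()
#' range(trial$env_means$yield)
#' @export
oat_trial <- function() {
  path <- function(f) system.file("extdata", f, package = "oatmet",
                                  mustWork = TRUE)
  environments <- read_env_metadata(path("env_metadata.csv"))
  physical <- readr::read_csv(path("env_means_physical.csv"),
                              show_col_types = FALSE, progress = FALSE)
  composition <- readr::read_csv(path("env_means_composition.csv"),
                                 show_col_types = FALSE, progress = FALSE)
  env_means <- merge(physical, composition, by = "environment", sort = TRUE)
  env_means <- tibble::as_tibble(env_means[order(env_means$environment), ])
  env_means$environment <- as.character(env_means$environment)
  variety_stability <- readr::read_csv(path("variety_stability.csv"),
                                       show_col_types = FALSE,
                                       progress = FALSE)
  published_correlations <- readr::read_csv(
    path("published_correlations.csv"), show_col_types = FALSE,
    progress = FALSE, na = "NA")
  published_correlations$stars[is.na(published_correlations$stars)] <- ""
  list(environments = environments, env_means = env_means,
       variety_stability = variety_stability,
       published_correlations = published_correlations)
}
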