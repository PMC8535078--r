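#' Construct a multi-environment trial phenotype table
#'
#' A `met_table` holds replicate-level phenotype records from a
#' multi-environment trial (MET) in long format: one row per
#' (environment, variety, replicate, trait) combination. Values may be
#' missing; missingness is carried explicitly (`NA`), never as a sentinel
#' number, and all downstream means are available-case averages.
#'
#' @param records A data frame with columns `environment`, `variety`,
#'   `replicate`, `trait`, `value`. `replicate` must be a positive integer,
#'   `value` numeric (may be `NA`), and the (environment, variety,
#'   replicate, trait) key unique.
#' @param units Optional named character vector registering one unit per
#'   trait label (after case normalisation), e.g.
#'   `c(yield = "t/ha", tgw = "g")`. Unregistered traits get
#'   `"unspecified"`.
#' @return A tibble of class `met_table` with a `units` attribute.
#' @examples
#' met <- met_table(data.frame(
#'   environment = "E1", variety = c("A", "A", "B", "B"),
#'   replicate = c(1, 2, 1, 2), trait = "yield", value = c(5, 6, 7, 8)
#' ), units = c(yield = "t/ha"))
#' cell_means(met, "yield")
#' @export
met_table <- function(records, units = NULL) {
  needed <- c("environment", "variety", "replicate", "trait", "value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_oatmet(paste0("missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "oatmet_schema_error")
  }
  out <- tibble::as_tibble(records[needed])
  out$environment <- as.character(out$environment)
  out$variety <- as.character(out$variety)
  out$trait <- normalize_trait(out$trait)
  rep_num <- suppressWarnings(as.numeric(out$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num))) {
    stop_oatmet("`replicate` must contain positive integers",
                "oatmet_integrity_error")
  }
  out$replicate <- as.integer(rep_num)
  out$value <- as.numeric(out$value)
  if (any(is.infinite(out$value))) {
    stop_oatmet("non-missing trait values must be finite",
                "oatmet_integrity_error")
  }

  key <- paste(out$environment, out$variety, out$replicate, out$trait,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- out[which(dup)[1L], ]
    stop_oatmet(sprintf(
      "duplicate record key: environment '%s', variety '%s', replicate %d, trait '%s'",
      first$environment, first$variety, first$replicate, first$trait),
      "oatmet_integrity_error")
  }

  traits <- unique(out$trait)
  reg <- stats::setNames(rep("unspecified", length(traits)), traits)
  if (!is.null(units)) {
    names(units) <- normalize_trait(names(units))
    known <- intersect(names(units), traits)
    reg[known] <- units[known]
  }
  attr(out, "units") <- reg
  class(out) <- c("met_table", class(out))
  out
}

#' Units registered for each trait in a MET table
#' @param met A [met_table()].
#' @return Named character vector of units.
#' @export
trait_units <- function(met) attr(met, "units")

#' Read a long-format MET phenotype CSV
#'
#' Reads a UTF-8 CSV with a header row into a [met_table()]. Cells that are
#' empty or match one of the `na` strings are recorded as missing; any other
#' unparseable value cell is also recorded as missing, with a single warning
#' reporting how many such cells were seen.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the standard column names
#'   (`environment`, `variety`, `replicate`, `trait`, `value`) to the column
#'   names used in the file. Defaults to the identity mapping.
#' @param na Strings to treat as missing values (default: empty string,
#'   `"na"`, `"NA"`).
#' @inheritParams met_table
#' @return A [met_table()].
#' @export
read_met <- function(path, schema = NULL, na = c("", "na", "NA"),
                     units = NULL) {
  if (!file.exists(path)) {
    stop_oatmet(sprintf("file not found: %s", path), "oatmet_io_error")
  }
  standard <- c("environment", "variety", "replicate", "trait", "value")
  map <- stats::setNames(standard, standard)
  if (!is.null(schema)) map[names(schema)] <- unname(schema)

  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop_oatmet(paste0("missing mandatory column(s) in ", path, ": ",
                       paste(missing_cols, collapse = ", ")),
                "oatmet_schema_error")
  }
  df <- stats::setNames(raw[unname(map)], names(map))

  val_chr <- trimws(df$value)
  is_na <- val_chr %in% na
  val <- suppressWarnings(as.numeric(val_chr))
  unparseable <- !is_na & is.na(val)
  if (any(unparseable)) {
    rlang::warn(sprintf("%d value cell(s) could not be parsed; recorded as missing",
                        sum(unparseable)))
  }
  df$value <- ifelse(is_na | unparseable, NA_real_, val)
  met_table(df, units = units)
}

#' Read environment (site x season) metadata
#'
#' @param path CSV with columns `environment`, `site`, `latitude`,
#'   `longitude`, `sowing_date`, `harvest_date` (ISO-8601), and optionally
#'   `spring_sown` (logical) plus any per-environment covariates.
#' @return A tibble, validated: harvest strictly after sowing, latitude in
#'   \[-90, 90\], longitude in \[-180, 180\].
#' @export
read_env_metadata <- function(path) {
  if (!file.exists(path)) {
    stop_oatmet(sprintf("file not found: %s", path), "oatmet_io_error")
  }
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("environment", "site", "latitude", "longitude",
              "sowing_date", "harvest_date")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    stop_oatmet(paste0("missing metadata column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "oatmet_schema_error")
  }
  meta$environment <- as.character(meta$environment)
  meta$sowing_date <- as.Date(meta$sowing_date)
  meta$harvest_date <- as.Date(meta$harvest_date)
  if (any(meta$harvest_date <= meta$sowing_date, na.rm = TRUE)) {
    stop_oatmet("harvest date must be strictly after sowing date",
                "oatmet_integrity_error")
  }
  if (any(abs(meta$latitude) > 90, na.rm = TRUE) ||
      any(abs(meta$longitude) > 180, na.rm = TRUE)) {
    stop_oatmet("latitude/longitude outside valid range",
                "oatmet_integrity_error")
  }
  if (!"spring_sown" %in% names(meta)) meta$spring_sown <- FALSE
  meta
}

#' Variety-by-environment cell means for one trait
#'
#' Averages replicate values into a g-variety x e-environment matrix of cell
#' means with an explicit observed mask and per-cell replicate counts. Cells
#' with no non-missing replicate are masked (`NA`).
#'
#' @param met A [met_table()].
#' @param trait Trait label (case-insensitive).
#' @return An object of class `cell_means`: a list with elements `trait`,
#'   `unit`, `values` (g x e matrix, `NA` where unobserved), `n` (replicate
#'   counts), `varieties`, `environments`.
#' @export
cell_means <- function(met, trait) {
  trait <- normalize_trait(trait)
  sub <- met[met$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_oatmet(sprintf("trait '%s' not found", trait),
                "oatmet_not_found_error")
  }
  varieties <- sort(unique(sub$variety))
  environments <- sort(unique(sub$environment))
  if (length(varieties) < 2L || length(environments) < 3L) {
    stop_oatmet(sprintf(
      "trait '%s' needs >= 2 varieties in >= 3 environments (have %d x %d)",
      trait, length(varieties), length(environments)),
      "oatmet_input_error")
  }
  fi <- factor(sub$variety, levels = varieties)
  fj <- factor(sub$environment, levels = environments)
  values <- tapply(sub$value, list(fi, fj), mean, na.rm = TRUE)
  values[is.nan(values)] <- NA_real_
  n <- tapply(!is.na(sub$value), list(fi, fj), sum)
  n[is.na(n)] <- 0L
  out <- structure(list(trait = trait,
                        unit = unname(trait_units(met)[trait]),
                        values = values, n = n,
                        varieties = varieties,
                        environments = environments),
                   class = "cell_means")
  validate_cell_means(out)
  out
}

#' Wrap an existing means matrix as a `cell_means` object
#'
#' Used when variety-by-environment trait means are available directly
#' (e.g. published summary tables) rather than from replicate records.
#'
#' @param values Numeric matrix, varieties in rows, environments in columns;
#'   `NA` marks unobserved cells.
#' @param trait,unit Trait label and unit.
#' @param n Optional replicate-count matrix (defaults to 1 per observed cell).
#' @return A `cell_means` object.
#' @export
as_cell_means <- function(values, trait = "trait", unit = "unspecified",
                          n = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("V", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("E", seq_len(ncol(values)))
  }
  if (is.null(n)) n <- (!is.na(values)) * 1L
  out <- structure(list(trait = normalize_trait(trait), unit = unit,
                        values = values, n = n,
                        varieties = rownames(values),
                        environments = colnames(values)),
                   class = "cell_means")
  validate_cell_means(out)
  out
}

validate_cell_means <- function(x) {
  v <- x$values
  if (any(is.infinite(v))) {
    stop_oatmet("observed cell means must be finite", "oatmet_integrity_error")
  }
  row_obs <- rowSums(!is.na(v))
  col_obs <- colSums(!is.na(v))
  if (any(row_obs < 2L)) {
    stop_oatmet(sprintf("variety '%s' has fewer than 2 observed cells",
                        x$varieties[which(row_obs < 2L)[1L]]),
                "oatmet_input_error")
  }
  if (any(col_obs < 2L)) {
    stop_oatmet(sprintf("environment '%s' has fewer than 2 observed cells",
                        x$environments[which(col_obs < 2L)[1L]]),
                "oatmet_input_error")
  }
  invisible(x)
}

#' @export
print.cell_means <- function(x, ...) {
  cat(sprintf("Cell means for trait '%s' (%s): %d varieties x %d environments, %d observed cells\n",
              x$trait, x$unit, nrow(x$values), ncol(x$values),
              sum(!is.na(x$values))))
  print(round(x$values, 3))
  invisible(x)
}

#' Per-environment trait means
#'
#' Unweighted mean over the observed varieties in each environment (the
#' convention used for published per-environment summary tables: the mean of
#' the varieties, not a replicate-weighted mean).
#'
#' @param cells A `cell_means` object.
#' @return Named numeric vector, one value per environment.
#' @export
environment_means <- function(cells) {
  colMeans(cells$values, na.rm = TRUE)
}

#' Per-variety trait means
#'
#' Unweighted mean over the observed environments for each variety.
#'
#' @param cells A `cell_means` object.
#' @return Named numeric vector, one value per variety.
#' @export
variety_means <- function(cells) {
  rowMeans(cells$values, na.rm = TRUE)
}
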