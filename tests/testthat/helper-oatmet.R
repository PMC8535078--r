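# shared helpers for building tiny METs and independent oracles

# long-format met_table from a varieties x environments matrix of cell
# values, one replicate per cell
met_from_matrix <- function(m, trait = "yield") {
  if (is.null(rownames(m))) rownames(m) <- paste0("V", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("E", seq_len(ncol(m)))
  idx <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  met_table(data.frame(
    environment = colnames(m)[idx$j],
    variety = rownames(m)[idx$i],
    replicate = 1L,
    trait = trait,
    value = m[cbind(idx$i, idx$j)]
  ))
}

# independent oracle for the complete-data joint regression: row means plus
# the rank-1 truncated SVD of the row-centred matrix
svd_rank1_oracle <- function(y) {
  yc <- y - rowMeans(y)
  sv <- svd(yc)
  list(V = rowMeans(y),
       bilinear = sv$d[1] * sv$u[, 1] %*% t(sv$v[, 1]))
}

# write a small CSV to a temp file and return its path
tmp_csv <- function(text) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

# named per-environment vector of one trait's means from the bundled trial
em_vec <- function(trial, trait) {
  stats::setNames(trial$env_means[[trait]], trial$env_means$environment)
}

# flat daily weather series spanning the given dates
flat_weather <- function(from, to, rain = 2, tmin = 4, tmax = 12) {
  days <- seq(as.Date(from), as.Date(to), by = "day")
  tibble::tibble(date = days, rain = rain, tmin = tmin, tmax = tmax)
}
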