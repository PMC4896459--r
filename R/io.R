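microdata_required <- c("country_id", "cluster_id", "stratum_id", "weight",
                        "age_years", "sex", "urban", "wealth_quintile",
                        "stunted")
macro_required <- c("country_id", "region", "lmic", "surveyed", "hdi",
                    "stunting_prop", "pop_3_4")

#' Read and validate a child microdata CSV
#'
#' Expects a header row, one row per child, with design variables
#' (`country_id`, `cluster_id`, `stratum_id`, `weight`), covariates
#' (`age_years`, `sex`, `urban`, `wealth_quintile`, `stunted`), optional
#' `stim_*` items and the ten `ecdi_*` response columns. Booleans are
#' accepted as 0/1, yes/no or true/false (case-insensitive); empty ECDI
#' cells parse as missing. Unknown columns are preserved.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_microdata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(country_id = "character",
                                      cluster_id = "character",
                                      stratum_id = "character"))
  missing_cols <- setdiff(microdata_required, names(d))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  ecdi_cols <- grep("^ecdi_", names(d), value = TRUE)
  if (length(ecdi_cols) == 0)
    stop(path, ": no ecdi_* response columns found")
  bad_w <- which(!is.finite(d$weight) | d$weight <= 0)
  if (length(bad_w))
    stop(sprintf("%s: non-positive weight in row(s): %s", path,
                 paste(utils::head(bad_w, 5), collapse = ", ")))
  bad_age <- which(!d$age_years %in% c(3, 4))
  if (length(bad_age))
    stop(sprintf("%s: age_years outside {3,4} in row(s): %s", path,
                 paste(utils::head(bad_age, 5), collapse = ", ")))
  bad_wq <- which(!d$wealth_quintile %in% 1:5)
  if (length(bad_wq))
    stop(sprintf("%s: wealth_quintile outside 1..5 in row(s): %s", path,
                 paste(utils::head(bad_wq, 5), collapse = ", ")))
  for (col in ecdi_cols) {
    v <- d[[col]]
    if (is.character(v)) v[trimws(v) == ""] <- NA_character_
    parse_binary(v, paste0(path, ": column ", col))  # validates codes
    d[[col]] <- v
  }
  d
}

#' Read and validate a country macro CSV
#'
#' @param path CSV path with columns `country_id`, `region`, `lmic`,
#'   `surveyed`, `hdi`, `stunting_prop`, `pop_3_4` (plus optional
#'   indicators such as `life_expectancy`).
#' @return validated data.frame with `lmic`/`surveyed` as logicals.
#' @export
read_macro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(country_id = "character"))
  missing_cols <- setdiff(macro_required, names(d))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  dup <- unique(d$country_id[duplicated(d$country_id)])
  if (length(dup))
    stop(sprintf("%s: duplicated country code(s): %s", path,
                 paste(dup, collapse = ", ")))
  d$lmic <- parse_binary(d$lmic, paste0(path, ": column lmic"))
  d$surveyed <- parse_binary(d$surveyed, paste0(path, ": column surveyed"))
  for (col in c("hdi", "stunting_prop")) {
    bad <- which(!is.na(d[[col]]) & (d[[col]] < 0 | d[[col]] > 1))
    if (length(bad))
      stop(sprintf("%s: column %s outside [0,1] in row(s): %s", path, col,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(d$pop_3_4 < 0, na.rm = TRUE))
    stop(path, ": negative pop_3_4")
  d
}

#' Write a table as CSV
#'
#' Plain CSV with a header row, no row names, proportions kept as decimals
#' (report-style percentage formatting happens only in display tables).
#' Output is re-readable by the package's own readers.
#'
#' @param df data.frame.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Published country-level ECDI counts
#'
#' Sample sizes and counts of children classified low (either domain,
#' cognitive, socioemotional) in the 35 MICS/DHS surveys with ECDI data,
#' as published; useful for reproducing the pooled prevalence arithmetic
#' without access to the restricted microdata.
#'
#' @return data.frame with `country`, `n`, `n_low_either`,
#'   `n_low_cognitive`, `n_low_socioemotional`.
#' @export
ecdi_survey_counts <- function() {
  utils::read.csv(system.file("extdata", "ecdi_survey_counts.csv",
                              package = "ecdiglobal", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published regional population and prevalence estimates
#'
#' Regional totals of 3-4-year-olds in 2010 (millions) with the published
#' estimated prevalence of low ECDI scores and its 95% interval, for
#' checking the projection arithmetic.
#'
#' @return data.frame with `region`, `pop_3_4_millions`, `prevalence`,
#'   `prev_lower`, `prev_upper`.
#' @export
lmic_region_estimates <- function() {
  utils::read.csv(system.file("extdata", "lmic_region_estimates.csv",
                              package = "ecdiglobal", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
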