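#' Configuration for the synthetic survey generator
#'
#' Bundles and validates every knob of the synthetic MICS/DHS-like data
#' generator. Defaults emulate the observed study setting: 35 surveyed
#' countries out of 138 LMICs, roughly 2,800 children per survey drawn as a
#' two-stage cluster sample, country HDI spanning 0.30-0.90, and a true
#' prevalence of low development that declines linearly in HDI.
#'
#' @param n_countries number of LMICs in the macro panel.
#' @param n_surveyed how many of them carry a survey (microdata).
#' @param clusters_per_country first-stage clusters (PSUs) per survey.
#' @param children_per_cluster children sampled per cluster.
#' @param seed integer RNG seed; the whole generator is deterministic in it.
#' @param hdi_range increasing pair in \[0,1\]: countries' HDI is uniform here.
#' @param prevalence_link list `(a, b)`: target prevalence of a low score in
#'   a country with human-development index `h` is `a + b*h`, clipped to
#'   \[0,1\]. `NULL` disables the calibration and uses the raw item baselines.
#' @param item_model list with `baseline` (named per-item log-odds of item
#'   failure) and `coef` (log-odds shifts for `one_minus_hdi`, `stunted`,
#'   `lowest_wealth`, `male`, `rural`, `low_stimulation`).
#' @param missing_rate fraction of children given at least one missing
#'   in-scope ECDI response, in \[0, 1).
#' @param weight_dispersion sdlog of the unit-mean log-normal sampling
#'   weights (0 gives equal weights).
#' @param cluster_sd standard deviation of the cluster-level random
#'   intercept on the item-failure log-odds scale.
#' @param p_male,p_urban,p_age4 covariate marginals: probability a child is
#'   male, lives in an urban cluster, is 4 years old (vs 3).
#' @param stratify_urban_rural if TRUE, strata are country x urbanicity;
#'   default is a single stratum per country.
#' @return a validated list of class `ecdi_sim_config`.
#' @export
sim_config <- function(n_countries = 138L,
                       n_surveyed = 35L,
                       clusters_per_country = 100L,
                       children_per_cluster = 28L,
                       seed = 1L,
                       hdi_range = c(0.30, 0.90),
                       prevalence_link = list(a = 1.00, b = -1.06),
                       item_model = default_item_model(),
                       missing_rate = 0.01,
                       weight_dispersion = 0.3,
                       cluster_sd = 0.3,
                       p_male = 0.5,
                       p_urban = 0.4,
                       p_age4 = 0.5,
                       stratify_urban_rural = FALSE) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
      stop(sprintf("invalid configuration field '%s': must be a positive integer", nm))
  }
  chk_prop <- function(x, nm, open_top = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1 ||
        (open_top && x == 1))
      stop(sprintf("invalid configuration field '%s': must be a proportion in [0,1%s",
                   nm, if (open_top) ")" else "]"))
  }
  chk_count(n_countries, "n_countries")
  chk_count(n_surveyed, "n_surveyed")
  chk_count(clusters_per_country, "clusters_per_country")
  chk_count(children_per_cluster, "children_per_cluster")
  if (n_surveyed > n_countries)
    stop("invalid configuration field 'n_surveyed': exceeds n_countries")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("invalid configuration field 'seed': must be a single integer")
  if (!is.numeric(hdi_range) || length(hdi_range) != 2 || anyNA(hdi_range) ||
      hdi_range[1] < 0 || hdi_range[2] > 1 || hdi_range[1] > hdi_range[2])
    stop("invalid configuration field 'hdi_range': must be a non-decreasing pair in [0,1]")
  if (!is.null(prevalence_link)) {
    if (!is.list(prevalence_link) || !all(c("a", "b") %in% names(prevalence_link)))
      stop("invalid configuration field 'prevalence_link': needs intercept 'a' and slope 'b'")
  }
  if (!is.list(item_model) || !all(c("baseline", "coef") %in% names(item_model)))
    stop("invalid configuration field 'item_model': needs 'baseline' and 'coef'")
  coef_names <- c("one_minus_hdi", "stunted", "lowest_wealth", "male",
                  "rural", "low_stimulation")
  missing_coef <- setdiff(coef_names, names(item_model$coef))
  if (length(missing_coef))
    stop("invalid configuration field 'item_model': coef lacks ",
         paste(missing_coef, collapse = ", "))
  chk_prop(missing_rate, "missing_rate", open_top = TRUE)
  if (!is.numeric(weight_dispersion) || weight_dispersion < 0)
    stop("invalid configuration field 'weight_dispersion': must be non-negative")
  if (!is.numeric(cluster_sd) || cluster_sd < 0)
    stop("invalid configuration field 'cluster_sd': must be non-negative")
  chk_prop(p_male, "p_male"); chk_prop(p_urban, "p_urban"); chk_prop(p_age4, "p_age4")
  structure(list(
    n_countries = as.integer(n_countries), n_surveyed = as.integer(n_surveyed),
    clusters_per_country = as.integer(clusters_per_country),
    children_per_cluster = as.integer(children_per_cluster),
    seed = as.integer(seed), hdi_range = hdi_range,
    prevalence_link = prevalence_link, item_model = item_model,
    missing_rate = missing_rate, weight_dispersion = weight_dispersion,
    cluster_sd = cluster_sd, p_male = p_male, p_urban = p_urban,
    p_age4 = p_age4, stratify_urban_rural = isTRUE(stratify_urban_rural)
  ), class = "ecdi_sim_config")
}

#' @rdname sim_config
#' @details `default_item_model()` gives every in-scope item a zero baseline
#'   (the country-level calibration to the prevalence link supplies the
#'   level) and moderate positive failure gradients for stunted, poorest,
#'   male, rural and low-stimulation children, mirroring the direction of
#'   the subgroup differences seen in caregiver-reported ECD data.
#'   Out-of-scope items get fixed baselines typical of 3-4-year-olds (most
#'   cannot yet read; nearly all manage a pincer grasp).
#' @export
default_item_model <- function() {
  items <- ecdi_items()
  baseline <- stats::setNames(rep(0, nrow(items)), items$item_id)
  baseline[c("identifies_letters", "reads_words", "knows_numbers")] <- c(1.2, 2.2, 1.0)
  baseline["too_sick_to_play"] <- -1.5
  baseline["picks_up_small_object"] <- -3.0
  list(
    baseline = baseline,
    coef = c(one_minus_hdi = 0, stunted = 0.35, lowest_wealth = 0.25,
             male = 0.10, rural = 0.15, low_stimulation = 0.25)
  )
}

lmic_regions <- c("East Asia/Pacific", "Latin America/Caribbean",
                  "North Africa/Middle East/Central Asia", "South Asia",
                  "Sub-Saharan Africa")

#' Probability of a low either-domain classification given a common
#' item-failure probability
#'
#' Under independent failures with probability `q` on each of the five
#' in-scope items, low-cognitive requires both cognitive failures (`q^2`)
#' and low-socioemotional at least two of three failures.
#'
#' @param q item-failure probability in \[0,1\].
#' @return probability of a low cognitive and/or socioemotional score.
#' @keywords internal
p_low_given_q <- function(q) {
  p_cog <- q^2
  p_soc <- 3 * q^2 * (1 - q) + q^3
  1 - (1 - p_cog) * (1 - p_soc)
}

# invert p_low_given_q; monotone on [0,1]
solve_item_failure <- function(target) {
  vapply(target, function(t) {
    if (t <= 0) return(0)
    if (t >= 1) return(1)
    stats::uniroot(function(q) p_low_given_q(q) - t, c(0, 1),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Generate a synthetic LMIC country panel
#'
#' Draws a macro table of LMICs: HDI uniform on the configured range,
#' stunting negatively associated with HDI, a positive population of 3-4
#' year olds, and development indicators (life expectancy, schooling, GNI)
#' increasing in HDI. A random subset of `n_surveyed` countries is flagged
#' as carrying a survey.
#'
#' @param config an [sim_config()] object.
#' @return data.frame with one row per country: `country_id`, `region`,
#'   `lmic`, `surveyed`, `hdi`, `stunting_prop`, `pop_3_4`,
#'   `life_expectancy`, `mean_schooling_years`, `gni_per_capita`.
#' @export
generate_country_panel <- function(config) {
  stopifnot(inherits(config, "ecdi_sim_config"))
  set.seed(config$seed)
  n <- config$n_countries
  hdi <- stats::runif(n, config$hdi_range[1], config$hdi_range[2])
  panel <- data.frame(
    country_id = sprintf("C%03d", seq_len(n)),
    region = sample(lmic_regions, n, replace = TRUE),
    lmic = TRUE,
    surveyed = FALSE,
    hdi = hdi,
    stunting_prop = clip01(0.65 - 0.60 * hdi + stats::rnorm(n, 0, 0.05)),
    pop_3_4 = round(stats::rlnorm(n, meanlog = log(1e6), sdlog = 1.0)),
    life_expectancy = pmax(35, 45 + 30 * hdi + stats::rnorm(n, 0, 2)),
    mean_schooling_years = pmax(0, 1 + 11 * hdi + stats::rnorm(n, 0, 0.8)),
    gni_per_capita = exp(5.5 + 4 * hdi + stats::rnorm(n, 0, 0.3)),
    stringsAsFactors = FALSE
  )
  panel$surveyed[sample.int(n, config$n_surveyed)] <- TRUE
  panel
}

#' Generate MICS/DHS-like child microdata for the surveyed countries
#'
#' For each surveyed country, draws a two-stage cluster sample:
#' `clusters_per_country` PSUs of `children_per_cluster` children each.
#' Child covariates follow the configured marginals (urbanicity assigned at
#' cluster level, stunting at the country's stunting proportion). Each ECDI
#' item fails with probability `logistic(country offset + item baseline +
#' covariate effects + cluster effect)`; reverse-coded items are emitted on
#' the raw yes/no scale (a failure on "easily distracted" is recorded as
#' "yes"). When a prevalence link is configured, the country offset is
#' calibrated so the country's expected share of low-scoring children
#' equals `a + b*hdi` (clipped to \[0,1\]), with covariate effects centered
#' within country.
#'
#' @param panel country panel from [generate_country_panel()].
#' @param config an [sim_config()] object.
#' @return data.frame of child records (one row per child) with design
#'   variables, covariates, six `stim_*` items and ten `ecdi_*` responses
#'   ("yes"/"no", NA for missing). The per-country target prevalence (when
#'   a link is configured) is attached as attribute `target_prevalence`.
#' @export
generate_microdata <- function(panel, config) {
  stopifnot(inherits(config, "ecdi_sim_config"))
  if (nrow(panel) == 0) stop("panel is empty")
  surveyed <- panel[panel$surveyed, , drop = FALSE]
  if (nrow(surveyed) == 0) stop("no surveyed countries in panel")
  if (config$clusters_per_country < 1L)
    stop("invalid configuration field 'clusters_per_country': surveyed countries need at least one cluster")
  set.seed(config$seed + 1L)

  n_cty <- nrow(surveyed)
  n_cl <- config$clusters_per_country
  n_ch <- config$children_per_cluster
  per_cty <- n_cl * n_ch
  n <- n_cty * per_cty

  cty_idx <- rep(seq_len(n_cty), each = per_cty)
  cl_within <- rep(rep(seq_len(n_cl), each = n_ch), times = n_cty)
  country_id <- surveyed$country_id[cty_idx]
  cluster_id <- sprintf("%s_cl%03d", country_id, cl_within)

  # cluster-level draws (urbanicity and random intercept are PSU traits)
  cl_key <- paste(country_id, cl_within)
  ucl <- !duplicated(cl_key)
  n_clusters <- sum(ucl)
  cl_urban <- stats::rbinom(n_clusters, 1, config$p_urban)
  cl_effect <- stats::rnorm(n_clusters, 0, config$cluster_sd)
  cl_map <- match(cl_key, cl_key[ucl])
  urban <- cl_urban[cl_map]
  cluster_eff <- cl_effect[cl_map]

  stratum_id <- if (config$stratify_urban_rural)
    paste0(country_id, "_", ifelse(urban == 1, "urban", "rural"))
  else country_id

  age_years <- 3L + stats::rbinom(n, 1, config$p_age4)
  sex <- ifelse(stats::rbinom(n, 1, config$p_male) == 1, "male", "female")
  wealth_quintile <- sample.int(5L, n, replace = TRUE)
  stunted <- stats::rbinom(n, 1, surveyed$stunting_prop[cty_idx])
  weight <- if (config$weight_dispersion > 0)
    stats::rlnorm(n, meanlog = -config$weight_dispersion^2 / 2,
                  sdlog = config$weight_dispersion)
  else rep(1, n)

  # six stimulation items, more likely with household wealth
  stim_names <- paste0("stim_", c("read", "play", "stories", "count", "sing", "outing"))
  p_stim <- stats::plogis(0.3 + 0.35 * (wealth_quintile - 3))
  stim <- matrix(stats::rbinom(n * 6L, 1, rep(p_stim, 6L)), n, 6L,
                 dimnames = list(NULL, stim_names))
  low_stim <- rowSums(stim) <= 2L

  cf <- config$item_model$coef
  eta <- cf[["one_minus_hdi"]] * (1 - surveyed$hdi[cty_idx]) +
    cf[["stunted"]] * stunted +
    cf[["lowest_wealth"]] * (wealth_quintile == 1L) +
    cf[["male"]] * (sex == "male") +
    cf[["rural"]] * (1 - urban) +
    cf[["low_stimulation"]] * low_stim +
    cluster_eff

  items <- ecdi_items()
  baseline <- config$item_model$baseline[items$item_id]
  if (anyNA(baseline))
    stop("invalid configuration field 'item_model': baseline must name all ten items")

  link <- config$prevalence_link
  if (!is.null(link)) {
    target <- clip01(link$a + link$b * surveyed$hdi)
    offset <- pmin(20, pmax(-20, stats::qlogis(
      pmin(1 - 1e-12, pmax(1e-12, solve_item_failure(target))))))
    eta_scope <- eta - stats::ave(eta, country_id)  # centered: country mean on target
    offset_child <- offset[cty_idx]
  } else {
    target <- NULL
    eta_scope <- eta
    offset_child <- 0
  }

  micro <- data.frame(
    country_id = country_id, cluster_id = cluster_id, stratum_id = stratum_id,
    weight = weight, age_years = age_years, sex = sex, urban = urban,
    wealth_quintile = wealth_quintile, stunted = stunted,
    stringsAsFactors = FALSE
  )
  micro <- cbind(micro, as.data.frame(stim))

  for (j in seq_len(nrow(items))) {
    eta_j <- if (items$in_scope[j]) offset_child + eta_scope else eta
    p_fail <- stats::plogis(baseline[[j]] + eta_j)
    fail <- stats::rbinom(n, 1, p_fail) == 1L
    yes <- if (items$reverse_coded[j]) fail else !fail
    micro[[paste0("ecdi_", items$item_id[j])]] <- ifelse(yes, "yes", "no")
  }

  if (config$missing_rate > 0) {
    m <- round(config$missing_rate * n)
    if (m > 0) {
      who <- sample.int(n, m)
      scope_cols <- paste0("ecdi_", items$item_id[items$in_scope])
      which_item <- sample(scope_cols, m, replace = TRUE)
      for (col in unique(which_item))
        micro[who[which_item == col], col] <- NA_character_
    }
  }

  if (!is.null(target))
    attr(micro, "target_prevalence") <-
      data.frame(country_id = surveyed$country_id, target = target,
                 stringsAsFactors = FALSE)
  micro
}

#' Write a simulated dataset with its provenance
#'
#' Writes the microdata and macro panel as CSV plus the generating
#' configuration as JSON, so a simulated dataset is always reproducible.
#'
#' @param panel country panel.
#' @param microdata child records.
#' @param config the [sim_config()] that generated them.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(panel, microdata, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    macro = file.path(out_dir, "macro.csv"),
    microdata = file.path(out_dir, "microdata.csv"),
    config = file.path(out_dir, "sim_config.json")
  )
  write_table(panel, paths[["macro"]])
  write_table(microdata, paths[["microdata"]])
  jsonlite::write_json(unclass(config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
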