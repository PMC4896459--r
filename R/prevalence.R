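#' Design-based weighted prevalence of a binary outcome
#'
#' Point estimate is the weighted mean (Hajek ratio estimator)
#' `sum(w*y)/sum(w)`; the standard error uses Taylor linearization with a
#' with-replacement first-stage approximation: linearized scores are
#' totalled within clusters (PSUs) and their between-cluster variance is
#' accumulated within strata. This is the standard variance estimator for
#' MICS/DHS-style two-stage designs. The estimate is invariant to rescaling
#' all weights by a constant.
#'
#' @param flags logical (or 0/1) outcome vector, no NAs; excluded children
#'   must already be removed.
#' @param weights positive sampling weights; NULL means equal weights.
#' @param clusters PSU labels; NULL treats each observation as its own
#'   cluster (simple random sampling).
#' @param strata stratum labels; NULL pools everything in one stratum.
#' @return an object of class `prevalence_estimate`: a list with `n`,
#'   `n_low` (unweighted count of TRUE flags), `prevalence`, `se` (NA when
#'   any stratum holds a single cluster), `weighted`.
#' @export
#' @examples
#' est <- weighted_prevalence(c(rep(TRUE, 2982), rep(FALSE, 4451 - 2982)))
#' format_percent(est$prevalence)  # "67.0%"
weighted_prevalence <- function(flags, weights = NULL, clusters = NULL,
                                strata = NULL) {
  if (length(flags) == 0) stop("cannot estimate a prevalence from no observations")
  y <- as.numeric(parse_binary(flags, "outcome flag"))
  if (anyNA(y)) stop("flags must not contain NA; drop excluded children first")
  n <- length(y)
  weighted <- !is.null(weights)
  w <- if (weighted) as.numeric(weights) else rep(1, n)
  if (length(w) != n) stop("weights must match flags in length")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  cl <- if (is.null(clusters)) as.character(seq_len(n)) else as.character(clusters)
  st <- if (is.null(strata)) rep("_all_", n) else as.character(strata)
  if (length(cl) != n || length(st) != n)
    stop("clusters and strata must match flags in length")

  W <- sum(w)
  p <- sum(w * y) / W

  # linearized score for the ratio estimator
  u <- w * (y - p) / W
  key <- paste(st, cl, sep = "\r")
  t_c <- tapply(u, key, sum)
  st_c <- sub("\r.*$", "", names(t_c))
  var_hat <- 0
  single_cluster <- FALSE
  for (h in unique(st_c)) {
    th <- t_c[st_c == h]
    nh <- length(th)
    if (nh < 2) { single_cluster <- TRUE; next }
    var_hat <- var_hat + nh / (nh - 1) * sum((th - mean(th))^2)
  }
  se <- if (single_cluster) {
    warning("a stratum contains a single cluster; standard error undefined")
    NA_real_
  } else sqrt(var_hat)

  structure(list(n = n, n_low = sum(y == 1), prevalence = p, se = se,
                 weighted = weighted),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("Prevalence %s (se %s) from n = %d (%d events)%s\n",
              format_percent(x$prevalence),
              ifelse(is.na(x$se), "NA", formatC(x$se, format = "f", digits = 4)),
              x$n, x$n_low,
              if (x$weighted) ", survey-weighted" else ", unweighted"))
  invisible(x)
}

subgroup_vars <- c("sex", "stunted", "wealth_quintile", "urban", "age_years",
                   "stim_quintile")

#' Prevalence of low ECDI scores by subgroup
#'
#' Splits classified microdata by one stratifier (sex, stunting status,
#' wealth quintile, urbanicity, age 3 vs 4, or cognitive-stimulation
#' quintile), optionally within country, and estimates a design-based
#' prevalence per cell. Excluded children (missing ECDI data) are dropped;
#' children missing the grouping variable are dropped with a warning.
#'
#' @param classified microdata with classification columns from
#'   [classify_microdata()] (plus `stim_quintile` if grouping by it, see
#'   [build_stimulation_quintiles()]).
#' @param by one of `"sex"`, `"stunted"`, `"wealth_quintile"`, `"urban"`,
#'   `"age_years"`, `"stim_quintile"`.
#' @param per_country if TRUE, estimates per country x level.
#' @param outcome which low flag to estimate (default `"low_either"`).
#' @return data.frame with the grouping columns plus `n`, `n_low`,
#'   `prevalence`, `se`.
#' @export
subgroup_prevalence <- function(classified, by, per_country = FALSE,
                                outcome = "low_either") {
  if (!by %in% subgroup_vars)
    stop("unknown grouping variable '", by, "'; expected one of: ",
         paste(subgroup_vars, collapse = ", "))
  if (!by %in% names(classified))
    stop("grouping variable '", by, "' not present in the data")
  if (!outcome %in% names(classified))
    stop("outcome column '", outcome, "' not present; run classify_microdata() first")
  d <- classified[!classified$excluded, , drop = FALSE]
  if (anyNA(d[[by]])) {
    warning(sum(is.na(d[[by]])), " children missing '", by, "' dropped")
    d <- d[!is.na(d[[by]]), , drop = FALSE]
  }
  keys <- if (per_country) list(country_id = d$country_id, level = d[[by]])
          else list(level = d[[by]])
  splits <- split(seq_len(nrow(d)), keys, drop = TRUE)
  rows <- lapply(names(splits), function(nm) {
    i <- splits[[nm]]
    est <- weighted_prevalence(d[[outcome]][i], d$weight[i],
                               d$cluster_id[i], d$stratum_id[i])
    lab <- if (per_country) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      stats::setNames(data.frame(parts[1], parts[2], stringsAsFactors = FALSE),
                      c("country_id", by))
    } else stats::setNames(data.frame(nm, stringsAsFactors = FALSE), by)
    cbind(lab, data.frame(n = est$n, n_low = est$n_low,
                          prevalence = est$prevalence, se = est$se))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cognitive stimulation index and quintiles
#'
#' The stimulation index counts how many of six caregiver activities
#' (reading, playing, storytelling, counting, singing, outings) the child
#' received. Quintiles cut the raw 0-6 score at the weighted 20/40/60/80th
#' percentiles of the reference sample; ties at a cut-point fall in the
#' lower quintile. Children missing any stimulation item get an NA quintile
#' (they are not excluded from ECDI analyses).
#'
#' @param stim_items data.frame or matrix of six binary items, one row per
#'   child.
#' @param weights positive sampling weights (NULL for equal).
#' @return data.frame with `raw_score` (0-6) and `quintile` (1-5).
#' @export
build_stimulation_quintiles <- function(stim_items, weights = NULL) {
  m <- as.matrix(as.data.frame(lapply(as.data.frame(stim_items), function(col)
    as.numeric(parse_binary(col, "stimulation item")))))
  if (ncol(m) != 6L) stop("expected six stimulation items, got ", ncol(m))
  raw <- rowSums(m)  # NA if any item missing
  w <- if (is.null(weights)) rep(1, nrow(m)) else as.numeric(weights)
  ok <- !is.na(raw)
  if (!any(ok)) stop("no complete stimulation records")
  cuts <- weighted_quantile(raw[ok], w[ok], c(0.2, 0.4, 0.6, 0.8))
  quintile <- rep(NA_integer_, length(raw))
  quintile[ok] <- 1L + rowSums(outer(raw[ok], cuts, `>`))
  data.frame(raw_score = as.integer(raw), quintile = quintile)
}

#' Weighted point-biserial correlation
#'
#' Weighted Pearson correlation between a 0/1 low-development flag and a
#' binary covariate (equal to the phi coefficient when both are binary),
#' with a large-sample t-based p-value.
#'
#' @param low_flags binary outcome.
#' @param covariate binary covariate, coded per the reporting convention
#'   (e.g. girls = 1, boys = 0).
#' @param weights positive weights (NULL for equal).
#' @return list with `r`, `p_value`, `n`.
#' @export
point_biserial <- function(low_flags, covariate, weights = NULL) {
  y <- as.numeric(parse_binary(low_flags, "low flag"))
  x <- as.numeric(parse_binary(covariate, "covariate"))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)[ok]
  if (stats::var(x) == 0)
    stop("covariate is constant; point-biserial correlation undefined")
  if (stats::var(y) == 0)
    stop("outcome is constant; point-biserial correlation undefined")
  W <- sum(w)
  mx <- sum(w * x) / W; my <- sum(w * y) / W
  vx <- sum(w * (x - mx)^2) / W; vy <- sum(w * (y - my)^2) / W
  r <- sum(w * (x - mx) * (y - my)) / W / sqrt(vx * vy)
  tstat <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p_value = p, n = n)
}

#' Country-level Pearson correlation
#'
#' Unweighted correlation across countries between an estimated prevalence
#' and a macro predictor (stunting proportion or HDI).
#'
#' @param prevalences numeric per-country prevalences.
#' @param predictor numeric per-country predictor, same order.
#' @return the Pearson correlation coefficient.
#' @export
country_level_correlation <- function(prevalences, predictor) {
  ok <- !is.na(prevalences) & !is.na(predictor)
  if (sum(ok) < 3) stop("need at least 3 countries with both values")
  stats::cor(prevalences[ok], predictor[ok])
}

#' Compare surveyed and unsurveyed countries on macro indicators
#'
#' Welch two-sample comparison of country means between the surveyed and
#' unsurveyed groups, one row per indicator. Used to assess whether the
#' surveyed countries are representative of all LMICs.
#'
#' @param macro country panel with a logical `surveyed` column.
#' @param indicators macro columns to compare.
#' @return data.frame with `indicator`, `mean_surveyed`, `mean_unsurveyed`,
#'   `difference`, `p_value`.
#' @export
compare_country_groups <- function(macro,
                                   indicators = c("hdi", "life_expectancy",
                                                  "mean_schooling_years",
                                                  "gni_per_capita")) {
  absent <- setdiff(indicators, names(macro))
  if (length(absent))
    stop("indicator not present in macro table: ", paste(absent, collapse = ", "))
  s <- parse_binary(macro$surveyed, "surveyed")
  if (!any(s) || !any(!s)) stop("both surveyed and unsurveyed groups must be non-empty")
  rows <- lapply(indicators, function(ind) {
    a <- macro[[ind]][s]; b <- macro[[ind]][!s]
    tt <- stats::t.test(a, b)
    data.frame(indicator = ind, mean_surveyed = mean(a),
               mean_unsurveyed = mean(b), difference = mean(a) - mean(b),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-country prevalence of low ECDI scores
#'
#' Convenience wrapper: design-based prevalence of `outcome` for each
#' country in classified microdata, the input to the country-level
#' prediction models.
#'
#' @inheritParams subgroup_prevalence
#' @return data.frame with `country_id`, `n`, `n_low`, `prevalence`, `se`.
#' @export
country_prevalence <- function(classified, outcome = "low_either") {
  d <- classified[!classified$excluded, , drop = FALSE]
  rows <- lapply(split(seq_len(nrow(d)), d$country_id), function(i) {
    est <- weighted_prevalence(d[[outcome]][i], d$weight[i],
                               d$cluster_id[i], d$stratum_id[i])
    data.frame(country_id = d$country_id[i][1], n = est$n, n_low = est$n_low,
               prevalence = est$prevalence, se = est$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
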