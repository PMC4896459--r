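#' Predict low-development prevalence and counts for all LMICs
#'
#' Applies a selected country-level model to every LMIC in the macro table.
#' The linear predictor is clipped to \[0,1\]; the 95% confidence interval
#' is `clip(prediction +/- z * cv_rmse)` using the model's cross-validated
#' out-of-sample RMSE, and prevalences are converted to child counts by
#' multiplying by the country's population aged 3-4 years.
#'
#' @param fit an `ecdi_model_fit` with `cv_rmse` populated.
#' @param macro country panel; LMIC rows need the model's predictors and
#'   `pop_3_4`.
#' @param z normal quantile for the interval (default 1.96).
#' @param rmse_k which leave-out RMSE builds the interval (default 2).
#' @param use_observed if TRUE, surveyed countries get their observed
#'   survey prevalence instead of the model prediction.
#' @param observed data.frame `country_id`, `prevalence` (required when
#'   `use_observed`).
#' @return data.frame with one row per projected LMIC: `country_id`,
#'   `region`, `pop_3_4`, `predicted_prev`, `prev_lower`, `prev_upper`,
#'   `n_low`, `n_low_lower`, `n_low_upper`, `source`. Countries dropped for
#'   missing predictors are listed in attribute `excluded_countries`.
#' @export
predict_all_lmics <- function(fit, macro, z = 1.96, rmse_k = 2L,
                              use_observed = FALSE, observed = NULL) {
  stopifnot(inherits(fit, "ecdi_model_fit"))
  if (z <= 0) stop("z must be positive")
  rmse <- fit$cv_rmse[[as.character(rmse_k)]]
  if (is.null(rmse)) stop("model has no cv_rmse for k = ", rmse_k)
  lm_rows <- macro[parse_binary(macro$lmic, "lmic"), , drop = FALSE]
  need <- c(fit$spec$predictors, "pop_3_4")
  absent <- setdiff(need, names(lm_rows))
  if (length(absent)) stop("macro table lacks columns: ",
                           paste(absent, collapse = ", "))
  complete <- stats::complete.cases(lm_rows[, need, drop = FALSE])
  excluded <- lm_rows$country_id[!complete]
  if (length(excluded))
    warning("countries dropped for missing predictors: ",
            paste(excluded, collapse = ", "))
  d <- lm_rows[complete, , drop = FALSE]

  beta <- fit$coefficients
  lin <- rep(if (fit$spec$include_intercept) beta[["(Intercept)"]] else 0,
             nrow(d))
  for (pr in fit$spec$predictors) lin <- lin + beta[[pr]] * d[[pr]]

  pred <- clip01(lin)
  lower <- clip01(lin - z * rmse)
  upper <- clip01(lin + z * rmse)
  source <- rep("predicted", nrow(d))

  if (use_observed) {
    if (is.null(observed)) stop("use_observed = TRUE requires 'observed'")
    m <- match(d$country_id, observed$country_id)
    hit <- !is.na(m) & parse_binary(d$surveyed %||% FALSE, "surveyed")
    pred[hit] <- observed$prevalence[m[hit]]
    lower[hit] <- clip01(pred[hit] - z * rmse)
    upper[hit] <- clip01(pred[hit] + z * rmse)
    source[hit] <- "observed"
  }

  out <- data.frame(
    country_id = d$country_id, region = d$region, pop_3_4 = d$pop_3_4,
    predicted_prev = pred, prev_lower = lower, prev_upper = upper,
    n_low = pred * d$pop_3_4,
    n_low_lower = lower * d$pop_3_4,
    n_low_upper = upper * d$pop_3_4,
    source = source, stringsAsFactors = FALSE
  )
  attr(out, "excluded_countries") <- excluded
  out
}

#' Aggregate country projections to regions and the global total
#'
#' Regional child counts (and their confidence bounds) are sums of country
#' counts; regional prevalence is the count/population ratio. The global
#' row sums the regional rows, so its interval equals the sum of the
#' regional interval bounds.
#'
#' @param projections output of [predict_all_lmics()], or any data.frame
#'   with `region`, `pop_3_4`, `n_low`, `n_low_lower`, `n_low_upper`.
#' @param global_label label for the all-LMIC row (default `"All LMICs"`).
#' @return data.frame with `region`, `pop_3_4`, `prevalence`, `prev_lower`,
#'   `prev_upper`, `n_low`, `n_low_lower`, `n_low_upper`; regional rows
#'   first, global row last.
#' @export
aggregate_projections <- function(projections, global_label = "All LMICs") {
  if (anyNA(projections$region) || any(projections$region == ""))
    stop("unmapped region for countries: ",
         paste(projections$country_id[is.na(projections$region) |
                                        projections$region == ""],
               collapse = ", "))
  agg <- function(d, label) {
    pop <- sum(d$pop_3_4)
    n_low <- sum(d$n_low)
    data.frame(region = label, pop_3_4 = pop,
               prevalence = n_low / pop,
               prev_lower = sum(d$n_low_lower) / pop,
               prev_upper = sum(d$n_low_upper) / pop,
               n_low = n_low,
               n_low_lower = sum(d$n_low_lower),
               n_low_upper = sum(d$n_low_upper),
               stringsAsFactors = FALSE)
  }
  regions <- lapply(split(projections, projections$region),
                    function(d) agg(d, d$region[1]))
  out <- do.call(rbind, c(regions, list(agg(projections, global_label))))
  rownames(out) <- NULL
  out
}

#' Combine cognitive/socioemotional and physical-growth deficits
#'
#' Adds to the overall prevalence of low cognitive and/or socioemotional
#' scores the share of children who are stunted yet not low-scoring,
#' `stunting_prev * (1 - p_low_given_stunted)`, giving the share of
#' children failing to meet their potential in at least one of the three
#' areas. Assumes the stunting rate among 3-4-year-olds equals the under-5
#' rate (logged as a message).
#'
#' @param overall_low_prev prevalence of a low cognitive and/or
#'   socioemotional score among all children, in \[0,1\].
#' @param stunting_prev prevalence of stunting, in \[0,1\].
#' @param p_low_given_stunted conditional probability that a stunted child
#'   scores low, in \[0,1\].
#' @return list with `additional_stunted_only` (stunted but not
#'   low-scoring) and `combined` (either deficit), both proportions.
#' @export
#' @examples
#' d <- combine_development_deficits(0.329, 0.299, 0.442)
#' format_percent(d$additional_stunted_only)  # "16.7%"
#' format_percent(d$combined)                 # "49.6%"
combine_development_deficits <- function(overall_low_prev, stunting_prev,
                                         p_low_given_stunted) {
  args <- c(overall_low_prev, stunting_prev, p_low_given_stunted)
  if (any(!is.finite(args)) || any(args < 0) || any(args > 1))
    stop("all arguments must be proportions in [0,1]")
  message("assuming stunting prevalence among 3-4-year-olds equals the under-5 rate")
  additional <- stunting_prev * (1 - p_low_given_stunted)
  combined <- overall_low_prev + additional
  if (combined > 1)
    stop("combined proportion exceeds 1; check that p_low_given_stunted is conditional on stunting")
  list(additional_stunted_only = additional, combined = combined)
}
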