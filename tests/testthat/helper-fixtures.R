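# Shared fixture builders. All data is generated in code at test time.

# compact simulation for fast tests
small_sim_config <- function(...) {
  args <- list(n_countries = 30L, n_surveyed = 10L, clusters_per_country = 15L,
               children_per_cluster = 12L, seed = 11L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# a clean-slate item model: no covariate effects
null_item_model <- function(baseline = 0) {
  items <- ecdi_items()
  list(baseline = stats::setNames(rep(baseline, nrow(items)), items$item_id),
       coef = c(one_minus_hdi = 0, stunted = 0, lowest_wealth = 0, male = 0,
                rural = 0, low_stimulation = 0))
}

# one child record with all ten ECDI responses; override individual items
child_record <- function(...) {
  items <- ecdi_items()
  # favorable raw response: "no" for reverse-coded items, "yes" otherwise
  resp <- ifelse(items$reverse_coded, "no", "yes")
  rec <- as.list(stats::setNames(resp, paste0("ecdi_", items$item_id)))
  over <- list(...)
  rec[names(over)] <- over
  rec
}

# expand published counts into equal-weight 0/1 flags
expand_flags <- function(n, n_low) c(rep(TRUE, n_low), rep(FALSE, n - n_low))

# independent brute-force weighted quantile: smallest value whose weighted
# CDF reaches p (computed by direct enumeration, no shared code path)
brute_weighted_quantile <- function(x, w, p) {
  vals <- sort(unique(x))
  total <- sum(w)
  for (v in vals) if (sum(w[x <= v]) / total >= p - 1e-12) return(v)
  vals[length(vals)]
}

# random country panel for regression property tests
random_panel <- function(n = 35, a = 1.0, b = -1.06, sigma = 0.07,
                         hdi_range = c(0.30, 0.90)) {
  hdi <- stats::runif(n, hdi_range[1], hdi_range[2])
  data.frame(
    country_id = sprintf("P%03d", seq_len(n)),
    hdi = hdi,
    stunting_prop = clamp01(0.65 - 0.6 * hdi + stats::rnorm(n, 0, 0.05)),
    prevalence = a + b * hdi + stats::rnorm(n, 0, sigma)
  )
}

clamp01 <- function(x) pmin(1, pmax(0, x))
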