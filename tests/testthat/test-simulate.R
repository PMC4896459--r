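test_that("generation is deterministic under a fixed seed", {
  cfg <- small_sim_config()
  p1 <- generate_country_panel(cfg)
  p2 <- generate_country_panel(cfg)
  expect_identical(p1, p2)
  m1 <- generate_microdata(p1, cfg)
  m2 <- generate_microdata(p2, cfg)
  expect_identical(m1, m2)
  # a different seed changes the draw
  p3 <- generate_country_panel(small_sim_config(seed = 12L))
  expect_false(identical(p1$hdi, p3$hdi))
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_countries = 0), "n_countries")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(hdi_range = c(0.9, 0.3)), "hdi_range")
  expect_error(sim_config(weight_dispersion = -1), "weight_dispersion")
  expect_error(sim_config(n_surveyed = 40, n_countries = 30), "n_surveyed")
  expect_error(sim_config(item_model = list(baseline = 0)), "item_model")
})

test_that("the macro panel has the designed structure", {
  cfg <- sim_config(n_countries = 200L, n_surveyed = 35L, seed = 3L)
  panel <- generate_country_panel(cfg)
  expect_equal(nrow(panel), 200L)
  expect_equal(sum(panel$surveyed), 35L)
  expect_true(all(panel$hdi >= 0.30 & panel$hdi <= 0.90))
  expect_true(all(panel$stunting_prop >= 0 & panel$stunting_prop <= 1))
  expect_true(all(panel$pop_3_4 > 0))
  expect_true(all(panel$region %in% c(
    "East Asia/Pacific", "Latin America/Caribbean",
    "North Africa/Middle East/Central Asia", "South Asia",
    "Sub-Saharan Africa")))
  # stunting declines with development
  expect_lt(cor(panel$hdi, panel$stunting_prop), -0.8)
})

test_that("a degenerate hdi_range collapses every country to the same HDI", {
  cfg <- small_sim_config(hdi_range = c(0.5, 0.5))
  panel <- generate_country_panel(cfg)
  expect_true(all(panel$hdi == 0.5))
})

test_that("the null item model fails every item with probability one half", {
  cfg <- sim_config(n_countries = 4L, n_surveyed = 4L,
                    clusters_per_country = 40L, children_per_cluster = 25L,
                    seed = 5L, prevalence_link = NULL,
                    item_model = null_item_model(0), cluster_sd = 0,
                    missing_rate = 0)
  micro <- generate_microdata(generate_country_panel(cfg), cfg)
  items <- ecdi_items()
  for (j in seq_len(nrow(items))) {
    yes <- mean(micro[[paste0("ecdi_", items$item_id[j])]] == "yes")
    expect_lt(abs(yes - 0.5), 4 * sqrt(0.25 / nrow(micro)))
  }
})

test_that("country prevalence converges to the configured linear link", {
  # no covariate heterogeneity: the calibration is exact up to binomial noise
  n_ch <- 60L * 40L
  cfg <- sim_config(n_countries = 12L, n_surveyed = 12L,
                    clusters_per_country = 60L, children_per_cluster = 40L,
                    seed = 19L, prevalence_link = list(a = 1.0, b = -1.0),
                    item_model = null_item_model(0), cluster_sd = 0,
                    missing_rate = 0, weight_dispersion = 0)
  panel <- generate_country_panel(cfg)
  micro <- generate_microdata(panel, cfg)
  cl <- classify_microdata(micro)
  prev <- country_prevalence(cl)
  m <- merge(prev, panel[, c("country_id", "hdi")], by = "country_id")
  tol <- 4 * sqrt(0.25 / n_ch)
  expect_true(all(abs(m$prevalence - (1 - m$hdi)) < tol))
})

test_that("a positive stunting coefficient raises prevalence among stunted children", {
  im <- null_item_model(0)
  im$coef["stunted"] <- 0.8
  cfg <- sim_config(n_countries = 6L, n_surveyed = 6L,
                    clusters_per_country = 50L, children_per_cluster = 30L,
                    seed = 23L, prevalence_link = list(a = 0.9, b = -0.9),
                    item_model = im, cluster_sd = 0, missing_rate = 0)
  micro <- generate_microdata(generate_country_panel(cfg), cfg)
  cl <- classify_microdata(micro)
  by_stunt <- subgroup_prevalence(cl, "stunted")
  p <- stats::setNames(by_stunt$prevalence, by_stunt$stunted)
  expect_gt(p[["1"]], p[["0"]])
})

test_that("missingness control behaves at both ends", {
  cfg0 <- small_sim_config(missing_rate = 0)
  cl0 <- classify_microdata(generate_microdata(generate_country_panel(cfg0), cfg0))
  expect_equal(sum(cl0$excluded), 0L)

  cfg5 <- small_sim_config(missing_rate = 0.05)
  micro5 <- generate_microdata(generate_country_panel(cfg5), cfg5)
  cl5 <- classify_microdata(micro5)
  expect_equal(sum(cl5$excluded), round(0.05 * nrow(micro5)))
})

test_that("surveyed countries are required for microdata generation", {
  cfg <- small_sim_config()
  panel <- generate_country_panel(cfg)
  panel$surveyed <- FALSE
  expect_error(generate_microdata(panel, cfg), "no surveyed countries")
})
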