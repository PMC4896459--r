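test_that("equal weights reduce to the exact count ratio and SRS variance", {
  set.seed(1)
  flags <- stats::runif(400) < 0.3
  est <- weighted_prevalence(flags)
  p <- mean(flags)
  expect_identical(est$n_low, sum(flags))
  expect_equal(est$prevalence, p, tolerance = 1e-15)
  # one stratum, each child its own cluster: linearization gives p(1-p)/(n-1)
  expect_equal(est$se, sqrt(p * (1 - p) / (length(flags) - 1)),
               tolerance = 1e-12)
  expect_false(est$weighted)
})

test_that("estimates are invariant to rescaling all weights", {
  set.seed(2)
  n <- 300
  flags <- stats::runif(n) < 0.4
  w <- stats::rlnorm(n)
  cl <- sample(sprintf("c%02d", 1:20), n, replace = TRUE)
  st <- rep(c("s1", "s2"), length.out = n)
  e1 <- weighted_prevalence(flags, w, cl, st)
  e2 <- weighted_prevalence(flags, 2 * w, cl, st)
  expect_equal(e1$prevalence, e2$prevalence, tolerance = 1e-14)
  expect_equal(e1$se, e2$se, tolerance = 1e-14)
})

test_that("degenerate inputs behave as specified", {
  e0 <- weighted_prevalence(rep(FALSE, 50))
  expect_equal(e0$prevalence, 0)
  expect_equal(e0$se, 0)
  expect_error(weighted_prevalence(logical(0)), "no observations")
  expect_error(weighted_prevalence(c(TRUE, FALSE), weights = c(1, -1)),
               "positive")
  expect_warning(
    e1 <- weighted_prevalence(c(TRUE, FALSE, TRUE), clusters = c("a", "a", "a")),
    "single cluster")
  expect_true(is.na(e1$se))
  expect_equal(e1$prevalence, 2 / 3, tolerance = 1e-15)
})

test_that("linearized cluster SE agrees with a cluster-jackknife cross-check", {
  set.seed(3)
  n_cl <- 40; per <- 25
  cl <- rep(sprintf("c%02d", 1:n_cl), each = per)
  re <- rep(stats::rnorm(n_cl, 0, 0.6), each = per)
  flags <- stats::runif(n_cl * per) < stats::plogis(-0.5 + re)
  w <- stats::rlnorm(n_cl * per, 0, 0.3)
  est <- weighted_prevalence(flags, w, cl)
  # independent route: delete-one-cluster jackknife (JK1)
  p_del <- vapply(unique(cl), function(c0) {
    keep <- cl != c0
    sum(w[keep] * flags[keep]) / sum(w[keep])
  }, numeric(1))
  se_jk <- sqrt((n_cl - 1) / n_cl * sum((p_del - mean(p_del))^2))
  expect_gt(est$se / se_jk, 0.85)
  expect_lt(est$se / se_jk, 1.15)
})

test_that("pooled prevalence is the weight-share mean of country prevalences", {
  cfg <- small_sim_config()
  cl <- classify_microdata(generate_microdata(generate_country_panel(cfg), cfg))
  d <- cl[!cl$excluded, ]
  pooled <- weighted_prevalence(d$low_either, d$weight)$prevalence
  per_cty <- country_prevalence(cl)
  shares <- tapply(d$weight, d$country_id, sum) / sum(d$weight)
  expect_equal(pooled,
               sum(per_cty$prevalence * shares[per_cty$country_id]),
               tolerance = 1e-12)
  # subgroup decomposition: pooled lies inside the subgroup range
  by_sex <- subgroup_prevalence(cl, "sex")
  expect_gte(pooled, min(by_sex$prevalence) - 1e-12)
  expect_lte(pooled, max(by_sex$prevalence) + 1e-12)
  expect_error(subgroup_prevalence(cl, "shoe_size"), "unknown grouping")
})

test_that("a null covariate shows no gradient and a designed one does", {
  im <- null_item_model(0)
  cfg <- sim_config(n_countries = 5L, n_surveyed = 5L,
                    clusters_per_country = 40L, children_per_cluster = 30L,
                    seed = 31L, prevalence_link = list(a = 0.8, b = -0.8),
                    item_model = im, cluster_sd = 0, missing_rate = 0)
  cl <- classify_microdata(generate_microdata(generate_country_panel(cfg), cfg))
  by_stunt <- subgroup_prevalence(cl, "stunted")
  gap <- abs(diff(by_stunt$prevalence))
  expect_lt(gap, 4 * sqrt(sum(1 / by_stunt$n)))  # within sampling error

  # age fixture where 4-year-olds fail less
  im4 <- null_item_model(0)
  expect_true(all(im4$coef == 0))
  cfg4 <- small_sim_config(seed = 37L, prevalence_link = list(a = 0.9, b = -0.8),
                           cluster_sd = 0, missing_rate = 0)
  micro4 <- generate_microdata(generate_country_panel(cfg4), cfg4)
  cl4 <- classify_microdata(micro4)
  # overwrite the flags with a designed age gradient to test the estimator
  set.seed(99)
  p_by_age <- ifelse(cl4$age_years == 4, 0.25, 0.40)
  cl4$low_either <- stats::runif(nrow(cl4)) < p_by_age
  cl4$excluded <- FALSE
  by_age <- subgroup_prevalence(cl4, "age_years")
  p <- stats::setNames(by_age$prevalence, by_age$age_years)
  expect_lt(p[["4"]], p[["3"]])
})

test_that("stimulation scores and quintiles follow the weighted cut-points", {
  expect_equal(build_stimulation_quintiles(matrix(1, 1, 6))$raw_score, 6L)
  all0 <- build_stimulation_quintiles(rbind(rep(0, 6), rep(1, 6)))
  expect_equal(all0$raw_score, c(0L, 6L))
  expect_equal(all0$quintile[1], 1L)  # minimum score is always bottom quintile
  expect_gt(all0$quintile[2], all0$quintile[1])

  # uniform raw scores 0..6, equal weights: oracle boundaries {1,2,4,5}
  stim <- t(vapply(0:6, function(s) c(rep(1, s), rep(0, 6 - s)), numeric(6)))
  got <- build_stimulation_quintiles(stim)
  w <- rep(1, 7)
  cuts <- vapply(c(.2, .4, .6, .8), function(p)
    brute_weighted_quantile(0:6, w, p), numeric(1))
  expect_equal(cuts, c(1, 2, 4, 5))
  expect_equal(got$quintile, 1L + rowSums(outer(0:6, cuts, `>`)))
  # ties sit in the lower quintile: a raw score equal to a cut stays below it
  expect_equal(got$quintile[got$raw_score == 1], 1L)
  expect_equal(got$quintile[got$raw_score == 4], 3L)

  # missing item: NA quintile, not an error
  stim_na <- rbind(c(1, 1, NA, 0, 0, 0), rep(1, 6))
  q <- build_stimulation_quintiles(stim_na)
  expect_true(is.na(q$quintile[1]))
})

test_that("point-biserial equals phi on a 2x2 table and vanishes under independence", {
  ident <- point_biserial(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(ident$r, 1, tolerance = 1e-12)

  # 2x2 counts low&1:30, low&0:10, notlow&1:20, notlow&0:40
  low <- c(rep(1, 40), rep(0, 60))
  cov <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  a <- 30; b <- 10; c_ <- 20; d <- 40
  phi <- (a * d - b * c_) / sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
  got <- point_biserial(low, cov)
  expect_equal(got$r, phi, tolerance = 1e-12)
  expect_lt(got$p_value, 0.01)

  set.seed(8)
  n <- 1e5
  indep <- point_biserial(stats::runif(n) < 0.35, stats::runif(n) < 0.5)
  expect_lt(abs(indep$r), 0.01)

  expect_error(point_biserial(c(1, 0, 1), c(1, 1, 1)), "constant")
})

test_that("country-level correlation is exact and permutation-invariant", {
  hdi <- seq(0.3, 0.9, length.out = 10)
  expect_equal(country_level_correlation(1 - hdi, hdi), -1, tolerance = 1e-12)
  set.seed(9)
  prev <- clamp01(1 - hdi + stats::rnorm(10, 0, 0.03))
  r1 <- country_level_correlation(prev, hdi)
  perm <- sample(10)
  expect_equal(country_level_correlation(prev[perm], hdi[perm]), r1,
               tolerance = 1e-14)
  expect_lt(r1, -0.9)
  expect_error(country_level_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("surveyed/unsurveyed comparison behaves under null, identity and separation", {
  set.seed(10)
  macro <- data.frame(surveyed = rep(c(TRUE, FALSE), each = 20),
                      hdi = rep(stats::runif(20), 2))
  same <- compare_country_groups(macro, "hdi")
  expect_equal(same$difference, 0, tolerance = 1e-14)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  macro2 <- data.frame(surveyed = rep(c(TRUE, FALSE), each = 20),
                       hdi = c(stats::rnorm(20, 0, 1), stats::rnorm(20, 10, 1)))
  expect_lt(compare_country_groups(macro2, "hdi")$p_value, 1e-3)
  expect_error(compare_country_groups(macro2, "gdp"), "not present")

  # null calibration: rejection rate near the nominal level
  rej <- vapply(seq_len(300), function(i) {
    m <- data.frame(surveyed = rep(c(TRUE, FALSE), each = 15),
                    hdi = stats::rnorm(30))
    compare_country_groups(m, "hdi")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
})
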