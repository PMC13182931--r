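test_that("effect specifications validate their parameterization", {
  expect_s3_class(effect_spec("zn", "quadratic", center = 5, curvature = 0.2),
                  "effect_spec")
  expect_error(effect_spec("zn", "linear"), "beta")
  expect_error(effect_spec("zn", "quadratic", center = 5, curvature = -1),
               "curvature")
  expect_error(effect_spec("zn", "quadratic", center = 5, curvature = 0.2,
                           beta = 1), "only")
  expect_error(effect_spec("zn", "null", beta = 1), "no parameters")
})

test_that("log hazard is the stated additive form", {
  expect_identical(log_hazard(c(a = 3), c(zn = 99), list(), c(a = 0)), 0)
  expect_equal(log_hazard(numeric(0), c(zn = 10),
                          list(effect_spec("zn", "linear", beta = 0.1)),
                          numeric(0)), 1.0)
  expect_equal(log_hazard(numeric(0), c(zn = 3),
                          list(effect_spec("zn", "quadratic", center = 5,
                                           curvature = 0.2)),
                          numeric(0)), 0.8)
  expect_equal(log_hazard(c(a = 2, b = -1), c(zn = 10),
                          list(effect_spec("zn", "linear", beta = 0.1)),
                          c(a = 0.5, b = 1)),
               0.5 * 2 - 1 + 1)
  expect_error(log_hazard(numeric(0), c(other = 1),
                          list(effect_spec("zn", "linear", beta = 1)),
                          numeric(0)), "unknown nutrient")
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_patients = 2), "n_patients")
  expect_error(cohort_config(diet_missing_rate = 1.2), "diet_missing_rate")
  expect_error(cohort_config(follow_up_horizon = 4, window_length = 6),
               "follow_up_horizon")
  expect_error(cohort_config(baseline_hazard = list(shape = 1, scale = -1)),
               "baseline_hazard")
  expect_error(cohort_config(effect_specs = list(
    effect_spec("nope", "linear", beta = 1))), "nope")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_patients = 60, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$visits, b$visits)
  expect_identical(a$diets, b$diets)
  expect_identical(a$outcomes, b$outcomes)
})

test_that("cohort tables are structurally consistent", {
  ch <- generate_cohort(cohort_config(n_patients = 100, seed = 7))
  expect_equal(nrow(ch$baseline), 100)
  expect_true(all(ch$visits$patient_id %in% ch$baseline$patient_id))
  expect_true(all(ch$diets$patient_id %in% ch$baseline$patient_id))
  expect_true(all(ch$outcomes$tend > ch$outcomes$t0))
  expect_true(all(ch$outcomes$omega %in% c(0L, 1L)))
  # cohort round-trips through CSV
  d <- tempfile()
  write_cohort(ch, d)
  back <- read_cohort(d)
  expect_equal(back$outcomes$tend, ch$outcomes$tend)
  expect_equal(back$diets$zn, ch$diets$zn)
})

test_that("observed death fraction matches the integrated survival function", {
  labs0 <- lab_panel()
  labs0$gamma <- 0  # no confounder hazard: every patient has log HR 0
  cfg <- cohort_config(n_patients = 5000, seed = 11, labs = labs0,
                       baseline_hazard = list(shape = 1, scale = 300),
                       follow_up_horizon = 24, window_length = 6,
                       censor_rate = 0)
  ch <- generate_cohort(cfg)
  # numeric-integration oracle: P(T < h) = int_0^h h0(t) exp(-H0(t)) dt
  h0 <- function(t) (1 / 300) * exp(-t / 300)
  p <- integrate(h0, 0, 24, rel.tol = 1e-10)$value
  obs <- mean(ch$outcomes$omega)
  se <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(obs - p), 2 * se + 1e-12)
})

test_that("event-time sampler honours proportional hazards", {
  expect_error(sample_event_time(Inf, list(shape = 1, scale = 10)), "finite")
  expect_error(sample_event_time(0, list(shape = 1, scale = -2)), "positive")
  set.seed(42)
  bh <- list(shape = 1, scale = 20)
  t0 <- sample_event_time(rep(0, 1e5), bh)$time
  t1 <- sample_event_time(rep(log(2), 1e5), bh)$time
  expect_lt(abs(mean(t0) - 20), 2 * 20 / sqrt(1e5))
  expect_lt(abs(mean(t1) - 10), 2 * 10 / sqrt(1e5))
  expect_true(all(sample_event_time(rep(0, 100), bh, horizon = 5)$time <= 5))
})

test_that("analytic protective intervals match their definitions", {
  expect_null(true_protective_interval(effect_spec("x", "null"), 5, 1))
  qi <- true_protective_interval(
    effect_spec("x", "quadratic", center = 5, curvature = 0.2),
    intake_mean = 5, intake_sd = 1, lower = -Inf)
  expect_equal(qi, c(4, 6), tolerance = 1e-6)
  li <- true_protective_interval(effect_spec("x", "linear", beta = 0.3),
                                 intake_mean = 10, intake_sd = 2, lower = 0)
  expect_equal(li[2], 10, tolerance = 1e-6)
  ld <- true_protective_interval(effect_spec("x", "linear", beta = -0.3),
                                 intake_mean = 10, intake_sd = 2, lower = 0)
  expect_equal(ld, c(10, Inf), tolerance = 1e-6)
})

test_that("analytic interval agrees with a Monte-Carlo threshold estimate", {
  es <- effect_spec("x", "quadratic", center = 6, curvature = 0.1)
  iv <- true_protective_interval(es, intake_mean = 8, intake_sd = 2, lower = 0)
  set.seed(5)
  # rejection-sampled truncated normal draws
  x <- rnorm(4e5, 8, 2); x <- x[x >= 0]
  tau <- mean(0.1 * (x - 6)^2)
  grid <- seq(0, 20, by = 0.005)
  inside <- grid[0.1 * (grid - 6)^2 < tau]
  expect_lt(abs(min(inside) - iv[1]), 0.02)
  expect_lt(abs(max(inside) - iv[2]), 0.02)
})

test_that("realized missingness matches the configured rates", {
  cfg <- cohort_config(n_patients = 1000, seed = 9)
  ch <- generate_cohort(cfg)
  # diet records: fraction of scheduled visits without a diet record
  n_sched <- nrow(ch$visits)
  p <- cfg$diet_missing_rate
  obs <- 1 - nrow(ch$diets) / n_sched
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n_sched))
  # per-feature lab missingness among post-baseline visits
  post <- ch$visits$month > 0
  for (nm in c("albumin", "hs_crp", "serum_cl")) {
    r <- cfg$labs$missing_rate[cfg$labs$name == nm]
    obs <- mean(is.na(ch$visits[[nm]][post]))
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / sum(post)))
  }
})
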