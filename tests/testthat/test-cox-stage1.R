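test_that("Cox fitter rejects degenerate inputs", {
  expect_error(fit_cox(c(1, 2), c(0, 0), matrix(1:2)), "no events")
  expect_error(fit_cox(c(1, 2, 3), c(1, 1, 0),
                       matrix(c(1, 1, 1), dimnames = list(NULL, "k"))),
               "constant")
  expect_error(fit_cox(c(1, 2), c(1, 1), matrix(c(1, NA), ncol = 1)),
               "finite")
})

test_that("a symmetric design gives a zero coefficient", {
  # two tied deaths at each time, opposite covariates: data are invariant
  # under x -> 1 - x, so the Efron partial likelihood peaks at beta = 0
  fit <- fit_cox(c(1, 1, 2, 2), c(1, 1, 1, 1),
                 matrix(c(1, 0, 1, 0), ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
})

test_that("Cox MLE matches a brute-force partial-likelihood grid search", {
  # distinct event times: Breslow and Efron coincide, so the hand-written
  # partial likelihood is an exact oracle
  time <- c(3, 1, 4, 2, 5)
  status <- c(1, 1, 1, 1, 1)
  x <- c(0.5, -1.2, 2.0, 0.3, -0.7)
  grid <- seq(-3, 3, by = 1e-4)
  pl <- vapply(grid, brute_pl, numeric(1), time = time, status = status, x = x)
  b_oracle <- grid[which.max(pl)]
  fit <- fit_cox(time, status, matrix(x, dimnames = list(NULL, "x")))
  expect_lt(abs(unname(fit$coef) - b_oracle), 1e-4)

  # censored variant
  status2 <- c(1, 0, 1, 1, 0)
  pl2 <- vapply(grid, brute_pl, numeric(1), time = time, status = status2, x = x)
  fit2 <- fit_cox(time, status2, matrix(x, dimnames = list(NULL, "x")))
  expect_lt(abs(unname(fit2$coef) - grid[which.max(pl2)]), 1e-4)
})

test_that("estimates recover a known hazard coefficient with nominal coverage", {
  set.seed(17)
  cover <- logical(200)
  for (r in seq_len(200)) {
    x <- rnorm(500)
    t <- rexp(500, 0.05 * exp(0.5 * x))
    fit <- fit_cox(t, rep(1, 500), matrix(x, dimnames = list(NULL, "x")))
    se <- sqrt(fit$vcov[1, 1])
    cover[r] <- abs(fit$coef[1] - 0.5) <= 1.96 * se
  }
  expect_gt(mean(cover), 0.95 - 2 * sqrt(0.95 * 0.05 / 200))
  expect_lt(mean(cover), 0.95 + 2 * sqrt(0.95 * 0.05 / 200))
})

test_that("hazard ratios transform exactly under unit scaling and shifts", {
  set.seed(4)
  ch <- generate_cohort(cohort_config(n_patients = 200, seed = 4))
  pr <- suppressWarnings(build_profiles(ch))
  h1 <- nutrient_hr(pr, "protein", confounders = c("albumin", "hb"),
                    unit_scale = 1)
  h10 <- nutrient_hr(pr, "protein", confounders = c("albumin", "hb"),
                     unit_scale = 10)
  expect_equal(log(h10$hr), 10 * log(h1$hr), tolerance = 1e-6)
  expect_equal(h10$p_wald, h1$p_wald, tolerance = 1e-8)
  # shifting a covariate leaves every HR unchanged
  pr2 <- pr
  pr2$albumin <- pr2$albumin + 100
  h_shift <- nutrient_hr(pr2, "protein", confounders = c("albumin", "hb"),
                         unit_scale = 1)
  expect_equal(h_shift$hr, h1$hr, tolerance = 1e-6)
})

test_that("small strata trigger an informative size error", {
  ch <- generate_cohort(cohort_config(n_patients = 60, seed = 2))
  pr <- suppressWarnings(build_profiles(ch))
  expect_error(nutrient_hr(pr, "protein", subset = 1:10),
               "confounder set")
})

test_that("risk scores are the centred exponentiated linear predictor", {
  X <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(risk_scores(c(x = 0), X), c(1, 1))
  expect_equal(risk_scores(c(x = 1), X), c(exp(-0.5), exp(0.5)))
  expect_error(risk_scores(c(z = 1), X), "absent")
  set.seed(6)
  Xr <- matrix(rnorm(200), 50, 4,
               dimnames = list(NULL, paste0("v", 1:4)))
  s <- risk_scores(setNames(rnorm(4), paste0("v", 1:4)), Xr)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-10)
})

test_that("risk pairs are a per-patient pass-through", {
  p <- build_risk_pairs(c(1, 2, 3), c(0.5, 1, 2), "zn")
  expect_equal(p$t, c(1, 2, 3))
  expect_equal(p$s, c(0.5, 1, 2))
  expect_equal(nrow(p), 3)
  expect_error(build_risk_pairs(numeric(0), numeric(0)), "empty")
  expect_error(build_risk_pairs(1:3, 1:2), "align")
})

test_that("U-shaped truth makes the score grow with distance from center", {
  set.seed(9)
  d <- sim_surv(1000, quad = list(center = 0, curvature = 0.5))
  d$patient_id <- seq_len(nrow(d))
  fit <- diet_response(d, "x", confounders = "z")
  rho <- cor(abs(fit$pairs$t), fit$pairs$s, method = "spearman")
  expect_gt(rho, 0)
})
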