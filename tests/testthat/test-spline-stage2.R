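test_that("knots land on the conventional percentiles", {
  expect_equal(choose_knots(0:100, k = 4), c(5, 35, 65, 95))
  expect_equal(choose_knots(0:100, k = 3), c(10, 50, 90))
  expect_error(choose_knots(rep(3, 50)), "distinct")
  expect_error(choose_knots(0:100, k = 6), "3, 4 or 5")
})

test_that("restricted basis vanishes below the first knot", {
  kn <- c(2, 4, 6, 8)
  B <- rcs_basis(c(0, 1, 1.9), kn)
  expect_true(all(B[, -1] == 0))
  expect_equal(B[, 1], c(0, 1, 1.9))
  expect_error(rcs_basis(c(1, NA), kn), "finite")
  expect_error(rcs_basis(1:3, c(5, 5, 6)), "strictly increasing")
})

test_that("fit of an exactly linear target has zero nonlinear coefficients", {
  set.seed(12)
  t <- sort(runif(50, 0, 10))
  pairs <- build_risk_pairs(t, exp(2 * t + 1))
  kn <- choose_knots(t)
  fit <- fit_spline(pairs, kn)
  cf <- fit$coefficients
  expect_equal(unname(cf["(Intercept)"]), 1, tolerance = 1e-8)
  expect_equal(unname(cf["x"]), 2, tolerance = 1e-8)
  expect_true(all(abs(cf[grep("^c", names(cf))]) < 1e-8))
  expect_equal(suppressWarnings(summary(fit$lm)$r.squared), 1,
               tolerance = 1e-10)
})

test_that("fitted curve is exactly linear beyond the boundary knots", {
  set.seed(13)
  t <- runif(300, 0, 10)
  y <- exp((t - 5)^2 / 10 + rnorm(300, 0, 0.05))
  fit <- fit_spline(build_risk_pairs(t, y))
  kn <- fit$knots
  for (gx in list(seq(min(t), kn[1], length.out = 30),
                  seq(kn[length(kn)], max(t), length.out = 30))) {
    g <- predict(fit, gx)
    expect_lt(max(abs(diff(diff(g)))), 1e-8)
  }
  # ... and curved between the knots
  mid <- seq(kn[2], kn[3], length.out = 30)
  expect_gt(max(abs(diff(diff(predict(fit, mid))))), 1e-6)
})

test_that("spline fit is invariant to pair order and recovers a minimum", {
  set.seed(14)
  t <- runif(500, 0, 10)
  s <- exp((t - 5)^2 / 10 + rnorm(500, 0, 0.05))
  pairs <- build_risk_pairs(t, s)
  kn <- choose_knots(t)
  fit <- fit_spline(pairs, kn)
  perm <- sample(500)
  fit_p <- fit_spline(build_risk_pairs(t[perm], s[perm]), kn)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-10)
  gx <- seq(min(t), max(t), length.out = 400)
  expect_lt(abs(gx[which.min(predict(fit, gx))] - 5), 0.3)
})

test_that("nested F-tests separate linear from nonlinear signals", {
  set.seed(15)
  t <- runif(200, 0, 10)
  # noiseless linear target: zero nonlinear F by the nesting identity
  lin <- anova_nonlinearity(build_risk_pairs(t, exp(0.3 * t)))
  expect_equal(lin$p_nonlinear, 1)
  # strong curvature: decisively nonlinear
  s <- exp((t - 5)^2 / 5 + rnorm(200, 0, 0.05))
  quad <- anova_nonlinearity(build_risk_pairs(t, s))
  expect_lt(quad$p_nonlinear, 1e-6)
  expect_lt(quad$p_overall, 1e-6)
  # pure noise: neither test should fire decisively
  s0 <- exp(rnorm(200, 0, 0.1))
  nul <- anova_nonlinearity(build_risk_pairs(t, s0))
  expect_true(nul$p_nonlinear >= 0 && nul$p_nonlinear <= 1)
})

test_that("protective ranges match analytic crossings of known curves", {
  set.seed(16)
  # U-shaped curve g(x) = (x-2)(x-4)/4 on [0,6]; with the centring over
  # the uniform intake distribution the protective set is where
  # g(x) < E[g(X)] = 0.5, i.e. x^2 - 6x + 6 < 0 -> (3 - sqrt(3), 3 + sqrt(3))
  t <- seq(0, 6, length.out = 600)
  s <- exp((t - 2) * (t - 4) / 4 + rnorm(600, 0, 0.01))
  fit <- fit_spline(build_risk_pairs(t, s))
  rng <- extract_ranges(fit)
  expect_lt(abs(rng$A - (3 - sqrt(3))), 0.1)
  expect_lt(abs(rng$B - (3 + sqrt(3))), 0.1)
  expect_true(is.na(rng$C))

  # monotone decreasing g(x) = 3 - x on [0,10]: E[g] = -2, protective set
  # is the upper half-line above x = 5, so B is absent
  t2 <- seq(0, 10, length.out = 500)
  s2 <- exp(3 - t2 + rnorm(500, 0, 0.01))
  rng2 <- extract_ranges(fit_spline(build_risk_pairs(t2, s2)))
  expect_lt(abs(rng2$A - 5), 0.1)
  expect_true(is.na(rng2$B))

  # flat curve: hazard ratio identically 1, protective set empty
  s3 <- rep(1, 500)
  rng3 <- extract_ranges(fit_spline(build_risk_pairs(t2, s3)))
  expect_true(is.na(rng3$A) && is.na(rng3$B) && is.na(rng3$C))
})

test_that("reported components bracket exactly the sub-unity grid region", {
  set.seed(18)
  t <- runif(400, 0, 10)
  s <- exp(sin(t / 2) + rnorm(400, 0, 0.05))
  fit <- fit_spline(build_risk_pairs(t, s))
  rng <- suppressWarnings(extract_ranges(fit))
  crv <- rng$curve
  if (nrow(rng$components)) {
    for (i in seq_len(nrow(rng$components))) {
      inside <- crv$x > rng$components[i, 1] & crv$x < rng$components[i, 2]
      expect_true(all(crv$hr[inside] < 1))
    }
    outside <- rep(TRUE, nrow(crv))
    for (i in seq_len(nrow(rng$components)))
      outside <- outside & !(crv$x >= rng$components[i, 1] &
                             crv$x <= rng$components[i, 2])
    # outside points may only dip below 1 inside suppressed slivers
    expect_lt(mean(crv$hr[outside] < 1), 0.05)
  }
  expect_error(fit_spline(build_risk_pairs(c(1, 2, 3), c(1, 1, 1)),
                          knots = c(1, 2, 3)), "k \\+ 2|distinct|pairs")
})
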