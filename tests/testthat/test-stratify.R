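test_that("tertile split partitions at the 1/3 and 2/3 quantiles", {
  a <- tertile_split(1:9)
  expect_equal(as.character(a$group),
               rep(c("low", "medium", "high"), each = 3))
  expect_error(tertile_split(c(1, 2)), "at least 3")
  expect_warning(a2 <- tertile_split(rep(5, 10)), "degenerate")
  expect_true(all(a2$group == "medium"))
})

test_that("tertile assignment is invariant to permutation and near-balanced", {
  set.seed(21)
  v <- rnorm(656, 37, 5)
  a <- tertile_split(v, ids = seq_along(v))
  perm <- sample(656)
  b <- tertile_split(v[perm], ids = seq_along(v)[perm])
  m <- match(a$patient_id, b$patient_id)
  expect_identical(as.character(a$group), as.character(b$group[m]))
  sizes <- sort(as.integer(table(a$group)))
  expect_true(all(abs(sizes - sort(c(219, 219, 218))) <= 1))
})

test_that("group comparisons match closed-form ANOVA and chi-square", {
  prof <- data.frame(patient_id = 1:9,
                     v = rep(c(1, 2, 3), 3),
                     stringsAsFactors = FALSE)
  asg <- data.frame(patient_id = 1:9,
                    group = factor(rep(c("low", "medium", "high"), each = 3),
                                   levels = c("low", "medium", "high")))
  class(asg) <- c("subtype_assignment", "data.frame")
  cmp <- compare_groups(prof, asg, "v")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)

  # widely separated groups with tiny jitter: compare F to the closed form
  set.seed(2)
  jit <- rnorm(12, 0, 1e-3)
  prof2 <- data.frame(patient_id = 1:12,
                      v = rep(c(0, 10, 20), each = 4) + jit)
  asg2 <- data.frame(patient_id = 1:12,
                     group = factor(rep(c("low", "medium", "high"), each = 4),
                                    levels = c("low", "medium", "high")))
  cmp2 <- compare_groups(prof2, asg2, "v")
  g <- rep(1:3, each = 4)
  gm <- tapply(prof2$v, g, mean)
  ssb <- sum(4 * (gm - mean(prof2$v))^2)
  ssw <- sum((prof2$v - gm[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(cmp2$statistic, f_oracle, tolerance = 1e-8)
  expect_lt(cmp2$p, 1e-6)
  expect_named(cmp2$pairwise)

  # balanced contingency table with equal proportions: chi-square 0
  prof3 <- data.frame(patient_id = 1:12,
                      v = rep(c("a", "b"), 6), stringsAsFactors = FALSE)
  cmp3 <- compare_groups(prof3, asg2, "v")
  expect_equal(cmp3$statistic, 0)
  expect_equal(cmp3$p, 1)
})

test_that("constant data yields p = 1 with a warning", {
  prof <- data.frame(patient_id = 1:6, v = rep(4, 6))
  asg <- data.frame(patient_id = 1:6,
                    group = factor(rep(c("low", "high"), each = 3),
                                   levels = c("low", "medium", "high")))
  expect_warning(cmp <- compare_groups(prof, asg, "v"), "variance")
  expect_equal(cmp$p, 1)
})

test_that("Kaplan-Meier and log-rank behave on degenerate designs", {
  # identical survival experience in all 3 groups
  t <- rep(c(2, 4, 6, 8), 3)
  s <- rep(c(1, 0, 1, 1), 3)
  g <- rep(c("low", "medium", "high"), each = 4)
  km <- km_logrank(t, s, g)
  expect_lt(km$chisq, 1e-10)
  expect_equal(km$p, 1, tolerance = 1e-8)
  # no events: survival identically 1
  km2 <- km_logrank(c(1, 2, 3), c(0, 0, 0), rep("a", 3))
  expect_true(all(km2$curves$survival == 1))
  expect_error(km_logrank(c(0, 1), c(1, 1), c("a", "b")), "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(8)
  t <- rexp(40, 0.1)
  km <- km_logrank(t, rep(1, 40), rep("a", 40))
  emp <- vapply(km$curves$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$curves$survival, emp, tolerance = 1e-12)
})

test_that("log-rank detects a doubled hazard", {
  set.seed(31)
  rej <- mean(replicate(100, {
    t1 <- rexp(500, 0.05); t2 <- rexp(500, 0.10)
    km <- km_logrank(c(t1, t2), rep(1, 1000),
                     rep(c("a", "b"), each = 500))
    km$p < 0.05
  }))
  expect_gt(rej, 0.95)
})
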