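test_that("stack_long counts records and drops missing values", {
  set.seed(2)
  wide <- data.frame(subject = sprintf("S%02d", 1:50),
                     group = rep(c("control", "LBP"), each = 25),
                     m1 = rnorm(50), m2 = rnorm(50),
                     m3 = rnorm(50), m4 = rnorm(50))
  long <- stack_long(wide, c("m1", "m2", "m3", "m4"))
  expect_equal(nrow(long), 200)
  expect_equal(attr(long, "n_dropped"), 0)
  wide2 <- wide
  wide2$m1[1:7] <- NA; wide2$m2[1:3] <- NA; wide2$m4[1:3] <- NA
  long2 <- stack_long(wide2, c("m1", "m2", "m3", "m4"))
  expect_equal(nrow(long2), 187)
  expect_equal(attr(long2, "n_dropped"), 13)
  expect_error(stack_long(wide, character(0)), "empty")
  expect_error(stack_long(wide, c("m1", "nope")), "nope")
})

test_that("balanced two-test contrasts equal group mean differences", {
  # noiseless data: exact per-cell solution, flagged singular
  long0 <- simulate_outcome_table(6, c("a", "b"),
                                  effects = c(a = 1.5, b = -2),
                                  subject_sd = 0, residual_sd = 0,
                                  seed = 4)
  f0 <- fit_group_model(long0)
  expect_true(f0$singular)
  expect_equal(unname(coef(f0)), c(1.5, -2), tolerance = 1e-9)
  expect_equal(estimates(f0)$se, c(0, 0))

  # noisy but balanced and complete: the mixed-model contrast equals the
  # plain per-test difference in group means
  long <- simulate_outcome_table(12, c("a", "b"),
                                 effects = c(a = 0.5, b = 2),
                                 subject_sd = 0.8, residual_sd = 1,
                                 seed = 7)
  f <- fit_group_model(long)
  expect_equal(unname(coef(f)), unname(oracle_mean_diffs(long)),
               tolerance = 1e-6)
})

test_that("homogeneous and per-test-variance engines agree on balanced
           equal-variance data", {
  long <- simulate_outcome_table(15, c("a", "b", "c"),
                                 effects = c(a = 0, b = 1, c = 2),
                                 subject_sd = 0.6, residual_sd = 1,
                                 seed = 21)
  f1 <- mvmm(value ~ group, long)
  f2 <- mvmm(value ~ group, long, var_by_test = TRUE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-3)
  expect_equal(estimates(f1)$se, estimates(f2)$se, tolerance = 0.05)
})

test_that("estimates are invariant to row order of the long table", {
  long <- simulate_outcome_table(10, c("a", "b", "c"),
                                 effects = c(a = 1, b = 0, c = -1),
                                 seed = 33)
  f1 <- fit_group_model(long)
  set.seed(1)
  f2 <- fit_group_model(long[sample(nrow(long)), ])
  expect_equal(estimates(f1)$beta, estimates(f2)$beta, tolerance = 1e-10)
  expect_equal(estimates(f1)$se, estimates(f2)$se, tolerance = 1e-10)
})

test_that("confidence intervals bracket the estimate symmetrically", {
  long <- simulate_outcome_table(10, c("a", "b"), effects = c(a = 0, b = 1),
                                 seed = 5)
  f <- fit_group_model(long)
  est <- estimates(f)
  expect_true(all(est$ci_low <= est$beta & est$beta <= est$ci_high))
  expect_equal(est$ci_high - est$beta, est$beta - est$ci_low,
               tolerance = 1e-9)
  expect_equal(est$ci_high - est$ci_low, 2 * qnorm(0.975) * est$se,
               tolerance = 1e-9)
  ci <- confint(f)
  expect_equal(unname(ci[, 1]), est$ci_low)
})

test_that("association models recover planted slopes; constant predictor
           is rejected", {
  set.seed(61)
  n <- 40
  subjects <- sprintf("S%02d", 1:n)
  pred <- data.frame(subject = subjects, score = runif(n, 0, 10))
  u <- rnorm(n, 0, 0.5)
  long <- do.call(rbind, lapply(c("m1", "m2"), function(m) {
    b <- if (m == "m1") 0.8 else 0
    data.frame(subject = subjects, group = "all", test = m,
               value = 2 + b * pred$score + u + rnorm(n, 0, 0.5))
  }))
  f <- fit_association_model(long, pred, "score")
  est <- estimates(f)
  expect_lt(abs(est$beta[est$test == "m1"] - 0.8), 0.15)
  expect_true(est$ci_low[est$test == "m1"] <= 0.8 &
              0.8 <= est$ci_high[est$test == "m1"])
  expect_gt(est$p[est$test == "m2"], 0.05)

  predc <- data.frame(subject = subjects, score = 5)
  expect_error(fit_association_model(long, predc, "score"), "variance")
  expect_error(fit_association_model(long, pred, "nope"), "nope")
})

test_that("stratified refits expose planted slope heterogeneity", {
  set.seed(91)
  n <- 30
  subjects <- sprintf("S%02d", 1:(2 * n))
  groups <- data.frame(subject = subjects,
                       group = rep(c("control", "LBP"), each = n))
  pred <- data.frame(subject = subjects, score = runif(2 * n, 0, 10))
  slope <- ifelse(groups$group == "LBP", 1.2, 0)   # LBP-only association
  long <- do.call(rbind, lapply(c("m1", "m2"), function(m) {
    data.frame(subject = subjects, group = groups$group, test = m,
               value = 1 + slope * pred$score + rnorm(2 * n, 0, 0.8))
  }))
  pooled <- fit_association_model(long, pred, "score")
  expect_lt(min(estimates(pooled)$p), 0.05)   # gate passes
  # no subject intercept is planted here, so singular fits are expected
  in_lbp <- suppressWarnings(
    stratified_association(long, pred, "score", groups, "LBP"))
  in_ctl <- suppressWarnings(
    stratified_association(long, pred, "score", groups, "control"))
  expect_lt(max(abs(coef(in_lbp) - 1.2)), 0.3)
  expect_true(all(estimates(in_lbp)$p < 0.05))
  expect_true(all(estimates(in_ctl)$p > 0.05))
  expect_lt(max(abs(coef(in_ctl))), 0.3)
  # a homogeneous slope is recovered in both strata
  long2 <- long
  long2$value <- 1 + 0.9 * pred$score[match(long2$subject, subjects)] +
    rnorm(nrow(long2), 0, 0.8)
  both <- lapply(c("control", "LBP"), function(g) {
    coef(suppressWarnings(
      stratified_association(long2, pred, "score", groups, g)))
  })
  expect_true(all(abs(unlist(both) - 0.9) < 0.3))
  # subgroup too small
  tiny <- groups[c(1, 2, n + 1), ]
  expect_error(stratified_association(long, pred, "score", tiny,
                                      "control"), "fewer than 3")
})

test_that("predictors must be two-level factors or varying numerics", {
  long <- simulate_outcome_table(5, c("a", "b"), seed = 2)
  long3 <- long
  long3$group <- as.character(long3$group)
  long3$group[1:3] <- "other"
  expect_error(mvmm(value ~ group, long3), "2 observed levels")
})

test_that("render_tables bolds below alpha and applies multipliers", {
  est <- data.frame(test = c("tpd", "vibration"),
                    beta = c(0.425, 1), se = c(0.210, 0.5),
                    ci_low = c(0.015, 0.02), ci_high = c(0.835, 1.98),
                    p = c(0.049, 0.051))
  tab <- render_tables(est)
  expect_match(tab$p[1], "^\\*\\*")       # 0.049: bold
  expect_false(grepl("\\*\\*", tab$p[2])) # 0.051: not bold
  # two-point discrimination reported per 5 mm step
  tab5 <- render_tables(est, multipliers = c(tpd = 5))
  expect_match(tab5$beta_se[1], "2.125")
  expect_match(tab5$beta_se[2], "1.000")
  empty <- render_tables(data.frame(test = character(0),
                                    beta = numeric(0), se = numeric(0),
                                    ci_low = numeric(0),
                                    ci_high = numeric(0), p = numeric(0)))
  expect_equal(nrow(empty), 0)
  one <- render_tables(est[1, ])
  expect_equal(nrow(one), 1)
})
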