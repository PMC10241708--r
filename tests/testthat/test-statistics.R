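test_that("median dichotomization sends ties low and balances groups", {
  g <- dichotomize(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  g2 <- dichotomize(c(5, 5, 5, 9))
  expect_identical(as.character(g2), c("low", "low", "low", "high"))
  expect_equal(attr(g2, "cutoff"), 5)
  # near-balance for distinct continuous draws
  set.seed(61)
  g3 <- dichotomize(runif(1000))
  expect_lte(abs(sum(g3 == "low") - sum(g3 == "high")), 1)
  expect_error(dichotomize(c(NA_real_, NA_real_)), "missing")
})

test_that("spearman handles perfect monotone association and the exact case", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  s1 <- spearman(x, x * 2 + 1)
  expect_equal(s1$rho, 1)
  s2 <- spearman(x, -x)
  expect_equal(s2$rho, -1)

  # 8-pair fixture: rho equals Pearson on ranks, p equals the full 8!
  # permutation enumeration
  y <- c(2.1, 0.4, 3.3, 2.0, 5.1, 0.9, 4.0, 3.1)
  s <- spearman(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)))
  expect_equal(s$p, spearman_perm(x, y), tolerance = 1e-10)
  expect_identical(s$method, "exact")

  expect_warning(s0 <- spearman(rep(1, 6), 1:6), "constant")
  expect_true(is.na(s0$rho))
})

test_that("group tests separate extreme groups and dispatch on group count", {
  v <- c(1:10, 100:110)
  g <- rep(c("a", "b"), c(10, 11))
  r <- group_tests(v, g)
  expect_identical(r$test, "mann-whitney")
  expect_lt(r$p, 0.001)
  expect_equal(r$statistic, 0)   # U = 0 for full separation

  set.seed(62)
  r3 <- group_tests(rnorm(60), rep(c("a", "b", "c"), 20))
  expect_identical(r3$test, "kruskal-wallis")
  expect_gt(r3$p, 0)
  expect_error(group_tests(1:5, rep("a", 5)), "2 non-empty groups")
})

test_that("null group tests hold their size", {
  set.seed(63)
  rej <- mean(replicate(400, {
    v <- rnorm(40)
    group_tests(v, sample(rep(c("a", "b"), 20)))$p < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  t <- c(3, 1, 4, 2, 6, 5)
  kl <- km_logrank(t, rep(1, 6), rep("a", 6))
  s <- summary(kl$fit)
  expect_equal(s$surv, 1 - seq_len(6) / 6)
  # identical groups: chi-square 0, p 1
  kl2 <- km_logrank(rep(t, 2), rep(1, 12), rep(c("a", "b"), each = 6))
  expect_equal(kl2$chisq, 0, tolerance = 1e-12)
  expect_equal(kl2$p, 1)
  # no events: flagged undefined
  expect_warning(kl3 <- km_logrank(t, rep(0, 6), rep(c("a", "b"), 3)), "no events")
  expect_true(is.na(kl3$p))
})

test_that("log-rank matches the hand-computed observed/expected table", {
  # 6 subjects, 3 per group, all events, no ties:
  # group a dies at 1, 3, 5; group b dies at 2, 4, 6.
  # At each event time t_i with n at risk and 1 death, E_a = n_a / n:
  # E_a = 3/6 + 2/5 + 2/4 + 1/3 + 1/2 + 0/1 = 2.2333...; O_a = 3
  # V = sum n_a*n_b*(n-1)... for single deaths: n_a*n_b/n^2 * 1 each
  time <- 1:6
  event <- rep(1, 6)
  group <- rep(c("a", "b"), 3)
  e_a <- 3/6 + 2/5 + 2/4 + 1/3 + 1/2 + 0
  v_a <- (3*3)/36 + (2*3)/25 + (2*2)/16 + (1*2)/9 + (1*1)/4 + 0
  chisq_hand <- (3 - e_a)^2 / v_a
  kl <- km_logrank(time, event, group)
  expect_equal(kl$chisq, chisq_hand, tolerance = 1e-10)
  # invariant under group relabeling
  kl_swap <- km_logrank(time, event, rev(group))
  expect_equal(kl$chisq, kl_swap$chisq, tolerance = 1e-12)
})

test_that("Cox fit equals the brute-force partial-likelihood maximizer", {
  # 8 subjects, one binary covariate, no ties
  time <- c(2, 4, 5, 7, 9, 11, 14, 17)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  fit <- cox_fit(time, event, x)
  expect_equal(fit$table$coef[1], cox_brute(time, event, x), tolerance = 1e-6)
  # identical survival in both groups -> HR 1
  t2 <- rep(c(1, 2, 3, 4), 2); e2 <- rep(1, 8); g2 <- rep(c(0, 1), each = 4)
  f2 <- cox_fit(t2, e2, g2)
  expect_equal(f2$table$HR[1], 1, tolerance = 1e-6)
  expect_gt(f2$table$p[1], 0.95)
})

test_that("Cox partial likelihood is invariant to dataset duplication", {
  set.seed(64)
  co <- generate_cohort(120, true_log_hr = log(2), censoring_rate = 0.2, seed = 65)
  x <- as.integer(co$group == "high")
  f1 <- cox_fit(co$time, co$event, x)
  f2 <- cox_fit(rep(co$time, 2), rep(co$event, 2), rep(x, 2))
  expect_equal(f2$table$coef[1], f1$table$coef[1], tolerance = 1e-8)
  expect_equal(f2$table$se[1], f1$table$se[1] / sqrt(2), tolerance = 0.01)
})

test_that("Cox errors are explicit for no events and separation", {
  expect_error(cox_fit(1:5, rep(0, 5), rep(0:1, length.out = 5)), "no events")
  # complete separation: all events in one group, late in the other
  tt <- c(1, 2, 3, 4, 100, 110, 120, 130)
  ee <- c(1, 1, 1, 1, 1, 1, 1, 1)
  xx <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_error(cox_fit(tt, ee, xx), "converge|infinite")
})

test_that("multivariable Cox reports each term against its reference", {
  co <- generate_cohort(300, true_log_hr = log(2.5), censoring_rate = 0.3, seed = 66)
  f <- cox_fit(co$time, co$event,
               data.frame(size = dichotomize(co$size_um), grade = co$grade,
                          nodal = co$nodal_status))
  expect_identical(nrow(f$table), 4L)  # size, grade2, grade3, nodal N1
  expect_true(all(f$table$ci_low < f$table$HR & f$table$HR < f$table$ci_high))
  expect_true(all(f$table$HR > 0))
})

test_that("subgroup forest reduces to the univariable fit and flags gaps", {
  co <- generate_cohort(200, true_log_hr = log(2), censoring_rate = 0.3, seed = 67)
  co$metric_group <- dichotomize(co$size_um)
  whole <- subgroup_forest(co, "metric_group")
  uni <- cox_fit(co$time, co$event, data.frame(metric_group = co$metric_group))
  expect_equal(whole$HR, uni$table$HR[1])
  expect_equal(whole$p, uni$table$p[1])

  # a subgroup without events is not estimable
  sub <- list(dead = co$event == 1, none = co$event == 0)
  ft <- subgroup_forest(co, "metric_group", sub)
  expect_true(ft$estimable[ft$subgroup == "dead"])
  expect_false(ft$estimable[ft$subgroup == "none"])
  expect_true(is.na(ft$HR[ft$subgroup == "none"]))
})

test_that("effects injected in one stratum stay in that stratum", {
  hrs <- sapply(1:8, function(s) {
    coA <- generate_cohort(250, true_log_hr = log(3), censoring_rate = 0.2,
                           seed = 700 + s)
    coB <- generate_cohort(250, true_log_hr = 0, censoring_rate = 0.2,
                           seed = 900 + s)
    coA$stratum <- "A"; coB$stratum <- "B"
    coB$case_id <- paste0(coB$case_id, "b")
    co <- rbind(coA, coB)
    co$metric_group <- factor(c(as.character(dichotomize(coA$size_um)),
                                as.character(dichotomize(coB$size_um))),
                              levels = c("low", "high"))
    ft <- subgroup_forest(co, "metric_group",
                          list(A = co$stratum == "A", B = co$stratum == "B"))
    ft$HR
  })
  expect_lt(abs(mean(hrs[1, ]) - 3) / 3, 0.2)   # stratum A near truth
  expect_lt(abs(mean(hrs[2, ]) - 1), 0.2)       # stratum B near null
})
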