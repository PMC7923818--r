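test_that("Fisher's exact test reproduces printed cohort-table p-values", {
  expect_equal(round(fisher_exact_2x2(2, 8, 13, 20)$p_value, 2), 0.45)
  expect_equal(round(fisher_exact_2x2(2, 10, 13, 18)$p_value, 2), 0.16)
  expect_equal(round(fisher_exact_2x2(1, 4, 14, 24)$p_value, 2), 0.64)
  expect_equal(fisher_exact_2x2(1, 1, 14, 27)$p_value, 1)
  expect_equal(round(fisher_exact_2x2(0, 3, 15, 25)$p_value, 2), 0.54)
})

test_that("Fisher matches full-support enumeration for all margins up to N = 20", {
  enum_fisher <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    support <- max(0, r1 + c1 - n):min(r1, c1)
    logp <- vapply(support, function(x) {
      lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
    }, numeric(1))
    obs <- logp[support == a]
    sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  }
  for (n in 2:20) {
    for (r1 in 0:n) {
      for (c1 in 0:n) {
        for (a in max(0, r1 + c1 - n):min(r1, c1)) {
          b <- r1 - a; c <- c1 - a; d <- n - r1 - c1 + a
          res <- fisher_exact_2x2(a, b, c, d)
          if (res$degenerate) {
            expect_equal(res$p_value, 1)
          } else {
            expect_equal(res$p_value, min(enum_fisher(a, b, c, d), 1),
                         tolerance = 1e-12)
          }
        }
      }
    }
  }
})

test_that("chi-squared statistic, tail and independence boundary", {
  res <- chi_squared_2x2(4, 18, 11, 10)
  expect_equal(round(res$p_value, 2), 0.02)
  # ad = bc gives zero statistic and p = 1
  indep <- chi_squared_2x2(2, 4, 3, 6)
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p_value, 1)
  # upper tail against numeric integration of the 1-df density
  for (stat in c(0.5, 2.3, 5.4)) {
    quad <- integrate(function(x) dchisq(x, df = 1), stat, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(pchisq(stat, 1, lower.tail = FALSE), quad,
                 tolerance = 1e-10)
  }
  # reference implementation agreement
  ref <- chisq.test(matrix(c(4, 18, 11, 10), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  yates <- chi_squared_2x2(4, 18, 11, 10, continuity = TRUE)
  ref_y <- chisq.test(matrix(c(4, 18, 11, 10), 2, byrow = TRUE))
  expect_equal(yates$statistic, unname(ref_y$statistic), tolerance = 1e-12)
  expect_error(chi_squared_2x2(0, 0, 3, 4), "margin")
})

test_that("Welch t from summaries matches raw-data Welch tests", {
  res <- welch_t_from_summary(15, 62.3, 13.1, 28, 64.4, 12.8)
  expect_equal(round(res$p_value, 2), 0.62)
  # construct raw data with exactly the requested summaries
  make <- function(n, mean, sd) {
    z <- scale(rnorm(n))[, 1]
    mean + sd * z
  }
  set.seed(2)
  x <- make(15, 62.3, 13.1)
  y <- make(28, 64.4, 12.8)
  ref <- t.test(x, y)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  # equal summaries: t = 0, p = 1
  eq <- welch_t_from_summary(10, 5, 1, 12, 5, 1)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(welch_t_from_summary(1, 0, 1, 5, 0, 1), "n >= 2")
})

test_that("Wilcoxon exact branch and its boundary behaviour", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  same <- wilcoxon_rank_sum(c(1, 2, 5, 9), c(1, 2, 5, 9))
  expect_equal(same$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # exact and approximate branches agree near the size boundary
  set.seed(9)
  diffs <- vapply(1:100, function(i) {
    x <- rnorm(6)
    y <- rnorm(6, 0.5)
    exact_p <- wilcox.test(x, y, exact = TRUE)$p.value
    approx_p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    abs(exact_p - approx_p)
  }, numeric(1))
  expect_lt(max(diffs), 0.02 + 0.03)  # small-sample normal approx slack
  expect_lt(median(diffs), 0.02)
})

test_that("Kaplan-Meier matches hand values and reduces to the empirical curve", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$estimate[km$time == 0], 1)
  expect_equal(km$estimate[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$estimate[km$time == 2], 2 / 3, tolerance = 1e-12)
  expect_equal(km$estimate[km$time == 3], 0)
  expect_true(all(diff(km$estimate) <= 1e-12))
  expect_true(all(km$std_error >= 0))
  # no censoring: empirical survivor function
  set.seed(4)
  t_obs <- sample(1:50, 20, replace = TRUE)
  km2 <- kaplan_meier(t_obs, rep(1, 20))
  for (i in which(km2$time > 0)) {
    expect_equal(km2$estimate[i], mean(t_obs > km2$time[i]),
                 tolerance = 1e-12)
  }
  # all censored: flat at 1
  km3 <- kaplan_meier(c(5, 8, 13), c(0, 0, 0))
  expect_true(all(km3$estimate == 1))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("log-rank matches a pencil-and-paper two-event-time example", {
  times <- c(2, 5, 3, 5)
  events <- c(1, 1, 1, 0)
  groups <- c("A", "A", "B", "B")
  res <- log_rank(times, events, groups)
  e1 <- 2 * 1 / 4 + 1 * 1 / 3 + 1 * 1 / 2
  v <- 2 * 2 * 1 * 3 / (16 * 3) + 1 * 2 * 1 * 2 / (9 * 2) +
    1 * 1 * 1 * 1 / (4 * 1)
  expect_equal(res$observed[1], 2)
  expect_equal(res$expected[1], e1, tolerance = 1e-12)
  expect_equal(res$chisq, (2 - e1)^2 / v, tolerance = 1e-12)
  # label swap leaves the statistic unchanged
  swapped <- log_rank(times, events, rev(groups)[c(3, 4, 1, 2)])
  expect_equal(swapped$chisq, res$chisq, tolerance = 1e-12)
})

test_that("log-rank agrees with the survival-package reference", {
  co <- get_cohort(1)
  cl <- co$clinical
  ours <- log_rank(cl$pfs_time, cl$pfs_event, cl$cluster)
  ref <- survival::survdiff(survival::Surv(pfs_time, pfs_event) ~ cluster,
                            data = cl)
  expect_equal(ours$chisq, ref$chisq, tolerance = 1e-9)
  expect_equal(ours$observed, unname(ref$obs))
  expect_equal(ours$expected, unname(ref$exp), tolerance = 1e-9)
})

test_that("log-rank degenerates correctly and has power on the planted hazards", {
  t_obs <- c(3, 7, 12, 20)
  ev <- c(1, 1, 0, 1)
  dup <- log_rank(c(t_obs, t_obs), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(dup$chisq, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1)
  expect_error(log_rank(t_obs, rep(0, 4), c("a", "a", "b", "b")), "events")
  expect_error(log_rank(t_obs, ev, rep("a", 4)), "2 groups")
  hits <- 0
  for (seed in 1:20) {
    co <- get_cohort(seed)
    cl <- co$clinical
    res <- log_rank(cl$pfs_time, cl$pfs_event, cl$cluster)
    hits <- hits + (res$p_value < 0.05)
  }
  expect_gte(hits, 18)
})

test_that("cohort table reproduces the reference rows under exact margins", {
  co <- simulate_cohort(sim_config(exact_margins = TRUE), seed = 1)
  tab <- cohort_table(co$clinical)
  p_of <- function(variable, level) {
    row <- tab[tab$variable == variable &
                 (is.na(level) | tab$level == level), ]
    row$p_value[1]
  }
  expect_equal(round(p_of("sex", "male"), 2), 0.45)
  expect_equal(round(p_of("edema", "high"), 2), 0.02)
  expect_equal(round(p_of("location", "convexity"), 2), 0.16)
  expect_equal(round(p_of("location", "petroclival"), 2), 1)
  expect_equal(round(p_of("location", "others"), 2), 0.64)
  expect_equal(round(p_of("simpson", "grade_3"), 2), 0.54)
  expect_equal(tab$test[tab$variable == "edema"], "chi_squared")
  expect_equal(tab$test[tab$variable == "age"], "welch_t")
  expect_equal(tab$test[tab$variable == "kps_pre"], "wilcoxon")
  # single cluster errors; missing variables are dropped with a warning
  expect_error(cohort_table(co$clinical, rep(1, 43)), "2 clusters")
  expect_warning(cohort_table(co$clinical[, !names(co$clinical) %in% "sex"]),
                 "sex")
})

test_that("BH adjustment matches a direct sort-based oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(p.adjust(p, "BH") >= p - 1e-15))
  }
})
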