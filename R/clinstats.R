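#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the table `rbind(c(a, b), c(c, d))`. The
#' two-sided p-value sums the hypergeometric point probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed one (up to a 1 + 1e-7 relative tolerance), computed in log
#' space. A degenerate margin returns p = 1 with a flag rather than a
#' test.
#'
#' @param a,b,c,d Non-negative integer cell counts (first row `a b`,
#'   second row `c d`).
#' @return One-row tibble `method`, `a`, `b`, `c`, `d`, `statistic` (NA),
#'   `p_value`, `odds_ratio` (`ad/bc`, possibly `Inf`), `degenerate`.
#' @examples
#' fisher_exact_2x2(2, 8, 13, 20)$p_value  # ~0.45
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  tab <- matrix(counts, 2L, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  tibble(method = "fisher_exact", a = a, b = b, c = c, d = d,
         statistic = NA_real_, p_value = min(p, 1),
         odds_ratio = (a * d) / (b * c), degenerate = degenerate)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, without Yates
#' continuity correction by default; p from the upper tail of the
#' chi-squared distribution with 1 df.
#'
#' @inheritParams fisher_exact_2x2
#' @param continuity Apply the Yates correction (default `FALSE`).
#' @return One-row tibble as in [fisher_exact_2x2()] with the chi-squared
#'   statistic.
#' @examples
#' chi_squared_2x2(4, 18, 11, 10)$p_value  # ~0.02
#' @export
chi_squared_2x2 <- function(a, b, c, d, continuity = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("cell counts must be non-negative")
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) abort("chi-squared undefined: zero margin")
  dev <- abs(a * d - b * c)
  if (continuity) dev <- max(dev - n / 2, 0)
  stat <- n * dev^2 / (r1 * r2 * c1 * c2)
  tibble(method = if (continuity) "chi_squared_yates" else "chi_squared",
         a = a, b = b, c = c, d = d, statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         odds_ratio = (a * d) / (b * c), degenerate = FALSE)
}

#' Welch's t test from group summaries
#'
#' Unequal-variance two-sample t test computed directly from per-group
#' sample sizes, means and standard deviations (as printed in clinical
#' characteristics tables), with the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries (`n >= 2`, `sd > 0`).
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_from_summary(15, 62.3, 13.1, 28, 64.4, 12.8)$p_value  # ~0.62
#' @export
welch_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) abort("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) abort("standard deviations must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(statistic = tstat, df = df,
         p_value = 2 * pt(-abs(tstat), df = df))
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution when `n1 + n2 <= 12`
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return One-row tibble `statistic` (Mann-Whitney W), `p_value`,
#'   `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 12) && !ties
  fit <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                      correct = TRUE))
  tibble(statistic = unname(fit$statistic), p_value = fit$p.value,
         exact = use_exact)
}

#' Kaplan-Meier survivor curve
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' the distinct event times (fitted with [survival::survfit()]); samples
#' censored at an event time count as at risk for that time.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events Event indicator (1 = progression, 0 = censored).
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `estimate`,
#'   `std_error` (Greenwood), including the `S(0) = 1` origin row.
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) abort("survival times must be non-negative")
  if (length(times) != length(events)) abort("times and events differ in length")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  se <- fit$std.err * fit$surv          # Greenwood, on the survival scale
  se[!is.finite(se)] <- 0
  tibble(
    time = c(0, fit$time),
    n_risk = c(fit$n, fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    estimate = c(1, fit$surv),
    std_error = c(0, se)
  )
}

#' Two-group log-rank test
#'
#' At every distinct event time `j`, the expected group-1 events are
#' `E_1j = n_1j d_j / n_j` and the hypergeometric variance is
#' `V_j = n_1j n_2j d_j (n_j - d_j) / (n_j^2 (n_j - 1))`; the statistic is
#' `(O_1 - E_1)^2 / sum(V_j)` on 1 df.
#'
#' @param times,events As in [kaplan_meier()].
#' @param groups Two-level group label per sample.
#' @return Object of class `"metab_logrank"`: `chisq`, `p_value`,
#'   `observed` / `expected` per group, `by_time` (per-event-time O/E/V
#'   table) and `curves` (per-group [kaplan_meier()] estimates).
#' @export
log_rank <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) abort("log-rank comparison needs exactly 2 groups")
  if (sum(events) == 0) abort("no events observed; log-rank undefined")
  if (any(times < 0)) abort("survival times must be non-negative")

  ev_times <- sort(unique(times[events == 1]))
  g1 <- groups == levels(groups)[1L]
  by_time <- list_rbind(map(ev_times, function(t) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & g1)
    v <- if (n_j > 1) {
      n1_j * (n_j - n1_j) * d_j * (n_j - d_j) / (n_j^2 * (n_j - 1))
    } else 0
    tibble(time = t, n_risk = n_j, n_risk_1 = n1_j, n_event = d_j,
           observed_1 = d1_j, expected_1 = n1_j * d_j / n_j, variance = v)
  }))
  o1 <- sum(by_time$observed_1)
  e1 <- sum(by_time$expected_1)
  v <- sum(by_time$variance)
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  o <- c(o1, sum(events) - o1)
  e <- c(e1, sum(events) - e1)

  curves <- list_rbind(map(levels(groups), function(g) {
    kaplan_meier(times[groups == g], events[groups == g]) |>
      mutate(group = g, .before = 1L)
  }))
  structure(
    list(chisq = chisq,
         p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
         groups = levels(groups), observed = o, expected = e,
         variance = v, by_time = by_time, curves = curves),
    class = "metab_logrank"
  )
}

#' @export
print.metab_logrank <- function(x, ...) {
  cat(sprintf("<metab_logrank> chisq = %.3f (1 df), p = %.4g\n",
              x$chisq, x$p_value))
  print(tibble(group = x$groups, observed = x$observed,
               expected = x$expected))
  invisible(x)
}

#' Clinical characteristics table
#'
#' Compares every clinical variable between two clusters with the test a
#' cohort table would use: Fisher's exact test for sparse categorical
#' rows (sex, each location, each Simpson grade, the MIB-1 dichotomy,
#' WHO grade I vs II+III), Pearson chi-squared for the edema 2x2 (all
#' expected counts >= 5), Welch's t for age and size, and Wilcoxon for
#' the KPS scores. P-values are kept at full precision with a two-decimal
#' display column.
#'
#' @param clinical Clinical tibble (see [simulate_cohort()]).
#' @param labels Two-group cluster label per sample (defaults to the
#'   `cluster` column).
#' @return Tibble `variable`, `level`, `summary_1`, `summary_2`, `test`,
#'   `p_value`, `p_display`.
#' @export
cohort_table <- function(clinical, labels = clinical$cluster) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) abort("cohort table needs exactly 2 clusters")
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1)
  n2 <- sum(!g1)

  count_row <- function(variable, level, in_level, test = "fisher") {
    a <- sum(in_level & g1); b <- sum(in_level & !g1)
    res <- if (test == "chisq") {
      chi_squared_2x2(a, b, n1 - a, n2 - b)
    } else {
      fisher_exact_2x2(a, b, n1 - a, n2 - b)
    }
    tibble(variable = variable, level = level,
           summary_1 = sprintf("%d (%.1f%%)", a, 100 * a / n1),
           summary_2 = sprintf("%d (%.1f%%)", b, 100 * b / n2),
           test = res$method, p_value = res$p_value)
  }
  numeric_row <- function(variable, values, test) {
    x <- values[g1]; y <- values[!g1]
    if (test == "welch") {
      res <- welch_t_from_summary(n1, mean(x), sd(x), n2, mean(y), sd(y))
      tibble(variable = variable, level = NA_character_,
             summary_1 = sprintf("%.1f ± %.1f", mean(x), sd(x)),
             summary_2 = sprintf("%.1f ± %.1f", mean(y), sd(y)),
             test = "welch_t", p_value = res$p_value)
    } else {
      res <- wilcoxon_rank_sum(x, y)
      tibble(variable = variable, level = NA_character_,
             summary_1 = sprintf("%.0f (median)", median(x)),
             summary_2 = sprintf("%.0f (median)", median(y)),
             test = "wilcoxon", p_value = res$p_value)
    }
  }

  rows <- list()
  miss <- function(v) {
    if (!v %in% names(clinical)) {
      warn(paste0("variable '", v, "' missing; row omitted"))
      return(TRUE)
    }
    FALSE
  }
  if (!miss("sex")) {
    rows <- c(rows, list(count_row("sex", "male", clinical$sex == "male")))
  }
  if (!miss("age")) rows <- c(rows, list(numeric_row("age", clinical$age, "welch")))
  if (!miss("size")) rows <- c(rows, list(numeric_row("size", clinical$size, "welch")))
  if (!miss("edema")) {
    rows <- c(rows, list(count_row("edema", "high",
                                   clinical$edema == "high", test = "chisq")))
  }
  if (!miss("location")) {
    for (l in sort(unique(clinical$location))) {
      rows <- c(rows, list(count_row("location", l, clinical$location == l)))
    }
  }
  if (!miss("simpson")) {
    for (s in sort(unique(clinical$simpson))) {
      rows <- c(rows, list(count_row("simpson", paste0("grade_", s),
                                     clinical$simpson == s)))
    }
  }
  if (!miss("kps_pre")) rows <- c(rows, list(numeric_row("kps_pre", clinical$kps_pre, "wilcoxon")))
  if (!miss("kps_post")) rows <- c(rows, list(numeric_row("kps_post", clinical$kps_post, "wilcoxon")))
  if (!miss("mib1")) {
    rows <- c(rows, list(count_row("mib1", "below_5pct", clinical$mib1 < 5)))
  }
  if (!miss("who_grade")) {
    rows <- c(rows, list(count_row("who_grade", "I",
                                   clinical$who_grade == "I")))
  }
  out <- list_rbind(rows)
  out$p_display <- formatC(round(out$p_value, 2L), format = "g")
  out
}
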