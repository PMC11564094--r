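test_that("g-test matches direct evaluation of 2*sum(O*ln(O/E))", {
  O <- matrix(c(10, 20, 20, 10), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(g_test(O)$statistic, 2 * sum(O * log(O / E)))
  expect_equal(g_test(O)$statistic, 6.796, tolerance = 1e-3)
  expect_equal(g_test(O)$dof, 1)
  expect_equal(g_test(O)$p_value, 0.00914, tolerance = 1e-2)
  # zero observed cells contribute 0; zero-expected categories are dropped
  O2 <- cbind(O, c(0, 0))
  expect_equal(g_test(O2)$statistic, g_test(O)$statistic)
  expect_equal(g_test(O2)$dropped_categories, "3")
  # large counts: g approximates the chi-squared statistic within 5%
  O3 <- matrix(c(120, 80, 90, 110), 2)
  chi <- suppressWarnings(chisq.test(O3, correct = FALSE)$statistic)
  expect_lt(abs(g_test(O3)$statistic - chi) / chi, 0.05)
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(71)
  for (i in 1:5) {
    p <- runif(20)
    adj <- p.adjust(p, "BH")
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    # monotone: adjustment preserves the ordering of the raw p-values
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_identical(p.adjust(p, "BH"), adj)  # deterministic
  }
})

test_that("feature ranking tests each group against the rest with BH", {
  set.seed(72)
  n <- 600
  g <- sample(c("a", "b", "c"), n, TRUE)
  lab <- rnorm(n) + (g == "a") * 2        # marker of group a
  noise <- rnorm(n)
  drug <- ifelse(g == "b" & runif(n) < 0.8, "x", sample(c("x", "y"), n, TRUE))
  f <- tempfile(fileext = ".csv")
  writeLines(c("lab,noise,drug", paste(lab, noise, drug, sep = ",")), f)
  fr <- read_tabular(f)
  fr$obs$grp <- factor(g)
  rk <- rank_features_groups(fr, "grp")
  a <- rk[rk$group == "a", ]
  expect_equal(a$feature[1], "lab")       # strongest marker ranks first
  expect_true(all(a$padj >= a$pvalue - 1e-15))
  expect_equal(sort(a$padj), sort(p.adjust(a$pvalue, "BH")))
  b <- rk[rk$group == "b", ]
  expect_lt(b$padj[b$feature == "drug"], 0.01)
  expect_equal(b$test[b$feature == "drug"], "g-test")
  # identical distributions on both sides: t ~ 0, p near 1 for the noise
  expect_gt(min(rk$pvalue[rk$feature == "noise"]), 0.001)
  expect_error(rank_features_groups(fr, "ghost"), "unknown")
  fr$obs$one <- factor(rep("g", n))
  expect_error(rank_features_groups(fr, "one"), "2 levels")
})

test_that("zero-variance features on both sides get p = 1 with zero statistic", {
  fr <- mkframe(cbind(rep(3, 40), rnorm(40)))
  fr$obs$grp <- factor(rep(c("x", "y"), 20))
  rk <- rank_features_groups(fr, "grp")
  expect_equal(rk$pvalue[rk$feature == "v1"], c(1, 1))
  expect_equal(rk$statistic[rk$feature == "v1"], c(0, 0))
})

test_that("kaplan-meier equals the hand product-limit, exhaustively to n = 6", {
  # spec'd small case: [1,2,3] all events
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))$all
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # exhaustive event/censor patterns for n = 1..6, distinct times 1..n
  for (n in 1:6) {
    for (mask in 0:(2^n - 1)) {
      ev <- as.integer(intToBits(mask))[1:n]
      fit <- kaplan_meier(seq_len(n), ev)$all
      orc <- km_oracle(seq_len(n), ev)
      at <- match(orc$time, fit$time)
      expect_equal(fit$surv[at], orc$surv, tolerance = 1e-12)
    }
  }
  # no events: survival stays at 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))$all
  expect_true(all(km0$surv == 1))
  # duplicating every observation leaves the estimate unchanged
  km2 <- kaplan_meier(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))$all
  km1 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))$all
  expect_equal(km2$surv[km2$n_event > 0], km1$surv[km1$n_event > 0])
  # confidence band brackets the estimate within [0, 1]
  set.seed(73)
  kmc <- kaplan_meier(rexp(50), rbinom(50, 1, 0.7))$all
  ok <- !is.na(kmc$lower)
  expect_true(all(kmc$lower[ok] <= kmc$surv[ok] + 1e-12))
  expect_true(all(kmc$upper[ok] >= kmc$surv[ok] - 1e-12))
  expect_true(all(kmc$lower[ok] >= 0 & kmc$upper[ok] <= 1))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("log-rank: identical groups give p 1; strong effects are detected", {
  d <- c(1, 2, 3, 4, 5); e <- c(1, 1, 0, 1, 1)
  r <- logrank_test(c(d, d), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  expect_equal(r$dof, 1)
  set.seed(74)
  detected <- mean(replicate(20, {
    fr <- simulate_survival_cohort(200, c(g1 = 1, g2 = 3), censor_rate = 0.2,
                                   seed = sample.int(2^30, 1))
    logrank_test(fr$obs$duration, fr$obs$event, fr$obs$group)$p_value < 0.001
  }))
  expect_gte(detected, 0.95)
  expect_error(logrank_test(d, e, rep("a", 5)), "2 groups")
})

test_that("log-rank p agrees with a permutation null on toy data", {
  set.seed(75)
  d <- rexp(40); e <- rbinom(40, 1, 0.8); g <- rep(c("a", "b"), 20)
  obs_stat <- logrank_test(d, e, g)$statistic
  perm <- replicate(400, logrank_test(d, e, sample(g))$statistic)
  p_perm <- mean(perm >= obs_stat)
  p_asym <- logrank_test(d, e, g)$p_value
  expect_lt(abs(p_perm - p_asym), 0.1)   # within Monte-Carlo error
})

test_that("cox model recovers a known hazard ratio and flags degeneracies", {
  fr <- simulate_survival_cohort(1000, c(a = 1, b = 2), censor_rate = 0.3, seed = 76)
  fr$obs$z <- as.integer(fr$obs$group == "b")
  cx <- cox_ph(fr, "duration", "event", "z")
  expect_lt(abs(cx$coefficients$coef - log(2)) / cx$coefficients$se, 3)
  expect_true(cx$coefficients$lower < cx$coefficients$coef &
                cx$coefficients$coef < cx$coefficients$upper)
  expect_gt(cx$coefficients$hr, 0)
  expect_equal(length(cx$partial_hazards), 2000)
  fr$obs$const <- 1
  expect_error(cox_ph(fr, "duration", "event", "const"), "constant")
  fr$obs$z[1] <- NA
  expect_error(cox_ph(fr, "duration", "event", "z"), "missing")
})

test_that("concordance index behaves at its analytic anchors", {
  # perfect ordering: highest risk fails first
  d <- c(1, 2, 3, 4); e <- c(1, 1, 1, 1); h <- c(4, 3, 2, 1)
  cc <- concordance_ci(h, d, e, n_boot = 50, seed = 1)
  expect_equal(cc$c_index, 1)
  # sign reversal maps C to 1 - C
  set.seed(77)
  d2 <- rexp(100); e2 <- rbinom(100, 1, 0.7); h2 <- rnorm(100)
  c_pos <- concordance_ci(h2, d2, e2, n_boot = 10, seed = 1)$c_index
  c_neg <- concordance_ci(-h2, d2, e2, n_boot = 10, seed = 1)$c_index
  expect_equal(c_pos + c_neg, 1)
  # random scores at large n: C ~ 0.5 inside the bootstrap CI
  set.seed(78)
  d3 <- rexp(400); e3 <- rbinom(400, 1, 0.7); h3 <- rnorm(400)
  cc3 <- concordance_ci(h3, d3, e3, n_boot = 200, seed = 2)
  expect_true(cc3$ci[1] <= 0.5 && 0.5 <= cc3$ci[2])
  # cross-check against the survival package on a fitted model
  fr <- simulate_survival_cohort(300, c(a = 1, b = 2), seed = 79)
  fr$obs$z <- as.integer(fr$obs$group == "b")
  cx <- cox_ph(fr, "duration", "event", "z")
  ours <- concordance_ci(cx$partial_hazards, fr$obs$duration, fr$obs$event,
                         n_boot = 10, seed = 3)$c_index
  ref <- survival::concordance(
    survival::Surv(fr$obs$duration, as.integer(fr$obs$event)) ~ cx$partial_hazards,
    reverse = TRUE)$concordance
  expect_equal(ours, unname(ref), tolerance = 1e-12)
  expect_error(concordance_ci(1, 5, 0), "comparable")
})

test_that("glm wrapper and nested-model comparison follow likelihood theory", {
  set.seed(80)
  n <- 300
  df <- data.frame(x = rnorm(n), w = rnorm(n))
  df$y <- 1 + 2 * df$x + rnorm(n)
  fit <- fit_glm(df, y ~ x, family = "gaussian")
  ols <- lm(y ~ x, data = df)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-8)
  # intercept-only: intercept equals the outcome mean (identity link)
  fit0 <- fit_glm(df, y ~ 1)
  expect_equal(unname(coef(fit0)), mean(df$y))
  # noise predictor barely helps; the true predictor is decisive
  big <- fit_glm(df, y ~ x + w)
  expect_gt(compare_glm(big, fit)$p_value, 1e-4)
  expect_lt(compare_glm(fit, fit0)$p_value, 1e-10)
  # degenerate self-comparison
  expect_equal(compare_glm(fit, fit)$p_value, 1)
  expect_error(compare_glm(fit, fit_glm(df, y ~ w)), "not nested")
  expect_error(fit_glm(df, y ~ x, family = "nope"), "unknown family")
  # works straight off an ehrframe
  fr <- mkframe(cbind(df$x, df$y))
  expect_equal(unname(coef(fit_glm(fr, v2 ~ v1))), unname(coef(ols)),
               tolerance = 1e-8)
})
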