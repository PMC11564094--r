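test_that("qc metrics count missingness per variable and per observation", {
  Y <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2)
  fr <- mkframe(Y)
  q <- qc_metrics(fr)
  expect_equal(unname(q$var_metrics$missing_frac), c(1 / 3, 0))
  expect_equal(unname(q$obs_metrics$missing_frac), c(0, 1 / 2, 0))
  # conservation: marginal sums reconcile with the total
  expect_equal(sum(q$var_metrics$missing_count), q$total_missing)
  expect_equal(sum(q$obs_metrics$missing_count), q$total_missing)
  # complete frame: all zero
  q0 <- qc_metrics(mkframe(matrix(1:9, 3, 3)))
  expect_true(all(q0$var_metrics$missing_frac == 0))
  # annotations written back
  expect_equal(q$frame$var$missing_frac, unname(q$var_metrics$missing_frac))
})

test_that("qc missing fractions match the injected MCAR rate at large n", {
  fr <- mkframe(matrix(rnorm(10000), ncol = 1))
  fr <- inject_mcar(fr, "v1", 0.3, seed = 11)
  q <- qc_metrics(fr)
  expect_lt(abs(q$var_metrics$missing_frac[1] - 0.3), 0.02)
})

test_that("summarize_features collapses repeated measurements per patient", {
  Y <- matrix(c(1, 2, 3, 10, NA, NA), 3, 2)
  fr <- mkframe(Y)
  fr$obs$patient <- c("p1", "p1", "p2")
  out <- summarize_features(fr, "patient")
  expect_equal(n_obs(out), 2)
  expect_equal(unname(out$X["p1", c("v1_min", "v1_max", "v1_mean")]), c(1, 2, 1.5))
  # degenerate single-value group: min = max = mean
  expect_equal(unname(out$X["p2", c("v1_min", "v1_max", "v1_mean")]), c(3, 3, 3))
  # all-missing group gets the missing marker
  expect_true(is.na(out$X["p2", "v2_mean"]))
  expect_equal(unname(out$X["p1", "v2_mean"]), 10)
})

test_that("winsorize clamps at empirical quantiles and is idempotent", {
  x <- as.numeric(1:100)
  fr <- mkframe(matrix(x, ncol = 1))
  w <- winsorize(fr, "v1", limits = c(0.05, 0.05))
  expect_equal(min(w$X), quantile(x, 0.05, type = 1, names = FALSE))
  expect_equal(max(w$X), quantile(x, 0.95, type = 1, names = FALSE))
  expect_identical(winsorize(w, "v1", limits = c(0.05, 0.05))$X, w$X)
  # zero limits and constant columns are no-ops
  expect_identical(winsorize(fr, "v1", limits = c(0, 0))$X, fr$X)
  cc <- mkframe(matrix(rep(7, 10), ncol = 1))
  expect_identical(winsorize(cc, "v1", limits = c(0.2, 0.2))$X, cc$X)
  expect_error(winsorize(fr, "v1", limits = c(0.6, 0)), "limits")
})

test_that("clip_features clamps into bounds and reports modified counts", {
  fr <- mkframe(matrix(c(-5, 0, 5, NA), ncol = 1))
  out <- clip_features(fr, list(v1 = c(0, 3)))
  expect_equal(unname(out$frame$X[1:3, 1]), c(0, 0, 3))
  expect_true(is.na(out$frame$X[4, 1]))
  expect_equal(unname(out$n_clipped["v1"]), 2L)
  expect_error(clip_features(fr, list(v1 = c(3, 0))), "inverted")
  # clipping twice equals clipping once
  out2 <- clip_features(out$frame, list(v1 = c(0, 3)))
  expect_identical(out2$frame$X, out$frame$X)
  expect_equal(unname(out2$n_clipped["v1"]), 0L)
})

test_that("standardized mean differences recover constructed group shifts", {
  set.seed(21)
  n <- 10000
  g <- rep(c("A", "B"), each = n / 2)
  x_null <- rnorm(n)                     # identical distributions
  x_shift <- rnorm(n) + (g == "A") * 1   # +1 sd in group A
  fr <- mkframe(cbind(x_null, x_shift))
  fr$obs$grp <- factor(g)
  rep_ <- detect_bias(fr, "grp")
  smd <- rep_$smd
  expect_lt(abs(smd$smd[smd$variable == "v1"]), 0.05)
  expect_lt(abs(smd$smd[smd$variable == "v2"] - 1), 0.1)
  # correlation of a variable with itself is 1
  expect_equal(unname(diag(rep_$correlations)), c(1, 1))
  expect_error(detect_bias(fr, "v1"), "unknown obs column")
  fr$obs$num <- rnorm(n)
  expect_error(detect_bias(fr, "num"), "categorical")
})

test_that("categorical bias deltas and importance ranking are reported", {
  set.seed(22)
  n <- 2000
  g <- rep(c("A", "B"), each = n / 2)
  drug <- ifelse(g == "A" & runif(n) < 0.7, "x", sample(c("x", "y"), n, TRUE))
  f <- tempfile(fileext = ".csv")
  writeLines(c("drug", drug), f)
  fr <- read_tabular(f)
  fr$obs$grp <- factor(g)
  # add a numeric predictor of the target
  fr2 <- mkframe(matrix(rnorm(2 * n), ncol = 2))
  fr2$obs$grp <- factor(g)
  fr2$obs$target <- fr2$X[, 1] * 2 + rnorm(n, sd = 0.1)
  rep_ <- detect_bias(fr2, "grp", target = "target")
  expect_equal(names(rep_$importance)[1], "v1")
  repc <- detect_bias(fr, "grp")
  expect_true(all(c("count_diff", "prop_diff") %in% colnames(repc$categorical_diffs)))
  dx <- repc$categorical_diffs
  expect_gt(dx$prop_diff[dx$category == "x"], 0.1)
})

test_that("subsample and balanced_sample honour sizes, seeds and balance", {
  fr <- mkframe(matrix(rnorm(200), 100, 2))
  fr$obs$grp <- factor(rep(c("big", "small"), c(80, 20)))
  s <- subsample(fr, 0.5, seed = 3)
  expect_equal(n_obs(s), 50)
  expect_identical(subsample(fr, 0.5, seed = 3)$X, s$X)
  expect_equal(n_obs(subsample(fr, 1.0, seed = 1)), 100)
  expect_error(subsample(fr, 0), "fraction")
  u <- balanced_sample(fr, "grp", "under", seed = 4)
  expect_equal(as.integer(table(u$obs$grp)), c(20L, 20L))
  o <- balanced_sample(fr, "grp", "over", seed = 4)
  expect_equal(as.integer(table(o$obs$grp)), c(80L, 80L))
  expect_error(balanced_sample(fr, "ghost"), "unknown")
})
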