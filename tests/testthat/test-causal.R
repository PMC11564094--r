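fixture_dags <- function() {
  list(
    chain = c("T -> Y"),
    confounder = c("Z -> T", "Z -> Y", "T -> Y"),
    mediator = c("T -> M", "M -> Y"),
    mediator_confounder = c("Z -> T", "Z -> Y", "T -> M", "M -> Y"),
    two_confounders = c("A -> T", "A -> Y", "B -> T", "B -> Y", "T -> Y"),
    collider = c("T -> C", "Y -> C", "T -> Y"),
    m_bias = c("U1 -> Z", "U1 -> T", "U2 -> Z", "U2 -> Y", "T -> Y"),
    butterfly = c("Z -> T", "Z -> Y", "W -> Z", "W -> Y", "T -> Y")
  )
}

test_that("causal graphs validate structure", {
  g <- causal_graph(c("a -> b", "b -> c"))
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_error(causal_graph(c("a -> b", "b -> a")), "acyclic")
  expect_error(causal_graph("a - b"), "parent -> child")
  expect_error(backdoor_set(causal_graph("a -> b"), "a", "a"), "differ")
  expect_error(backdoor_set(causal_graph("a -> b"), "a", "zz"), "nodes")
})

test_that("backdoor sets match textbook cases", {
  expect_equal(backdoor_set(causal_graph("T -> Y"), "T", "Y"), character(0))
  expect_equal(backdoor_set(causal_graph(fixture_dags()$confounder), "T", "Y"), "Z")
  # mediator never enters an adjustment set
  g <- causal_graph(fixture_dags()$mediator_confounder)
  expect_equal(backdoor_set(g, "T", "Y"), "Z")
  expect_false("M" %in% backdoor_set(g, "T", "Y"))
  expect_setequal(backdoor_set(causal_graph(fixture_dags()$two_confounders),
                               "T", "Y"), c("A", "B"))
  # collider downstream of both: no backdoor path, empty set
  expect_equal(backdoor_set(causal_graph(fixture_dags()$collider), "T", "Y"),
               character(0))
  # m-bias: no backdoor path open; conditioning on Z would open one
  expect_equal(backdoor_set(causal_graph(fixture_dags()$m_bias), "T", "Y"),
               character(0))
})

test_that("backdoor sets agree with exhaustive d-separation enumeration", {
  for (nm in names(fixture_dags())) {
    g <- causal_graph(fixture_dags()[[nm]])
    valid <- backdoor_oracle_sets(g$edges, "T", "Y")
    got <- tryCatch(backdoor_set(g, "T", "Y"), error = function(e) NULL)
    if (length(valid)) {
      expect_false(is.null(got), info = nm)
      expect_true(any(vapply(valid, function(z) setequal(z, got), logical(1))),
                  info = nm)
      # minimality: no strictly smaller valid set exists
      min_size <- min(lengths(valid))
      expect_equal(length(got), min_size, info = nm)
    } else {
      expect_null(got, info = nm)
    }
  }
})

test_that("d-separation agrees with the path-enumeration oracle", {
  set.seed(91)
  for (nm in names(fixture_dags())) {
    g <- causal_graph(fixture_dags()[[nm]])
    others <- setdiff(g$nodes, c("T", "Y"))
    subsets <- list(character(0))
    for (k in seq_along(others))
      subsets <- c(subsets, utils::combn(others, k, simplify = FALSE))
    for (z in subsets) {
      expect_equal(ehrkit:::d_separated(g, "T", "Y", z),
                   dsep_oracle(g$edges, "T", "Y", z),
                   info = paste(nm, paste(z, collapse = ",")))
    }
  }
})

test_that("adjusted estimation recovers the simulated effect; omission biases it", {
  g <- causal_graph(fixture_dags()$confounder)
  spec <- scm_spec(g, c("Z->T" = 0.5, "T->Y" = 2, "Z->Y" = 1),
                   binarize_treatment = "T")
  fr <- simulate_scm(spec, 5000, seed = 92)
  expect_equal(fr$uns$true_effects$Y, 2)
  est <- estimate_effect(fr, g, "T", "Y")
  expect_equal(est$adjustment, "Z")
  expect_lt(abs(est$effect - 2), 0.1)
  expect_lt(abs(est$effect - 2) / est$se, 3)
  unadj <- estimate_effect(fr, g, "T", "Y", adjustment = character(0))
  expect_gt(abs(unadj$effect - est$effect), 0.2)      # confounding bias
  expect_gt(abs(unadj$effect - 2) / est$se, 3)
  # outcome identical to treatment: effect exactly 1
  fr2 <- mkframe(cbind(rnorm(50)))
  fr2$obs$t <- rnorm(50)
  d <- data.frame(t = rnorm(100))
  d$y <- d$t
  g2 <- causal_graph("t -> y")
  # lm warns about the (intentionally) perfect fit
  eff <- suppressWarnings(estimate_effect(d, g2, "t", "y")$effect)
  expect_equal(eff, 1, tolerance = 1e-12)
})

test_that("zero-effect models keep nominal CI coverage", {
  g <- causal_graph(fixture_dags()$confounder)
  spec <- scm_spec(g, c("Z->T" = 0.5, "T->Y" = 0, "Z->Y" = 1),
                   binarize_treatment = "T")
  set.seed(93)
  cover <- mean(vapply(1:40, function(i) {
    fr <- simulate_scm(spec, 400, seed = sample.int(2^30, 1))
    ci <- estimate_effect(fr, g, "T", "Y")$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1)))
  expect_gte(cover, 0.85)
})

test_that("refuters behave as designed on a known SCM", {
  g <- causal_graph(fixture_dags()$confounder)
  spec <- scm_spec(g, c("Z->T" = 0.5, "T->Y" = 2, "Z->Y" = 1),
                   binarize_treatment = "T")
  fr <- simulate_scm(spec, 5000, seed = 94)
  est <- estimate_effect(fr, g, "T", "Y")
  pl <- refute_estimate(fr, g, est, "placebo_treatment", seed = 1)
  expect_lt(abs(pl$refuted_value), 0.05)
  expect_true(pl$pass)
  dm <- refute_estimate(fr, g, est, "dummy_outcome", seed = 2)
  expect_lt(abs(dm$refuted_value), 0.05)
  rc <- refute_estimate(fr, g, est, "random_common_cause", seed = 3)
  expect_lt(abs(rc$refuted_value - est$effect), 0.05)
  bs <- refute_estimate(fr, g, est, "bootstrap", seed = 4)
  expect_true(bs$pass)
  expect_true(bs$details$ci[1] <= est$effect && est$effect <= bs$details$ci[2])
  ds <- refute_estimate(fr, g, est, "data_subset", seed = 5)
  expect_true(ds$pass)
  uc <- refute_estimate(fr, g, est, "unobserved_common_cause", seed = 6)
  expect_true(is.na(uc$pass))                       # sensitivity curve only
  expect_equal(length(uc$details$estimates), length(uc$details$strengths))
  expect_error(refute_estimate(fr, g, est, "mystery"), "unknown refuter")
  # determinism given seed
  pl2 <- refute_estimate(fr, g, est, "placebo_treatment", seed = 1)
  expect_identical(pl2$refuted_value, pl$refuted_value)
})

test_that("scm sampling matches its closed-form covariance", {
  # linear gaussian chain Z -> T -> Y plus Z -> Y, no binarization:
  # path tracing gives the full covariance
  g <- causal_graph(c("Z -> T", "Z -> Y", "T -> Y"))
  spec <- scm_spec(g, c("Z->T" = 0.8, "T->Y" = 1.5, "Z->Y" = 0.7))
  fr <- simulate_scm(spec, 20000, seed = 95)
  S <- cov(fr$X)
  var_t <- 0.8^2 + 1
  cov_zt <- 0.8
  cov_zy <- 0.7 + 0.8 * 1.5
  var_y <- 1.5^2 * var_t + 0.7^2 + 2 * 1.5 * 0.7 * cov_zt + 1
  expect_equal(S["Z", "T"], cov_zt, tolerance = 0.05)
  expect_equal(S["T", "T"], var_t, tolerance = 0.07)
  expect_equal(S["Z", "Y"], cov_zy, tolerance = 0.07)
  expect_equal(S["Y", "Y"], var_y, tolerance = 0.15)
  # true total effect: sum of path products = 1.5 for T, 0.7 + 0.8*1.5 for Z
  expect_equal(fr$uns$true_effects$T, 0.8)
  expect_equal(fr$uns$true_effects$Y, 0.7 + 0.8 * 1.5)
  # noise scale 0 gives exact functional relations
  spec0 <- scm_spec(g, c("Z->T" = 1, "T->Y" = 2, "Z->Y" = 0),
                    noise = c(T = 0, Y = 0))
  fr0 <- simulate_scm(spec0, 100, seed = 96)
  expect_equal(fr0$X[, "Y"], 2 * fr0$X[, "T"], tolerance = 1e-12)
})
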