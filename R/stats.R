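#' Rank features characterizing each group
#'
#' Tests every feature for association with group membership, each group
#' against the union of all other groups: numeric variables with a
#' two-sided Welch t-test, raw categorical/boolean variables with a g-test
#' (likelihood-ratio test, \eqn{G = 2 \sum O \ln(O/E)}) on the
#' group-vs-rest by category contingency table. P values are
#' Benjamini-Hochberg adjusted across features within each group, and
#' features are ordered by adjusted p, then by decreasing |statistic|.
#'
#' @param frame an `ehrframe`.
#' @param groupby categorical obs column with at least two levels.
#' @param groups optional subset of group levels to test.
#' @return data.frame of class `ehr_rank_result` with columns `group`,
#'   `feature`, `test`, `statistic`, `dof`, `pvalue`, `padj`, `summary`.
#' @export
rank_features_groups <- function(frame, groupby, groups = NULL) {
  if (!groupby %in% colnames(frame$obs)) stop("unknown obs column: ", groupby)
  g <- as.character(frame$obs[[groupby]])
  levels_ <- sort(unique(g[!is.na(g)]))
  if (length(levels_) < 2) stop("groupby needs at least 2 levels")
  groups <- groups %||% levels_
  numv <- colnames(frame$X)[frame$var$kind == "numeric" |
                              frame$var$encoding_state != "raw"]
  catv <- colnames(frame$X)[frame$var$kind %in% c("categorical", "boolean") &
                              frame$var$encoding_state == "raw"]
  rows <- list()
  for (gr in groups) {
    in_g <- !is.na(g) & g == gr
    rest <- !is.na(g) & g != gr
    res_g <- list()
    for (v in numv) {
      x <- as.numeric(frame$X[, v])
      x1 <- x[in_g & !is.na(x)]; x2 <- x[rest & !is.na(x)]
      if (length(x1) < 2 || length(x2) < 2) next
      if (sd(x1) == 0 && sd(x2) == 0) {
        stat <- 0; pv <- 1; dof <- NA_real_
      } else {
        tt <- t.test(x1, x2)                        # Welch
        stat <- unname(tt$statistic); pv <- tt$p.value
        dof <- unname(tt$parameter)
      }
      res_g[[length(res_g) + 1]] <- data.frame(
        group = gr, feature = v, test = "t-test", statistic = stat,
        dof = dof, pvalue = pv,
        summary = sprintf("%.3g+/-%.3g vs %.3g+/-%.3g",
                          mean(x1), sd(x1), mean(x2), sd(x2)))
    }
    for (v in catv) {
      tok <- as.character(frame$X[, v])
      tab <- table(factor(ifelse(in_g, "group", "rest"))[!is.na(tok) & (in_g | rest)],
                   tok[!is.na(tok) & (in_g | rest)])
      if (nrow(tab) < 2 || ncol(tab) < 2) next
      gt <- g_test(tab)
      top <- names(sort(table(tok[in_g & !is.na(tok)]), decreasing = TRUE))[1]
      res_g[[length(res_g) + 1]] <- data.frame(
        group = gr, feature = v, test = "g-test", statistic = gt$statistic,
        dof = gt$dof, pvalue = gt$p_value,
        summary = paste0("mode=", top %||% NA))
    }
    if (!length(res_g)) next
    df <- do.call(rbind, res_g)
    df$padj <- p.adjust(df$pvalue, method = "BH")
    df <- df[order(df$padj, -abs(df$statistic)), ]
    df$rank <- seq_len(nrow(df))
    rows[[gr]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ehr_rank_result", "data.frame")
  out
}

#' Likelihood-ratio (g-) test of independence
#'
#' \eqn{G = 2\sum O \ln(O/E)} over the cells of a contingency table, with
#' expected counts from the margins. Observed zeros contribute 0; a
#' category whose expected count is 0 is dropped with a flag. G is
#' asymptotically chi-squared with `(r-1)(c-1)` degrees of freedom.
#'
#' @param table a contingency table (matrix of counts).
#' @return list with `statistic`, `dof`, `p_value`, `dropped_categories`.
#' @examples
#' g_test(matrix(c(10, 20, 20, 10), 2))  # G ~ 6.796
#' @export
g_test <- function(table) {
  O <- as.matrix(table)
  dropped <- character(0)
  keep <- colSums(O) > 0
  if (!all(keep)) {
    dropped <- colnames(O)[!keep] %||% as.character(which(!keep))
    O <- O[, keep, drop = FALSE]
  }
  keep_r <- rowSums(O) > 0
  O <- O[keep_r, , drop = FALSE]
  if (nrow(O) < 2 || ncol(O) < 2)
    return(list(statistic = 0, dof = 0, p_value = 1, dropped_categories = dropped))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  dof <- (nrow(O) - 1) * (ncol(O) - 1)
  list(statistic = G, dof = dof,
       p_value = pchisq(G, dof, lower.tail = FALSE),
       dropped_categories = dropped)
}

#' Kaplan-Meier product-limit survival curves
#'
#' Fits \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} with a Greenwood
#' 95% confidence band on the log(-log) scale (so bounds stay in `[0,1]`),
#' optionally per group.
#'
#' @param durations non-negative follow-up times.
#' @param events logical/0-1 event indicators (FALSE = censored).
#' @param groupby optional group labels.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `ehr_km` mapping group name (or `"all"`) to a
#'   data.frame with `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`.
#' @export
kaplan_meier <- function(durations, events, groupby = NULL, conf_level = 0.95) {
  if (any(durations < 0)) stop("durations must be non-negative")
  events <- as.integer(as.logical(events))
  df <- data.frame(time = durations, status = events)
  curves <- list()
  if (is.null(groupby)) {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = df,
                             conf.type = "log-log", conf.int = conf_level)
    curves[["all"]] <- km_table(fit)
  } else {
    df$group <- as.character(groupby)
    for (lv in sort(unique(df$group))) {
      fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                               data = df[df$group == lv, ],
                               conf.type = "log-log", conf.int = conf_level)
      curves[[lv]] <- km_table(fit)
    }
  }
  class(curves) <- "ehr_km"
  curves
}

km_table <- function(fit) {
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv,
             lower = ifelse(is.na(fit$lower), NA, fit$lower),
             upper = ifelse(is.na(fit$upper), NA, fit$upper))
}

#' Log-rank test for equality of survival across groups
#'
#' Chi-squared test on observed-minus-expected event counts accumulated at
#' every event time (log-rank weights; ties handled with the standard
#' hypergeometric variance), with `k - 1` degrees of freedom for `k`
#' groups. Tests \eqn{H_0: h_1(t) = \dots = h_k(t)} against proportional
#' alternatives \eqn{h_1(t) = c\,h_2(t)}, \eqn{c \ne 1}.
#'
#' @param durations non-negative follow-up times.
#' @param events logical/0-1 event indicators.
#' @param groups labels with at least 2 levels, each non-empty.
#' @return list of class `ehr_logrank` with `statistic`, `dof`, `p_value`.
#' @export
logrank_test <- function(durations, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  df <- data.frame(time = durations, status = as.integer(as.logical(events)),
                   group = groups)
  sd_ <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
  dof <- length(sd_$n) - 1
  out <- list(statistic = unname(sd_$chisq), dof = dof,
              p_value = pchisq(unname(sd_$chisq), dof, lower.tail = FALSE))
  class(out) <- "ehr_logrank"
  out
}

#' Cox proportional hazards model
#'
#' Fits the semiparametric hazard model
#' \eqn{h(t \mid x) = h_0(t) \exp(x^\top \beta)} by partial likelihood and
#' returns log hazard ratios with standard errors, Wald 95% CIs and
#' p-values, plus per-observation partial hazards \eqn{\exp(x^\top \beta)}.
#'
#' @param frame an `ehrframe` or a data.frame.
#' @param duration_col,event_col column names of follow-up time and event
#'   indicator (obs table or variables for an `ehrframe`).
#' @param covariates covariate column names (numeric/encoded, complete).
#' @return list of class `ehr_cox` with `coefficients` (data.frame),
#'   `loglik`, `partial_hazards` and the underlying `survival::coxph` fit.
#' @export
cox_ph <- function(frame, duration_col, event_col, covariates) {
  df <- if (inherits(frame, "ehrframe")) as.data.frame(frame) else frame
  need <- c(duration_col, event_col, covariates)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyNA(df[, need])) stop("model columns contain missing values; impute first")
  for (v in covariates)
    if (is.numeric(df[[v]]) && sd(df[[v]]) == 0)
      stop("constant covariate: ", v)
  fml <- as.formula(paste0("survival::Surv(`", duration_col, "`, `", event_col,
                           "`) ~ ", paste0("`", covariates, "`", collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (any(is.na(coef(fit)))) stop("Cox fit failed (aliased coefficients)")
  s <- summary(fit)
  co <- data.frame(covariate = rownames(s$coefficients),
                   coef = s$coefficients[, "coef"],
                   se = s$coefficients[, "se(coef)"],
                   hr = exp(s$coefficients[, "coef"]),
                   lower = s$coefficients[, "coef"] - qnorm(0.975) * s$coefficients[, "se(coef)"],
                   upper = s$coefficients[, "coef"] + qnorm(0.975) * s$coefficients[, "se(coef)"],
                   p_value = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL)
  out <- list(coefficients = co, loglik = fit$loglik[2],
              partial_hazards = unname(predict(fit, type = "risk")),
              fit = fit)
  class(out) <- "ehr_cox"
  out
}

#' Concordance index with a bootstrap confidence interval
#'
#' Harrell's C over comparable pairs: a pair is comparable when the earlier
#' time is an observed event; it is concordant when the earlier-failing
#' subject has the higher predicted hazard (ties in hazard count 1/2).
#' The CI resamples the (hazard, duration, event) triples with replacement
#' `n_boot` times and takes the 2.5% and 97.5% percentiles of the
#' recomputed C.
#'
#' @param partial_hazards predicted risk scores (higher = earlier failure).
#' @param durations follow-up times.
#' @param events logical/0-1 event indicators.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed (default 0).
#' @return list with `c_index`, `ci` (length-2), `n_boot`.
#' @export
concordance_ci <- function(partial_hazards, durations, events,
                           n_boot = 1000, seed = 0) {
  events <- as.integer(as.logical(events))
  c0 <- c_index(partial_hazards, durations, events)
  if (is.na(c0)) stop("no comparable pairs")
  set.seed(seed)
  n <- length(durations)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    c_index(partial_hazards[idx], durations[idx], events[idx])
  }, numeric(1))
  list(c_index = c0,
       ci = quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       n_boot = n_boot)
}

# Harrell's C over comparable pairs (vectorized O(n^2))
c_index <- function(h, d, e) {
  earlier <- outer(d, d, "<") & (e == 1)     # row i fails first, observed
  n_comp <- sum(earlier)
  if (n_comp == 0) return(NA_real_)
  conc <- sum(earlier & outer(h, h, ">"))
  ties <- sum(earlier & outer(h, h, "=="))
  (conc + 0.5 * ties) / n_comp
}

#' Fit a generalized linear model on frame columns
#'
#' Thin wrapper around [stats::glm()] operating on the combined
#' variables + obs table of an `ehrframe` (or a plain data.frame).
#'
#' @param frame an `ehrframe` or data.frame.
#' @param formula model formula (`outcome ~ predictors`).
#' @param family family name or family object (default `"gaussian"`).
#' @return the fitted `glm` object.
#' @export
fit_glm <- function(frame, formula, family = "gaussian") {
  df <- if (inherits(frame, "ehrframe")) as.data.frame(frame) else frame
  fam <- if (is.character(family)) {
    if (!exists(family, mode = "function")) stop("unknown family: ", family)
    get(family, mode = "function")()
  } else family
  glm(formula, data = df, family = fam)
}

#' Likelihood-ratio comparison of nested GLMs
#'
#' Computes the LRT p-value for the larger model against a nested smaller
#' model fitted on the same data; the degrees of freedom are the
#' parameter-count difference (a zero difference is degenerate and returns
#' p = 1).
#'
#' @param larger,smaller fitted `glm` objects, `smaller` nested in `larger`.
#' @return list with `statistic`, `dof`, `p_value`.
#' @export
compare_glm <- function(larger, smaller) {
  t_l <- attr(terms(larger), "term.labels")
  t_s <- attr(terms(smaller), "term.labels")
  if (!all(t_s %in% t_l)) stop("models are not nested")
  if (nobs(larger) != nobs(smaller)) stop("models were fitted on different data")
  stat <- max(0, 2 * (as.numeric(logLik(larger)) - as.numeric(logLik(smaller))))
  dof <- attr(logLik(larger), "df") - attr(logLik(smaller), "df")
  p <- if (dof <= 0) 1 else pchisq(stat, dof, lower.tail = FALSE)
  list(statistic = stat, dof = dof, p_value = p)
}
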