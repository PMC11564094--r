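#' Configuration for a synthetic EHR cohort
#'
#' Describes a mixed-type cohort with optional group structure: numeric
#' features are Gaussian with per-group mean shifts, categorical features
#' multinomial. Every generator in the package is a pure function of
#' (config, seed).
#'
#' @param n_patients cohort size (>= 1).
#' @param numeric named list; each entry
#'   `list(mean =, sd =, shift = c(group = delta, ...))` (shift optional).
#' @param categorical named list; each entry
#'   `list(levels = c(...), probs = c(...))` with probabilities summing
#'   to 1.
#' @param group optional `list(name =, levels =, probs =)` group variable
#'   written to the obs table.
#' @param seed RNG seed (default 0).
#' @return object of class `ehr_cohort_config`.
#' @export
cohort_config <- function(n_patients, numeric = list(), categorical = list(),
                          group = NULL, seed = 0) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  for (nm in names(categorical)) {
    pr <- categorical[[nm]]$probs
    if (abs(sum(pr) - 1) > 1e-8)
      stop("probabilities for '", nm, "' must sum to 1")
    if (length(pr) != length(categorical[[nm]]$levels))
      stop("levels/probs length mismatch for '", nm, "'")
  }
  if (!is.null(group) && abs(sum(group$probs) - 1) > 1e-8)
    stop("group probabilities must sum to 1")
  structure(list(n_patients = n_patients, numeric = numeric,
                 categorical = categorical, group = group, seed = seed),
            class = "ehr_cohort_config")
}

#' Generate a synthetic mixed-type cohort
#'
#' Samples the cohort described by a [cohort_config()]: numeric features
#' as Gaussians (with per-group mean shifts when a group variable is
#' configured), categorical features as multinomials. The group variable
#' lands in the obs table; features form the value matrix.
#'
#' @param config an `ehr_cohort_config`.
#' @return an `ehrframe`, deterministic given `config$seed`.
#' @examples
#' cfg <- cohort_config(100, numeric = list(age = list(mean = 50, sd = 10)),
#'                      seed = 1)
#' make_cohort(cfg)
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "ehr_cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  g <- if (!is.null(config$group))
    sample(config$group$levels, n, replace = TRUE, prob = config$group$probs)
  cols <- list(); kinds <- character(0)
  for (nm in names(config$numeric)) {
    sp <- config$numeric[[nm]]
    x <- rnorm(n, sp$mean, sp$sd)
    if (!is.null(sp$shift) && !is.null(g)) {
      sh <- sp$shift[g]; sh[is.na(sh)] <- 0
      x <- x + unname(sh)
    }
    cols[[nm]] <- x
    kinds[nm] <- "numeric"
  }
  for (nm in names(config$categorical)) {
    sp <- config$categorical[[nm]]
    cols[[nm]] <- sample(sp$levels, n, replace = TRUE, prob = sp$probs)
    kinds[nm] <- "categorical"
  }
  ids <- paste0("p", seq_len(n))
  if (!length(cols)) stop("config describes no features")
  tok <- lapply(cols, function(x) if (is.numeric(x)) fmt_num(x) else x)
  X <- do.call(cbind, tok)
  rownames(X) <- ids
  if (all(kinds == "numeric"))
    X <- matrix(as.numeric(X), n, length(cols), dimnames = list(ids, names(cols)))
  var <- data.frame(kind = unname(kinds), encoding_state = "raw",
                    row.names = names(cols))
  uns <- list()
  for (nm in names(config$categorical))
    uns$categories[[nm]] <- sort(config$categorical[[nm]]$levels)
  obs <- data.frame(row.names = ids)
  if (!is.null(g)) obs[[config$group$name]] <- factor(g, levels = config$group$levels)
  ehrframe(X, obs = obs, var = var, uns = uns)
}

#' Inject MCAR missingness
#'
#' Sets each entry of the variable missing independently with probability
#' `rate` (missing completely at random).
#'
#' @param frame an `ehrframe`.
#' @param variable variable name.
#' @param rate missingness probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return the updated `ehrframe`.
#' @export
inject_mcar <- function(frame, variable, rate, seed = 0) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!variable %in% colnames(frame$X)) stop("unknown variable: ", variable)
  set.seed(seed)
  drop <- runif(n_obs(frame)) < rate
  x <- var_values(frame, variable)
  x[drop] <- NA
  set_var_values(frame, variable, x)
}

#' Inject MAR missingness driven by an observed variable
#'
#' Standardizes the driver to mean 0 / sd 1 (population convention),
#' computes per-row missingness probabilities
#' `plogis(scale * z + offset)` and removes entries of the target by
#' Bernoulli sampling. The defaults (`scale = 1.2`, `offset = -0.6`)
#' produce a missingness rate near 40% with a strong dependence on the
#' driver, so the mechanism is missing-at-random with respect to the
#' observed driver.
#'
#' @param frame an `ehrframe`.
#' @param target variable to receive missingness.
#' @param driver complete numeric variable (or obs column) driving it.
#' @param scale logistic slope on the standardized driver (default 1.2).
#' @param offset logistic intercept (default -0.6).
#' @param seed RNG seed.
#' @return the updated `ehrframe`.
#' @export
inject_mar <- function(frame, target, driver, scale = 1.2, offset = -0.6,
                       seed = 0) {
  if (!target %in% colnames(frame$X)) stop("unknown variable: ", target)
  d <- if (driver %in% colnames(frame$X)) var_values(frame, driver)
  else if (driver %in% colnames(frame$obs)) frame$obs[[driver]]
  else stop("unknown driver: ", driver)
  if (!is.numeric(d)) stop("driver must be numeric")
  if (anyNA(d)) stop("driver must be complete")
  z <- (d - mean(d)) / sqrt(mean((d - mean(d))^2))
  set.seed(seed)
  drop <- runif(length(z)) < plogis(scale * z + offset)
  x <- var_values(frame, target)
  x[drop] <- NA
  set_var_values(frame, target, x)
}

#' Inject MNAR missingness driven by the value itself
#'
#' As [inject_mar()], but the logistic missingness probability is
#' evaluated on the standardized value being removed, so missingness
#' depends on unobserved data (missing not at random).
#'
#' @inheritParams inject_mar
#' @param scale,offset logistic parameters on the standardized target.
#' @return the updated `ehrframe`.
#' @export
inject_mnar <- function(frame, target, scale = 1.2, offset = -0.6, seed = 0) {
  if (!target %in% colnames(frame$X)) stop("unknown variable: ", target)
  x <- var_values(frame, target)
  if (!is.numeric(x)) stop("target must be numeric")
  z <- (x - mean(x, na.rm = TRUE)) /
    sqrt(mean((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE))
  set.seed(seed)
  drop <- !is.na(z) & runif(length(z)) < plogis(scale * z + offset)
  x[drop] <- NA
  set_var_values(frame, target, x)
}

#' Simulate a grouped survival cohort
#'
#' Draws exponential event times with a per-group hazard and independent
#' exponential censoring calibrated so that a fraction `censor_rate` of
#' each group is censored. Durations, event indicators and group labels
#' are written to the obs table; a standard-normal noise feature fills the
#' value matrix.
#'
#' @param n_per_group observations per group.
#' @param hazards named (or unnamed) positive per-group hazard rates.
#' @param censor_rate expected censoring fraction in `[0, 1)` (default 0.3).
#' @param seed RNG seed.
#' @return an `ehrframe` with obs columns `duration`, `event`, `group`.
#' @export
simulate_survival_cohort <- function(n_per_group, hazards, censor_rate = 0.3,
                                     seed = 0) {
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor rate must be in [0, 1)")
  if (is.null(names(hazards)))
    names(hazards) <- paste0("g", seq_along(hazards))
  set.seed(seed)
  rows <- lapply(names(hazards), function(gn) {
    h <- hazards[[gn]]
    t_event <- rexp(n_per_group, h)
    if (censor_rate > 0) {
      hc <- h * censor_rate / (1 - censor_rate)   # P(censor) = hc/(h+hc)
      t_cens <- rexp(n_per_group, hc)
    } else t_cens <- rep(Inf, n_per_group)
    data.frame(duration = pmin(t_event, t_cens),
               event = t_event <= t_cens, group = gn)
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  ids <- paste0("p", seq_len(n))
  X <- matrix(rnorm(n), n, 1, dimnames = list(ids, "noise"))
  obs <- data.frame(duration = df$duration, event = df$event,
                    group = factor(df$group), row.names = ids)
  ehrframe(X, obs = obs)
}

#' Specification of a linear structural causal model
#'
#' @param graph an `ehr_causal_graph`.
#' @param coefficients named numeric vector of per-edge linear weights,
#'   names `"parent->child"`; every edge must have one.
#' @param noise named per-node Gaussian noise sd (default 1 for all).
#' @param binarize_treatment optional node name whose value is binarized
#'   to `1{latent > 0}` before children consume it.
#' @return object of class `ehr_scm_spec`.
#' @export
scm_spec <- function(graph, coefficients, noise = NULL,
                     binarize_treatment = NULL) {
  stopifnot(inherits(graph, "ehr_causal_graph"))
  keys <- paste0(graph$edges$from, "->", graph$edges$to)
  missing_k <- setdiff(keys, names(coefficients))
  if (length(missing_k))
    stop("coefficients missing for edge(s): ", paste(missing_k, collapse = ", "))
  noise_full <- setNames(rep(1, length(graph$nodes)), graph$nodes)
  if (!is.null(noise)) noise_full[names(noise)] <- noise
  structure(list(graph = graph, coefficients = coefficients,
                 noise = noise_full, binarize_treatment = binarize_treatment),
            class = "ehr_scm_spec")
}

#' Sample from a linear structural causal model
#'
#' Ancestral sampling in topological order: each node is the
#' coefficient-weighted sum of its parents plus Gaussian noise; an
#' optional treatment node is binarized to `1{latent > 0}` before its
#' children consume it. The true total effect of the (binarized or raw)
#' treatment on every other node — the sum over directed paths of the
#' products of edge coefficients — is recorded in
#' `uns$true_effects` for test harnesses.
#'
#' @param spec an `ehr_scm_spec`.
#' @param n sample size.
#' @param seed RNG seed.
#' @return an `ehrframe` with one numeric variable per node.
#' @export
simulate_scm <- function(spec, n, seed = 0) {
  stopifnot(inherits(spec, "ehr_scm_spec"))
  g <- spec$graph
  ord <- names(igraph::topo_sort(g$igraph))
  set.seed(seed)
  vals <- matrix(0, n, length(g$nodes), dimnames = list(NULL, g$nodes))
  for (node in ord) {
    pa <- graph_parents(g, node)
    x <- rnorm(n, 0, spec$noise[[node]])
    for (p in pa)
      x <- x + spec$coefficients[[paste0(p, "->", node)]] * vals[, p]
    if (!is.null(spec$binarize_treatment) && node == spec$binarize_treatment)
      x <- as.numeric(x > 0)
    vals[, node] <- x
  }
  rownames(vals) <- paste0("p", seq_len(n))
  fr <- ehrframe(vals)
  src <- spec$binarize_treatment %||% ord[1]
  fr$uns$true_effects <- setNames(
    lapply(setdiff(g$nodes, src), function(tgt) path_effect(g, spec, src, tgt)),
    setdiff(g$nodes, src))
  fr$uns$scm <- list(nodes = g$nodes, treatment = spec$binarize_treatment)
  fr
}

# total causal effect src -> tgt: sum over directed paths of coefficient
# products
path_effect <- function(graph, spec, src, tgt) {
  total <- 0
  walk <- function(node, weight) {
    if (node == tgt) { total <<- total + weight; return(invisible()) }
    for (ch in graph$edges$to[graph$edges$from == node])
      walk(ch, weight * spec$coefficients[[paste0(node, "->", ch)]])
  }
  walk(src, 1)
  total
}
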