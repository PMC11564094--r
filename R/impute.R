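#' Replace missing entries with a designated value
#'
#' @param frame an `ehrframe`.
#' @param value scalar replacement, or a named list/vector mapping variable
#'   to its own replacement.
#' @param variables optional variable subset (default: all, or the names of
#'   `value` when it is a map).
#' @return list with the completed `frame` and an imputation `report`
#'   (per-variable imputed counts, method, parameters).
#' @export
impute_explicit <- function(frame, value, variables = NULL) {
  per_var <- length(value) > 1 || !is.null(names(value))
  variables <- variables %||% (if (per_var) names(value) else colnames(frame$X))
  counts <- setNames(integer(length(variables)), variables)
  for (v in variables) {
    x <- var_values(frame, v)
    val <- if (per_var) value[[v]] else value
    if (is.numeric(x) && !is.numeric(val))
      stop("replacement for numeric variable '", v, "' must be numeric")
    miss <- is.na(x)
    counts[v] <- sum(miss)
    x[miss] <- val
    frame <- set_var_values(frame, v, x)
  }
  list(frame = frame,
       report = imputation_report("explicit", counts, list(value = value)))
}

#' Impute missing entries with a per-variable summary statistic
#'
#' `mean` and `median` apply to numeric variables only; `most_frequent`
#' (the mode of the observed tokens) applies to any kind. The statistic is
#' computed over the non-missing entries of each variable. Note that under
#' MCAR with missing rate \eqn{r}, mean imputation preserves the mean but
#' shrinks the standard deviation by a factor of about \eqn{\sqrt{1-r}}.
#'
#' @param frame an `ehrframe`.
#' @param strategy `"mean"`, `"median"` or `"most_frequent"`.
#' @param variables optional variable subset.
#' @return list with the completed `frame` and the imputation `report`.
#' @export
impute_simple <- function(frame, strategy = c("mean", "median", "most_frequent"),
                          variables = NULL) {
  strategy <- match.arg(strategy)
  # mean/median only make sense for numeric variables; when no explicit
  # selection is given, target those (an explicit non-numeric request errors)
  variables <- variables %||% (if (strategy == "most_frequent") colnames(frame$X)
                               else colnames(frame$X)[numeric_valued(frame)])
  counts <- setNames(integer(length(variables)), variables)
  fills <- list()
  for (v in variables) {
    x <- var_values(frame, v)
    if (!is.numeric(x) && strategy %in% c("mean", "median"))
      stop(strategy, " imputation requires a numeric variable: ", v)
    obs <- x[!is.na(x)]
    if (!length(obs)) next
    fill <- switch(strategy,
      mean = mean(obs),
      median = median(obs),
      most_frequent = names(sort(table(obs), decreasing = TRUE))[1])
    if (is.numeric(x)) fill <- as.numeric(fill)
    miss <- is.na(x)
    counts[v] <- sum(miss)
    x[miss] <- fill
    fills[[v]] <- fill
    frame <- set_var_values(frame, v, x)
  }
  list(frame = frame,
       report = imputation_report(paste0("simple_", strategy), counts,
                                  list(fill_values = fills)))
}

#' k-nearest-neighbour imputation
#'
#' Each missing entry is replaced by the average of that variable over the
#' k nearest observations. Distances between incomplete rows are Euclidean
#' over the jointly observed coordinates, rescaled by
#' \eqn{\sqrt{p / p_{observed}}} so rows with few shared coordinates are
#' not artificially close. Neighbours must have the target variable
#' observed. O(n^2) in observations.
#'
#' @param frame an `ehrframe` with fully numeric `X` (encode first).
#' @param k neighbour count, default 20.
#' @param variables optional variable subset.
#' @return list with the completed `frame` and the imputation `report`.
#' @export
impute_knn <- function(frame, k = 20, variables = NULL) {
  if (!is_numeric_frame(frame))
    stop("impute_knn requires a numeric matrix; encode categoricals first")
  X <- frame$X
  n <- nrow(X); p <- ncol(X)
  if (k >= n) stop("k must be smaller than n_obs")
  variables <- variables %||% colnames(X)
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  # pairwise squared distances over shared observed coordinates
  shared <- tcrossprod(M * 1)
  D2 <- tcrossprod(X0^2, M * 1) + tcrossprod(M * 1, X0^2) - 2 * tcrossprod(X0)
  D2 <- D2 * p / pmax(shared, 1)
  D2[shared == 0] <- Inf
  diag(D2) <- Inf
  counts <- setNames(integer(length(variables)), variables)
  out <- X
  for (v in variables) {
    miss_rows <- which(is.na(X[, v]))
    counts[v] <- length(miss_rows)
    if (!length(miss_rows)) next
    donors_all <- which(!is.na(X[, v]))
    for (i in miss_rows) {
      d <- D2[i, donors_all]
      nb <- donors_all[order(d)[seq_len(min(k, length(donors_all)))]]
      out[i, v] <- mean(X[nb, v])
    }
  }
  frame$X <- out
  list(frame = frame,
       report = imputation_report("knn", counts, list(k = k)))
}

#' Iterative random-forest (MissForest-style) imputation
#'
#' Missing values are first filled with simple statistics (mean, or mode for
#' label-encoded categoricals); then, looping over variables in order of
#' increasing missingness, each variable is regressed on all others with a
#' random forest fitted on its originally observed rows and the originally
#' missing rows are re-predicted. Iteration stops when the normalized
#' squared change of the imputed values first increases (the values from
#' the preceding iteration are returned) or after `max_iter` sweeps.
#' Deterministic given `seed`.
#'
#' @param frame an `ehrframe` with fully numeric `X` (encode first).
#' @param max_iter maximum sweeps, default 10.
#' @param n_trees trees per forest, default 100.
#' @param seed RNG seed, default 0.
#' @param variables optional subset of variables to impute (all variables
#'   are still used as predictors).
#' @return list with the completed `frame` and the imputation `report`
#'   (including the convergence trace).
#' @export
impute_missforest <- function(frame, max_iter = 10, n_trees = 100, seed = 0,
                              variables = NULL) {
  if (!is_numeric_frame(frame))
    stop("impute_missforest requires a numeric matrix; encode categoricals first")
  X <- frame$X
  if (ncol(X) < 2) stop("iterative imputation needs at least 2 variables")
  variables <- variables %||% colnames(X)
  miss <- is.na(X)
  counts <- setNames(colSums(miss)[variables], variables)
  if (sum(counts) == 0)
    return(list(frame = frame,
                report = imputation_report("missforest", counts,
                                           list(iterations = 0, trace = numeric(0)))))
  is_label <- frame$var$encoding_state == "label"
  names(is_label) <- colnames(X)
  # initialization: mean (mode for label-encoded categoricals)
  cur <- X
  for (v in colnames(X)) {
    m <- miss[, v]
    if (!any(m)) next
    obs <- X[!m, v]
    cur[m, v] <- if (is_label[v])
      as.numeric(names(sort(table(obs), decreasing = TRUE))[1]) else mean(obs)
  }
  order_vars <- variables[order(counts[variables])]
  order_vars <- order_vars[counts[order_vars] > 0]
  set.seed(seed)
  trace <- numeric(0)
  prev <- cur
  best <- cur
  last_gamma <- Inf
  it <- 0
  for (it in seq_len(max_iter)) {
    for (v in order_vars) {
      m <- miss[, v]
      d <- as.data.frame(cur[, setdiff(colnames(X), v), drop = FALSE])
      resp <- cur[, v]
      dtrain <- d[!m, , drop = FALSE]
      ytrain <- if (is_label[v]) factor(resp[!m]) else resp[!m]
      if (is_label[v] && nlevels(ytrain) < 2) next
      dtrain$.y <- ytrain
      fit <- ranger::ranger(.y ~ ., data = dtrain, num.trees = n_trees,
                            seed = seed + it, num.threads = 1,
                            respect.unordered.factors = TRUE)
      pred <- predict(fit, data = d[m, , drop = FALSE], num.threads = 1)$predictions
      cur[m, v] <- if (is_label[v]) as.numeric(as.character(pred)) else pred
    }
    dif <- (cur - prev)[miss]
    denom <- sum(cur[miss]^2)
    gamma <- if (denom > 0) sum(dif^2) / denom else 0
    trace <- c(trace, gamma)
    if (gamma >= last_gamma) { cur <- prev; it <- it - 1; break }
    last_gamma <- gamma
    prev <- cur
    if (gamma == 0) break
  }
  frame$X <- cur
  list(frame = frame,
       report = imputation_report("missforest", counts,
                                  list(iterations = it, trace = trace,
                                       n_trees = n_trees, seed = seed)))
}

imputation_report <- function(method, counts, params = list()) {
  structure(list(method = method, imputed_counts = counts, params = params),
            class = "ehr_imputation_report")
}

#' @export
print.ehr_imputation_report <- function(x, ...) {
  cat(sprintf("imputation report: method=%s, %d entries imputed across %d variables\n",
              x$method, sum(x$imputed_counts), sum(x$imputed_counts > 0)))
  invisible(x)
}
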