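#' Missingness and value-range quality-control metrics
#'
#' Computes the absolute and relative number of missing values per variable
#' and per observation, plus min/max/mean/sd of the non-missing values of
#' each numeric-valued variable. Results are returned and also written into
#' the frame's obs/var tables when `write = TRUE` (use the returned
#' `$frame`).
#'
#' @param frame an `ehrframe`.
#' @param write also annotate the frame's obs/var tables (default TRUE).
#' @return list of class `ehr_qc_metrics` with `obs_metrics`, `var_metrics`,
#'   `total_missing` and (if `write`) the annotated `frame`.
#' @export
qc_metrics <- function(frame, write = TRUE) {
  miss <- is.na(frame$X)
  n <- nrow(miss); p <- ncol(miss)
  var_abs <- colSums(miss); obs_abs <- rowSums(miss)
  vm <- data.frame(missing_count = var_abs,
                   missing_frac = if (n > 0) var_abs / n else rep(0, p),
                   row.names = colnames(frame$X))
  numv <- numeric_valued(frame)
  vm$min <- vm$max <- vm$mean <- vm$sd <- NA_real_
  for (j in which(numv)) {
    x <- as.numeric(frame$X[, j]); x <- x[!is.na(x)]
    if (length(x)) {
      vm$min[j] <- min(x); vm$max[j] <- max(x)
      vm$mean[j] <- mean(x); vm$sd[j] <- if (length(x) > 1) sd(x) else NA_real_
    }
  }
  om <- data.frame(missing_count = obs_abs,
                   missing_frac = if (p > 0) obs_abs / p else rep(0, n),
                   row.names = rownames(frame$X))
  out <- list(obs_metrics = om, var_metrics = vm, total_missing = sum(miss))
  class(out) <- "ehr_qc_metrics"
  if (write) {
    frame$var$missing_count <- vm$missing_count
    frame$var$missing_frac <- vm$missing_frac
    frame$obs$missing_count <- om$missing_count
    frame$obs$missing_frac <- om$missing_frac
    out$frame <- frame
  }
  out
}

#' Collapse repeated per-patient measurements into summary statistics
#'
#' Groups observations by an obs-table key and replaces each numeric
#' variable by the requested statistics over the group's non-missing
#' values, yielding one observation per group (e.g. one row per patient
#' from many visits). A group with no observed value gets the missing
#' marker.
#'
#' @param frame an `ehrframe` with numeric-valued variables.
#' @param groupby obs-table column defining the groups.
#' @param statistics subset of `c("min", "max", "mean")`.
#' @param variables optional variable subset (default: all).
#' @return a new `ehrframe` with one observation per group and variables
#'   named `<variable>_<statistic>`.
#' @export
summarize_features <- function(frame, groupby,
                               statistics = c("min", "max", "mean"),
                               variables = NULL) {
  statistics <- match.arg(statistics, c("min", "max", "mean"), several.ok = TRUE)
  if (!groupby %in% colnames(frame$obs)) stop("unknown obs column: ", groupby)
  variables <- variables %||% colnames(frame$X)
  jj <- match(variables, colnames(frame$X))
  if (anyNA(jj)) stop("unknown variable(s)")
  if (!all(numeric_valued(frame)[jj]))
    stop("summarize_features requires numeric variables")
  g <- as.character(frame$obs[[groupby]])
  groups <- unique(g)
  funs <- list(min = function(x) if (length(x)) min(x) else NA_real_,
               max = function(x) if (length(x)) max(x) else NA_real_,
               mean = function(x) if (length(x)) mean(x) else NA_real_)
  out <- matrix(NA_real_, length(groups), length(variables) * length(statistics),
                dimnames = list(groups,
                                as.vector(t(outer(variables, statistics, paste, sep = "_")))))
  for (v in variables) {
    x <- as.numeric(frame$X[, v])
    for (st in statistics) {
      agg <- vapply(groups, function(gr) funs[[st]](x[g == gr & !is.na(x)]), numeric(1))
      out[, paste0(v, "_", st)] <- agg
    }
  }
  obs <- data.frame(row.names = groups)
  obs[[groupby]] <- groups
  ehrframe(out, obs = obs)
}

#' Winsorize extreme values at quantile limits
#'
#' Values below the `limits[1]` quantile are raised to that quantile and
#' values above the `1 - limits[2]` quantile lowered to it, per variable.
#' Quantiles use the inverse-empirical-CDF convention (`stats::quantile`
#' type 1), so the clamp values are order statistics of the data; with an
#' interpolated convention the operation would not be idempotent, with
#' this one applying it twice equals applying it once. Missing entries are
#' untouched.
#'
#' @param frame an `ehrframe`.
#' @param variables numeric variables to treat (default: all numeric-valued).
#' @param limits length-2 lower/upper tail fractions, each in `[0, 0.5)`.
#' @return the updated `ehrframe`.
#' @export
winsorize <- function(frame, variables = NULL, limits = c(0.01, 0.01)) {
  if (length(limits) != 2 || any(limits < 0) || any(limits >= 0.5))
    stop("limits must be two fractions in [0, 0.5)")
  variables <- variables %||% colnames(frame$X)[numeric_valued(frame)]
  for (v in variables) {
    x <- var_values(frame, v)
    if (!is.numeric(x)) stop("winsorize requires numeric variables: ", v)
    obsd <- !is.na(x)
    if (!any(obsd)) next
    lo <- quantile(x[obsd], limits[1], type = 1, names = FALSE)
    hi <- quantile(x[obsd], 1 - limits[2], type = 1, names = FALSE)
    x[obsd] <- pmin(pmax(x[obsd], lo), hi)
    frame <- set_var_values(frame, v, x)
  }
  frame
}

#' Clamp feature values into fixed bounds
#'
#' @param frame an `ehrframe`.
#' @param bounds named list mapping variable to `c(low, high)`.
#' @return list with the updated `frame` and `n_clipped`, the count of
#'   modified entries per variable.
#' @export
clip_features <- function(frame, bounds) {
  n_clipped <- setNames(integer(length(bounds)), names(bounds))
  for (v in names(bounds)) {
    b <- bounds[[v]]
    if (length(b) != 2 || b[1] > b[2]) stop("inverted bounds for ", v)
    x <- var_values(frame, v)
    if (!is.numeric(x)) stop("clip_features requires numeric variables: ", v)
    out <- pmin(pmax(x, b[1]), b[2])
    n_clipped[v] <- sum(out != x, na.rm = TRUE)
    frame <- set_var_values(frame, v, out)
  }
  list(frame = frame, n_clipped = n_clipped)
}

#' Audit a frame for distributional bias between sensitive groups
#'
#' Produces (i) Pearson pairwise-complete correlations over numeric
#' variables, (ii) standardized mean differences
#' \eqn{(\bar x_1 - \bar x_2)/s_{pooled}} for every numeric variable and
#' every pair of levels of each sensitive column, (iii) per-category count
#' and proportion differences for categorical variables across the same
#' group pairs, and (iv), when a target is named, a random-forest
#' permutation-free impurity importance ranking for predicting it.
#'
#' @param frame an `ehrframe`.
#' @param sensitive character vector of categorical obs columns (or factor
#'   obs columns) defining the groups.
#' @param target optional obs column or variable to rank feature importance
#'   for.
#' @param n_trees forest size for the importance ranking (default 200).
#' @param seed RNG seed for the forest (default 0).
#' @return list of class `ehr_bias_report` with `correlations`, `smd`,
#'   `categorical_diffs` and optionally `importance`.
#' @export
detect_bias <- function(frame, sensitive, target = NULL, n_trees = 200, seed = 0) {
  for (s in sensitive) {
    if (!s %in% colnames(frame$obs)) stop("unknown obs column: ", s)
    if (is.numeric(frame$obs[[s]]))
      stop("sensitive column must be categorical: ", s)
  }
  numv <- colnames(frame$X)[numeric_valued(frame)]
  Xn <- matrix(as.numeric(frame$X[, numv, drop = FALSE]),
               nrow(frame$X), length(numv), dimnames = list(rownames(frame$X), numv))
  correlations <- if (length(numv) > 1)
    cor(Xn, use = "pairwise.complete.obs") else NULL

  smd_rows <- list(); cat_rows <- list()
  catv <- colnames(frame$X)[frame$var$kind %in% c("categorical", "boolean") &
                              frame$var$encoding_state == "raw"]
  for (s in sensitive) {
    g <- as.character(frame$obs[[s]])
    lv <- sort(unique(g[!is.na(g)]))
    if (length(lv) < 2) next
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    for (pr in pairs) {
      i1 <- which(g == pr[1]); i2 <- which(g == pr[2])
      for (v in numv) {
        x1 <- Xn[i1, v]; x2 <- Xn[i2, v]
        x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
        if (length(x1) < 2 || length(x2) < 2) next
        sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                     (length(x1) + length(x2) - 2))
        smd_rows[[length(smd_rows) + 1]] <- data.frame(
          sensitive = s, group1 = pr[1], group2 = pr[2], variable = v,
          smd = if (sp > 0) (mean(x1) - mean(x2)) / sp else 0)
      }
      for (v in catv) {
        tok <- as.character(frame$X[, v])
        cats <- sort(unique(tok[!is.na(tok)]))
        for (cc in cats) {
          c1 <- sum(tok[i1] == cc, na.rm = TRUE)
          c2 <- sum(tok[i2] == cc, na.rm = TRUE)
          cat_rows[[length(cat_rows) + 1]] <- data.frame(
            sensitive = s, group1 = pr[1], group2 = pr[2], variable = v,
            category = cc, count_diff = c1 - c2,
            prop_diff = c1 / length(i1) - c2 / length(i2))
        }
      }
    }
  }
  out <- list(correlations = correlations,
              smd = if (length(smd_rows)) do.call(rbind, smd_rows) else NULL,
              categorical_diffs = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL)
  if (!is.null(target)) {
    y <- if (target %in% colnames(frame$obs)) frame$obs[[target]]
    else if (target %in% colnames(frame$X)) var_values(frame, target)
    else stop("unknown target: ", target)
    preds <- setdiff(numv, target)
    d <- as.data.frame(Xn[, preds, drop = FALSE])
    d$.target <- if (is.character(y)) factor(y) else y
    d <- d[complete.cases(d), , drop = FALSE]
    fit <- ranger::ranger(.target ~ ., data = d, num.trees = n_trees,
                          importance = "impurity", seed = seed,
                          num.threads = 1)
    out$importance <- sort(fit$variable.importance, decreasing = TRUE)
  }
  class(out) <- "ehr_bias_report"
  out
}

#' Randomly subsample observations
#'
#' Draws `floor(fraction * n_obs)` observations without replacement;
#' deterministic for a given seed.
#'
#' @param frame an `ehrframe`.
#' @param fraction fraction of observations to keep, in `(0, 1]`.
#' @param seed RNG seed.
#' @return the subsampled `ehrframe`.
#' @export
subsample <- function(frame, fraction, seed = 0) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_keep <- floor(fraction * n_obs(frame))
  set.seed(seed)
  frame_subset(frame, i = sort(sample.int(n_obs(frame), n_keep)))
}

#' Balance group sizes by random over- or undersampling
#'
#' Undersampling draws the minority-group size from every group without
#' replacement; oversampling draws the majority size with replacement.
#'
#' @param frame an `ehrframe`.
#' @param groupby categorical obs column with at least two levels.
#' @param method `"under"` (default) or `"over"`.
#' @param seed RNG seed.
#' @return the resampled `ehrframe` with exactly equal group sizes.
#' @export
balanced_sample <- function(frame, groupby, method = c("under", "over"), seed = 0) {
  method <- match.arg(method)
  if (!groupby %in% colnames(frame$obs)) stop("unknown obs column: ", groupby)
  g <- as.character(frame$obs[[groupby]])
  sizes <- table(g)
  if (length(sizes) < 2) stop("groupby needs at least 2 levels")
  if (any(sizes == 0)) stop("empty group in ", groupby)
  size <- if (method == "under") min(sizes) else max(sizes)
  set.seed(seed)
  idx <- unlist(lapply(names(sizes), function(lv) {
    rows <- which(g == lv)
    if (method == "under") sample(rows, size) else sample(rows, size, replace = TRUE)
  }))
  out <- frame_subset(frame, i = sort(idx), validate = FALSE)
  # oversampling duplicates rows: re-key observation identifiers
  if (anyDuplicated(rownames(out$X))) {
    ids <- make.unique(rownames(out$X), sep = "-dup")
    rownames(out$X) <- ids
    rownames(out$obs) <- ids
  }
  validate_ehrframe(out)
  out
}
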