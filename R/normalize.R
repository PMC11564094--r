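#' Normalize numeric variables, optionally per group
#'
#' Aligns the distributions of numeric variables with one of eight
#' transforms, fitted per variable (and independently within each level of
#' `group_key` when given — the group-wise variant that can mask true
#' between-group differences if applied carelessly):
#'
#' * `log`: `log1p` (natural base); requires values > -1.
#' * `maxabs`: divide by the maximum absolute value.
#' * `minmax`: rescale to `[0, 1]` from the observed min/max.
#' * `power`: Yeo-Johnson transform, lambda fitted by maximum likelihood,
#'   then standardized; makes skewed data more Gaussian-like.
#' * `quantile`: map every variable onto the across-variable mean
#'   order-statistic profile so all quantiles match; ties share averaged
#'   ranks.
#' * `robust_scale`: subtract the median, divide by the IQR.
#' * `scale`: subtract the mean, divide by the population (1/n) standard
#'   deviation.
#' * `offset`: shift so the lowest negative value becomes 0 (no-op when no
#'   negative values are present).
#'
#' Missing entries are excluded from parameter fitting and left missing.
#' A constant column under `scale`/`maxabs`/`minmax`/`robust_scale` maps to
#' all zeros with a warning.
#'
#' @param frame an `ehrframe`.
#' @param method one of `"log"`, `"maxabs"`, `"minmax"`, `"power"`,
#'   `"quantile"`, `"robust_scale"`, `"scale"`, `"offset"`.
#' @param variables numeric variables to transform (default: all
#'   numeric-valued).
#' @param group_key optional categorical obs column; parameters are fitted
#'   and applied within each group separately.
#' @return list with the transformed `frame` and a `record` (class
#'   `ehr_normalization_record`) holding the fitted parameters.
#' @examples
#' X <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
#'             dimnames = list(NULL, c("a", "b")))
#' normalize(ehrframe(X), "minmax")$frame$X
#' @export
normalize <- function(frame, method, variables = NULL, group_key = NULL) {
  methods_ok <- c("log", "maxabs", "minmax", "power", "quantile",
                  "robust_scale", "scale", "offset")
  if (!method %in% methods_ok) stop("unknown normalization method: ", method)
  variables <- variables %||% colnames(frame$X)[numeric_valued(frame)]
  jj <- match(variables, colnames(frame$X))
  if (anyNA(jj)) stop("unknown variable(s)")
  if (!all(numeric_valued(frame)[jj]))
    stop("normalize requires numeric variables")
  groups <- if (is.null(group_key)) {
    list(all = seq_len(n_obs(frame)))
  } else {
    if (!group_key %in% colnames(frame$obs)) stop("unknown obs column: ", group_key)
    g <- as.character(frame$obs[[group_key]])
    if (is.numeric(frame$obs[[group_key]]))
      stop("group_key must be categorical")
    split(seq_along(g), g)
  }
  params <- list()
  Xv <- matrix(as.numeric(frame$X[, variables, drop = FALSE]),
               n_obs(frame), length(variables), dimnames = list(NULL, variables))
  for (gname in names(groups)) {
    rows <- groups[[gname]]
    if (method == "quantile") {
      res <- quantile_normalize(Xv[rows, , drop = FALSE])
      Xv[rows, ] <- res$X
      params[[gname]] <- res$params
      next
    }
    for (v in variables) {
      x <- Xv[rows, v]
      obs <- !is.na(x)
      xo <- x[obs]
      if (!length(xo)) next
      res <- switch(method,
        log = {
          if (any(xo <= -1)) stop("log normalization requires values > -1 (variable ", v, ")")
          list(x = log1p(xo), p = list())
        },
        maxabs = {
          m <- max(abs(xo))
          if (m == 0) { warning("constant zero column '", v, "' left as zeros"); m <- 1 }
          list(x = xo / m, p = list(max_abs = m))
        },
        minmax = {
          lo <- min(xo); hi <- max(xo)
          if (hi == lo) { warning("constant column '", v, "' mapped to 0"); hi <- lo + 1 }
          list(x = (xo - lo) / (hi - lo), p = list(min = lo, max = hi))
        },
        power = {
          lam <- yeo_johnson_mle(xo)
          y <- yeo_johnson(xo, lam)
          mu <- mean(y); s <- sqrt(mean((y - mu)^2))
          if (s == 0) s <- 1
          list(x = (y - mu) / s, p = list(lambda = lam, mean = mu, sd = s))
        },
        robust_scale = {
          md <- median(xo); iqr <- quantile(xo, 0.75, names = FALSE) -
            quantile(xo, 0.25, names = FALSE)
          if (iqr == 0) { warning("zero IQR for '", v, "'; values mapped to 0"); iqr <- 1 }
          list(x = (xo - md) / iqr, p = list(median = md, iqr = iqr))
        },
        scale = {
          mu <- mean(xo); s <- sqrt(mean((xo - mu)^2))
          if (s == 0) { warning("constant column '", v, "' mapped to 0"); s <- 1 }
          list(x = (xo - mu) / s, p = list(mean = mu, sd = s))
        },
        offset = {
          lo <- min(xo)
          off <- if (lo < 0) -lo else 0
          list(x = xo + off, p = list(offset = off))
        })
      x[obs] <- res$x
      Xv[rows, v] <- x
      params[[gname]][[v]] <- res$p
    }
  }
  for (v in variables) frame <- set_var_values(frame, v, Xv[, v])
  record <- structure(list(method = method, group_key = group_key,
                           variables = variables, params = params),
                      class = "ehr_normalization_record")
  # stored unclassed so the uns slot stays plainly serializable
  frame$uns$normalization <- c(frame$uns$normalization, list(unclass(record)))
  list(frame = frame, record = record)
}

# map each column onto the across-column mean order-statistic profile;
# NAs left in place, ties averaged
quantile_normalize <- function(X) {
  p <- ncol(X)
  grid <- seq(0, 1, length.out = max(nrow(X), 2))
  profs <- sapply(seq_len(p), function(j) {
    xo <- X[!is.na(X[, j]), j]
    if (!length(xo)) return(rep(NA_real_, length(grid)))
    quantile(xo, grid, type = 7, names = FALSE)
  })
  ref <- rowMeans(profs, na.rm = TRUE)
  for (j in seq_len(p)) {
    obs <- !is.na(X[, j])
    if (!any(obs)) next
    r <- rank(X[obs, j], ties.method = "average")
    pos <- (r - 1) / max(sum(obs) - 1, 1)
    X[obs, j] <- approx(grid, ref, xout = pos, rule = 2)$y
  }
  list(X = X, params = list(reference_profile = ref))
}

# Yeo-Johnson power transform and its profile-likelihood lambda fit
yeo_johnson <- function(x, lambda) {
  y <- x
  pos <- x >= 0
  if (abs(lambda) > 1e-10) y[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  else y[pos] <- log1p(x[pos])
  if (abs(lambda - 2) > 1e-10)
    y[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  else y[!pos] <- -log1p(-x[!pos])
  y
}

yeo_johnson_mle <- function(x) {
  n <- length(x)
  ll <- function(lambda) {
    y <- yeo_johnson(x, lambda)
    s2 <- mean((y - mean(y))^2)
    if (s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
  }
  stats::optimize(ll, c(-5, 5), maximum = TRUE)$maximum
}

#' @export
print.ehr_normalization_record <- function(x, ...) {
  cat(sprintf("normalization record: method=%s%s, %d variable(s)\n", x$method,
              if (!is.null(x$group_key)) paste0(", group_key=", x$group_key) else "",
              length(x$variables)))
  invisible(x)
}

#' Residualize variables on covariates
#'
#' Replaces each targeted variable by the residuals of an ordinary
#' least-squares fit on the given obs-table covariates (intercept
#' included), removing unwanted sources of variation. The fit uses the
#' rows complete in both variable and covariates; other rows keep their
#' value status. Rank-deficient designs are handled by the pivoted QR
#' (aliased columns dropped) with a warning.
#'
#' @param frame an `ehrframe`.
#' @param covariates obs-table columns (numeric, or factors which are
#'   expanded to indicators).
#' @param variables numeric variables to residualize (default: all
#'   numeric-valued).
#' @return the updated `ehrframe`.
#' @export
regress_out <- function(frame, covariates, variables = NULL) {
  unknown <- setdiff(covariates, colnames(frame$obs))
  if (length(unknown)) stop("unknown obs column(s): ", paste(unknown, collapse = ", "))
  variables <- variables %||% colnames(frame$X)[numeric_valued(frame)]
  cov_df <- frame$obs[, covariates, drop = FALSE]
  D <- model.matrix(~ ., data = cov_df)
  if (qr(D)$rank < ncol(D))
    warning("rank-deficient covariate design; aliased columns dropped")
  for (v in variables) {
    y <- var_values(frame, v)
    if (!is.numeric(y)) stop("regress_out requires numeric variables: ", v)
    ok <- !is.na(y) & complete.cases(cov_df)
    if (sum(ok) <= ncol(D)) next
    fit <- lm.fit(D[ok, , drop = FALSE], y[ok])
    y[ok] <- fit$residuals
    frame <- set_var_values(frame, v, y)
  }
  frame
}
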