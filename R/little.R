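#' Little's test of the missing-completely-at-random hypothesis
#'
#' Tests the null hypothesis that the missing entries of the selected
#' numeric variables are MCAR. Observations are grouped by their
#' missingness pattern; the grand mean vector \eqn{\hat\mu} and covariance
#' \eqn{\hat\Sigma} are estimated by expectation-maximization under the
#' multivariate-normal model, and the statistic
#' \deqn{d^2 = \sum_j m_j\,(\bar y_{obs,j} - \hat\mu_{obs,j})^\top
#'   \hat\Sigma_{obs,j}^{-1} (\bar y_{obs,j} - \hat\mu_{obs,j})}
#' sums the Mahalanobis distances of each pattern's observed-variable mean
#' from the EM grand mean, restricted to that pattern's observed variables.
#' Under MCAR, \eqn{d^2} is asymptotically chi-squared with
#' \eqn{\sum_j p_j - p} degrees of freedom. A significant result indicates
#' the data are not MCAR (e.g. MAR on an observed driver); a non-significant
#' result is consistent with, but does not prove, MCAR.
#'
#' @param frame an `ehrframe`, or a numeric matrix/data.frame.
#' @param variables numeric variables to include (default: all
#'   numeric-valued variables of the frame).
#' @param tol EM convergence tolerance on parameter change (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @return list of class `ehr_mcar_test` with `statistic`, `dof`,
#'   `p_value`, `n_patterns` and the EM estimates `mu`, `sigma`.
#' @examples
#' set.seed(1)
#' Y <- MASS::mvrnorm(200, c(0, 0), diag(2))
#' Y[sample(200, 40), 1] <- NA
#' little_mcar_test(Y)$p_value
#' @export
little_mcar_test <- function(frame, variables = NULL, tol = 1e-6,
                             max_iter = 200) {
  Y <- if (inherits(frame, "ehrframe")) {
    variables <- variables %||% colnames(frame$X)[numeric_valued(frame)]
    jj <- match(variables, colnames(frame$X))
    if (anyNA(jj)) stop("unknown variable(s)")
    if (!all(numeric_valued(frame)[jj]))
      stop("little_mcar_test requires numeric variables")
    matrix(as.numeric(frame$X[, jj, drop = FALSE]), n_obs(frame),
           length(jj), dimnames = list(NULL, variables))
  } else as.matrix(frame)
  storage.mode(Y) <- "double"
  p <- ncol(Y)
  # drop rows with nothing observed: they carry no information
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  n <- nrow(Y)
  pat_id <- apply((!is.na(Y)) * 1L, 1, paste, collapse = "")
  pats <- unique(pat_id)
  if (length(pats) < 2)
    stop("degenerate input: need at least 2 distinct missingness patterns")

  est <- em_norm(Y, tol = tol, max_iter = max_iter)
  mu <- est$mu; sigma <- est$sigma

  d2 <- 0; dof <- 0
  for (pt in pats) {
    rows <- which(pat_id == pt)
    obs <- which(strsplit(pt, "")[[1]] == "1")
    m_j <- length(rows); p_j <- length(obs)
    dof <- dof + p_j
    ybar <- colMeans(Y[rows, obs, drop = FALSE])
    S <- sigma[obs, obs, drop = FALSE]
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("singular covariance for missingness pattern '", pt, "'"))
    d <- ybar - mu[obs]
    d2 <- d2 + m_j * drop(t(d) %*% Sinv %*% d)
  }
  dof <- dof - p
  out <- list(statistic = d2, dof = dof,
              p_value = pchisq(d2, df = dof, lower.tail = FALSE),
              n_patterns = length(pats), mu = mu, sigma = sigma,
              n_iter = est$n_iter, converged = est$converged)
  class(out) <- "ehr_mcar_test"
  out
}

#' @export
print.ehr_mcar_test <- function(x, ...) {
  cat(sprintf("Little's MCAR test: d^2 = %.4f, dof = %d, p = %.4g (%d patterns)\n",
              x$statistic, x$dof, x$p_value, x$n_patterns))
  invisible(x)
}

# EM estimation of a multivariate-normal mean/covariance under arbitrary
# missingness. Returns maximum-likelihood (1/n) estimates.
em_norm <- function(Y, tol = 1e-6, max_iter = 200) {
  n <- nrow(Y); p <- ncol(Y)
  miss <- is.na(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  v <- apply(Y, 2, var, na.rm = TRUE)
  v[is.na(v) | v <= 0] <- 1
  sigma <- diag(v, p)
  cc <- complete.cases(Y)
  if (sum(cc) > p) {
    S0 <- cov(Y[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
    if (all(is.finite(S0)) && det(S0) > 0) sigma <- S0
  }
  pat_id <- apply((!miss) * 1L, 1, paste, collapse = "")
  pats <- unique(pat_id)
  converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    sum_y <- numeric(p)
    sum_yy <- matrix(0, p, p)
    for (pt in pats) {
      rows <- which(pat_id == pt)
      obs <- which(strsplit(pt, "")[[1]] == "1")
      mis <- setdiff(seq_len(p), obs)
      Yo <- Y[rows, obs, drop = FALSE]
      m_j <- length(rows)
      if (!length(mis)) {
        sum_y <- sum_y + colSums(Yo)
        sum_yy <- sum_yy + crossprod(Yo)
        next
      }
      Soo_inv <- solve(sigma[obs, obs, drop = FALSE])
      B <- sigma[mis, obs, drop = FALSE] %*% Soo_inv          # regression coefs
      cond_mu <- matrix(mu[mis], m_j, length(mis), byrow = TRUE) +
        (Yo - matrix(mu[obs], m_j, length(obs), byrow = TRUE)) %*% t(B)
      C <- sigma[mis, mis, drop = FALSE] -
        B %*% sigma[obs, mis, drop = FALSE]                   # conditional cov
      Yc <- matrix(0, m_j, p)
      Yc[, obs] <- Yo
      Yc[, mis] <- cond_mu
      sum_y <- sum_y + colSums(Yc)
      cp <- crossprod(Yc)
      cp[mis, mis] <- cp[mis, mis, drop = FALSE] + m_j * C
      sum_yy <- sum_yy + cp
    }
    mu_new <- sum_y / n
    sigma_new <- sum_yy / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(mu = mu, sigma = sigma, n_iter = it, converged = converged)
}
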