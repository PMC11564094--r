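#' Annotated observations x variables container for EHR tables
#'
#' An `ehrframe` holds a patient-visit table as a value matrix `X`
#' (observations are rows, measured quantities are columns) together with
#' aligned annotation tables and named result slots:
#'
#' * `X`: the value matrix. Numeric (`double`) once every variable is
#'   numeric-valued; of mode character while unencoded categorical, boolean,
#'   date or free-text variables are present, in which case it stores the
#'   raw input tokens. Missing entries are `NA` in either mode.
#' * `obs`: per-observation annotations, one row per observation.
#' * `var`: per-variable annotations; always carries the feature schema
#'   columns `kind` (one of `numeric`, `categorical`, `boolean`, `datetime`,
#'   `text`) and `encoding_state` (`raw`, `one_hot` or `label`).
#' * `layers`: named list of matrices with the same shape as `X`.
#' * `obsm` / `varm`: named matrices with one row per observation /
#'   variable (embeddings, loadings).
#' * `obsp`: named observation-by-observation relations (possibly sparse).
#' * `uns`: free-form keyed results (encoding maps, fitted parameters,
#'   pipeline provenance).
#'
#' Ordered category levels of categorical variables are kept in
#' `uns$categories[[variable]]`.
#'
#' @param X matrix (double or character) with unique row and column names.
#' @param obs data.frame of per-observation annotations (`nrow(X)` rows).
#' @param var data.frame of per-variable annotations (`ncol(X)` rows).
#' @param layers,obsm,varm,obsp named lists of aligned matrices.
#' @param uns named list of unstructured results.
#' @return A validated `ehrframe` object.
#' @examples
#' X <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("p", 1:3), c("a", "b")))
#' ehrframe(X)
#' @export
ehrframe <- function(X, obs = NULL, var = NULL, layers = list(),
                     obsm = list(), varm = list(), obsp = list(),
                     uns = list()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(dimnames(X))) dimnames(X) <- list(NULL, NULL)
  if (is.null(rownames(X)) && nrow(X) > 0)
    rownames(X) <- paste0("obs_", seq_len(nrow(X)))
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("var_", seq_len(ncol(X)))
  if (is.null(obs)) obs <- data.frame(row.names = rownames(X))
  if (is.null(var)) var <- data.frame(row.names = colnames(X))
  if (is.null(var$kind)) var$kind <- rep("numeric", ncol(X))
  if (is.null(var$encoding_state)) var$encoding_state <- rep("raw", ncol(X))
  frame <- structure(
    list(X = X, obs = obs, var = var, layers = layers, obsm = obsm,
         varm = varm, obsp = obsp, uns = uns),
    class = "ehrframe"
  )
  validate_ehrframe(frame)
  frame
}

#' Validate the alignment invariants of an ehrframe
#'
#' Checks that all row-aligned components have exactly `n_obs` rows, all
#' column-aligned components `n_vars` rows, every layer matches the shape of
#' `X`, and observation/variable identifiers are unique. Called by every
#' operation that rebuilds a frame.
#'
#' @param frame an `ehrframe`.
#' @return `frame`, invisibly; signals an error on any violation.
#' @export
validate_ehrframe <- function(frame) {
  stopifnot(inherits(frame, "ehrframe"))
  X <- frame$X
  n <- nrow(X); p <- ncol(X)
  if (anyDuplicated(rownames(X))) stop("observation identifiers must be unique")
  if (anyDuplicated(colnames(X))) stop("variable identifiers must be unique")
  if (nrow(frame$obs) != n) stop("obs table must have n_obs rows")
  if (nrow(frame$var) != p) stop("var table must have n_vars rows")
  if (n > 0 && !identical(rownames(frame$obs), rownames(X)))
    stop("obs table rownames must match observation identifiers")
  if (p > 0 && !identical(rownames(frame$var), colnames(X)))
    stop("var table rownames must match variable identifiers")
  for (nm in names(frame$layers)) {
    L <- frame$layers[[nm]]
    if (!all(dim(L) == c(n, p))) stop("layer '", nm, "' must have the shape of X")
  }
  for (nm in names(frame$obsm))
    if (nrow(frame$obsm[[nm]]) != n) stop("obsm '", nm, "' must have n_obs rows")
  for (nm in names(frame$varm))
    if (nrow(frame$varm[[nm]]) != p) stop("varm '", nm, "' must have n_vars rows")
  for (nm in names(frame$obsp))
    if (!all(dim(frame$obsp[[nm]]) == c(n, n)))
      stop("obsp '", nm, "' must be n_obs x n_obs")
  invisible(frame)
}

#' @export
dim.ehrframe <- function(x) dim(x$X)

#' Number of observations / variables
#' @param frame an `ehrframe`.
#' @return integer count.
#' @export
n_obs <- function(frame) nrow(frame$X)

#' @rdname n_obs
#' @export
n_vars <- function(frame) ncol(frame$X)

#' @export
print.ehrframe <- function(x, ...) {
  cat(sprintf("ehrframe: %d observations x %d variables (%s X)\n",
              nrow(x$X), ncol(x$X),
              if (is.numeric(x$X)) "numeric" else "mixed"))
  kinds <- table(x$var$kind)
  cat("  var kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  slot_line <- function(label, nms)
    if (length(nms)) cat(sprintf("  %s: %s\n", label, paste(nms, collapse = ", ")))
  slot_line("obs columns", colnames(x$obs))
  slot_line("layers", names(x$layers))
  slot_line("obsm", names(x$obsm))
  slot_line("varm", names(x$varm))
  slot_line("obsp", names(x$obsp))
  slot_line("uns", names(x$uns))
  invisible(x)
}

# TRUE once every variable holds numeric values (numeric kind or encoded)
is_numeric_frame <- function(frame) is.numeric(frame$X)

# TRUE per variable when its column in X holds numbers
numeric_valued <- function(frame) {
  frame$var$kind == "numeric" | frame$var$encoding_state != "raw"
}

#' Extract the values of one variable with its native type
#'
#' Numeric-valued variables (kind `numeric`, or any encoded variable) are
#' returned as `numeric`; all other kinds as `character` tokens. Missing
#' entries are `NA`.
#'
#' @param frame an `ehrframe`.
#' @param name variable name.
#' @return numeric or character vector of length `n_obs`.
#' @export
var_values <- function(frame, name) {
  if (!name %in% colnames(frame$X)) stop("unknown variable: ", name)
  v <- frame$X[, name]
  j <- match(name, colnames(frame$X))
  if (numeric_valued(frame)[j]) as.numeric(v) else as.character(v)
}

# replace one column of X, keeping storage mode consistent
set_var_values <- function(frame, name, values) {
  if (is.numeric(frame$X)) {
    frame$X[, name] <- as.numeric(values)
  } else {
    # full-precision tokens so numeric values survive the character matrix;
    # missing entries stay NA, never the literal token "NA"
    tok <- if (is.numeric(values)) fmt_num(values) else as.character(values)
    tok[is.na(values)] <- NA
    frame$X[, name] <- tok
  }
  frame
}

# collapse X to double storage when every variable is numeric-valued
maybe_numeric_X <- function(frame) {
  if (!is.numeric(frame$X) && all(numeric_valued(frame))) {
    X <- frame$X
    num <- suppressWarnings(matrix(as.numeric(X), nrow(X), ncol(X),
                                   dimnames = dimnames(X)))
    frame$X <- num
  }
  frame
}

# subset observations (i) and/or variables (j); keeps every slot aligned
frame_subset <- function(frame, i = NULL, j = NULL, validate = TRUE) {
  if (!is.null(i)) {
    i <- if (is.character(i)) match(i, rownames(frame$X)) else i
    frame$X <- frame$X[i, , drop = FALSE]
    frame$obs <- frame$obs[i, , drop = FALSE]
    frame$layers <- lapply(frame$layers, function(L) L[i, , drop = FALSE])
    frame$obsm <- lapply(frame$obsm, function(M) M[i, , drop = FALSE])
    frame$obsp <- lapply(frame$obsp, function(P) P[i, i, drop = FALSE])
    if (!is.null(frame$uns$encoding$raw))
      frame$uns$encoding$raw <- lapply(frame$uns$encoding$raw, function(v) v[i])
  }
  if (!is.null(j)) {
    j <- if (is.character(j)) match(j, colnames(frame$X)) else j
    dropped <- setdiff(colnames(frame$X), colnames(frame$X)[j])
    frame$X <- frame$X[, j, drop = FALSE]
    frame$var <- frame$var[j, , drop = FALSE]
    frame$layers <- lapply(frame$layers, function(L) L[, j, drop = FALSE])
    frame$varm <- lapply(frame$varm, function(M) M[j, , drop = FALSE])
    frame$uns$categories <- frame$uns$categories[
      intersect(names(frame$uns$categories), colnames(frame$X))]
    for (d in dropped) {
      frame$uns$encoding$raw[[d]] <- NULL
      frame$uns$encoding$map[[d]] <- NULL
    }
  }
  if (validate) validate_ehrframe(frame)
  frame
}

#' @export
`[.ehrframe` <- function(x, i, j, ...) {
  frame_subset(x,
               i = if (missing(i)) NULL else i,
               j = if (missing(j)) NULL else j)
}

#' Convert an ehrframe to a data.frame
#'
#' Binds the typed variable columns of `X` with the obs table (obs columns
#' prefixed only on name collision).
#'
#' @param x an `ehrframe`.
#' @param ... unused.
#' @return data.frame with `n_obs` rows.
#' @export
as.data.frame.ehrframe <- function(x, ...) {
  cols <- lapply(colnames(x$X), function(v) var_values(x, v))
  names(cols) <- colnames(x$X)
  df <- data.frame(cols, row.names = rownames(x$X), check.names = FALSE)
  for (cn in colnames(x$obs)) {
    nm <- if (cn %in% names(df)) paste0("obs.", cn) else cn
    df[[nm]] <- x$obs[[cn]]
  }
  df
}
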