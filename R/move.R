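#' Move variables from the value matrix into the obs table
#'
#' Removes the named variables from `X`/`var` and appends them to the obs
#' table with their native type restored: numeric values, factors with the
#' recorded category levels, logicals for booleans, `Date`s for datetimes.
#' Encoded variables are decoded first. Typical use: park outcome labels or
#' sensitive attributes where models cannot see them.
#'
#' @param frame an `ehrframe`.
#' @param variables character vector of variable names.
#' @return the updated `ehrframe` with `n_vars` reduced accordingly.
#' @export
move_to_obs <- function(frame, variables) {
  if (!length(variables)) return(frame)
  unknown <- setdiff(variables, c(colnames(frame$X),
                                  names(frame$uns$encoding$map)))
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  encoded <- intersect(variables, names(frame$uns$encoding$map))
  if (length(encoded)) frame <- decode(frame, encoded)
  clash <- intersect(variables, colnames(frame$obs))
  if (length(clash)) stop("obs column(s) already exist: ", paste(clash, collapse = ", "))
  for (v in variables) {
    j <- match(v, colnames(frame$X))
    kind <- frame$var$kind[j]
    vals <- var_values(frame, v)
    frame$obs[[v]] <- switch(kind,
      numeric = vals,
      categorical = factor(vals, levels = frame$uns$categories[[v]] %||%
                             sort(unique(vals[!is.na(vals)]))),
      boolean = tolower(vals) %in% c("1", "true", "yes") & !is.na(vals),
      datetime = as.Date(vals),
      vals)
    if (kind == "boolean") frame$obs[[v]][is.na(vals)] <- NA
  }
  maybe_numeric_X(frame_subset(frame, j = setdiff(colnames(frame$X), variables)))
}

#' Move obs-table columns into the value matrix
#'
#' Inverse of [move_to_obs()]: removes the named columns from the obs table
#' and appends them to `X` with an inferred feature schema.
#'
#' @param frame an `ehrframe`.
#' @param obs_columns character vector of obs column names.
#' @return the updated `ehrframe` with `n_vars` increased accordingly.
#' @export
move_to_x <- function(frame, obs_columns) {
  if (!length(obs_columns)) return(frame)
  unknown <- setdiff(obs_columns, colnames(frame$obs))
  if (length(unknown)) stop("unknown obs column(s): ", paste(unknown, collapse = ", "))
  clash <- intersect(obs_columns, colnames(frame$X))
  if (length(clash))
    stop("variable name collision with existing matrix column(s): ",
         paste(clash, collapse = ", "))
  for (cn in obs_columns) {
    col <- frame$obs[[cn]]
    if (is.factor(col)) {
      kind <- "categorical"; levels_ <- levels(col); tokens <- as.character(col)
    } else if (is.logical(col)) {
      kind <- "boolean"; levels_ <- NULL
      tokens <- ifelse(is.na(col), NA, ifelse(col, "true", "false"))
    } else if (inherits(col, "Date")) {
      kind <- "datetime"; levels_ <- NULL; tokens <- format(col, "%Y-%m-%d")
    } else if (is.numeric(col)) {
      kind <- "numeric"; levels_ <- NULL
      tokens <- ifelse(is.na(col), NA, fmt_num(col))
    } else {
      tokens <- as.character(col)
      kind <- infer_kind(tokens)
      levels_ <- if (kind == "categorical") sort(unique(tokens[!is.na(tokens)]))
    }
    if (kind != "numeric" && is.numeric(frame$X)) {
      frame$X <- matrix(ifelse(is.na(frame$X), NA, fmt_num(frame$X)),
                        nrow(frame$X), ncol(frame$X), dimnames = dimnames(frame$X))
    }
    newcol <- if (is.numeric(frame$X)) as.numeric(tokens) else tokens
    frame$X <- cbind(frame$X, matrix(newcol, ncol = 1, dimnames = list(NULL, cn)))
    newrow <- frame$var[0, , drop = FALSE]
    newrow[cn, ] <- NA
    newrow[cn, "kind"] <- kind
    newrow[cn, "encoding_state"] <- "raw"
    if ("missing_frac" %in% colnames(frame$var))
      newrow[cn, "missing_frac"] <- mean(is.na(tokens))
    frame$var <- rbind(frame$var, newrow)
    if (!is.null(levels_)) frame$uns$categories[[cn]] <- levels_
    frame$obs[[cn]] <- NULL
    frame$layers <- lapply(frame$layers, function(L)
      cbind(L, matrix(NA, nrow(L), 1, dimnames = list(NULL, cn))))
    frame$varm <- lapply(frame$varm, function(M)
      rbind(M, matrix(NA, 1, ncol(M), dimnames = list(cn, NULL))))
  }
  frame <- maybe_numeric_X(frame)
  validate_ehrframe(frame)
  frame
}

`%||%` <- function(a, b) if (is.null(a)) b else a
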