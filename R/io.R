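#' Read a delimited patient-visit table into an ehrframe
#'
#' Parses a rectangular CSV/TSV file with a header row into an [ehrframe()],
#' one observation per data row. Column kinds are inferred from the cell
#' tokens (see [infer_feature_types()]) unless overridden. Empty cells and
#' `na_tokens` become the missing marker `NA`.
#'
#' @param path file path.
#' @param delimiter field separator, default `","`.
#' @param index_column optional column name used as observation identifiers.
#' @param type_overrides named character vector mapping column name to a
#'   kind in `numeric`, `categorical`, `boolean`, `datetime`, `text`.
#' @param na_tokens tokens treated as missing, default `c("", "NA", "NaN", "null")`.
#' @param max_categories distinct-token threshold separating `categorical`
#'   from `text` during inference (default 100).
#' @return an `ehrframe`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("age,sex", "34,M", "51,F", "47,M"), f)
#' read_tabular(f)
#' @export
read_tabular <- function(path, delimiter = ",", index_column = NULL,
                         type_overrides = NULL,
                         na_tokens = c("", "NA", "NaN", "null"),
                         max_categories = 100) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  widths <- utils::count.fields(path, sep = delimiter, quote = "\"")
  if (length(unique(widths)) > 1)
    stop("ragged rows: file is not a rectangular table")
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  if (!is.null(type_overrides)) {
    bad <- setdiff(names(type_overrides), colnames(df))
    if (length(bad)) stop("type override names absent column(s): ",
                          paste(bad, collapse = ", "))
  }
  obs_ids <- if (!is.null(index_column)) {
    if (!index_column %in% colnames(df)) stop("index column not found: ", index_column)
    ids <- df[[index_column]]
    df[[index_column]] <- NULL
    ids
  } else paste0("obs_", seq_len(nrow(df)))
  for (cn in colnames(df)) df[[cn]][df[[cn]] %in% na_tokens] <- NA
  build_frame_from_tokens(df, obs_ids, type_overrides, max_categories)
}

# assemble an ehrframe from a character data.frame of raw tokens
build_frame_from_tokens <- function(df, obs_ids, type_overrides = NULL,
                                    max_categories = 100) {
  kinds <- vapply(colnames(df), function(cn) {
    if (!is.null(type_overrides) && cn %in% names(type_overrides))
      type_overrides[[cn]]
    else infer_kind(df[[cn]], max_categories)
  }, character(1))
  X <- as.matrix(df)
  rownames(X) <- obs_ids
  if (all(kinds == "numeric")) {
    X <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
  }
  var <- data.frame(kind = unname(kinds),
                    encoding_state = "raw",
                    row.names = colnames(df))
  var$missing_frac <- colMeans(is.na(X))
  uns <- list()
  for (cn in colnames(df)[kinds == "categorical"])
    uns$categories[[cn]] <- sort(unique(df[[cn]][!is.na(df[[cn]])]))
  ehrframe(X, var = var, uns = uns)
}

boolean_token_sets <- list(c("0", "1"), c("false", "true"), c("no", "yes"))

# kind of a single token column: numeric / boolean / datetime / categorical / text
infer_kind <- function(tokens, max_categories = 100) {
  vals <- tokens[!is.na(tokens)]
  if (!length(vals)) return("numeric")
  num <- suppressWarnings(as.numeric(vals))
  lower <- unique(tolower(vals))
  is_bool <- any(vapply(boolean_token_sets,
                        function(s) all(lower %in% s) && length(lower) <= 2,
                        logical(1)))
  if (is_bool && !all(lower %in% c("0", "1"))) return("boolean")
  if (!anyNA(num)) return("numeric")
  if (is_bool) return("boolean")
  if (all(grepl("^\\d{4}-\\d{2}-\\d{2}$", vals)) &&
      !anyNA(suppressWarnings(as.Date(vals, format = "%Y-%m-%d"))))
    return("datetime")
  if (length(unique(vals)) <= max_categories) return("categorical")
  "text"
}

#' Re-infer feature kinds from current values
#'
#' Assigns each variable a kind by inspecting its values: all parseable as
#' numbers gives `numeric`; a two-token set from \{0,1\}, \{true,false\},
#' \{yes,no\} (case-insensitive) gives `boolean`; ISO dates give `datetime`;
#' at most `max_categories` distinct tokens give `categorical`; anything
#' else is `text`. The decision is recorded in the var table; category
#' levels are refreshed in `uns$categories`.
#'
#' @param frame an `ehrframe`.
#' @param max_categories categorical/text threshold (default 100).
#' @return the updated `ehrframe`.
#' @export
infer_feature_types <- function(frame, max_categories = 100) {
  if (n_vars(frame) == 0) stop("cannot infer feature types of an empty frame")
  for (j in seq_len(n_vars(frame))) {
    if (frame$var$encoding_state[j] != "raw") next
    cn <- colnames(frame$X)[j]
    tokens <- as.character(frame$X[, j])
    kind <- infer_kind(tokens, max_categories)
    frame$var$kind[j] <- kind
    if (kind == "categorical")
      frame$uns$categories[[cn]] <- sort(unique(tokens[!is.na(tokens)]))
  }
  maybe_numeric_X(frame)
}

## ---------------------------------------------------------------------------
## On-disk store. Same group layout as the h5ad convention (X, obs, var,
## layers, obsm, varm, obsp, uns), realised as a directory of plain-text
## files; numerics are written with 17 significant digits so doubles
## round-trip bitwise.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_matrix_txt <- function(M, path) {
  ch <- if (is.numeric(M)) matrix(fmt_num(M), nrow(M), ncol(M)) else
    matrix(ifelse(is.na(M), "\033NA", M), nrow(M), ncol(M))
  df <- as.data.frame(ch, stringsAsFactors = FALSE)
  if (!is.null(colnames(M))) colnames(df) <- colnames(M)
  utils::write.table(df, path, sep = ",", qmethod = "double",
                     row.names = FALSE, col.names = TRUE, quote = !is.numeric(M))
}

read_matrix_txt <- function(path, mode, dimnames_) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  M <- as.matrix(df)
  if (mode == "double") {
    M[M == "NA"] <- NA
    M <- matrix(as.numeric(M), nrow(M), ncol(M))
  } else {
    M[M == "\033NA"] <- NA
  }
  dimnames(M) <- dimnames_
  M
}

write_df_txt <- function(df, path) {
  meta <- lapply(df, function(col) {
    if (is.factor(col)) list(class = "factor", levels = levels(col))
    else list(class = class(col)[1])
  })
  ch <- data.frame(`_index` = rownames(df), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (cn in colnames(df)) {
    col <- df[[cn]]
    ch[[cn]] <- if (is.numeric(col)) fmt_num(col)
    else ifelse(is.na(col), "\033NA", as.character(col))
  }
  utils::write.table(ch, path, sep = ",", qmethod = "double",
                     row.names = FALSE, col.names = TRUE, quote = TRUE)
  meta
}

read_df_txt <- function(path, meta) {
  ch <- utils::read.table(path, sep = ",", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  df <- data.frame(row.names = ch[["_index"]])
  for (cn in setdiff(colnames(ch), "_index")) {
    col <- ch[[cn]]
    cls <- meta[[cn]]$class
    df[[cn]] <- switch(cls,
      numeric = , double = { col[col == "NA"] <- NA; as.numeric(col) },
      integer = { col[col == "NA"] <- NA; as.integer(col) },
      logical = { col[col == "NA"] <- NA; as.logical(col) },
      factor = { col[col == "\033NA"] <- NA; factor(col, levels = meta[[cn]]$levels) },
      { col[col == "\033NA"] <- NA; col })
  }
  df
}

#' Write an ehrframe to an on-disk store
#'
#' Persists every component of the frame into a directory using the familiar
#' annotated-matrix group layout (`X`, `obs`, `var`, `layers`, `obsm`,
#' `varm`, `obsp`, `uns`) as plain-text CSV/JSON. Numeric values are written
#' with 17 significant digits, so [read_store()] reproduces the frame
#' bitwise, including missing markers and category order.
#'
#' @param frame an `ehrframe`.
#' @param path directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_store <- function(frame, path) {
  validate_ehrframe(frame)
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  meta <- list(
    n_obs = nrow(frame$X), n_vars = ncol(frame$X),
    obs_names = rownames(frame$X), var_names = colnames(frame$X),
    X_mode = if (is.numeric(frame$X)) "double" else "character",
    layers = names(frame$layers), obsm = names(frame$obsm),
    varm = names(frame$varm), obsp = names(frame$obsp)
  )
  write_matrix_txt(frame$X, file.path(path, "X.csv"))
  meta$obs_columns <- write_df_txt(frame$obs, file.path(path, "obs.csv"))
  meta$var_columns <- write_df_txt(frame$var, file.path(path, "var.csv"))
  for (slot in c("layers", "obsm", "varm", "obsp")) {
    if (!length(frame[[slot]])) next
    dir.create(file.path(path, slot))
    for (nm in names(frame[[slot]])) {
      M <- frame[[slot]][[nm]]
      if (inherits(M, "Matrix")) M <- as.matrix(M)
      write_matrix_txt(M, file.path(path, slot, paste0(nm, ".csv")))
      meta[[paste0(slot, "_mode")]][[nm]] <- if (is.numeric(M)) "double" else "character"
      if (slot %in% c("obsm", "varm"))
        meta[[paste0(slot, "_colnames")]][[nm]] <- colnames(M)
    }
  }
  jsonlite::write_json(frame$uns, file.path(path, "uns.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null", na = "null")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' Read an ehrframe back from an on-disk store
#'
#' Inverse of [write_store()]. A store with a missing or unreadable
#' component fails with an error naming the offending component.
#'
#' @param path store directory written by [write_store()].
#' @return the reconstructed `ehrframe`.
#' @export
read_store <- function(path) {
  if (!dir.exists(path)) stop("store does not exist: ", path)
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("corrupt store: missing component '", f, "'")
    fp
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  X <- read_matrix_txt(need("X.csv"), meta$X_mode,
                       list(meta$obs_names, meta$var_names))
  obs <- read_df_txt(need("obs.csv"), meta$obs_columns)
  var <- read_df_txt(need("var.csv"), meta$var_columns)
  slots <- list(layers = list(), obsm = list(), varm = list(), obsp = list())
  for (slot in names(slots)) {
    for (nm in meta[[slot]]) {
      mode <- meta[[paste0(slot, "_mode")]][[nm]]
      dn <- switch(slot,
        layers = list(meta$obs_names, meta$var_names),
        obsm = list(meta$obs_names, meta[[paste0(slot, "_colnames")]][[nm]]),
        varm = list(meta$var_names, meta[[paste0(slot, "_colnames")]][[nm]]),
        obsp = list(meta$obs_names, meta$obs_names))
      slots[[slot]][[nm]] <- read_matrix_txt(
        need(file.path(slot, paste0(nm, ".csv"))), mode, dn)
    }
  }
  uns <- jsonlite::read_json(need("uns.json"), simplifyVector = TRUE)
  uns <- rapply(uns, function(x) x, how = "replace")
  ehrframe(X, obs = obs, var = var, layers = slots$layers, obsm = slots$obsm,
           varm = slots$varm, obsp = slots$obsp, uns = as.list(uns))
}
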