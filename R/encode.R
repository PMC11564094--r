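#' Encode categorical and boolean variables numerically
#'
#' Converts categorical/boolean variables into numeric columns so that the
#' value matrix becomes fully numeric. Two methods are available:
#'
#' * `one_hot`: one binary indicator column per category, named
#'   `<variable>_<category>` (suffix-indexed on collision). Each non-missing
#'   row has exactly one 1; missing rows carry a full row of missing markers.
#' * `label`: consecutive integer codes `0..k-1` assigned in category order
#'   (lexicographic by default).
#'
#' The pre-encoding tokens are kept in the frame (`uns$encoding`) so that
#' [decode()] restores the original columns exactly, including missingness.
#'
#' @param frame an `ehrframe`.
#' @param spec optional named character vector mapping variable name to
#'   method; unnamed variables fall back to `default_method`. When `NULL`,
#'   all raw categorical/boolean variables are encoded.
#' @param default_method `"one_hot"` (default) or `"label"`.
#' @return the updated `ehrframe` (numeric `X` once no raw non-numeric
#'   variables remain).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sex,age", "M,34", "F,51", "M,47"), f)
#' fr <- encode(read_tabular(f))
#' colnames(fr$X)
#' @export
encode <- function(frame, spec = NULL, default_method = "one_hot") {
  methods_ok <- c("one_hot", "label")
  if (!default_method %in% methods_ok) stop("unknown encoding method: ", default_method)
  if (is.null(spec)) {
    targets <- colnames(frame$X)[frame$var$kind %in% c("categorical", "boolean") &
                                   frame$var$encoding_state == "raw"]
    spec <- setNames(rep(default_method, length(targets)), targets)
  } else {
    spec <- unlist(spec)
    bad <- setdiff(spec, methods_ok)
    if (length(bad)) stop("unknown encoding method: ", paste(bad, collapse = ", "))
  }
  if (!length(spec)) return(maybe_numeric_X(frame))
  unknown <- setdiff(names(spec), colnames(frame$X))
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  jj <- match(names(spec), colnames(frame$X))
  if (any(frame$var$kind[jj] == "numeric"))
    stop("cannot encode numeric variable(s): ",
         paste(names(spec)[frame$var$kind[jj] == "numeric"], collapse = ", "))
  if (any(frame$var$encoding_state[jj] != "raw"))
    stop("variable(s) already encoded: ",
         paste(names(spec)[frame$var$encoding_state[jj] != "raw"], collapse = ", "))
  expands <- any(spec == "one_hot")
  if (expands && (length(frame$layers) || length(frame$varm)))
    stop("one-hot encoding changes n_vars; drop layers/varm first")

  # keep numeric-variable tokens once so a later decode can restore a
  # character-mode matrix verbatim
  if (!is.numeric(frame$X) && is.null(frame$uns$encoding$numeric_tokens)) {
    num_vars <- colnames(frame$X)[frame$var$kind == "numeric"]
    frame$uns$encoding$numeric_tokens <-
      lapply(setNames(num_vars, num_vars), function(v) unname(frame$X[, v]))
  }

  blocks <- list(); var_rows <- list()
  for (j in seq_len(ncol(frame$X))) {
    v <- colnames(frame$X)[j]
    if (!v %in% names(spec)) {
      blocks[[v]] <- frame$X[, j, drop = FALSE]
      var_rows[[v]] <- frame$var[j, , drop = FALSE]
      next
    }
    method <- spec[[v]]
    tokens <- as.character(frame$X[, j])
    cats <- frame$uns$categories[[v]] %||% sort(unique(tokens[!is.na(tokens)]))
    if (!length(cats)) stop("variable '", v, "' has no observed categories")
    if (method == "label") {
      codes <- match(tokens, cats) - 1
      blk <- matrix(codes, ncol = 1, dimnames = list(rownames(frame$X), v))
      cols <- v
    } else {
      cols <- paste0(v, "_", cats)
      taken <- c(colnames(frame$X)[-j], unlist(lapply(blocks, colnames)))
      for (ci in seq_along(cols)) {
        k <- 1
        while (cols[ci] %in% c(taken, cols[-ci])) {
          cols[ci] <- paste0(v, "_", cats[ci], ".", k); k <- k + 1
        }
      }
      blk <- outer(tokens, cats, `==`) * 1
      blk[is.na(tokens), ] <- NA
      dimnames(blk) <- list(rownames(frame$X), cols)
    }
    blocks[[v]] <- blk
    vr <- frame$var[rep(j, length(cols)), , drop = FALSE]
    rownames(vr) <- cols
    vr$encoding_state <- method
    var_rows[[v]] <- vr
    frame$uns$encoding$raw[[v]] <- tokens
    frame$uns$encoding$map[[v]] <- list(method = method, kind = frame$var$kind[j],
                                        categories = cats, columns = cols,
                                        position = j)
  }
  newX <- do.call(cbind, unname(blocks))
  newvar <- do.call(rbind, unname(var_rows))
  # X stays character-mode while unencoded non-numeric variables remain
  if (!is.numeric(newX) || !all(newvar$kind == "numeric" | newvar$encoding_state != "raw")) {
    num_blocks <- vapply(blocks, is.numeric, logical(1))
    if (any(num_blocks) && !all(num_blocks)) {
      blocks <- lapply(blocks, function(b) {
        if (is.numeric(b)) matrix(ifelse(is.na(b), NA, fmt_num(b)),
                                  nrow(b), ncol(b), dimnames = dimnames(b)) else b
      })
      newX <- do.call(cbind, unname(blocks))
    }
  }
  frame$X <- newX
  frame$var <- newvar
  frame <- maybe_numeric_X(frame)
  validate_ehrframe(frame)
  frame
}

#' Restore encoded variables to their original categorical form
#'
#' Inverse of [encode()]: generated indicator/code columns are removed and
#' the original token columns reinstated at their previous positions,
#' missing entries included. With no encoded variables left, the backup
#' bookkeeping is cleared.
#'
#' @param frame an `ehrframe`.
#' @param variables optional subset of encoded variable names; default all.
#' @return the updated `ehrframe`.
#' @export
decode <- function(frame, variables = NULL) {
  emap <- frame$uns$encoding$map
  if (is.null(emap) || !length(emap)) stop("frame has no encoding map; nothing to decode")
  variables <- variables %||% names(emap)
  unknown <- setdiff(variables, names(emap))
  if (length(unknown)) stop("no encoding recorded for: ", paste(unknown, collapse = ", "))
  # rebuild column blocks in current order, replacing each encoded group
  cur <- colnames(frame$X)
  blocks <- list(); var_rows <- list(); consumed <- character(0)
  for (j in seq_along(cur)) {
    cn <- cur[j]
    if (cn %in% consumed) next
    owner <- NULL
    for (v in variables) if (cn %in% emap[[v]]$columns && is.null(owner)) owner <- v
    if (is.null(owner)) {
      blocks[[cn]] <- frame$X[, j, drop = FALSE]
      var_rows[[cn]] <- frame$var[j, , drop = FALSE]
      next
    }
    m <- emap[[owner]]
    consumed <- c(consumed, m$columns)
    tokens <- frame$uns$encoding$raw[[owner]]
    blocks[[owner]] <- matrix(tokens, ncol = 1,
                              dimnames = list(rownames(frame$X), owner))
    vr <- frame$var[j, , drop = FALSE]
    rownames(vr) <- owner
    vr$kind <- m$kind
    vr$encoding_state <- "raw"
    var_rows[[owner]] <- vr
    if (m$kind == "categorical") frame$uns$categories[[owner]] <- m$categories
  }
  char_needed <- TRUE  # decoded tokens force character mode
  blocks <- lapply(blocks, function(b) {
    if (is.numeric(b)) matrix(ifelse(is.na(b), NA, fmt_num(b)),
                              nrow(b), ncol(b), dimnames = dimnames(b)) else b
  })
  # reinstate verbatim tokens of numeric variables where the value is
  # unchanged since encoding (imputed/transformed entries keep new tokens)
  ntok <- frame$uns$encoding$numeric_tokens
  for (v in intersect(names(ntok), names(blocks))) {
    old <- ntok[[v]]
    curv <- suppressWarnings(as.numeric(blocks[[v]]))
    same <- !is.na(old) & !is.na(curv) &
      suppressWarnings(as.numeric(old)) == curv
    same[is.na(old) & is.na(curv)] <- TRUE
    blocks[[v]][same] <- old[same]
  }
  frame$X <- do.call(cbind, unname(blocks))
  frame$var <- do.call(rbind, unname(var_rows))
  for (v in variables) {
    frame$uns$encoding$raw[[v]] <- NULL
    frame$uns$encoding$map[[v]] <- NULL
  }
  if (!length(frame$uns$encoding$map)) frame$uns$encoding <- NULL
  frame <- maybe_numeric_X(frame)
  validate_ehrframe(frame)
  frame
}
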