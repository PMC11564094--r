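#' Start a cohort provenance log
#'
#' Initializes an ordered record of cohort filtering with a step-0 snapshot
#' of the full cohort: the population count and, for each tracked column, a
#' distribution snapshot (category counts for categorical columns; mean,
#' sd and quartiles for numeric ones). Snapshots store distributions, not
#' row identifiers, so logs stay small and privacy-preserving.
#'
#' @param frame an `ehrframe`.
#' @param columns obs-table columns or variables to track (may be empty:
#'   counts only).
#' @return object of class `ehr_cohort_log`.
#' @export
tracker_start <- function(frame, columns = character(0)) {
  for (cn in columns)
    if (!cn %in% c(colnames(frame$obs), colnames(frame$X)))
      stop("unknown tracked column: ", cn)
  log <- structure(list(columns = columns, steps = list()),
                   class = "ehr_cohort_log")
  log$steps[[1]] <- cohort_snapshot(frame, columns, reason = "initial cohort",
                                    n_before = n_obs(frame))
  attr(log, "last_ids") <- rownames(frame$X)
  log
}

cohort_snapshot <- function(frame, columns, reason, n_before) {
  snap <- list(reason = reason, n_before = n_before, n_after = n_obs(frame),
               distributions = list())
  for (cn in columns) {
    x <- if (cn %in% colnames(frame$obs)) frame$obs[[cn]] else var_values(frame, cn)
    snap$distributions[[cn]] <- if (is.numeric(x)) {
      q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      list(type = "numeric", mean = mean(x, na.rm = TRUE),
           sd = sd(x, na.rm = TRUE), q25 = q[1], median = q[2], q75 = q[3])
    } else {
      counts <- table(as.character(x), useNA = "ifany")
      nm <- names(counts); nm[is.na(nm)] <- "(missing)"
      list(type = "categorical", counts = setNames(as.integer(counts), nm))
    }
  }
  snap
}

#' Record a filtering step in a cohort log
#'
#' Appends a step with the post-filter population count, updated tracked
#' distributions and a free-text reason. Tracking is for monotone
#' filtering: the observation set must not grow, and must be a subset of
#' the previous step's observations.
#'
#' @param log an `ehr_cohort_log`.
#' @param frame the filtered `ehrframe`.
#' @param reason free-text description of the filtering operation.
#' @return the extended `ehr_cohort_log`.
#' @export
tracker_record <- function(log, frame, reason) {
  stopifnot(inherits(log, "ehr_cohort_log"))
  prev_ids <- attr(log, "last_ids")
  prev_n <- log$steps[[length(log$steps)]]$n_after
  if (n_obs(frame) > prev_n)
    stop("observation set grew; cohort tracking records filtering only")
  if (!is.null(prev_ids) && !all(rownames(frame$X) %in% prev_ids))
    stop("observations are not a subset of the previous step")
  log$steps[[length(log$steps) + 1]] <-
    cohort_snapshot(frame, log$columns, reason, n_before = prev_n)
  attr(log, "last_ids") <- rownames(frame$X)
  log
}

#' Cohort summary table at a log step
#'
#' Renders a tableone-style summary of the tracked columns at one step:
#' `"count (percent%)"` rows per category for categorical columns and
#' `"mean +/- sd"` for numeric ones.
#'
#' @param log an `ehr_cohort_log`.
#' @param step 1-based step index (1 = initial cohort).
#' @return data.frame with columns `column`, `level`, `value`.
#' @export
tracker_summary <- function(log, step = 1) {
  if (step < 1 || step > length(log$steps)) stop("no such step: ", step)
  snap <- log$steps[[step]]
  rows <- list(data.frame(column = "n", level = "", value = as.character(snap$n_after)))
  for (cn in names(snap$distributions)) {
    d <- snap$distributions[[cn]]
    if (d$type == "categorical") {
      for (lv in names(d$counts)) {
        cnt <- d$counts[[lv]]
        rows[[length(rows) + 1]] <- data.frame(
          column = cn, level = lv,
          value = sprintf("%d (%.1f%%)", cnt, 100 * cnt / snap$n_after))
      }
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        column = cn, level = "",
        value = sprintf("%.2f +/- %.2f", d$mean, d$sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consort-style flow data for a cohort log
#'
#' @param log an `ehr_cohort_log`.
#' @return list with `nodes` (step, n, reason) and `edges` (from, to,
#'   reason, excluded count) data.frames; excluded counts sum to
#'   `n_initial - n_final`.
#' @export
tracker_flow <- function(log) {
  k <- length(log$steps)
  nodes <- data.frame(step = seq_len(k) - 1,
                      n = vapply(log$steps, function(s) s$n_after, numeric(1)),
                      reason = vapply(log$steps, function(s) s$reason, character(1)))
  edges <- if (k > 1) data.frame(
    from = seq_len(k - 1) - 1, to = seq_len(k - 1),
    reason = nodes$reason[-1],
    excluded = nodes$n[-k] - nodes$n[-1]) else
    data.frame(from = integer(0), to = integer(0),
               reason = character(0), excluded = numeric(0))
  list(nodes = nodes, edges = edges)
}

#' Serialize / restore a cohort log as JSON
#'
#' @param log an `ehr_cohort_log`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
cohort_log_to_json <- function(log, path = NULL) {
  # named count vectors must serialize as JSON objects, not bare arrays
  steps <- lapply(log$steps, function(s) {
    s$distributions <- lapply(s$distributions, function(d) {
      if (d$type == "categorical") d$counts <- as.list(d$counts)
      d
    })
    s
  })
  payload <- list(columns = log$columns, steps = steps)
  if (is.null(path))
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname cohort_log_to_json
#' @param json JSON string or file path produced by [cohort_log_to_json()].
#' @export
cohort_log_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  log <- structure(list(columns = unlist(payload$columns) %||% character(0),
                        steps = lapply(payload$steps, function(s) {
                          s$distributions <- lapply(s$distributions, function(d) {
                            if (d$type == "categorical") d$counts <- unlist(d$counts)
                            d
                          })
                          s
                        })),
                   class = "ehr_cohort_log")
  log
}

#' @export
print.ehr_cohort_log <- function(x, ...) {
  cat(sprintf("cohort log: %d step(s), tracking %s\n", length(x$steps),
              if (length(x$columns)) paste(x$columns, collapse = ", ") else "(counts only)"))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  step %d: n %d -> %d  (%s)\n", i - 1, s$n_before, s$n_after, s$reason))
  }
  invisible(x)
}
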