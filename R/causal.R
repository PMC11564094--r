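#' Construct a causal directed acyclic graph
#'
#' Accepts edges as a character vector of `"parent -> child"` lines, a
#' two-column `from`/`to` data.frame, or a two-column character matrix.
#' Isolated nodes can be added via `nodes`.
#'
#' @param edges edge specification (see above).
#' @param nodes optional additional node names.
#' @return object of class `ehr_causal_graph` with `nodes` and an `edges`
#'   data.frame; construction fails on cycles.
#' @examples
#' g <- causal_graph(c("Z -> T", "Z -> Y", "T -> Y"))
#' @export
causal_graph <- function(edges, nodes = NULL) {
  ed <- if (is.character(edges)) {
    parts <- strsplit(trimws(edges[nzchar(trimws(edges))]), "->", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("edge lines must be 'parent -> child'")
    data.frame(from = trimws(vapply(parts, `[`, "", 1)),
               to = trimws(vapply(parts, `[`, "", 2)))
  } else {
    ed <- as.data.frame(edges)
    colnames(ed)[1:2] <- c("from", "to")
    ed[, c("from", "to")]
  }
  nodes <- unique(c(ed$from, ed$to, nodes))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) stop("causal graph must be acyclic")
  structure(list(nodes = nodes, edges = ed, igraph = g),
            class = "ehr_causal_graph")
}

#' @export
print.ehr_causal_graph <- function(x, ...) {
  cat(sprintf("causal DAG: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

graph_parents <- function(graph, node)
  graph$edges$from[graph$edges$to == node]

graph_descendants <- function(graph, node) {
  out <- igraph::subcomponent(graph$igraph, node, mode = "out")
  setdiff(names(out), node)
}

graph_ancestors <- function(graph, node) {
  out <- igraph::subcomponent(graph$igraph, node, mode = "in")
  setdiff(names(out), node)
}

# d-separation via the moralized ancestral graph: x _||_ y | z iff x and y
# are disconnected after (1) restricting to ancestors of {x,y,z}, (2)
# marrying co-parents, (3) dropping z
d_separated <- function(graph, x, y, z = character(0)) {
  keep <- unique(c(x, y, z,
                   unlist(lapply(c(x, y, z), function(n) graph_ancestors(graph, n)))))
  ed <- graph$edges[graph$edges$from %in% keep & graph$edges$to %in% keep, ]
  adj <- setNames(vector("list", length(keep)), keep)
  link <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (i in seq_len(nrow(ed))) link(ed$from[i], ed$to[i])
  for (n in keep) {
    pa <- intersect(graph_parents(graph, n), keep)
    if (length(pa) > 1)
      for (cmb in utils::combn(pa, 2, simplify = FALSE)) link(cmb[1], cmb[2])
  }
  blocked <- z
  visited <- x
  queue <- x
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in setdiff(adj[[cur]], c(visited, blocked))) {
      if (nb == y) return(FALSE)
      visited <- c(visited, nb)
      queue <- c(queue, nb)
    }
  }
  TRUE
}

#' Minimal backdoor adjustment set
#'
#' Searches for a covariate set satisfying the backdoor criterion: it
#' blocks every backdoor path from treatment to outcome (d-separation in
#' the graph with the treatment's outgoing edges removed) and contains no
#' descendant of the treatment. Candidate sets are enumerated by
#' increasing cardinality with lexicographic tie-breaking, so the returned
#' set is minimal. The empty set is returned when no backdoor path exists.
#'
#' @param graph an `ehr_causal_graph`.
#' @param treatment,outcome node names.
#' @return character vector of adjustment variables (possibly empty);
#'   errors when no valid set exists.
#' @export
backdoor_set <- function(graph, treatment, outcome) {
  stopifnot(inherits(graph, "ehr_causal_graph"))
  if (!all(c(treatment, outcome) %in% graph$nodes))
    stop("treatment/outcome must be graph nodes")
  if (treatment == outcome) stop("treatment and outcome must differ")
  gb <- graph
  gb$edges <- graph$edges[graph$edges$from != treatment, , drop = FALSE]
  gb$igraph <- igraph::graph_from_data_frame(
    gb$edges, directed = TRUE, vertices = data.frame(name = graph$nodes))
  if (d_separated(gb, treatment, outcome)) return(character(0))
  cands <- sort(setdiff(graph$nodes,
                        c(treatment, outcome, graph_descendants(graph, treatment))))
  for (size in seq_along(cands)) {
    for (z in utils::combn(cands, size, simplify = FALSE)) {
      if (d_separated(gb, treatment, outcome, z)) return(z)
    }
  }
  stop("no valid backdoor adjustment set exists for ", treatment, " -> ", outcome)
}

#' Backdoor-adjusted causal effect estimate
#'
#' Four-step procedure on a user-supplied DAG: (1) model — take the graph
#' as given; (2) identify — find a minimal backdoor adjustment set; (3)
#' estimate — ordinary least squares of the outcome on treatment plus the
#' adjustment set, the treatment coefficient being the average effect in
#' outcome units per unit treatment; (4) refute — see [refute_estimate()].
#'
#' @param frame an `ehrframe` or data.frame holding the node columns.
#' @param graph an `ehr_causal_graph`.
#' @param treatment,outcome column/node names; treatment binary or numeric.
#' @param method currently `"linear_regression"`.
#' @param adjustment optional explicit adjustment set overriding the
#'   backdoor search.
#' @return object of class `ehr_causal_estimate` with `effect`, `se`,
#'   `ci`, `adjustment`, and the inputs needed by refuters.
#' @export
estimate_effect <- function(frame, graph, treatment, outcome,
                            method = "linear_regression", adjustment = NULL) {
  if (method != "linear_regression") stop("unknown estimation method: ", method)
  df <- if (inherits(frame, "ehrframe")) as.data.frame(frame) else as.data.frame(frame)
  adjustment <- adjustment %||% backdoor_set(graph, treatment, outcome)
  need <- c(treatment, outcome, adjustment)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  est <- ols_effect(df, treatment, outcome, adjustment)
  structure(list(treatment = treatment, outcome = outcome,
                 adjustment = adjustment, method = method,
                 effect = est$effect, se = est$se, ci = est$ci),
            class = "ehr_causal_estimate")
}

ols_effect <- function(df, treatment, outcome, adjustment) {
  rhs <- paste(c(sprintf("`%s`", treatment),
                 if (length(adjustment)) sprintf("`%s`", adjustment)),
               collapse = " + ")
  fit <- lm(as.formula(paste0("`", outcome, "` ~ ", rhs)), data = df)
  sm <- summary(fit)$coefficients
  rn <- paste0("`", treatment, "`")
  rn <- if (rn %in% rownames(sm)) rn else treatment
  eff <- sm[rn, "Estimate"]; se <- sm[rn, "Std. Error"]
  list(effect = unname(eff), se = unname(se),
       ci = unname(eff + c(-1, 1) * qnorm(0.975) * se))
}

#' @export
print.ehr_causal_estimate <- function(x, ...) {
  cat(sprintf("causal estimate: %s -> %s = %.4f (SE %.4f, 95%% CI %.4f..%.4f)\n",
              x$treatment, x$outcome, x$effect, x$se, x$ci[1], x$ci[2]))
  if (length(x$adjustment))
    cat("  adjusted for:", paste(x$adjustment, collapse = ", "), "\n")
  invisible(x)
}

#' Refute a causal estimate
#'
#' Perturbation checks of an estimate's robustness, deterministic given
#' `seed`:
#'
#' * `placebo_treatment`: permute the treatment; the re-estimated effect
#'   should collapse to about 0.
#' * `random_common_cause`: add an independent noise covariate to the
#'   adjustment set; the estimate should barely move.
#' * `data_subset`: re-estimate on random subsets (default 5 draws of 80%);
#'   estimates should be stable.
#' * `unobserved_common_cause`: report the estimate over a grid of
#'   simulated-confounder strengths (a sensitivity curve, no pass/fail —
#'   no threshold is principled).
#' * `dummy_outcome`: replace the outcome by noise; the effect should be
#'   about 0.
#' * `bootstrap`: resample rows (default 200 times); the reference
#'   estimate should fall inside the 95% percentile interval.
#'
#' Pass tolerance for placebo/dummy/random-cause/subset deviations is
#' `max(tolerance_rel * |reference|, tolerance_abs)`.
#'
#' @param frame the `ehrframe`/data.frame used for the estimate.
#' @param graph the `ehr_causal_graph` used for the estimate.
#' @param estimate an `ehr_causal_estimate`.
#' @param method one of `"placebo_treatment"`, `"random_common_cause"`,
#'   `"data_subset"`, `"unobserved_common_cause"`, `"dummy_outcome"`,
#'   `"bootstrap"`.
#' @param seed RNG seed (default 0).
#' @param n_draws subset/bootstrap resample count (default 5 / 200).
#' @param subset_fraction fraction per data subset (default 0.8).
#' @param tolerance_rel,tolerance_abs pass tolerances (defaults 0.1, 0.05).
#' @return object of class `ehr_refutation` with `refuter`,
#'   `refuted_value`, `reference`, `pass` (NA for the sensitivity curve)
#'   and `details`.
#' @export
refute_estimate <- function(frame, graph, estimate, method, seed = 0,
                            n_draws = NULL, subset_fraction = 0.8,
                            tolerance_rel = 0.1, tolerance_abs = 0.05) {
  refuters <- c("placebo_treatment", "random_common_cause", "data_subset",
                "unobserved_common_cause", "dummy_outcome", "bootstrap")
  if (!method %in% refuters) stop("unknown refuter: ", method)
  stopifnot(inherits(estimate, "ehr_causal_estimate"))
  df <- if (inherits(frame, "ehrframe")) as.data.frame(frame) else as.data.frame(frame)
  tr <- estimate$treatment; oc <- estimate$outcome; adj <- estimate$adjustment
  ref <- estimate$effect
  tol <- max(tolerance_rel * abs(ref), tolerance_abs)
  set.seed(seed)
  n <- nrow(df)
  res <- switch(method,
    placebo_treatment = {
      n_draws <- n_draws %||% 20
      ests <- vapply(seq_len(n_draws), function(b) {
        d2 <- df; d2[[tr]] <- sample(d2[[tr]])
        ols_effect(d2, tr, oc, adj)$effect
      }, numeric(1))
      e <- mean(ests)
      list(value = e, pass = abs(e) < tol,
           details = list(tolerance = tol, estimates = ests))
    },
    dummy_outcome = {
      n_draws <- n_draws %||% 20
      ests <- vapply(seq_len(n_draws), function(b) {
        d2 <- df; d2[[oc]] <- rnorm(n)
        ols_effect(d2, tr, oc, adj)$effect
      }, numeric(1))
      e <- mean(ests)
      list(value = e, pass = abs(e) < tol,
           details = list(tolerance = tol, estimates = ests))
    },
    random_common_cause = {
      n_draws <- n_draws %||% 20
      ests <- vapply(seq_len(n_draws), function(b) {
        d2 <- df; d2[[".rcc"]] <- rnorm(n)
        ols_effect(d2, tr, oc, c(adj, ".rcc"))$effect
      }, numeric(1))
      e <- mean(ests)
      list(value = e, pass = abs(e - ref) < tol,
           details = list(tolerance = tol, estimates = ests))
    },
    data_subset = {
      n_draws <- n_draws %||% 5
      ests <- vapply(seq_len(n_draws), function(b) {
        idx <- sample.int(n, floor(subset_fraction * n))
        ols_effect(df[idx, , drop = FALSE], tr, oc, adj)$effect
      }, numeric(1))
      list(value = mean(ests),
           pass = max(abs(ests - ref)) < max(tol, 4 * estimate$se),
           details = list(estimates = ests))
    },
    bootstrap = {
      n_draws <- n_draws %||% 200
      ests <- vapply(seq_len(n_draws), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        ols_effect(df[idx, , drop = FALSE], tr, oc, adj)$effect
      }, numeric(1))
      ci <- quantile(ests, c(0.025, 0.975), names = FALSE)
      list(value = mean(ests), pass = ref >= ci[1] && ref <= ci[2],
           details = list(ci = ci))
    },
    unobserved_common_cause = {
      strengths <- seq(0, 1, by = 0.2)
      tvals <- scale(as.numeric(df[[tr]]))[, 1]
      curve <- vapply(strengths, function(a) {
        d2 <- df
        d2[[".ucc"]] <- a * tvals + sqrt(max(0, 1 - a^2)) * rnorm(n)
        ols_effect(d2, tr, oc, c(adj, ".ucc"))$effect
      }, numeric(1))
      list(value = curve[length(curve)], pass = NA,
           details = list(strengths = strengths, estimates = curve))
    })
  structure(list(refuter = method, refuted_value = res$value, reference = ref,
                 pass = res$pass, details = res$details),
            class = "ehr_refutation")
}

#' @export
print.ehr_refutation <- function(x, ...) {
  cat(sprintf("refuter %s: refuted=%.4f reference=%.4f pass=%s\n",
              x$refuter, x$refuted_value, x$reference, as.character(x$pass)))
  invisible(x)
}
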