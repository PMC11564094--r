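# Independent oracles used to cross-check the package implementations.
# Each is written directly from the defining formula, not from package code.

# product-limit estimator by hand: S(t) = prod_{t_i <= t} (1 - d_i/n_i)
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- as.integer(event)[ord]
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = times, surv = rep(NA_real_, length(times)))
  for (i in seq_along(times)) {
    tt <- times[i]
    n_i <- sum(time >= tt)
    d_i <- sum(time == tt & event == 1)
    s <- s * (1 - d_i / n_i)
    out$surv[i] <- s
  }
  out
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# d-separation by exhaustive path enumeration: a path is blocked given Z if
# it contains a non-collider in Z, or a collider with no descendant
# (including itself) in Z
dsep_oracle <- function(edges, x, y, z = character(0)) {
  nodes <- unique(c(edges$from, edges$to))
  desc_of <- function(n) {
    out <- n; frontier <- n
    while (length(frontier)) {
      nxt <- edges$to[edges$from %in% frontier]
      frontier <- setdiff(nxt, out)
      out <- union(out, frontier)
    }
    out
  }
  # enumerate simple undirected paths x..y via DFS
  neigh <- function(n) union(edges$to[edges$from == n], edges$from[edges$to == n])
  paths <- list()
  dfs <- function(path) {
    cur <- path[length(path)]
    if (cur == y) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (nb in setdiff(neigh(cur), path)) dfs(c(path, nb))
  }
  dfs(x)
  if (!length(paths)) return(TRUE)
  is_edge <- function(a, b) any(edges$from == a & edges$to == b)
  for (pth in paths) {
    blocked <- FALSE
    if (length(pth) > 2) {
      for (i in 2:(length(pth) - 1)) {
        a <- pth[i - 1]; b <- pth[i]; c <- pth[i + 1]
        collider <- is_edge(a, b) && is_edge(c, b)
        if (collider) {
          if (!any(desc_of(b) %in% z)) { blocked <- TRUE; break }
        } else {
          if (b %in% z) { blocked <- TRUE; break }
        }
      }
    }
    if (!blocked) return(FALSE)  # open path found
  }
  TRUE
}

# verify a candidate set against the backdoor criterion by enumeration
backdoor_oracle_sets <- function(edges, treatment, outcome) {
  nodes <- unique(c(edges$from, edges$to))
  desc_of <- function(n) {
    out <- n; frontier <- n
    while (length(frontier)) {
      nxt <- edges$to[edges$from %in% frontier]
      frontier <- setdiff(nxt, out)
      out <- union(out, frontier)
    }
    setdiff(out, n)
  }
  gb <- edges[edges$from != treatment, , drop = FALSE]
  cands <- sort(setdiff(nodes, c(treatment, outcome, desc_of(treatment))))
  subsets <- list(character(0))
  for (k in seq_along(cands))
    subsets <- c(subsets, utils::combn(cands, k, simplify = FALSE))
  ok <- Filter(function(z) dsep_oracle(gb, treatment, outcome, z), subsets)
  ok
}

# small mixed-type CSV fixture written at test time
write_mixed_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("id,age,weight,sex,smoker,admit",
               "a,34,70.5,M,true,2020-01-03",
               "b,51,81.2,F,false,2020-02-11",
               "c,47,,M,true,2020-03-22",
               "d,29,66.0,F,false,2020-04-30"), path)
  path
}

mkframe <- function(Y, prefix = "v") {
  colnames(Y) <- paste0(prefix, seq_len(ncol(Y)))
  ehrframe(Y)
}

corr_normals <- function(n, p, rho = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  MASS::mvrnorm(n, rep(0, p), (1 - rho) * diag(p) + rho)
}
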