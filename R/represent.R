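#' Flag the most variable features
#'
#' Ranks numeric variables by the variance of their non-missing values
#' (ties broken by name) and flags the top `n_top` in the var table as
#' `highly_variable`. Constant features are never flagged.
#'
#' @param frame an `ehrframe`.
#' @param n_top number of features to flag.
#' @return the annotated `ehrframe`.
#' @export
highly_variable_features <- function(frame, n_top) {
  numv <- which(numeric_valued(frame))
  if (n_top > n_vars(frame)) stop("n_top exceeds the number of variables")
  disp <- rep(-Inf, n_vars(frame))
  for (j in numv) {
    x <- as.numeric(frame$X[, j]); x <- x[!is.na(x)]
    if (length(x) > 1) disp[j] <- var(x)
  }
  ord <- order(-disp, colnames(frame$X))
  flag <- rep(FALSE, n_vars(frame))
  chosen <- ord[seq_len(n_top)]
  flag[chosen[disp[chosen] > 0]] <- TRUE
  frame$var$highly_variable <- flag
  frame$uns$hvf <- list(n_top = n_top, criterion = "variance")
  frame
}

#' Principal component analysis of the value matrix
#'
#' Centers (but does not rescale; normalization is an explicit prior step)
#' the complete numeric matrix and stores the first `n_components` scores
#' in `obsm$X_pca`, the loadings in `varm$PCs` and the explained-variance
#' ratios in `uns$pca`.
#'
#' @param frame an `ehrframe` with complete numeric `X`.
#' @param n_components number of components (default 50, capped at
#'   `min(n_obs, n_vars)`).
#' @return the updated `ehrframe`.
#' @export
pca <- function(frame, n_components = 50) {
  if (!is_numeric_frame(frame))
    stop("pca requires a numeric matrix; encode categoricals first")
  if (anyNA(frame$X))
    stop("X contains missing values; impute before pca")
  n_components <- min(n_components, nrow(frame$X), ncol(frame$X))
  fit <- prcomp(frame$X, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- fit$x
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- rownames(frame$X)
  frame$obsm$X_pca <- scores
  loadings <- fit$rotation
  rownames(loadings) <- colnames(frame$X)
  frame$varm$PCs <- loadings
  total_var <- sum(apply(frame$X, 2, function(x) mean((x - mean(x))^2)))
  ev <- fit$sdev^2 * (nrow(frame$X) - 1) / nrow(frame$X)
  frame$uns$pca <- list(n_components = n_components,
                        variance = ev[seq_len(n_components)],
                        variance_ratio = if (total_var > 0)
                          ev[seq_len(n_components)] / total_var else
                          rep(0, n_components),
                        center = fit$center)
  frame
}

#' k-nearest-neighbour graph over a representation
#'
#' Finds the `k` nearest observations (Euclidean distance, exact search)
#' in the named representation, stores the neighbour distances in
#' `obsp$distances` and union-symmetrized binary connectivities in
#' `obsp$connectivities`, and records the parameters in `uns$neighbors`.
#'
#' @param frame an `ehrframe`.
#' @param k neighbour count (default 15).
#' @param use_representation `obsm` entry to use, or `"X"` for the value
#'   matrix (default `"X_pca"` when present, else `"X"`).
#' @return the updated `ehrframe`.
#' @export
neighbors <- function(frame, k = 15, use_representation = NULL) {
  use_representation <- use_representation %||%
    (if ("X_pca" %in% names(frame$obsm)) "X_pca" else "X")
  R <- representation_matrix(frame, use_representation)
  n <- nrow(R)
  if (k >= n) stop("k must be smaller than n_obs")
  nn <- RANN::nn2(R, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]      # drop self
  dst <- nn$nn.dists[, -1, drop = FALSE]
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(idx))
  D <- matrix(0, n, n, dimnames = list(rownames(frame$X), rownames(frame$X)))
  D[cbind(ii, jj)] <- as.vector(t(dst))
  C <- (D > 0) * 1
  C <- pmax(C, t(C))                         # union symmetrization
  frame$obsp$distances <- D
  frame$obsp$connectivities <- C
  frame$uns$neighbors <- list(k = k, metric = "euclidean",
                              use_representation = use_representation)
  frame
}

representation_matrix <- function(frame, name) {
  if (name == "X") {
    if (!is_numeric_frame(frame) || anyNA(frame$X))
      stop("representation 'X' must be complete and numeric")
    frame$X
  } else {
    if (!name %in% names(frame$obsm)) stop("unknown representation: ", name)
    frame$obsm[[name]]
  }
}

#' UMAP embedding of the patient landscape
#'
#' Computes a uniform manifold approximation and projection of the
#' representation underlying the neighbour graph, preserving local
#' neighbourhoods while keeping global structure interpretable. Requires
#' [neighbors()] to have been run (its `k` and representation are reused).
#' Deterministic for a fixed `seed` (single-threaded optimization).
#'
#' @param frame an `ehrframe` with a neighbour graph.
#' @param n_components embedding dimension (default 2).
#' @param seed RNG seed (default 0).
#' @return the updated `ehrframe` with `obsm$X_umap`.
#' @export
umap_embed <- function(frame, n_components = 2, seed = 0) {
  if (is.null(frame$uns$neighbors))
    stop("no neighbors graph; run neighbors() first")
  R <- representation_matrix(frame, frame$uns$neighbors$use_representation)
  k <- frame$uns$neighbors$k
  set.seed(seed)
  emb <- uwot::umap(R, n_neighbors = max(2, k), n_components = n_components,
                    n_threads = 1, n_sgd_threads = 1, ret_model = FALSE)
  rownames(emb) <- rownames(frame$X)
  colnames(emb) <- paste0("UMAP", seq_len(n_components))
  frame$obsm$X_umap <- emb
  frame$uns$umap <- list(n_components = n_components, seed = seed,
                         n_neighbors = k)
  frame
}

#' Leiden community detection on the neighbour graph
#'
#' Partitions the symmetrized connectivity graph with the Leiden algorithm
#' (modularity objective). Labels are written to the obs table as a factor
#' with contiguous levels `0, 1, ...` ordered by decreasing cluster size;
#' deterministic given `seed`.
#'
#' @param frame an `ehrframe` with a neighbour graph.
#' @param resolution resolution parameter of the quality function
#'   (default 1.0); lower values merge communities.
#' @param seed RNG seed (default 0).
#' @param key obs column to write (default `"leiden"`).
#' @return the updated `ehrframe`.
#' @export
cluster_leiden <- function(frame, resolution = 1.0, seed = 0, key = "leiden") {
  if (is.null(frame$obsp$connectivities))
    stop("no neighbors graph; run neighbors() first")
  A <- as.matrix(frame$obsp$connectivities)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  lab <- relabel[as.character(memb)]
  frame$obs[[key]] <- factor(lab, levels = sort(unique(lab)))
  frame$uns$leiden <- list(resolution = resolution, seed = seed, key = key,
                           n_clusters = length(sizes))
  frame
}
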