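#' Unsupervised embedding diagnostics
#'
#' Z-score-normalizes the raw intensities per channel, embeds the samples
#' in two dimensions, and scores the true labels on the 2-D coordinates
#' with the silhouette coefficient and the Davies-Bouldin index. PCA runs
#' natively; t-SNE (perplexity 30, 1000 iterations) and UMAP (15
#' neighbours, minimum distance 0.1) are called as established algorithms
#' through the system Python stack (scikit-learn and umap-learn), with a
#' fixed random state (default 42). Constant channels are dropped from
#' z-scoring with a warning.
#'
#' @param records list of spectrum records, or a numeric matrix of raw
#'   intensities (samples in rows).
#' @param labels class labels (defaults to the records' origins).
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param seed random state for the stochastic embeddings.
#' @param perplexity,n_iter t-SNE settings; `perplexity` is reduced
#'   automatically when the sample count is too small to support 30.
#' @param n_neighbors,min_dist UMAP settings.
#' @return list of class `"embedding_diagnostics"` with `method`,
#'   `coordinates` (n x 2), `explained_variance` (PCA only), `silhouette`
#'   and `davies_bouldin`.
#' @export
embed_and_score <- function(records, labels = NULL,
                            method = c("pca", "tsne", "umap"), seed = 42,
                            perplexity = 30, n_iter = 1000,
                            n_neighbors = 15, min_dist = 0.1) {
  method <- match.arg(method)
  X <- if (is.matrix(records)) records else intensity_matrix(records)
  if (is.null(labels)) {
    if (is.matrix(records))
      stopf("labels are required when records is a matrix")
    labels <- dataset_labels(records)
  }
  y <- factor(labels)
  if (nlevels(y) < 2) stopf("at least two classes are required")
  if (nrow(X) < 3) stopf("at least three samples are required")
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warnf("dropping %d constant channel(s) from z-scoring", sum(!keep))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  Z <- scale(X, center = TRUE, scale = sds)
  explained <- NULL
  if (method == "pca") {
    pc <- prcomp(Z, center = FALSE, scale. = FALSE)
    coords <- pc$x[, 1:2, drop = FALSE]
    explained <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  } else {
    coords <- .python_embed(Z, method, seed,
                            perplexity = min(perplexity,
                                             floor((nrow(Z) - 1) / 3)),
                            n_iter = n_iter,
                            n_neighbors = min(n_neighbors, nrow(Z) - 1),
                            min_dist = min_dist)
  }
  sil <- mean(cluster::silhouette(as.integer(y), stats::dist(coords))[, 3])
  structure(list(method = method, coordinates = coords,
                 explained_variance = explained,
                 silhouette = sil,
                 davies_bouldin = davies_bouldin(coords, y)),
            class = "embedding_diagnostics")
}

#' Davies-Bouldin index
#'
#' Average over clusters of the worst-case ratio of summed within-cluster
#' scatter to between-centroid separation; lower values mean tighter,
#' better separated clusters.
#'
#' @param coords numeric matrix of embedded coordinates (samples in rows).
#' @param labels cluster/class assignment.
#' @return non-negative scalar.
#' @export
davies_bouldin <- function(coords, labels) {
  y <- factor(labels)
  ks <- levels(y)
  centroids <- t(vapply(ks, function(k)
    colMeans(coords[y == k, , drop = FALSE]), numeric(ncol(coords))))
  scatter <- vapply(ks, function(k) {
    pts <- coords[y == k, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centroids[k, ])^2)))
  }, numeric(1))
  n <- length(ks)
  db <- 0
  for (i in seq_len(n)) {
    worst <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      sep <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      worst <- max(worst, (scatter[i] + scatter[j]) / sep)
    }
    db <- db + worst
  }
  db / n
}

# Run t-SNE or UMAP through the system Python (scikit-learn / umap-learn).
# Data is exchanged through temporary CSV files; deleted on exit.
.python_embed <- function(Z, method, seed, perplexity, n_iter,
                          n_neighbors, min_dist) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python))
    stopf("%s requires a python interpreter with scikit-learn/umap-learn on PATH",
          method)
  script <- system.file("python", "embed.py", package = "specfuse")
  if (!nzchar(script)) stopf("bundled embed.py not found")
  dir <- tempfile("embed")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  in_path <- file.path(dir, "X.csv")
  out_path <- file.path(dir, "coords.csv")
  data.table::fwrite(as.data.frame(Z), in_path, col.names = FALSE)
  cfg <- list(input = in_path, out = out_path, method = method,
              seed = as.integer(seed), perplexity = perplexity,
              n_iter = as.integer(n_iter),
              n_neighbors = as.integer(n_neighbors), min_dist = min_dist)
  cfg_path <- file.path(dir, "cfg.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  status <- system2(python, c(script, cfg_path), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(out_path))
    stopf("python embedding failed:\n%s", paste(status, collapse = "\n"))
  as.matrix(data.table::fread(out_path, header = FALSE))
}
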