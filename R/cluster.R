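#' Co-clustering dissimilarity among the innovation rates
#'
#' A Monte-Carlo estimate of \eqn{d_{rt} = \Pr\{\lambda_r \ne \lambda_t
#' \mid y\}}: the fraction of retained Gibbs draws in which epochs `r` and
#' `t` carry different rate atoms.  Equality within a draw is exact
#' floating-point equality, which is correct here because cluster members
#' share one atom by construction (the refresh step assigns the identical
#' value).  The result is symmetric with zero diagonal and entries in
#' `[0, 1]`; it need not satisfy the triangle inequality, so it is a
#' dissimilarity, not a distance.
#'
#' @param fit a `pyinar_fit` with co-clustering tallies (the default) or
#'   retained rate draws.
#' @return A symmetric `(T-p) x (T-p)` matrix of class
#'   `dissimilarity_matrix`.
#' @export
coclustering_dissimilarity <- function(fit) {
  stopifnot(inherits(fit, "pyinar_fit"))
  if (!is.null(fit$cocluster)) {
    d <- 1 - fit$cocluster
  } else if (!is.null(fit$draws$lambda)) {
    lam <- fit$draws$lambda
    n <- ncol(lam)
    co <- matrix(0, n, n)
    for (r in seq_len(nrow(lam))) {
      z <- match(lam[r, ], unique(lam[r, ]))
      co <- co + outer(z, z, "==")
    }
    d <- 1 - co / nrow(lam)
  } else {
    stop("fit carries neither co-clustering tallies nor rate draws")
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(d, class = c("dissimilarity_matrix", "matrix"))
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Torgerson scaling: double-center \eqn{-\tfrac12 d^2}, take the leading
#' `k` eigenpairs and clip negative eigenvalues to zero.  Deterministic
#' given its input (no random restarts), which keeps the clustering
#' pipeline reproducible; an iterative stress-majorization variant is
#' deliberately not used.
#'
#' @param d a symmetric dissimilarity matrix (zero diagonal).
#' @param k embedding dimension (default 2).
#' @return A numeric matrix of coordinates (`nrow(d)` rows, `k` columns)
#'   with attribute `stress`, the relative square-root stress between input
#'   dissimilarities and embedded distances.
#' @export
mds_embed <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  if (all(d == 0)) {
    xy <- matrix(0, n, k)
    attr(xy, "stress") <- 0
    return(xy)
  }
  # double centering: B = -1/2 J d^2 J with J = I - 11'/n
  b <- -0.5 * d^2
  b <- sweep(b, 1L, rowMeans(b))
  b <- sweep(b, 2L, colMeans(b))
  eg <- eigen(b, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(k)], 0)
  xy <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  dd <- as.matrix(dist(xy))
  num <- sum((d - dd)^2)
  attr(xy, "stress") <- sqrt(num / sum(d^2))
  xy
}

#' Cut a hierarchical clustering of the embedding into labels
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances, the
#' conventional choice for a Euclidean embedding; configurable) of the MDS
#' coordinates, with the dendrogram cut to exactly `n_clusters` groups.
#'
#' @param embedding coordinate matrix (one row per epoch).
#' @param n_clusters number of clusters to cut to, between 1 and the number
#'   of points.
#' @param method linkage passed to [stats::hclust()].
#' @return Integer labels in `1..n_clusters`.
#' @export
cut_clusters <- function(embedding, n_clusters, method = "ward.D2") {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n_clusters < 1L || n_clusters > n) {
    stop("n_clusters must lie between 1 and the number of points")
  }
  if (n_clusters == 1L) return(rep(1L, n))
  hc <- hclust(dist(embedding), method = method)
  unname(cutree(hc, k = n_clusters))
}

#' Confusion matrix and accuracy under optimal label matching
#'
#' Cluster labels are arbitrary up to permutation, so the predicted labels
#' are matched to the truth by the permutation maximizing the trace of the
#' confusion matrix (exhaustive search, supported up to 6 labels).
#' Accuracy is the matched trace over the total.
#'
#' @param predicted integer cluster labels.
#' @param truth integer reference labels (same length).
#' @return A list with `confusion` (rows = matched predicted labels,
#'   columns = truth), `accuracy`, and `permutation` (the relabeling
#'   applied to the predicted side).
#' @examples
#' confusion_and_accuracy(c(2, 2, 1, 1), c(1, 1, 2, 2))$accuracy  # 1
#' @export
confusion_and_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  pl <- match(predicted, sort(unique(predicted)))
  tl <- match(truth, sort(unique(truth)))
  k <- max(length(unique(pl)), length(unique(tl)))
  if (k > 6L) stop("optimal matching is exhaustive: at most 6 labels supported")
  tab <- matrix(0L, k, k)
  for (i in seq_along(pl)) tab[pl[i], tl[i]] <- tab[pl[i], tl[i]] + 1L
  perms <- permutations_of(k)
  best <- NULL; best_trace <- -1L
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    tr <- sum(diag(tab[pm, , drop = FALSE]))
    if (tr > best_trace) { best_trace <- tr; best <- pm }
  }
  list(confusion = tab[best, , drop = FALSE],
       accuracy = best_trace / length(truth),
       permutation = best)
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

#' Posterior point estimate of the innovation-rate clustering
#'
#' The full pipeline: co-clustering dissimilarity from the Gibbs draws,
#' two-dimensional classical MDS embedding, Ward cut of the dendrogram into
#' `n_clusters` labels, and (when true component labels are supplied) the
#' permutation-matched confusion matrix and accuracy.
#'
#' @param fit a `pyinar_fit`.
#' @param n_clusters number of clusters to cut to; default the posterior
#'   mode of `K` from the retained draws.
#' @param truth optional true component labels (length `T - p`).
#' @return An object of class `cluster_solution`: a list with
#'   `dissimilarity`, `embedding`, `labels`, `n_clusters`, and (with truth)
#'   `confusion` and `accuracy`.
#' @export
cluster_innovations <- function(fit, n_clusters = NULL, truth = NULL) {
  if (is.null(n_clusters)) n_clusters <- posterior_mode_k(fit)
  d <- coclustering_dissimilarity(fit)
  xy <- mds_embed(d, 2L)
  labels <- cut_clusters(xy, n_clusters)
  out <- list(dissimilarity = d, embedding = xy, labels = labels,
              n_clusters = n_clusters)
  if (!is.null(truth)) {
    ca <- confusion_and_accuracy(labels, truth)
    out$confusion <- ca$confusion
    out$accuracy <- ca$accuracy
  }
  structure(out, class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster solution: %d epochs cut into %d clusters\n",
              length(x$labels), x$n_clusters))
  print(table(labels = x$labels))
  if (!is.null(x$accuracy)) {
    cat("confusion matrix (rows = predicted, matched; cols = truth):\n")
    print(x$confusion)
    cat(sprintf("accuracy after optimal matching: %.1f%%\n",
                100 * x$accuracy))
  }
  invisible(x)
}

#' Serialize a cluster solution to CSV
#'
#' Writes `labels.csv` (epoch, embedding coordinates, label) and, when a
#' confusion matrix is present, `confusion.csv`.
#'
#' @param solution a `cluster_solution`.
#' @param dir output directory.
#' @param order model order `p` (used only to index epochs as `p+1..T`).
#' @return Invisibly, the paths written.
#' @export
write_cluster_solution <- function(solution, dir, order = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(solution$labels)
  df <- data.frame(t = order + seq_len(n),
                   mds1 = solution$embedding[, 1],
                   mds2 = solution$embedding[, 2],
                   label = solution$labels)
  paths <- file.path(dir, "labels.csv")
  write.csv(df, paths, row.names = FALSE, quote = FALSE)
  if (!is.null(solution$confusion)) {
    cp <- file.path(dir, "confusion.csv")
    write.csv(as.data.frame(solution$confusion), cp, row.names = FALSE,
              quote = FALSE)
    paths <- c(paths, cp)
  }
  invisible(paths)
}
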