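#' Scale each matrix row to \[-1, 1\]
#'
#' Per row min-max scaling `x -> 2 (x - min) / (max - min) - 1`, used to
#' compare features of different absolute abundance in heatmaps. Constant
#' rows map to all zeros.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape with row ranges \[-1, 1\].
#' @export
row_scale_minmax <- function(m) {
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  span <- hi - lo
  out <- 2 * (m - lo) / ifelse(span == 0, 1, span) - 1
  out[span == 0, ] <- 0
  out
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the columns (samples) of a row-scaled
#' expression matrix, Euclidean distance and complete linkage by default.
#'
#' @param m numeric matrix, features x samples (already scaled as desired).
#' @param distance `"euclidean"` (default) or any [stats::dist()] method.
#' @param linkage [stats::hclust()] method (default `"complete"`).
#' @param k optional number of clusters to cut into.
#' @return list with `tree` (hclust), `leaf_order` (sample ids in dendrogram
#'   order) and, when `k` is given, `clusters` (named integer vector).
#' @export
hierarchical_cluster <- function(m, distance = "euclidean",
                                 linkage = "complete", k = NULL) {
  if (ncol(m) < 2) stop("need >= 2 samples")
  if (anyNA(m)) stop("NA in matrix")
  d <- stats::dist(t(m), method = distance)
  tree <- stats::hclust(d, method = linkage)
  out <- list(tree = tree, leaf_order = colnames(m)[tree$order])
  if (!is.null(k))
    out$clusters <- stats::cutree(tree, k = k)
  out
}

#' PCA projection of samples
#'
#' Feature-centered (optionally scaled) singular value decomposition;
#' returns per-sample coordinates and variance-explained fractions. The sign
#' of each component is fixed by forcing its largest-magnitude feature
#' loading positive, so projections are reproducible.
#'
#' @param m numeric matrix, features x samples.
#' @param center,scale passed to [stats::prcomp()] (defaults TRUE / FALSE).
#' @return list with `coords` (samples x components), `var_explained`
#'   (fractions summing to 1 over full rank) and `degenerate` flag (true
#'   when the matrix has zero total variance).
#' @export
pca_project <- function(m, center = TRUE, scale = FALSE) {
  if (ncol(m) < 2 || nrow(m) < 2) stop("need >= 2 samples and features")
  x <- t(m)
  tot_var <- sum(apply(x, 2, stats::var))
  if (tot_var == 0)
    return(list(coords = matrix(0, nrow(x), 1,
                                dimnames = list(rownames(x), "PC1")),
                var_explained = 0, degenerate = TRUE))
  pc <- stats::prcomp(x, center = center, scale. = scale)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(coords = pc$x, var_explained = pc$sdev^2 / sum(pc$sdev^2),
       degenerate = FALSE)
}

#' Classify an immunohistochemistry H-score
#'
#' H-score = percent positively stained tumor cells x staining intensity
#' (0-3), hence a value in \[0, 300\]; binned as absent (0), low (0, 100\],
#' intermediate (100, 200\] and strong (200, 300\].
#'
#' @param h numeric H-score(s) in \[0, 300\].
#' @return character bin per value.
#' @export
hscore_classify <- function(h) {
  if (any(h < 0 | h > 300)) stop("H-score outside [0, 300]")
  ifelse(h == 0, "absent",
         ifelse(h <= 100, "low",
                ifelse(h <= 200, "intermediate", "strong")))
}
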