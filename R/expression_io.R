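#' Construct a count matrix with sample group labels
#'
#' Bundles an integer read-count matrix (features x samples) with a group
#' label per sample and per-sample library sizes. Library sizes default to
#' column sums but may be overridden (e.g. to use total mapped reads).
#'
#' @param counts integer matrix, features x samples, non-negative; must carry
#'   rownames (feature ids) and colnames (sample ids).
#' @param groups character vector of group labels, one per sample (named by
#'   sample or in column order).
#' @param lib_sizes optional positive numeric vector of library sizes, one per
#'   sample; defaults to column sums.
#' @return an object of class `count_matrix`: a list with elements `counts`,
#'   `groups` (named character) and `lib_sizes` (named numeric).
#' @export
count_matrix <- function(counts, groups, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing))
      stop("samples missing from group map: ", paste(missing, collapse = ", "))
    groups <- groups[colnames(counts)]
  } else {
    if (length(groups) != ncol(counts))
      stop("groups must name every sample")
    names(groups) <- colnames(counts)
  }
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  } else {
    if (length(lib_sizes) != ncol(counts) || any(lib_sizes <= 0))
      stop("lib_sizes must be positive, one per sample")
    names(lib_sizes) <- colnames(counts)
  }
  structure(
    list(counts = counts,
         groups = stats::setNames(as.character(groups), colnames(counts)),
         lib_sizes = lib_sizes),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds feature ids and whose
#' header row names the samples; every sample must be covered by `group_map`.
#'
#' @param path path to the TSV file.
#' @param group_map named character vector mapping sample id to group label,
#'   or a data.frame with columns `sample` and `group`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, group_map) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("count TSV needs a feature column and >= 1 sample")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  if (is.data.frame(group_map))
    group_map <- stats::setNames(as.character(group_map$group),
                                 group_map$sample)
  count_matrix(m, group_map)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Composition-normalization factors per sample. The reference sample is the
#' one whose upper-quartile CPM lies closest to the mean upper quartile.
#' For every sample, M (log2 expression ratio vs the reference) and
#' A (average log2 abundance) are computed over features with nonzero counts
#' in both samples; the most extreme `trim_m` of M values and `trim_a` of A
#' values are trimmed from each tail, and the factor is 2^(weighted mean M)
#' with inverse asymptotic-variance weights. Factors are rescaled to
#' geometric mean 1.
#'
#' @param cm a [count_matrix()].
#' @param trim_m two-sided trim fraction for M values (default 0.30 per tail).
#' @param trim_a two-sided trim fraction for A values (default 0.05 per tail).
#' @return named positive numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  y <- cm$counts
  lib <- cm$lib_sizes
  if (ncol(y) < 2) stop("TMM needs >= 2 samples")
  if (any(colSums(y) == 0)) stop("all-zero sample: cannot normalize")
  cpm0 <- sweep(y, 2, lib, "/") * 1e6
  uq <- apply(cpm0, 2, stats::quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))  # ties -> lowest index (which.min)
  f <- vapply(seq_len(ncol(y)), function(j) {
    .tmm_pair_factor(y[, j], y[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(y))
}

# one-sample-vs-reference TMM factor (rank-based two-sided trimming)
.tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  M <- log2(p_obs[keep] / p_ref[keep])
  A <- 0.5 * log2(p_obs[keep] * p_ref[keep])
  # asymptotic variance of M (delta method, binomial sampling)
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(use)) return(1)
  f <- sum(M[use] / w[use]) / sum(1 / w[use])
  if (!is.finite(f)) return(1)
  2^f
}

#' Counts per million (CPM), optionally log2
#'
#' `CPM_ij = counts_ij / (lib_size_j * factor_j) * 1e6`. With `log = TRUE`, a
#' library-size-scaled prior count is added before the ratio (the prior is
#' proportional to each sample's effective library size, so all values are
#' finite and zero counts map to comparable values across samples).
#'
#' @param cm a [count_matrix()].
#' @param factors positive normalization factors, one per sample (default 1).
#' @param log return log2 values?
#' @param prior_count average prior count added when `log = TRUE` (default 2).
#' @return an `expression_matrix`: numeric matrix with attribute
#'   `unit` = "CPM" or "log2CPM".
#' @export
cpm <- function(cm, factors = NULL, log = FALSE, prior_count = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(factors)) factors <- rep(1, ncol(cm$counts))
  if (length(factors) != ncol(cm$counts) || any(factors <= 0))
    stop("factors must be positive, one per sample")
  eff <- cm$lib_sizes * factors
  if (!log) {
    out <- sweep(cm$counts, 2, eff, "/") * 1e6
    attr(out, "unit") <- "CPM"
  } else {
    # scale the prior so that its CPM contribution is equal across samples
    pri <- prior_count * eff / mean(eff)
    adj <- eff + 2 * pri
    out <- log2(sweep(sweep(cm$counts, 2, pri, "+"), 2, adj, "/") * 1e6)
    attr(out, "unit") <- "log2CPM"
  }
  class(out) <- c("expression_matrix", class(out))
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", attr(x, "unit"), "]: ", nrow(x), " features x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' Filter features by mean abundance
#'
#' Retains features whose mean CPM across all samples meets the threshold;
#' the default mirrors dropping low-abundance miRNAs with average CPM < 100.
#' Input must be on the linear CPM scale (not log).
#'
#' @param em CPM matrix from [cpm()] with `log = FALSE`.
#' @param threshold minimum mean CPM (default 100).
#' @return character vector of retained feature ids, input order preserved.
#' @export
filter_by_abundance <- function(em, threshold = 100) {
  unit <- attr(em, "unit")
  if (!is.null(unit) && unit != "CPM")
    stop("filter_by_abundance expects linear CPM input, got ", unit)
  rownames(em)[rowMeans(em) >= threshold]
}
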