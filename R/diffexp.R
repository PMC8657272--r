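#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood of the NB dispersion over all
#' features and groups, after rescaling counts to library-size-equalized
#' pseudo-counts (geometric-mean effective library size target). The
#' conditional likelihood for one feature within one group of n samples with
#' (pseudo-)counts y and total z is
#' `sum(lgamma(y + 1/phi)) + lgamma(n/phi) - lgamma(z + n/phi) - n*lgamma(1/phi)`.
#' Groups with a single sample carry no information and are skipped.
#'
#' @param cm a [count_matrix()].
#' @param factors optional TMM factors (default: computed via [tmm_factors()]
#'   when >= 2 samples).
#' @return dispersion phi in `[0, 10]` (variance = mu + phi * mu^2).
#' @export
estimate_common_dispersion <- function(cm, factors = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2) stop("need >= 2 samples to estimate dispersion")
  if (is.null(factors)) factors <- tmm_factors(cm)
  eff <- cm$lib_sizes * factors
  target <- exp(mean(log(eff)))
  pseudo <- sweep(cm$counts, 2, target / eff, "*")
  groups <- cm$groups
  ok_groups <- names(which(table(groups) >= 2))
  if (!length(ok_groups))
    stop("no group with >= 2 samples")
  cols <- lapply(ok_groups, function(g) which(groups == g))
  negll <- function(lphi) {
    phi <- exp(lphi)
    r <- 1 / phi
    total <- 0
    for (idx in cols) {
      y <- pseudo[, idx, drop = FALSE]
      n <- length(idx)
      z <- rowSums(y)
      ll <- rowSums(lgamma(y + r)) + lgamma(n * r) - lgamma(z + n * r) -
        n * lgamma(r)
      total <- total + sum(ll)
    }
    -total
  }
  opt <- stats::optimize(negll, lower = log(1e-8), upper = log(10))
  phi <- exp(opt$minimum)
  # boundary: flat/decreasing likelihood means no overdispersion
  if (phi < 1e-6 || negll(log(1e-8)) <= opt$objective) phi <- 0
  min(phi, 10)
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' Conditions on the pooled count sum: under H0 both groups share the same
#' per-sample mean, group sums are NB with size `n_g / phi`, and the
#' conditional two-sided p-value sums the probabilities of all partitions of
#' the total that are at most as likely as the observed one. At `phi = 0`
#' the NB degenerates to Poisson and the conditional law is binomial.
#'
#' Counts are first rescaled to the geometric-mean effective library size and
#' group sums rounded, so that equal per-sample means are a meaningful null.
#'
#' @param counts_a,counts_b non-negative count vectors for the two groups.
#' @param phi NB dispersion (>= 0).
#' @param lib_a,lib_b effective library sizes per sample (default: all equal).
#' @return two-sided p-value in `(0, 1]`.
#' @export
nb_exact_test <- function(counts_a, counts_b, phi,
                          lib_a = rep(1, length(counts_a)),
                          lib_b = rep(1, length(counts_b))) {
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (phi < 0) stop("phi must be >= 0")
  target <- exp(mean(log(c(lib_a, lib_b))))
  s_a <- round(sum(counts_a * target / lib_a))
  s_b <- round(sum(counts_b * target / lib_b))
  n_a <- length(counts_a)
  n_b <- length(counts_b)
  total <- s_a + s_b
  if (total == 0) return(1)
  .cond_two_sided_p(s_a, total, n_a, n_b, phi)
}

# p = sum of conditional probabilities <= that of the observed group-A sum
.cond_two_sided_p <- function(s_a, total, n_a, n_b, phi) {
  pa <- n_a / (n_a + n_b)
  if (total > 20000) {
    # enumerate a +/- 40 sd window (outside mass < 1e-200, negligible in p)
    mu <- total / (n_a + n_b)
    sdev <- sqrt(total * pa * (1 - pa) * (1 + phi * mu))
    lo <- max(0, floor(total * pa - 40 * sdev))
    hi <- min(total, ceiling(total * pa + 40 * sdev))
    k <- min(lo, s_a):max(hi, s_a)
  } else {
    k <- 0:total
  }
  if (phi <= 0) {
    lp <- stats::dbinom(k, total, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu <- total / (n_a + n_b)
    lp <- stats::dnbinom(k, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(total - k, size = n_b / phi, mu = n_b * mu, log = TRUE)
    lp <- lp - .logsumexp(lp)
  }
  obs <- lp[match(s_a, k)]
  # 1e-4 log tolerance: outcomes analytically tied with the observed one
  # (e.g. twin binomial modes) stay included despite floating-point noise;
  # away from the mode, adjacent log-probability gaps are far larger
  keep <- lp <= obs + 1e-4
  p <- exp(.logsumexp(lp[keep]))
  min(p, 1)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Run the two-group differential-expression contrast
#'
#' TMM factors -> effective library sizes -> common dispersion -> per-feature
#' NB exact test -> BH FDR. The log2 fold change is computed from
#' prior-augmented group mean CPM. Direction is UP/DN by fold-change sign for
#' features with `fdr < de_fdr`, otherwise NS.
#'
#' @param cm a [count_matrix()].
#' @param case group label of the case class (default `"ATC"`); the contrast
#'   is case vs all other samples pooled.
#' @param de_fdr FDR cut used only for the direction label (default 0.01).
#' @param prior_count prior added to group mean CPM before the log-ratio.
#' @return a `data.frame` (class `de_table`) with columns `feature`,
#'   `log2fc`, `avg_log2cpm`, `p_value`, `fdr`, `direction`.
#' @export
run_de_contrast <- function(cm, case = "ATC", de_fdr = 0.01,
                            prior_count = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  is_case <- cm$groups == case
  if (!any(is_case) || all(is_case))
    stop("contrast needs samples in both classes")
  f <- tmm_factors(cm)
  eff <- cm$lib_sizes * f
  # dispersion estimated within the two contrast classes
  cm2 <- cm
  cm2$groups <- stats::setNames(ifelse(is_case, ".case", ".rest"),
                                names(cm$groups))
  phi <- estimate_common_dispersion(cm2, factors = f)
  ya <- cm$counts[, is_case, drop = FALSE]
  yb <- cm$counts[, !is_case, drop = FALSE]
  la <- eff[is_case]
  lb <- eff[!is_case]
  pv <- vapply(seq_len(nrow(cm$counts)), function(i) {
    nb_exact_test(ya[i, ], yb[i, ], phi, la, lb)
  }, numeric(1))
  cpm_lin <- cpm(cm, f, log = FALSE)
  ma <- rowMeans(cpm_lin[, is_case, drop = FALSE])
  mb <- rowMeans(cpm_lin[, !is_case, drop = FALSE])
  log2fc <- log2((ma + prior_count) / (mb + prior_count))
  avg <- rowMeans(cpm(cm, f, log = TRUE))
  fdr <- bh_fdr(pv)
  dir <- ifelse(fdr < de_fdr, ifelse(log2fc > 0, "UP", "DN"), "NS")
  dir[log2fc == 0] <- "NS"
  out <- data.frame(feature = rownames(cm$counts), log2fc = log2fc,
                    avg_log2cpm = avg, p_value = pv, fdr = fdr,
                    direction = dir, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  class(out) <- c("de_table", class(out))
  out
}

#' Select differentially expressed features
#'
#' Applies the deregulated-miRNA selection rule: `fdr < fdr_max` and mean CPM
#' strictly greater than `min_avg_cpm`, with UP/DN labels by fold-change sign.
#'
#' @param de a `de_table` from [run_de_contrast()].
#' @param cpm_matrix linear-scale CPM matrix covering the same features.
#' @param fdr_max FDR threshold (default 0.01, strict `<`).
#' @param min_avg_cpm abundance threshold (default 100, strict `>`).
#' @return `data.frame` with columns `feature`, `log2fc`, `fdr`, `direction`
#'   (UP or DN) for the selected features.
#' @export
select_de_features <- function(de, cpm_matrix, fdr_max = 0.01,
                               min_avg_cpm = 100) {
  if (!all(de$feature %in% rownames(cpm_matrix)))
    stop("cpm_matrix does not cover all DE-table features")
  avg_cpm <- rowMeans(cpm_matrix)[de$feature]
  keep <- de$fdr < fdr_max & avg_cpm > min_avg_cpm
  sel <- de[keep, c("feature", "log2fc", "fdr"), drop = FALSE]
  sel$direction <- ifelse(sel$log2fc > 0, "UP", "DN")
  rownames(sel) <- NULL
  sel
}

#' Per-gene differential expression from FPKM values
#'
#' The mRNA side of the pipeline consumes FPKM tables rather than raw counts;
#' fold changes and significance are computed by Welch t-tests on
#' log2(FPKM + 1) per gene, with BH FDR across genes. Genes with zero
#' within-group variance in both groups and equal means get p = 1.
#'
#' @param fpkm numeric matrix, genes x samples, linear FPKM.
#' @param groups group label per sample (named or column order).
#' @param case case class label (default `"ATC"`), contrasted vs the rest.
#' @return `data.frame` with `gene`, `log2fc`, `p_value`, `fdr`.
#' @export
mrna_de_table <- function(fpkm, groups, case = "ATC") {
  if (!is.null(names(groups))) groups <- groups[colnames(fpkm)]
  is_case <- groups == case
  if (!any(is_case) || all(is_case)) stop("need samples in both classes")
  x <- log2(fpkm + 1)
  a <- x[, is_case, drop = FALSE]
  b <- x[, !is_case, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  pv <- vapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(a[i, ]) == 0 && stats::sd(b[i, ]) == 0)
      return(if (log2fc[i] == 0) 1 else 0)
    stats::t.test(a[i, ], b[i, ])$p.value
  }, numeric(1))
  data.frame(gene = rownames(fpkm), log2fc = log2fc, p_value = pv,
             fdr = bh_fdr(pv), row.names = NULL, stringsAsFactors = FALSE)
}
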