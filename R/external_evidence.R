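#' Average gene essentiality across cell lines
#'
#' Arithmetic mean of CRISPR gene-effect scores over non-missing cell lines;
#' genes with no observed value stay missing (NA) and contribute a neutral 0
#' to downstream score components.
#'
#' @param es_table numeric matrix or data.frame, genes x cell lines, with
#'   gene ids as rownames (or a first column `gene`).
#' @return named numeric vector of per-gene means (NA if all missing).
#' @export
average_essentiality <- function(es_table) {
  if (is.data.frame(es_table) && "gene" %in% names(es_table)) {
    rn <- es_table$gene
    es_table <- as.matrix(es_table[, setdiff(names(es_table), "gene"),
                                   drop = FALSE])
    rownames(es_table) <- rn
  }
  es_table <- as.matrix(es_table)
  m <- rowMeans(es_table, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' Signed max-abs scaling to \[-1, 1\]
#'
#' After an optional transform (`log2` for hazard ratios, so HR = 1 maps
#' to 0), negative values are divided by the largest absolute negative value
#' and positive values by the largest positive value. Zeros stay 0 and
#' missing values become 0 (neutral evidence). The result is bounded in
#' \[-1, 1\] and monotone within each sign group.
#'
#' @param values numeric vector (may contain NA).
#' @param transform `"identity"` (essentiality scores) or `"log2"`
#'   (hazard ratios; requires positive values).
#' @return numeric vector in \[-1, 1\], names preserved.
#' @export
signed_scale <- function(values, transform = c("identity", "log2")) {
  transform <- match.arg(transform)
  x <- values
  if (transform == "log2") {
    if (any(x <= 0, na.rm = TRUE))
      stop("log2 transform requires positive values")
    x <- log2(x)
  }
  out <- rep(0, length(x))
  names(out) <- names(values)
  neg <- !is.na(x) & x < 0
  pos <- !is.na(x) & x > 0
  if (any(neg)) out[neg] <- x[neg] / max(abs(x[neg]))
  if (any(pos)) out[pos] <- x[pos] / max(x[pos])
  out
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group and the standard log-rank
#' observed/expected tabulation over distinct event times. The hazard ratio
#' is the ratio of O/E ratios with group 1 (first factor level / `high`)
#' in the numerator. With zero events overall, p and HR are NA and the
#' result is flagged.
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group two-level factor or character vector; the first level (or
#'   `"high"` if present) is group 1.
#' @return list with `groups`, `curves` (per group: data.frame time/surv),
#'   `observed`, `expected` (length-2 vectors), `chisq`, `p_value`, `hr`,
#'   `no_events` flag.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly two groups required")
  if ("high" %in% lev) lev <- c("high", setdiff(lev, "high"))
  g1 <- group == lev[1]
  curves <- lapply(c(TRUE, FALSE), function(first) {
    sel <- if (first) g1 else !g1
    .km_curve(time[sel], event[sel])
  })
  names(curves) <- lev
  if (sum(event) == 0) {
    return(list(groups = lev, curves = curves,
                observed = c(0, 0), expected = c(0, 0),
                chisq = NA_real_, p_value = NA_real_, hr = NA_real_,
                no_events = TRUE))
  }
  tab <- .logrank_table(time, event, g1)
  O <- c(sum(tab$d1), sum(tab$d2))
  E <- c(sum(tab$e1), sum(tab$d) - sum(tab$e1))
  V <- sum(tab$v)
  chisq <- if (V > 0) (O[1] - E[1])^2 / V else NA_real_
  p <- if (is.na(chisq)) NA_real_ else stats::pchisq(chisq, 1,
                                                     lower.tail = FALSE)
  hr <- if (all(E > 0) && O[2] > 0) (O[1] / E[1]) / (O[2] / E[2])
        else NA_real_
  list(groups = lev, curves = curves, observed = O, expected = E,
       chisq = chisq, p_value = p, hr = hr, no_events = FALSE)
}

# product-limit estimate: one row per distinct event time
.km_curve <- function(time, event) {
  if (!length(time))
    return(data.frame(time = numeric(0), surv = numeric(0)))
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# per-event-time log-rank tabulation (hypergeometric variance)
.logrank_table <- function(time, event, g1) {
  tt <- sort(unique(time[event == 1]))
  t1 <- time[g1]
  t2 <- time[!g1]
  te1 <- time[g1 & event == 1]
  te2 <- time[!g1 & event == 1]
  n1 <- vapply(tt, function(t) sum(t1 >= t), numeric(1))
  n2 <- vapply(tt, function(t) sum(t2 >= t), numeric(1))
  d1 <- vapply(tt, function(t) sum(te1 == t), numeric(1))
  d2 <- vapply(tt, function(t) sum(te2 == t), numeric(1))
  n <- n1 + n2
  d <- d1 + d2
  e1 <- d * n1 / n
  v <- ifelse(n > 1, d * (n1 / n) * (n2 / n) * (n - d) / pmax(n - 1, 1), 0)
  data.frame(time = tt, n1 = n1, n2 = n2, d1 = d1, d2 = d2, d = d,
             e1 = e1, v = v)
}

#' Per-gene survival screen by median expression split
#'
#' Drops genes whose summed FPKM across all samples is below 1, log2
#' transforms (`log2(FPKM + 1)`), splits samples at the per-gene median of
#' the transformed values (ties at the median go to the low group) and runs
#' a log-rank comparison of high vs low expression. Genes whose split leaves
#' an empty group (constant expression) get a missing HR.
#'
#' @param expr numeric matrix, genes x samples, linear FPKM.
#' @param clinical data.frame with columns `sample`, `time`, `event`.
#' @param min_total_fpkm expression filter on `rowSums` (default 1).
#' @return `data.frame` with `gene`, `hr`, `p_value`, `n_high`, `n_low`.
#' @export
gene_survival_screen <- function(expr, clinical, min_total_fpkm = 1) {
  common <- intersect(colnames(expr), clinical$sample)
  if (!length(common)) stop("no overlapping samples")
  expr <- expr[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample), ]
  keep <- rowSums(expr) >= min_total_fpkm
  expr <- expr[keep, , drop = FALSE]
  x <- log2(expr + 1)
  res <- lapply(rownames(x), function(g) {
    v <- x[g, ]
    med <- stats::median(v)
    grp <- ifelse(v > med, "high", "low")
    if (length(unique(grp)) < 2)
      return(data.frame(gene = g, hr = NA_real_, p_value = NA_real_,
                        n_high = sum(grp == "high"),
                        n_low = sum(grp == "low")))
    kl <- km_logrank(cl$time, cl$event, grp)
    data.frame(gene = g, hr = kl$hr, p_value = kl$p_value,
               n_high = sum(grp == "high"), n_low = sum(grp == "low"))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
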