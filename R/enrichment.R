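#' Unweighted running-sum enrichment score
#'
#' Classic enrichment statistic with exponent 0: walking down the ranking,
#' the running sum gains `1/|hits|` at each gene-set member and loses
#' `1/(N - |hits|)` at each non-member; the ES is the signed maximum
#' deviation from zero. Only set members present in the ranking count.
#'
#' @param ranking character vector of unique gene ids, best rank first.
#' @param gene_set character vector of member gene ids.
#' @return ES in \[-1, 1\].
#' @export
unweighted_es <- function(ranking, gene_set) {
  hits <- which(ranking %in% gene_set)
  nh <- length(hits)
  N <- length(ranking)
  if (!nh) stop("gene set does not overlap the ranking")
  if (nh == N) stop("gene set covers the entire ranking: ES undefined")
  .es_from_positions(hits, nh, N)
}

# ES from sorted hit positions; extrema occur at hits (max candidates) or
# just before hits (min candidates), plus the trailing tail toward 0
.es_from_positions <- function(pos, nh, N) {
  nm <- N - nh
  i <- seq_len(nh)
  after <- i / nh - (pos - i) / nm
  before <- (i - 1) / nh - (pos - i) / nm
  es_max <- max(after)
  es_min <- min(before, 0)
  if (abs(es_max) >= abs(es_min)) es_max else es_min
}

#' Pre-ranked gene set enrichment with a permutation null
#'
#' Runs [unweighted_es()] for every gene set with at least `min_size`
#' members in the ranking. The null distribution permutes gene labels:
#' for each permutation, `|hits|` positions are drawn uniformly without
#' replacement. NES is ES divided by the mean |null ES| of matching sign;
#' the p-value is the matching-sign null tail (with the +1 correction, so
#' p >= 1/(n_perm + 1)); FDR is Benjamini-Hochberg across reported sets.
#'
#' @param ranking character vector of unique gene ids, best first.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param min_size minimum overlap with the ranking (default 10).
#' @param n_perm number of label permutations (default 1000; fewer than 100
#'   triggers a warning about wide confidence intervals).
#' @param seed RNG seed for the permutations.
#' @return `data.frame`: `set_name`, `es`, `nes`, `p_value`, `fdr`,
#'   `set_size_used`.
#' @export
preranked_gsea <- function(ranking, gene_sets, min_size = 10,
                           n_perm = 1000, seed = 1) {
  if (anyDuplicated(ranking)) stop("ranking must contain unique gene ids")
  if (n_perm < 100)
    warning("n_perm < 100: permutation p-values will be imprecise")
  N <- length(ranking)
  sizes <- vapply(gene_sets, function(s) sum(ranking %in% s), integer(1))
  keep <- which(sizes >= min_size & sizes < N)
  if (!length(keep))
    return(data.frame(set_name = character(), es = numeric(),
                      nes = numeric(), p_value = numeric(), fdr = numeric(),
                      set_size_used = integer()))
  set.seed(seed)
  res <- lapply(keep, function(k) {
    nh <- sizes[k]
    es <- unweighted_es(ranking, gene_sets[[k]])
    null_es <- vapply(seq_len(n_perm), function(p) {
      .es_from_positions(sort(sample.int(N, nh)), nh, N)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(set_name = names(gene_sets)[k], es = es, nes = nes,
               p_value = p, set_size_used = nh, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out[, c("set_name", "es", "nes", "p_value", "fdr", "set_size_used")]
}

#' Rankings of IS-positive target genes by mRNA fold change
#'
#' Builds the two pre-ranked inputs for enrichment analysis: target genes of
#' DN-miRNAs with strictly positive scaled IS, and likewise for UP-miRNAs,
#' each deduplicated and ordered by target mRNA log2 fold change
#' (descending; ties broken by gene id). A gene targeted by both an UP- and
#' a DN-miRNA with positive IS appears in both rankings.
#'
#' @param scored output of [score_interactions()].
#' @param mrna_de mRNA DE table with `gene` and `log2fc`.
#' @return list with elements `dn` and `up`, each a `data.frame` with
#'   `gene` and `log2fc` in ranking order (possibly empty).
#' @export
target_subset_rankings <- function(scored, mrna_de) {
  fc <- stats::setNames(mrna_de$log2fc, mrna_de$gene)
  one <- function(dirn) {
    genes <- unique(scored$gene[scored$direction == dirn &
                                  scored$is_scaled > 0])
    genes <- genes[genes %in% names(fc)]
    d <- data.frame(gene = genes, log2fc = unname(fc[genes]),
                    stringsAsFactors = FALSE)
    d[order(-d$log2fc, d$gene), , drop = FALSE]
  }
  dn <- one("DN"); rownames(dn) <- NULL
  up <- one("UP"); rownames(up) <- NULL
  list(dn = dn, up = up)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output file.
#' @param description description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  description <- rep_len(description, length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], description[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate small synthetic gene-set collections for tests
#'
#' Builds `n_random` random sets over the given gene universe plus, when a
#' truth ledger is supplied, two planted sets (`SYN_ONCO_TARGETS`,
#' `SYN_TS_TARGETS`) holding the planted oncogene and suppressor targets.
#'
#' @param genes gene universe.
#' @param n_random number of random sets (default 20).
#' @param size_range set size range (default 10-40).
#' @param truth optional truth ledger from [generate_cohort()].
#' @param seed RNG seed.
#' @return named list of character vectors.
#' @export
make_synthetic_gmt <- function(genes, n_random = 20, size_range = c(10, 40),
                               truth = NULL, seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(n_random), function(i) {
    n <- sample(size_range[1]:size_range[2], 1)
    sample(genes, min(n, length(genes)))
  })
  names(sets) <- sprintf("SYN_RANDOM_%02d", seq_len(n_random))
  if (!is.null(truth)) {
    sets$SYN_ONCO_TARGETS <- unique(truth$gene_labels$gene[
      truth$gene_labels$label == "oncogene"])
    sets$SYN_TS_TARGETS <- unique(truth$gene_labels$gene[
      truth$gene_labels$label == "suppressor"])
  }
  sets
}
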