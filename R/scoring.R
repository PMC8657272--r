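#' Scaled fold-change component
#'
#' Scales a target mRNA log2 fold change against the full candidate-target
#' context so that the strongest upregulation maps to 1 and the strongest
#' downregulation to -1: positive values are divided by the context maximum,
#' negative values by the absolute context minimum, zero stays 0.
#'
#' @param log2fc fold change(s) to scale (vectorized).
#' @param context all candidate-target log2 fold changes defining the
#'   scaling population (non-empty).
#' @return component c2 in \[-1, 1\].
#' @export
fc_component <- function(log2fc, context) {
  if (!length(context)) stop("empty fold-change context")
  pos_max <- max(c(context[context > 0], 0))
  neg_max <- max(c(abs(context[context < 0]), 0))
  out <- numeric(length(log2fc))
  up <- !is.na(log2fc) & log2fc > 0
  dn <- !is.na(log2fc) & log2fc < 0
  if (any(up)) {
    if (pos_max == 0) stop("positive value outside context")
    out[up] <- log2fc[up] / pos_max
  }
  if (any(dn)) {
    if (neg_max == 0) stop("negative value outside context")
    out[dn] <- log2fc[dn] / neg_max
  }
  out
}

#' Inverse-association bonus
#'
#' 1 if (a) the target mRNA fold change is opposite in sign to the miRNA
#' deregulation and (b) the mRNA change is significant (`fdr < fdr_max`,
#' default 0.05); else 0. Missing fold change or FDR gives 0.
#'
#' @param mirna_direction `"UP"` or `"DN"` per interaction (vectorized).
#' @param target_log2fc target mRNA log2 fold change.
#' @param target_fdr target mRNA FDR.
#' @param fdr_max significance threshold (default 0.05).
#' @return component c3 in `{0, 1}`.
#' @export
inverse_bonus <- function(mirna_direction, target_log2fc, target_fdr,
                          fdr_max = 0.05) {
  if (!all(mirna_direction %in% c("UP", "DN")))
    stop("mirna_direction must be UP or DN")
  inverse <- (mirna_direction == "DN" & target_log2fc > 0) |
    (mirna_direction == "UP" & target_log2fc < 0)
  ok <- !is.na(inverse) & inverse & !is.na(target_fdr) & target_fdr < fdr_max
  as.numeric(ok)
}

#' Raw interaction score
#'
#' Direction-specific combination of the five evidence components
#' (binding c1, scaled target fold change c2, inverse bonus c3, scaled
#' essentiality c4, scaled hazard ratio c5):
#' * UP-miRNAs: `IS = c1 - c2 + c3 + c4 - c5`
#' * DN-miRNAs: `IS = c1 + c2 + c3 - c4 + c5`
#'
#' so that for a DN-miRNA an upregulated, essential, prognostically adverse
#' target (candidate oncogene) maximizes the score, and for an UP-miRNA a
#' downregulated, growth-suppressive, protective target does.
#'
#' @param c1,c2,c3,c4,c5 component vectors (missing evidence encoded as 0).
#' @param direction `"UP"` or `"DN"` per interaction.
#' @return raw IS (bounded by \[-4, 5\] given the component ranges).
#' @export
interaction_score_raw <- function(c1, c2, c3, c4, c5, direction) {
  if (!all(direction %in% c("UP", "DN")))
    stop("unknown direction: ", paste(setdiff(direction, c("UP", "DN")),
                                      collapse = ", "))
  s <- ifelse(direction == "UP", -1, 1)
  c1 + s * c2 + c3 - s * c4 + s * c5
}

#' Scale raw interaction scores to \[-1, 1\] within one miRNA
#'
#' Min-max mapping `x -> 2 (x - min) / (max - min) - 1` over all interactions
#' of a single miRNA. When all raw scores are equal the miRNA is degenerate:
#' every scaled value is 0 and the degenerate flag is set (such miRNAs are
#' excluded from prime-target selection).
#'
#' @param is_raw raw scores of one miRNA (non-empty).
#' @return list with `scaled` and `degenerate`.
#' @export
scale_is_per_mirna <- function(is_raw) {
  if (!length(is_raw)) stop("no interactions for miRNA")
  lo <- min(is_raw)
  hi <- max(is_raw)
  if (hi == lo)
    return(list(scaled = rep(0, length(is_raw)), degenerate = TRUE))
  list(scaled = 2 * (is_raw - lo) / (hi - lo) - 1, degenerate = FALSE)
}

#' Score all candidate miRNA-mRNA interactions
#'
#' Assembles the five evidence components for every interaction of the
#' differentially expressed miRNAs and computes raw and per-miRNA scaled
#' interaction scores. Records below the binding-probability threshold are
#' dropped; duplicate transcript-level records are collapsed to one
#' interaction per miRNA-gene pair (maximum binding probability). The
#' fold-change, essentiality and hazard-ratio scalings are computed across
#' the set of evaluated target genes; genes missing from a source contribute
#' a neutral 0.
#'
#' @param interactions interaction `data.frame`
#'   (see [read_interaction_table()]).
#' @param de_mirnas selected DE miRNAs: `data.frame` with `feature` and
#'   `direction` (`"UP"`/`"DN"`), from [select_de_features()].
#' @param mrna_de mRNA DE table with `gene`, `log2fc`, `fdr`
#'   (see [mrna_de_table()]).
#' @param es_mean named per-gene mean essentiality
#'   (see [average_essentiality()]); may be missing genes.
#' @param hr named per-gene hazard ratio (or a `data.frame` from
#'   [gene_survival_screen()]).
#' @param min_bp binding-probability threshold (default 0.95).
#' @return `data.frame` (class `scored_interactions`) with one row per
#'   miRNA-gene pair: components `c1`..`c5`, `is_raw`, `is_scaled` and a
#'   per-miRNA `degenerate` flag.
#' @export
score_interactions <- function(interactions, de_mirnas, mrna_de,
                               es_mean = NULL, hr = NULL, min_bp = 0.95) {
  if (is.data.frame(hr))
    hr <- stats::setNames(hr$hr, hr$gene)
  rec <- interactions[interactions$mirna %in% de_mirnas$feature &
                        interactions$binding_probability >= min_bp, ,
                      drop = FALSE]
  if (!nrow(rec)) stop("no interactions left after DE/binding filtering")
  rec <- collapse_interactions(rec)
  dir <- stats::setNames(de_mirnas$direction, de_mirnas$feature)[rec$mirna]

  genes <- unique(rec$gene)
  fc <- stats::setNames(mrna_de$log2fc, mrna_de$gene)[genes]
  fdr <- stats::setNames(mrna_de$fdr, mrna_de$gene)[genes]
  names(fc) <- names(fdr) <- genes
  context <- fc[!is.na(fc)]
  c2_gene <- stats::setNames(rep(0, length(genes)), genes)
  if (length(context))
    c2_gene[names(context)] <- fc_component(context, context)
  es_gene <- stats::setNames(rep(NA_real_, length(genes)), genes)
  if (!is.null(es_mean)) {
    hitg <- intersect(genes, names(es_mean))
    es_gene[hitg] <- es_mean[hitg]
  }
  hr_gene <- stats::setNames(rep(NA_real_, length(genes)), genes)
  if (!is.null(hr)) {
    hitg <- intersect(genes, names(hr))
    hr_gene[hitg] <- hr[hitg]
  }
  c4_gene <- signed_scale(es_gene, "identity")
  c5_gene <- signed_scale(hr_gene, "log2")

  sc <- data.frame(
    mirna = rec$mirna,
    direction = unname(dir),
    gene = rec$gene,
    c1 = binding_component(rec$binding_probability, rec$flag_ts,
                           rec$flag_mirdb),
    c2 = unname(c2_gene[rec$gene]),
    c3 = inverse_bonus(unname(dir), unname(fc[rec$gene]),
                       unname(fdr[rec$gene])),
    c4 = unname(c4_gene[rec$gene]),
    c5 = unname(c5_gene[rec$gene]),
    stringsAsFactors = FALSE)
  sc$is_raw <- interaction_score_raw(sc$c1, sc$c2, sc$c3, sc$c4, sc$c5,
                                     sc$direction)
  sc$is_scaled <- NA_real_
  sc$degenerate <- FALSE
  for (m in unique(sc$mirna)) {
    idx <- which(sc$mirna == m)
    s <- scale_is_per_mirna(sc$is_raw[idx])
    sc$is_scaled[idx] <- s$scaled
    sc$degenerate[idx] <- s$degenerate
  }
  class(sc) <- c("scored_interactions", class(sc))
  sc
}

#' Select prime targets (scaled IS = 1) per miRNA
#'
#' For every non-degenerate DE miRNA, returns all interactions whose scaled
#' IS equals 1 (ties are kept and flagged). Also reports, per gene, how many
#' miRNAs select it as prime.
#'
#' @param scored output of [score_interactions()].
#' @return `data.frame` of prime interactions with a `tied` flag and a
#'   `prime_count` per gene; attribute `multi_prime_genes` lists genes prime
#'   for more than one miRNA.
#' @export
select_prime_targets <- function(scored) {
  ok <- !scored$degenerate & scored$is_scaled >= 1 - 1e-12
  prime <- scored[ok, , drop = FALSE]
  if (nrow(prime)) {
    ties <- table(prime$mirna)
    prime$tied <- ties[prime$mirna] > 1
    cnt <- table(prime$gene)
    prime$prime_count <- as.integer(cnt[prime$gene])
  } else {
    prime$tied <- logical(0)
    prime$prime_count <- integer(0)
  }
  rownames(prime) <- NULL
  attr(prime, "multi_prime_genes") <-
    names(which(table(unique(prime[, c("mirna", "gene")])$gene) > 1))
  prime
}

#' OncoScore for the prime-target set
#'
#' `OS_raw = c2 - c4 + c5` per prime interaction: strongly upregulated,
#' essential (negative gene effect), prognostically adverse genes score
#' high (candidate oncogenes); the mirror pattern scores low (candidate
#' tumor suppressors). Genes prime for several miRNAs are represented by
#' their maximal-|OS_raw| interaction; gene-level values are then min-max
#' scaled to \[-1, 1\] across the prime set.
#'
#' @param prime output of [select_prime_targets()] (non-empty).
#' @return `data.frame`, one row per prime gene: `gene`, `os_raw`,
#'   `os_scaled`, `multiplicity` (number of prime miRNAs), `mirnas`
#'   (comma-separated), ordered by `os_scaled` descending.
#' @export
onco_score <- function(prime) {
  if (!nrow(prime)) stop("empty prime set")
  prime$os_raw <- prime$c2 - prime$c4 + prime$c5
  rows <- lapply(split(seq_len(nrow(prime)), prime$gene), function(idx) {
    i <- idx[which.max(abs(prime$os_raw[idx]))]
    data.frame(gene = prime$gene[i], os_raw = prime$os_raw[i],
               multiplicity = length(unique(prime$mirna[idx])),
               mirnas = paste(sort(unique(prime$mirna[idx])),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  lo <- min(g$os_raw)
  hi <- max(g$os_raw)
  g$os_scaled <- if (hi == lo) 0 else 2 * (g$os_raw - lo) / (hi - lo) - 1
  g <- g[order(-g$os_scaled, g$gene), c("gene", "os_raw", "os_scaled",
                                        "multiplicity", "mirnas")]
  rownames(g) <- NULL
  g
}

#' Extract the deduplicated gene signature
#'
#' Unique prime-target genes ordered by scaled OncoScore (descending), with
#' the number of prime miRNAs per gene.
#'
#' @param prime output of [select_prime_targets()].
#' @return `data.frame` with `gene`, `os_scaled`, `multiplicity`.
#' @export
extract_signature <- function(prime) {
  os <- onco_score(prime)
  os[, c("gene", "os_scaled", "multiplicity")]
}
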