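#' Read a predicted miRNA-mRNA interaction table
#'
#' Parses the CSV dialect produced by miRWalk-style predictors: one row per
#' predicted binding site with transcript-relative 3'-UTR coordinates
#' (1-based inclusive, position 1 = first UTR nucleotide), the predictor's
#' binding probability and binary flags from two further prediction sources.
#' Rows whose `region` is not `"3UTR"` are dropped and counted; malformed
#' rows abort with their row numbers.
#'
#' @param path CSV with columns `mirna`, `gene`, `transcript`, `site_start`,
#'   `site_end`, `binding_probability`, `flag_ts`, `flag_mirdb`, `region`.
#' @return `data.frame` of interaction records with attribute
#'   `dropped_non_utr3` (count of non-3'-UTR rows removed).
#' @export
read_interaction_table <- function(path) {
  req <- c("mirna", "gene", "transcript", "site_start", "site_end",
           "binding_probability", "flag_ts", "flag_mirdb", "region")
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  missing <- setdiff(req, names(dt))
  if (length(missing))
    stop("interaction table missing columns: ", paste(missing, collapse = ", "))
  dt <- dt[, req]
  bad <- which(!is.finite(dt$site_start) | !is.finite(dt$site_end) |
                 dt$site_start < 1 | dt$site_start > dt$site_end |
                 !is.finite(dt$binding_probability) |
                 dt$binding_probability < 0 | dt$binding_probability > 1 |
                 !(dt$flag_ts %in% c(0, 1)) | !(dt$flag_mirdb %in% c(0, 1)))
  if (length(bad))
    stop("malformed interaction rows: ", paste(utils::head(bad, 20),
                                               collapse = ", "))
  non_utr <- dt$region != "3UTR"
  out <- dt[!non_utr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_non_utr3") <- sum(non_utr)
  out
}

#' Combined binding-evidence component
#'
#' `(binding_probability + flag_ts + flag_mirdb) / 3`, so that a site
#' predicted with probability 1 by the primary source and supported by both
#' further predictors scores the maximum of 1. Records below the 0.95
#' probability threshold must have been excluded upstream and are an error.
#'
#' @param binding_probability probability in `[0.95, 1]` (vectorized).
#' @param flag_ts,flag_mirdb binary support flags from the two further
#'   prediction sources.
#' @return component c1 in `[0, 1]`.
#' @export
binding_component <- function(binding_probability, flag_ts, flag_mirdb) {
  if (any(binding_probability < 0.95))
    stop("binding_probability < 0.95: threshold must be applied upstream")
  (binding_probability + flag_ts + flag_mirdb) / 3
}

#' Load transcript annotation from GTF
#'
#' Reads a GTF (1-based inclusive) and indexes 3'-UTR blocks
#' (`type == "three_prime_utr"`) by transcript and gene.
#'
#' @param path GTF file path.
#' @return an `annotation` object: list with `utr3` (a `GRanges` of UTR
#'   blocks carrying `gene_id` and `transcript_id`) and `tx2gene`
#'   (data.frame transcript_id/gene_id).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  annotation_from_granges(gr)
}

#' Build an annotation object from a GRanges of GTF features
#'
#' @param gr `GRanges` with metadata columns `type`, `gene_id`,
#'   `transcript_id`; only `three_prime_utr` rows are indexed.
#' @return an `annotation` object (see [read_annotation()]).
#' @export
annotation_from_granges <- function(gr) {
  utr <- gr[S4Vectors::mcols(gr)$type == "three_prime_utr"]
  if (!length(utr)) stop("annotation contains no three_prime_utr features")
  tx <- unique(data.frame(
    transcript_id = S4Vectors::mcols(utr)$transcript_id,
    gene_id = S4Vectors::mcols(utr)$gene_id,
    stringsAsFactors = FALSE))
  structure(list(utr3 = utr, tx2gene = tx), class = "annotation")
}

#' Construct the meta-3'-UTR of a gene
#'
#' The union over all of the gene's transcript variants of their annotated
#' 3'-UTR genomic intervals, merged into sorted non-overlapping blocks.
#'
#' @param gene_id gene identifier present in the annotation.
#' @param annotation from [read_annotation()].
#' @return list with `gene_id`, `chrom`, `strand`, `blocks` (data.frame
#'   `start`/`end`, 0-based half-open, sorted) and `transcripts`.
#' @export
build_meta_utr <- function(gene_id, annotation) {
  stopifnot(inherits(annotation, "annotation"))
  utr <- annotation$utr3[S4Vectors::mcols(annotation$utr3)$gene_id == gene_id]
  if (!length(utr)) {
    if (!gene_id %in% annotation$tx2gene$gene_id)
      stop("gene not in annotation: ", gene_id)
    stop("gene has no annotated 3'-UTR: ", gene_id)
  }
  merged <- GenomicRanges::reduce(utr)
  merged <- sort(merged, ignore.strand = TRUE)
  list(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(merged))[1],
    strand = as.character(GenomicRanges::strand(merged))[1],
    blocks = data.frame(start = GenomicRanges::start(merged) - 1L,
                        end = GenomicRanges::end(merged)),
    transcripts = unique(S4Vectors::mcols(utr)$transcript_id)
  )
}

# 3'-UTR blocks of one transcript ordered 5'->3' along the transcript,
# as 0-based half-open [start, end) with chrom and strand
.tx_utr_blocks <- function(transcript_id, annotation) {
  utr <- annotation$utr3[
    S4Vectors::mcols(annotation$utr3)$transcript_id == transcript_id]
  if (!length(utr)) stop("transcript not in annotation: ", transcript_id)
  strand <- as.character(GenomicRanges::strand(utr))[1]
  o <- order(GenomicRanges::start(utr),
             decreasing = identical(strand, "-"))
  utr <- utr[o]
  list(chrom = as.character(GenomicRanges::seqnames(utr))[1],
       strand = strand,
       start = GenomicRanges::start(utr) - 1L,
       end = GenomicRanges::end(utr))
}

#' Map a transcript-relative binding site to genomic coordinates
#'
#' Walks the transcript's 3'-UTR blocks in transcript (5'->3') order and
#' converts the 1-based inclusive UTR-relative interval
#' `[site_start, site_end]` to genomic 0-based half-open intervals. On the
#' plus strand transcript order ascends genomically; on the minus strand it
#' descends. A site spanning a block junction yields multiple intervals whose
#' lengths sum to the site length.
#'
#' @param transcript_id transcript carrying the site.
#' @param site_start,site_end 1-based inclusive positions within the 3'-UTR.
#' @param annotation from [read_annotation()].
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`, sorted by
#'   genomic start.
#' @export
map_site_to_genome <- function(transcript_id, site_start, site_end,
                               annotation) {
  if (site_start < 1 || site_start > site_end)
    stop("invalid site interval")
  bl <- .tx_utr_blocks(transcript_id, annotation)
  w <- bl$end - bl$start
  offs <- cumsum(c(0, w))[seq_along(w)]  # UTR nucleotides preceding block i
  if (site_end > sum(w))
    stop("site extends beyond annotated 3'-UTR length (",
         sum(w), " nt) of ", transcript_id)
  out <- list()
  for (i in seq_along(w)) {
    a <- max(site_start, offs[i] + 1) - offs[i]   # local 1-based start
    b <- min(site_end, offs[i] + w[i]) - offs[i]  # local 1-based end
    if (a > b) next
    if (bl$strand == "-") {
      gs <- bl$end[i] - b
      ge <- bl$end[i] - a + 1
    } else {
      gs <- bl$start[i] + a - 1
      ge <- bl$start[i] + b
    }
    out[[length(out) + 1]] <- data.frame(chrom = bl$chrom, start = gs,
                                         end = ge, strand = bl$strand,
                                         stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Collapse duplicate records to one interaction per miRNA-gene pair
#'
#' The interaction score is defined per miRNA-gene pair; when several
#' transcripts contribute records for the same pair, the record with the
#' maximum binding probability is kept (ties: first occurrence).
#'
#' @param records interaction `data.frame` (see [read_interaction_table()]).
#' @return collapsed `data.frame`, one row per (mirna, gene).
#' @export
collapse_interactions <- function(records) {
  key <- paste(records$mirna, records$gene, sep = "\r")
  o <- order(key, -records$binding_probability)
  rec <- records[o, , drop = FALSE]
  rec <- rec[!duplicated(key[o]), , drop = FALSE]
  rec <- rec[order(rec$mirna, rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Stringent binding-site filter for locus-level summaries
#'
#' Retains records with binding probability exactly equal to `prob_exact`
#' (default 1.0), a targeting miRNA whose mean CPM across all samples
#' exceeds `min_avg_cpm`, and a mapped site intersecting the target gene's
#' meta-3'-UTR. Records whose transcript is absent from the annotation or
#' whose site exceeds the annotated UTR cannot be located and are excluded.
#'
#' @param records interaction `data.frame`.
#' @param cpm_matrix linear CPM matrix of miRNA expression (miRNAs x samples).
#' @param annotation from [read_annotation()].
#' @param prob_exact required binding probability (default 1.0).
#' @param min_avg_cpm miRNA abundance threshold (default 100, strict `>`).
#' @return `data.frame` of mapped site blocks: `mirna`, `gene`, `transcript`,
#'   `chrom`, `start`, `end`, `strand`, `binding_probability` (one row per
#'   genomic block; 0-based half-open).
#' @export
filter_binding_sites <- function(records, cpm_matrix, annotation,
                                 prob_exact = 1.0, min_avg_cpm = 100) {
  mirna_mean <- rowMeans(cpm_matrix)
  keep <- abs(records$binding_probability - prob_exact) < 1e-12 &
    records$mirna %in% rownames(cpm_matrix)
  keep[keep] <- mirna_mean[records$mirna[keep]] > min_avg_cpm
  rec <- records[keep, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rec))) {
    blocks <- tryCatch(
      map_site_to_genome(rec$transcript[i], rec$site_start[i],
                         rec$site_end[i], annotation),
      error = function(e) NULL)
    if (is.null(blocks)) next
    meta <- tryCatch(build_meta_utr(rec$gene[i], annotation),
                     error = function(e) NULL)
    if (is.null(meta)) next
    hit <- any(vapply(seq_len(nrow(blocks)), function(k) {
      any(blocks$start[k] < meta$blocks$end & blocks$end[k] > meta$blocks$start)
    }, logical(1)))
    if (!hit) next
    blocks$mirna <- rec$mirna[i]
    blocks$gene <- rec$gene[i]
    blocks$transcript <- rec$transcript[i]
    blocks$binding_probability <- rec$binding_probability[i]
    out[[length(out) + 1]] <- blocks
  }
  if (!length(out))
    return(data.frame(mirna = character(), gene = character(),
                      transcript = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(),
                      binding_probability = numeric()))
  res <- do.call(rbind, out)
  res[, c("mirna", "gene", "transcript", "chrom", "start", "end", "strand",
          "binding_probability")]
}

#' Write mapped binding sites as BED6
#'
#' 0-based half-open intervals; name is `mirna:gene`, score is the binding
#' probability scaled to 0-1000.
#'
#' @param sites output of [filter_binding_sites()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$start, sites$end,
                    paste(sites$mirna, sites$gene, sep = ":"),
                    as.integer(round(sites$binding_probability * 1000)),
                    sites$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
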