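write_toy_interactions <- function(rows) {
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(rows, path)
  path
}

toy_rows <- function() {
  data.frame(
    mirna = c("miR-1", "miR-1", "miR-2"),
    gene = c("G1", "G2", "G1"),
    transcript = c("G1.t1", "G2.t1", "G1.t1"),
    site_start = c(5, 10, 1),
    site_end = c(11, 16, 7),
    binding_probability = c(1, 0.97, 0.99),
    flag_ts = c(1, 0, 1),
    flag_mirdb = c(1, 1, 0),
    region = "3UTR",
    stringsAsFactors = FALSE)
}

test_that("read_interaction_table parses, drops non-3'-UTR rows, rejects bad rows", {
  expect_equal(nrow(read_interaction_table(write_toy_interactions(toy_rows()))), 3)

  rows <- toy_rows()
  rows$region[2] <- "CDS"
  got <- read_interaction_table(write_toy_interactions(rows))
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "dropped_non_utr3"), 1)

  rows <- toy_rows()
  rows$site_start[3] <- 20  # start > end
  expect_error(read_interaction_table(write_toy_interactions(rows)),
               "malformed.*3")
  rows <- toy_rows()[, -6]
  expect_error(read_interaction_table(write_toy_interactions(rows)),
               "missing columns")
})

test_that("binding_component follows the stated arithmetic and threshold", {
  expect_equal(binding_component(1.0, 1, 1), 1.0)
  expect_equal(binding_component(0.95, 1, 0), 0.65)
  expect_error(binding_component(0.94, 1, 1), "0.95")
})

test_that("build_meta_utr unions transcript 3'-UTRs", {
  # single transcript: meta equals its own UTR
  ann <- make_ann(data.frame(chrom = "chr1", start = 1001, end = 1200,
                             strand = "+", gene_id = "G1",
                             transcript_id = "G1.t1"))
  meta <- build_meta_utr("G1", ann)
  expect_equal(meta$blocks, data.frame(start = 1000L, end = 1200L))

  # overlapping variants merge into one block
  ann <- make_ann(data.frame(chrom = "chr1", start = c(1001, 1151),
                             end = c(1200, 1300), strand = "+",
                             gene_id = "G1",
                             transcript_id = c("G1.t1", "G1.t2")))
  expect_equal(build_meta_utr("G1", ann)$blocks,
               data.frame(start = 1000L, end = 1300L))

  # disjoint splice variants stay as two sorted blocks
  ann <- make_ann(data.frame(chrom = "chr1", start = c(2001, 501),
                             end = c(2100, 700), strand = "-",
                             gene_id = "G1",
                             transcript_id = c("G1.t1", "G1.t2")))
  expect_equal(build_meta_utr("G1", ann)$blocks,
               data.frame(start = c(500L, 2000L), end = c(700L, 2100L)))

  expect_error(build_meta_utr("nope", ann), "not in annotation")
})

test_that("meta-UTR is invariant to transcript input order", {
  df <- data.frame(chrom = "chr2", start = c(100, 400, 250),
                   end = c(220, 520, 420), strand = "+", gene_id = "G1",
                   transcript_id = c("t1", "t2", "t3"))
  m1 <- build_meta_utr("G1", make_ann(df))
  m2 <- build_meta_utr("G1", make_ann(df[c(3, 1, 2), ]))
  expect_equal(m1$blocks, m2$blocks)
})

test_that("plus-strand single-exon site maps by offset addition", {
  # UTR starts at genomic 1000 (0-based) = GTF start 1001
  ann <- make_ann(data.frame(chrom = "chr1", start = 1001, end = 1200,
                             strand = "+", gene_id = "G1",
                             transcript_id = "G1.t1"))
  got <- map_site_to_genome("G1.t1", 11, 17, ann)
  expect_equal(got$start, 1010)
  expect_equal(got$end, 1017)
  expect_error(map_site_to_genome("G1.t1", 195, 205, ann), "beyond")
})

test_that("minus-strand and junction mapping match the per-nucleotide oracle", {
  set.seed(42)
  for (i in 1:100) {
    ann <- random_ann()
    utr <- ann$utr3
    bl <- data.frame(start0 = GenomicRanges::start(utr) - 1,
                     end_excl = GenomicRanges::end(utr))
    strand <- as.character(GenomicRanges::strand(utr))[1]
    len <- sum(bl$end_excl - bl$start0)
    s <- sample(seq_len(len), 1)
    e <- min(len, s + sample(0:30, 1))
    got <- map_site_to_genome("G1.t1", s, e, ann)
    expect_equal(sum(got$end - got$start), e - s + 1)  # length conservation
    expect_equal(expand_blocks(got),
                 oracle_map_site(bl$start0, bl$end_excl, strand, s, e))
  }
})

test_that("a site straddling a junction returns blocks summing to its length", {
  ann <- make_ann(data.frame(chrom = "chr1", start = c(101, 301),
                             end = c(150, 350), strand = "+",
                             gene_id = "G1", transcript_id = "G1.t1"))
  got <- map_site_to_genome("G1.t1", 48, 55, ann)  # 3 nt in exon1, 5 in exon2
  expect_equal(nrow(got), 2)
  expect_equal(sum(got$end - got$start), 8)
  expect_equal(got$start, c(147, 300))
  expect_equal(got$end, c(150, 305))
})

test_that("collapse_interactions keeps the max-probability record per pair", {
  rec <- toy_rows()
  rec <- rbind(rec, within(rec[1, ], binding_probability <- 0.96))
  got <- collapse_interactions(rec)
  expect_equal(nrow(got), 3)
  expect_equal(got$binding_probability[got$mirna == "miR-1" &
                                         got$gene == "G1"], 1)
})

test_that("filter_binding_sites applies the stringent triple filter", {
  ds <- generate_cohort(small_config(seed = 9))
  cm <- ds$mirna_counts
  lin <- cpm(cm, tmm_factors(cm))
  sites <- filter_binding_sites(ds$interactions, lin, ds$annotation)

  # brute-force recomputation: probability exactly 1, miRNA mean CPM > 100,
  # mapped blocks overlapping the meta-UTR
  rec <- ds$interactions
  brute <- lapply(seq_len(nrow(rec)), function(i) {
    if (rec$binding_probability[i] != 1) return(NULL)
    if (mean(lin[rec$mirna[i], ]) <= 100) return(NULL)
    blocks <- map_site_to_genome(rec$transcript[i], rec$site_start[i],
                                 rec$site_end[i], ds$annotation)
    meta <- build_meta_utr(rec$gene[i], ds$annotation)
    ok <- FALSE
    for (k in seq_len(nrow(blocks)))
      for (j in seq_len(nrow(meta$blocks)))
        if (blocks$start[k] < meta$blocks$end[j] &&
              blocks$end[k] > meta$blocks$start[j]) ok <- TRUE
    if (ok) paste(rec$mirna[i], rec$gene[i]) else NULL
  })
  expect_setequal(unique(paste(sites$mirna, sites$gene)),
                  unique(unlist(brute)))
  # every retained site block intersects its gene's meta-UTR
  for (g in unique(sites$gene)) {
    meta <- build_meta_utr(g, ds$annotation)
    sub <- sites[sites$gene == g, ]
    hit <- vapply(seq_len(nrow(sub)), function(k)
      any(sub$start[k] < meta$blocks$end & sub$end[k] > meta$blocks$start),
      logical(1))
    expect_true(all(hit))
  }
  # excluded: record below probability 1
  expect_true(all(sites$binding_probability == 1))
})

test_that("write_sites_bed emits 6-column BED", {
  sites <- data.frame(mirna = "miR-1", gene = "G1", transcript = "G1.t1",
                      chrom = "chr1", start = 10, end = 17, strand = "+",
                      binding_probability = 1)
  path <- tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(ncol(bed), 6)
  expect_equal(bed$V2, 10)
  expect_equal(bed$V5, 1000)
})
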