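test_that("the substring index reports exact hits on both strands", {
  g <- make_genomes(tiny_config(exp_genome_length = 5000L,
                                n_chroms_exp = 1L))$experimental
  idx <- build_index(g, width = 49)
  q <- substr(g$chroms[[1]], 1001, 1049)
  hits <- query_index(idx, q)
  expect_identical(hits,
                   data.frame(chrom = "chrE1", pos = 1000L, strand = "+",
                              stringsAsFactors = FALSE))
  rhits <- query_index(idx, oracle_revcomp(q))
  expect_identical(rhits$pos, 1000L)
  expect_identical(rhits$strand, "-")
  none <- query_index(idx, strrep("A", 49))
  expect_identical(nrow(none), 0L)
  expect_error(build_index(g, width = 10), class = "sc_config_error")
  # non-indexed widths fall back to a full scan
  q30 <- substr(g$chroms[[1]], 2001, 2030)
  expect_identical(query_index(idx, q30), oracle_hits(q30, g$chroms))
})

test_that("align_unique recovers planted reads, excluding the first base", {
  g <- make_genomes(tiny_config(exp_genome_length = 8000L,
                                n_chroms_exp = 1L))$experimental
  idx <- build_index(g, width = 49)
  read <- substr(g$chroms[[1]], 3001, 3050)  # 0-based 3000..3049
  rec <- align_unique(read, idx, "r1")
  expect_identical(rec$start, 3001L)         # first base excluded
  expect_identical(rec$aligned_length, 49L)
  expect_identical(rec$strand, "+")
  # a mismatch in the first base must not prevent placement
  mut <- paste0(chartr("ACGT", "CAGT", substr(read, 1, 1)), substr(read, 2, 50))
  expect_identical(align_unique(mut, idx, "r2")$start, 3001L)
  # minus-strand read
  mrec <- align_unique(oracle_revcomp(read), idx, "r3")
  expect_identical(mrec$strand, "-")
  expect_identical(mrec$start, 3000L)        # trimming removes rightmost base
  expect_error(align_unique("ACGTXXAA", idx), class = "sc_malformed_read")
})

test_that("multi-aligned reads are discarded", {
  seg <- "ACGTTGCAGGATCCATTGCAAGCTTGGCACTGGCCGTCGTTTTACAACGT"  # 50-mer
  set.seed(3)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  chrom <- paste0(filler(200), seg, filler(200), seg, filler(200))
  g <- genome("experimental", c(chr1 = chrom))
  idx <- build_index(g, width = 49)
  expect_null(align_unique(seg, idx))
  hits <- query_index(idx, substr(seg, 2, 50))
  expect_identical(nrow(hits), 2L)
})

test_that("align_unique matches the naive full scan on random genomes", {
  for (seed in 1:3) {
    cfg <- tiny_config(exp_genome_length = 4000L, n_chroms_exp = 2L,
                       seed = seed)
    g <- make_genomes(cfg)$experimental
    idx <- build_index(g, width = 49)
    set.seed(seed * 100)
    for (i in 1:25) {
      ch <- sample(names(g$chroms), 1)
      p <- sample.int(nchar(g$chroms[[ch]]) - 50, 1)
      read <- substr(g$chroms[[ch]], p, p + 49)
      if (runif(1) < 0.5) read <- oracle_revcomp(read)
      if (runif(1) < 0.2)  # random read, most likely absent
        read <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
      rec <- align_unique(read, idx, "q")
      hits <- oracle_hits(substr(read, 2, 50), g$chroms)
      if (nrow(hits) == 1) {
        expect_identical(rec$chrom, hits$chrom)
        expect_identical(rec$start, hits$pos)
        expect_identical(rec$strand, hits$strand)
      } else {
        expect_null(rec)
      }
    }
  }
})

test_that("sequential assignment is exclusive and spike-first", {
  set.seed(8)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  shared <- filler(50)     # present in BOTH genomes
  sp_rep <- filler(50)     # repeated twice in spike, once in experimental
  spike <- genome("spike",
                  c(chrS1 = paste0(filler(300), shared, filler(100),
                                   sp_rep, filler(100), sp_rep, filler(100))))
  exper <- genome("experimental",
                  c(chrE1 = paste0(filler(300), shared, filler(200),
                                   sp_rep, filler(200))))
  idx_sp <- build_index(spike, width = 49)
  idx_ex <- build_index(exper, width = 49)
  reads <- data.frame(id = c("both", "multi_spike"),
                      seq = c(shared, sp_rep), stringsAsFactors = FALSE)
  res <- assign_exclusive(reads, idx_sp, idx_ex, "t")
  # placeable in both genomes: resolved to spike by the two-pass order
  expect_identical(res$spike$read_id, "both")
  # multi-mapped on spike, unique on experimental: falls through
  expect_identical(res$experimental$read_id, "multi_spike")
  expect_identical(res$stats$n_multi_spike, 1L)
  expect_identical(res$stats$n_cross_mappers, 1L)
  expect_length(intersect(res$spike$read_id, res$experimental$read_id), 0L)
})

test_that("planted read sets produce the expected library counts", {
  cfg <- tiny_config(exp_genome_length = 20000L, spike_genome_length = 8000L,
                     n_chroms_exp = 1L)
  g <- make_genomes(cfg)
  idx_sp <- build_index(g$spike, width = 49)
  idx_ex <- build_index(g$experimental, width = 49)
  set.seed(12)
  take <- function(gen, n) {
    vapply(seq_len(n), function(i) {
      ch <- sample(names(gen$chroms), 1)
      p <- sample.int(nchar(gen$chroms[[ch]]) - 50, 1)
      substr(gen$chroms[[ch]], p, p + 49)
    }, character(1))
  }
  reads <- data.frame(id = sprintf("r%03d", 1:100),
                      seq = c(take(g$spike, 10), take(g$experimental, 90)),
                      stringsAsFactors = FALSE)
  res <- assign_exclusive(reads, idx_sp, idx_ex, "planted")
  expect_identical(res$counts$n_spike, 10)
  expect_identical(res$counts$n_exp, 90)
  expect_length(intersect(res$spike$read_id, res$experimental$read_id), 0L)
})

test_that("SAM ingestion filters flags and converts coordinates", {
  sam <- tempfile(fileext = ".sam")
  seq49 <- strrep("A", 49); q49 <- strrep("I", 49)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrI\tLN:2000",
    paste("r1", 0, "chrI", 100, 42, "49M", "*", 0, 0, seq49, q49, sep = "\t"),
    paste("r2", 16, "chrI", 200, 42, "24M1D25M", "*", 0, 0, seq49, q49,
          sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, seq49, q49, sep = "\t"),
    paste("r4", 256, "chrI", 300, 42, "49M", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r5", 1024, "chrI", 400, 42, "49M", "*", 0, 0, seq49, q49,
          sep = "\t")), sam)
  aln <- read_alignments(sam, "experimental")
  expect_identical(aln$read_id, c("r1", "r2"))
  expect_identical(aln$start, c(99L, 199L))          # 1-based POS -> 0-based
  expect_identical(aln$strand, c("+", "-"))
  expect_identical(aln$aligned_length, c(49L, 50L))  # CIGAR reference width
})

test_that("BED ingestion and the internal BED writer round-trip records", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chrI\t99\t148\tr1\t0\t-", bed)
  aln <- read_alignments(bed, "spike")
  expect_identical(aln$start, 99L)
  expect_identical(aln$strand, "-")
  expect_identical(aln$aligned_length, 49L)
  expect_identical(aln$genome_label, "spike")
  out <- tempfile(fileext = ".bed")
  write_alignments(aln, out)
  back <- read_alignments(out, "spike")
  expect_identical(back[, c("read_id", "chrom", "start", "strand",
                            "aligned_length")],
                   aln[, c("read_id", "chrom", "start", "strand",
                           "aligned_length")])
  expect_error(read_alignments(tempfile(fileext = ".xyz"), "spike"),
               class = "sc_format_error")
})
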