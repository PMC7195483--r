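test_that("genome generation is deterministic, seed-sensitive and validated", {
  cfg <- tiny_config()
  g1 <- make_genomes(cfg)
  g2 <- make_genomes(cfg)
  expect_identical(g1, g2)
  expect_identical(sum(nchar(g1$experimental$chroms)), 30000L)
  expect_identical(names(g1$experimental$chroms), c("chrE1", "chrE2"))
  g3 <- make_genomes(tiny_config(seed = 202L))
  expect_false(identical(g1$experimental$chroms, g3$experimental$chroms))
  # spike and experimental come from distinct streams
  expect_false(identical(substr(g1$experimental$chroms[[1]], 1, 1000),
                         substr(g1$spike$chroms[[1]], 1, 1000)))
  expect_error(sim_config(exp_genome_length = 40, read_length = 50,
                          frag_len_min = 50, frag_len_max = 60),
               class = "sc_config_error")
})

test_that("gene placement respects spacing, margins and determinism", {
  g <- make_genomes(tiny_config(exp_genome_length = 100000L,
                                n_chroms_exp = 1L))$experimental
  gs <- make_geneset(g, 20, 3000, seed = 5)
  expect_identical(nrow(gs), 20L)
  expect_false(anyDuplicated(gs$id) > 0)
  d <- diff(sort(gs$tss))
  expect_true(all(d >= 3000))
  L <- nchar(g$chroms[[1]])
  expect_true(all(ifelse(gs$strand == "+", L - gs$tss, gs$tss + 1) >= 1500))
  expect_identical(gs, make_geneset(g, 20, 3000, seed = 5))
  expect_error(make_geneset(g, 500, 3000, seed = 5),
               class = "sc_placement_error")
})

test_that("enrichment weight follows the exponential-decay model", {
  cfg <- tiny_config(peak_amplitude = 9, background_rate = 1,
                     decay_length = 500, efficiency = 1.0)
  genes <- data.frame(id = "g1", chrom = "chrE1", tss = 5000L, strand = "+",
                      amplitude = 1, stringsAsFactors = FALSE)
  expect_equal(enrichment_weight(5000, "chrE1", genes, cfg), 10.0)
  expect_equal(enrichment_weight(5500, "chrE1", genes, cfg),
               1 + 9 * exp(-1))
  expect_equal(enrichment_weight(5000, "chrE1", genes, cfg, efficiency = 0.2),
               2.8)
  # upstream of the TSS and beyond 3 decay lengths: background only
  expect_equal(enrichment_weight(4999, "chrE1", genes, cfg), 1.0)
  expect_equal(enrichment_weight(5000 + 1501, "chrE1", genes, cfg), 1.0)
  # minus-strand gene decays leftward
  genes_m <- transform(genes, strand = "-")
  expect_equal(enrichment_weight(4500, "chrE1", genes_m, cfg), 1 + 9 * exp(-1))
  expect_equal(enrichment_weight(5001, "chrE1", genes_m, cfg), 1.0)
  # band means strictly decrease with distance-band index
  bands <- sapply(0:2, function(k) {
    pos <- (5000 + k * 500):(5000 + (k + 1) * 500 - 1)
    mean(enrichment_weight(pos, "chrE1", genes, cfg))
  })
  expect_true(all(diff(bands) < 0))
})

test_that("weight vectors agree with the scalar weight function", {
  cfg <- tiny_config(peak_amplitude = 6, decay_length = 300)
  g <- make_genomes(cfg)$experimental
  genes <- make_geneset(g, 4, 3500, seed = 9)
  wv <- spikechip:::weight_vectors(g, genes, cfg, efficiency = 0.7)
  for (ch in names(wv)) {
    pos <- seq(0, length(wv[[ch]]) - 1, by = 173)
    expect_equal(wv[[ch]][pos + 1],
                 enrichment_weight(pos, ch, genes, cfg, efficiency = 0.7))
  }
})

test_that("input samples hit the spike mass fraction within binomial error", {
  cfg <- tiny_config(n_input_reads = 100000L, seed = 31L)
  g <- make_genomes(cfg)
  genes <- make_geneset(g$experimental, 4, 3500, seed = 1)
  sg <- make_geneset(g$spike, 2, 3000, seed = 2)
  s <- simulate_sample(cfg, g, genes, sg, "input", "inp")
  truth <- parse_read_ids(s$reads$id)
  frac <- mean(truth$genome == "spike")
  expect_equal(s$truth$p_spike_expected, 0.10)
  expect_lt(abs(frac - 0.10), 4 * sqrt(0.1 * 0.9 / 100000))
})

test_that("simulated reads reproduce their recorded genomic coordinates", {
  cfg <- tiny_config(seed = 77L)
  g <- make_genomes(cfg)
  genes <- make_geneset(g$experimental, 4, 3500, seed = 1)
  sg <- make_geneset(g$spike, 2, 3000, seed = 2)
  s <- simulate_sample(cfg, g, genes, sg, "IP", "ip1")
  truth <- parse_read_ids(s$reads$id)
  bc <- nchar(cfg$barcode)
  idx <- seq(1, nrow(truth), by = 97)
  for (i in idx) {
    chrom_seq <- g[[truth$genome[i]]]$chroms[[truth$chrom[i]]]
    ref <- substr(chrom_seq, truth$left[i] + 1, truth$left[i] + 50)
    obs <- substr(s$reads$seq[i], bc + 1, bc + 50)
    expect_identical(obs, if (truth$strand[i] == "+") ref
                          else oracle_revcomp(ref))
  }
  # minus-strand reads are the reverse complement of the fragment's last
  # read_length bases, so they must match the reference at their 5' end
  expect_true(all(truth$strand %in% c("+", "-")))
})

test_that("mutant efficiency lowers experimental yield as the weight integrals predict", {
  cfg1 <- tiny_config(n_ip_reads = 60000L, peak_amplitude = 8, seed = 55L)
  cfg2 <- tiny_config(n_ip_reads = 60000L, peak_amplitude = 8, seed = 55L,
                      efficiency = 0.3)
  g <- make_genomes(cfg1)
  genes <- make_geneset(g$experimental, 4, 3500, seed = 1)
  sg <- make_geneset(g$spike, 2, 3000, seed = 2)
  s1 <- simulate_sample(cfg1, g, genes, sg, "IP", "a")
  s2 <- simulate_sample(cfg2, g, genes, sg, "IP", "a")
  emp <- c(mean(parse_read_ids(s1$reads$id)$genome == "experimental"),
           mean(parse_read_ids(s2$reads$id)$genome == "experimental"))
  pred <- sapply(c(1.0, 0.3), function(eff) {
    we <- mean(unlist(spikechip:::weight_vectors(g$experimental, genes,
                                                 cfg1, eff)))
    ws <- mean(unlist(spikechip:::weight_vectors(g$spike, sg, cfg1, 1.0)))
    0.9 * we / (0.9 * we + 0.1 * ws)
  })
  expect_lt(sum(parse_read_ids(s2$reads$id)$genome == "experimental"),
            sum(parse_read_ids(s1$reads$id)$genome == "experimental"))
  expect_lt(max(abs(emp - pred)), 4 * sqrt(0.1 * 0.9 / 60000))
})

test_that("degenerate all-zero profiles are rejected", {
  cfg <- tiny_config(background_rate = 0)
  g <- make_genomes(cfg)
  empty_genes <- data.frame(id = character(0), chrom = character(0),
                            tss = integer(0), strand = character(0),
                            amplitude = numeric(0), stringsAsFactors = FALSE)
  expect_error(simulate_sample(cfg, g, empty_genes, empty_genes, "IP", "x"),
               class = "sc_degenerate_profile")
})

test_that("experiments are reproducible byte for byte and validated", {
  cfg <- tiny_config(n_ip_reads = 1500L, n_input_reads = 1500L)
  samples <- data.frame(name = c("ip1", "inp"),
                        barcode = c("ACGTAC", "TGCATG"),
                        kind = c("IP", "input"),
                        efficiency = c(1, 1), stringsAsFactors = FALSE)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  sim1 <- simulate_experiment(cfg, samples, d1)
  sim2 <- simulate_experiment(cfg, samples, d2)
  expect_identical(readLines(sim1$paths$fastq), readLines(sim2$paths$fastq))
  expect_identical(unname(tools::md5sum(sim1$paths$exp_genome)),
                   unname(tools::md5sum(sim2$paths$exp_genome)))
  expect_length(sim1$truth$samples, 2L)
  dup <- samples; dup$barcode <- c("ACGTAC", "ACGTAC")
  expect_error(simulate_experiment(cfg, dup, tempfile()),
               class = "sc_config_error")
})

test_that("truth records round-trip losslessly through JSON", {
  cfg <- tiny_config(n_ip_reads = 500L, n_input_reads = 500L)
  samples <- data.frame(name = c("ip1", "inp"),
                        barcode = c("ACGTAC", "TGCATG"),
                        kind = c("IP", "input"), stringsAsFactors = FALSE)
  sim <- simulate_experiment(cfg, samples, tempfile())
  rt <- read_truth(sim$paths$truth)
  expect_equal(rt$spike_mass_fraction, sim$truth$spike_mass_fraction)
  expect_equal(rt$genes$tss, sim$truth$genes$tss)
  expect_equal(rt$genes$amplitude, sim$truth$genes$amplitude)
  expect_equal(rt$config$n_ip_reads, 500L)
  expect_equal(rt$samples[[1]]$stream_seed, sim$truth$samples[[1]]$stream_seed)
})
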