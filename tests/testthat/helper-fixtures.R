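# Shared fixtures and independent oracles. The oracles are deliberately
# written as plain loops / direct formula evaluation so they stay
# independent of the vectorised implementation paths they check.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(exp_genome_length = 30000L, spike_genome_length = 10000L,
         n_chroms_exp = 2L, n_chroms_spike = 1L, n_genes = 4L,
         min_gene_spacing = 3500L, n_ip_reads = 4000L, n_input_reads = 4000L,
         seed = 101L),
    list(...))
  do.call(sim_config, args)
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force exact search of `q` over every position and strand.
oracle_hits <- function(q, chroms) {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
  w <- nchar(q)
  rq <- oracle_revcomp(q)
  for (ch in names(chroms)) {
    s <- chroms[[ch]]
    L <- nchar(s)
    if (L < w) next
    for (p in 0:(L - w)) {
      seg <- substr(s, p + 1, p + w)
      if (seg == q)
        out <- rbind(out, data.frame(chrom = ch, pos = p, strand = "+",
                                     stringsAsFactors = FALSE))
      if (seg == rq)
        out <- rbind(out, data.frame(chrom = ch, pos = p, strand = "-",
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

# Per-base loop pileup oracle: extend each read `ext` bases from its 5' end
# in the read direction, truncated at [0, L).
oracle_pileup <- function(aln, chrom_lengths, ext = 150L) {
  vals <- lapply(chrom_lengths, numeric)
  for (i in seq_len(nrow(aln))) {
    ch <- aln$chrom[i]
    L <- chrom_lengths[[ch]]
    if (aln$strand[i] == "+") {
      fp <- aln$start[i]
      rng <- fp:(fp + ext - 1L)
    } else {
      fp <- aln$start[i] + aln$aligned_length[i] - 1L
      rng <- (fp - ext + 1L):fp
    }
    for (p in rng) if (p >= 0 && p < L)
      vals[[ch]][p + 1L] <- vals[[ch]][p + 1L] + 1
  }
  vals
}

random_alignments <- function(n, chrom_lengths, seed,
                              aligned_length = 49L) {
  set.seed(seed)
  chs <- sample(names(chrom_lengths), n, replace = TRUE)
  data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    genome_label = "experimental",
    chrom = chs,
    start = vapply(chs, function(ch)
      sample.int(chrom_lengths[[ch]] - aligned_length, 1) - 1L, integer(1)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    aligned_length = aligned_length,
    stringsAsFactors = FALSE)
}

constant_track <- function(value, lens = c(chrA = 200L),
                           provenance = "raw", reads_used = 10L) {
  tr <- coverage_track("experimental",
                       lapply(lens, function(L) rep(value, L)),
                       "raw", reads_used = reads_used)
  tr$provenance <- provenance
  tr
}

parse_read_ids <- function(ids) {
  p <- strsplit(ids, ":", fixed = TRUE)
  data.frame(sample = vapply(p, `[`, "", 1),
             genome = vapply(p, `[`, "", 3),
             chrom = vapply(p, `[`, "", 4),
             left = as.integer(vapply(p, `[`, "", 5)),
             strand = vapply(p, `[`, "", 6),
             stringsAsFactors = FALSE)
}
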