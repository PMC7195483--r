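#' Simulation configuration
#'
#' Parameters of the synthetic dual-genome ChIP-seq experiment. Defaults
#' encode the experimental design being emulated: 10% spike-in chromatin by
#' mass, 200-500 bp library fragments, 50 bp single-end reads, and a
#' promoter-proximal enrichment profile decaying exponentially downstream of
#' each TSS. Genome and gene-set sizes are desk-scale stand-ins for a
#' compact yeast-like genome; the enrichment amplitude (5-fold over
#' background at the TSS, jittered per gene) and 500 bp decay length give a
#' signal geometry in which roughly 11% of input chromatin weight sits in
#' gene windows, comparable to a promoter-restricted histone mark.
#'
#' @param exp_genome_length,spike_genome_length Total genome sizes in bases.
#' @param n_chroms_exp,n_chroms_spike Chromosome counts.
#' @param n_genes Number of genes placed on the experimental genome.
#' @param min_gene_spacing Minimum TSS-to-TSS distance on a chromosome (bp).
#' @param peak_amplitude Fold-enrichment over background at the TSS
#'   (dimensionless; multiplied by a per-gene amplitude factor).
#' @param decay_length Exponential decay constant of enrichment downstream
#'   of the TSS (bp).
#' @param background_rate Uniform background weight (dimensionless).
#' @param efficiency Global ChIP efficiency multiplier in (0, 1]; 1.0 for
#'   wild type, lower values model a genotype with globally reduced signal.
#' @param spike_mass_fraction Mass fraction of spike-in chromatin in (0, 1);
#'   default 0.10.
#' @param frag_len_min,frag_len_max Library fragment length range (bp);
#'   defaults 200 and 500.
#' @param read_length Read length (bp); default 50.
#' @param n_ip_reads,n_input_reads Reads simulated per IP / input sample.
#' @param barcode In-line sample barcode over A/C/G/T.
#' @param seed Master RNG seed; per-sample streams are derived from it.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(exp_genome_length = 4800000L,
                       spike_genome_length = 960000L,
                       n_chroms_exp = 6L,
                       n_chroms_spike = 1L,
                       n_genes = 240L,
                       min_gene_spacing = 4000L,
                       peak_amplitude = 5,
                       decay_length = 500,
                       background_rate = 1,
                       efficiency = 1.0,
                       spike_mass_fraction = 0.10,
                       frag_len_min = 200L,
                       frag_len_max = 500L,
                       read_length = 50L,
                       n_ip_reads = 400000L,
                       n_input_reads = 400000L,
                       barcode = "ACGTAC",
                       seed = 1L) {
  cfg <- list(exp_genome_length = as.integer(exp_genome_length),
              spike_genome_length = as.integer(spike_genome_length),
              n_chroms_exp = as.integer(n_chroms_exp),
              n_chroms_spike = as.integer(n_chroms_spike),
              n_genes = as.integer(n_genes),
              min_gene_spacing = as.integer(min_gene_spacing),
              peak_amplitude = peak_amplitude,
              decay_length = decay_length,
              background_rate = background_rate,
              efficiency = efficiency,
              spike_mass_fraction = spike_mass_fraction,
              frag_len_min = as.integer(frag_len_min),
              frag_len_max = as.integer(frag_len_max),
              read_length = as.integer(read_length),
              n_ip_reads = as.integer(n_ip_reads),
              n_input_reads = as.integer(n_input_reads),
              barcode = barcode,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  pos <- c("exp_genome_length", "spike_genome_length", "n_chroms_exp",
           "n_chroms_spike", "n_genes", "min_gene_spacing", "decay_length",
           "frag_len_min", "frag_len_max", "read_length", "n_ip_reads",
           "n_input_reads")
  for (f in pos)
    sc_check(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] > 0,
             "sc_config_error", paste0(f, " must be a positive scalar"))
  sc_check(cfg$frag_len_min <= cfg$frag_len_max, "sc_config_error",
           "frag_len_min must not exceed frag_len_max")
  sc_check(cfg$read_length <= cfg$frag_len_min, "sc_config_error",
           "read_length must not exceed frag_len_min")
  sc_check(cfg$spike_mass_fraction > 0 && cfg$spike_mass_fraction < 1,
           "sc_config_error", "spike_mass_fraction must be in (0, 1)")
  sc_check(cfg$efficiency > 0 && cfg$efficiency <= 1, "sc_config_error",
           "efficiency must be in (0, 1]")
  sc_check(cfg$background_rate >= 0 && cfg$peak_amplitude >= 0,
           "sc_config_error", "rates and amplitudes must be nonnegative")
  sc_check(cfg$exp_genome_length >= cfg$read_length &&
           cfg$spike_genome_length >= cfg$read_length,
           "sc_config_error", "genome shorter than read_length")
  sc_check(grepl("^[ACGT]+$", cfg$barcode), "sc_config_error",
           "barcode must be a non-empty A/C/G/T string")
  invisible(cfg)
}
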