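#' Generate the two reference genomes
#'
#' Draws uniform-random A/C/G/T sequences for the experimental and spike-in
#' genomes from two distinct named RNG streams derived from the master seed,
#' so shared k-mers of near read length arise only by chance and adding one
#' genome never perturbs the other.
#'
#' @param config A [sim_config()].
#' @return List with elements `experimental` and `spike`, both `Genome`s.
#' @export
make_genomes <- function(config) {
  validate_sim_config(config)
  sc_check(config$exp_genome_length >= config$read_length &&
           config$spike_genome_length >= config$read_length,
           "sc_config_error", "genome shorter than read_length")
  gen_one <- function(total, n_chroms, label, prefix) {
    base <- total %/% n_chroms
    lens <- rep(base, n_chroms)
    lens[n_chroms] <- lens[n_chroms] + total - sum(lens)
    sc_check(all(lens >= config$read_length), "sc_config_error",
             "chromosome shorter than read_length")
    chroms <- with_seed(derive_seed(config$seed, "genome", label), {
      vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1))
    })
    names(chroms) <- paste0(prefix, seq_len(n_chroms))
    genome(label, chroms)
  }
  list(experimental = gen_one(config$exp_genome_length, config$n_chroms_exp,
                              "experimental", "chrE"),
       spike = gen_one(config$spike_genome_length, config$n_chroms_spike,
                       "spike", "chrS"))
}

#' Place a gene set on a genome
#'
#' TSSs are placed uniformly at random subject to a minimum same-chromosome
#' spacing and at least `margin` bases of room between the TSS and the
#' chromosome end in the gene's direction (so TSS-anchored windows always
#' fit). Each gene receives a random strand and a per-gene amplitude factor
#' (uniform on `amp_jitter`) multiplying the configured peak amplitude, so
#' simulated genes differ in enrichment strength as real genes do.
#'
#' @param genome A `Genome`.
#' @param n_genes Number of genes.
#' @param min_gene_spacing Minimum TSS-to-TSS distance on a chromosome (bp).
#' @param seed RNG seed for this placement.
#' @param margin Downstream room required in the gene direction (bp).
#' @param amp_jitter Range of the per-gene amplitude factor.
#' @return Data.frame with `id`, `chrom`, `tss` (0-based), `strand`,
#'   `amplitude`.
#' @export
make_geneset <- function(genome, n_genes, min_gene_spacing, seed,
                         margin = 1500L, amp_jitter = c(0.25, 1.75)) {
  lens <- chrom_lengths(genome)
  sc_check(n_genes >= 1, "sc_config_error", "n_genes must be >= 1")
  sc_check(any(lens > 2 * margin), "sc_placement_error",
           "no chromosome long enough for the TSS window margin")
  with_seed(seed, {
    placed <- data.frame(chrom = character(0), tss = integer(0),
                         strand = character(0), stringsAsFactors = FALSE)
    tries <- 0L
    max_tries <- 1000L * n_genes
    while (nrow(placed) < n_genes) {
      tries <- tries + 1L
      if (tries > max_tries)
        sc_error("sc_placement_error", sprintf(
          "could not place %d genes with spacing %d after %d attempts",
          n_genes, min_gene_spacing, max_tries))
      chrom <- sample(names(lens), 1, prob = as.numeric(lens))
      L <- lens[[chrom]]
      if (L <= 2 * margin) next
      strand <- sample(c("+", "-"), 1)
      tss <- if (strand == "+") sample.int(L - margin, 1) - 1L
             else sample.int(L - margin, 1) - 1L + margin
      same <- placed$tss[placed$chrom == chrom]
      if (length(same) && min(abs(same - tss)) < min_gene_spacing) next
      placed <- rbind(placed, data.frame(chrom = chrom, tss = tss,
                                         strand = strand,
                                         stringsAsFactors = FALSE))
    }
    placed <- placed[order(placed$chrom, placed$tss), , drop = FALSE]
    placed$id <- sprintf("gene%03d", seq_len(nrow(placed)))
    placed$amplitude <- stats::runif(nrow(placed), amp_jitter[1], amp_jitter[2])
    rownames(placed) <- NULL
    placed[, c("id", "chrom", "tss", "strand", "amplitude")]
  })
}

#' Ground-truth enrichment weight at a position
#'
#' The simulator's per-base fragment weight: `background_rate` everywhere,
#' plus `efficiency * peak_amplitude * amplitude_g * exp(-d / decay_length)`
#' when the position lies within `3 * decay_length` downstream (in the gene
#' direction) of a TSS, where `d >= 0` is the strand-oriented distance to
#' the nearest such TSS.
#'
#' @param position 0-based position(s) on `chrom`.
#' @param chrom Chromosome name.
#' @param genes Gene set as from [make_geneset()]; an `amplitude` column is
#'   optional (defaults to 1).
#' @param config A [sim_config()].
#' @param efficiency Global efficiency multiplier; defaults to the config's.
#' @return Numeric weight(s), same length as `position`.
#' @export
enrichment_weight <- function(position, chrom, genes, config,
                              efficiency = config$efficiency) {
  lam <- config$decay_length
  sig <- numeric(length(position))
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  amp_g <- if ("amplitude" %in% names(g)) g$amplitude else rep(1, nrow(g))
  for (i in seq_len(nrow(g))) {
    d <- if (g$strand[i] == "+") position - g$tss[i] else g$tss[i] - position
    ok <- d >= 0 & d <= 3 * lam
    term <- ifelse(ok, efficiency * config$peak_amplitude * amp_g[i] *
                       exp(-d / lam), 0)
    sig <- pmax(sig, term)
  }
  config$background_rate + sig
}

# Per-chromosome weight vectors for a whole genome (0-based position i is
# element i+1). Vectorized version of enrichment_weight.
weight_vectors <- function(genome, genes, config, efficiency) {
  lam <- config$decay_length
  span <- floor(3 * lam)
  lens <- chrom_lengths(genome)
  out <- lapply(names(lens), function(ch) {
    w <- numeric(lens[[ch]])
    g <- genes[genes$chrom == ch, , drop = FALSE]
    amp_g <- if ("amplitude" %in% names(g)) g$amplitude else rep(1, nrow(g))
    for (i in seq_len(nrow(g))) {
      d <- 0:span
      pos <- if (g$strand[i] == "+") g$tss[i] + d else g$tss[i] - d
      keep <- pos >= 0 & pos < lens[[ch]]
      idx <- pos[keep] + 1L
      term <- efficiency * config$peak_amplitude * amp_g[i] * exp(-d[keep] / lam)
      w[idx] <- pmax(w[idx], term)
    }
    w + config$background_rate
  })
  names(out) <- names(lens)
  out
}

# Draw m fragment midpoints proportional to per-base weights via inverse CDF
# over the precomputed cumulative weight vector of the concatenated genome.
draw_midpoints <- function(wv, m) {
  lens <- lengths(wv)
  cw <- cumsum(unlist(wv, use.names = FALSE))
  total <- cw[length(cw)]
  if (!isTRUE(total > 0)) sc_error("sc_degenerate_profile",
    "enrichment profile has zero total weight")
  u <- stats::runif(m) * total
  idx <- findInterval(u, cw) + 1L
  bounds <- cumsum(lens)
  ci <- findInterval(idx - 1L, bounds) + 1L
  offset <- c(0L, bounds)[ci]
  data.frame(chrom = names(wv)[ci], pos = idx - offset - 1L,
             stringsAsFactors = FALSE)
}

#' Simulate one sequencing sample
#'
#' Fragments are assigned to the spike or experimental genome with
#' probability proportional to chromatin mass times mean pull-down weight;
#' for input samples both weight fields are uniform, so the expected spike
#' read fraction equals `spike_mass_fraction` exactly. For IP samples,
#' experimental fragment midpoints follow the enrichment weight at the
#' sample's efficiency while spike fragments follow a fixed spike profile at
#' efficiency 1 (the spike chromatin is identical in every tube, which is
#' the premise of spike-in calibration). Fragment lengths are uniform on
#' `[frag_len_min, frag_len_max]`; each read is the first `read_length`
#' bases from the 5' end of a uniformly chosen strand of the fragment
#' (reverse-complemented on the minus strand), with the sample barcode
#' prepended in-line and a constant quality string.
#'
#' @param config A [sim_config()] (its `efficiency` and `barcode` apply to
#'   this sample).
#' @param genomes List with `experimental` and `spike` `Genome`s.
#' @param gene_set Genes on the experimental genome.
#' @param spike_gene_set Pseudo-genes defining the fixed spike profile.
#' @param sample_kind `"IP"` or `"input"`.
#' @param sample_name Sample name; with the master seed it determines this
#'   sample's private RNG stream.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`; read ids embed
#'   the true genome, chromosome, 0-based read start and strand) and `truth`.
#' @export
simulate_sample <- function(config, genomes, gene_set, spike_gene_set,
                            sample_kind = c("IP", "input"),
                            sample_name = "sample") {
  sample_kind <- match.arg(sample_kind)
  validate_sim_config(config)
  n <- if (sample_kind == "IP") config$n_ip_reads else config$n_input_reads
  f <- config$spike_mass_fraction
  rl <- config$read_length

  if (sample_kind == "IP") {
    wv_exp <- weight_vectors(genomes$experimental, gene_set, config,
                             config$efficiency)
    wv_sp <- weight_vectors(genomes$spike, spike_gene_set, config,
                            efficiency = 1.0)
  } else {
    wv_exp <- lapply(chrom_lengths(genomes$experimental), numeric)
    wv_exp <- lapply(wv_exp, function(v) v + 1)
    wv_sp <- lapply(chrom_lengths(genomes$spike), numeric)
    wv_sp <- lapply(wv_sp, function(v) v + 1)
  }
  mean_exp <- mean(unlist(wv_exp, use.names = FALSE))
  mean_sp <- mean(unlist(wv_sp, use.names = FALSE))
  if (!isTRUE(mean_exp > 0) || !isTRUE(mean_sp > 0))
    sc_error("sc_degenerate_profile", "enrichment profile has zero total weight")
  p_spike <- f * mean_sp / (f * mean_sp + (1 - f) * mean_exp)

  stream <- derive_seed(config$seed, sample_name)
  reads <- with_seed(stream, {
    is_spike <- stats::runif(n) < p_spike
    frag_len <- config$frag_len_min +
      floor(stats::runif(n) * (config$frag_len_max - config$frag_len_min + 1L))
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    chrom <- character(n); fstart <- integer(n)
    for (lab in c("spike", "experimental")) {
      sel <- if (lab == "spike") is_spike else !is_spike
      m <- sum(sel)
      if (m == 0) next
      wv <- if (lab == "spike") wv_sp else wv_exp
      mid <- draw_midpoints(wv, m)
      L <- chrom_lengths(genomes[[lab]])[mid$chrom]
      s <- mid$pos - frag_len[sel] %/% 2L
      s <- pmax(0L, pmin(s, as.integer(L) - frag_len[sel]))
      chrom[sel] <- mid$chrom
      fstart[sel] <- s
    }
    # read placement: 5' end of a uniformly chosen fragment strand
    left <- ifelse(strand == "+", fstart, fstart + frag_len - rl)
    glabel <- ifelse(is_spike, "spike", "experimental")
    seqs <- character(n)
    for (lab in c("spike", "experimental")) {
      chs <- genomes[[lab]]$chroms
      for (ch in names(chs)) {
        sel <- which(glabel == lab & chrom == ch)
        if (!length(sel)) next
        seqs[sel] <- substring(chs[[ch]], left[sel] + 1L, left[sel] + rl)
      }
    }
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    id <- sprintf("%s:%06d:%s:%s:%d:%s", sample_name, seq_len(n), glabel,
                  chrom, left, strand)
    full <- paste0(config$barcode, seqs)
    data.frame(id = id, seq = full,
               qual = strrep("I", nchar(config$barcode) + rl),
               stringsAsFactors = FALSE)
  })

  truth <- list(sample = sample_name, kind = sample_kind,
                efficiency = if (sample_kind == "IP") config$efficiency else NA,
                barcode = config$barcode, n_reads = n,
                stream_seed = stream, p_spike_expected = p_spike,
                spike_mass_fraction = f)
  list(reads = reads, truth = truth)
}

#' Simulate a full multiplexed experiment
#'
#' Builds the two genomes and the gene sets once, simulates every sample
#' from its own named RNG stream, interleaves all reads into one multiplexed
#' FASTQ, and writes FASTA genomes, a BED6 gene annotation, a barcode table
#' and a JSON truth record holding every parameter and seed.
#'
#' @param config A [sim_config()]; per-sample `efficiency` and `barcode`
#'   come from `samples`.
#' @param samples Data.frame with columns `name`, `barcode`,
#'   `kind` (`"IP"`/`"input"`) and optionally `efficiency` (default 1).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths`, `truth`, `genomes`, `genes`,
#'   `spike_genes`.
#' @export
simulate_experiment <- function(config, samples, dir) {
  validate_sim_config(config)
  sc_check(nrow(samples) >= 1, "sc_config_error", "no samples given")
  sc_check(!anyDuplicated(samples$name), "sc_config_error",
           "duplicate sample names")
  sc_check(!anyDuplicated(samples$barcode), "sc_config_error",
           "duplicate barcodes")
  sc_check(length(unique(nchar(samples$barcode))) == 1, "sc_config_error",
           "barcodes must all have the same length")
  sc_check(all(samples$kind %in% c("IP", "input")), "sc_config_error",
           "sample kind must be IP or input")
  if (is.null(samples$efficiency)) samples$efficiency <- 1.0

  genomes <- make_genomes(config)
  genes <- make_geneset(genomes$experimental, config$n_genes,
                        config$min_gene_spacing,
                        derive_seed(config$seed, "genes", "experimental"))
  n_sp <- max(2L, round(config$n_genes * config$spike_genome_length /
                        config$exp_genome_length))
  spike_genes <- make_geneset(genomes$spike, n_sp, config$min_gene_spacing,
                              derive_seed(config$seed, "genes", "spike"))

  sims <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    cfg_i <- config
    cfg_i$efficiency <- samples$efficiency[i]
    cfg_i$barcode <- samples$barcode[i]
    sims[[i]] <- simulate_sample(cfg_i, genomes, genes, spike_genes,
                                 sample_kind = samples$kind[i],
                                 sample_name = samples$name[i])
  }
  # round-robin interleave across samples by read index
  all_reads <- do.call(rbind, lapply(sims, `[[`, "reads"))
  read_i <- unlist(lapply(sims, function(s) seq_len(nrow(s$reads))))
  samp_i <- rep(seq_along(sims), vapply(sims, function(s) nrow(s$reads),
                                        integer(1)))
  all_reads <- all_reads[order(read_i, samp_i), , drop = FALSE]

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(exp_genome = file.path(dir, "exp_genome.fa"),
                spike_genome = file.path(dir, "spike_genome.fa"),
                genes = file.path(dir, "genes.bed"),
                fastq = file.path(dir, "multiplexed.fastq"),
                barcodes = file.path(dir, "barcodes.tsv"),
                truth = file.path(dir, "truth.json"))
  write_genome(genomes$experimental, paths$exp_genome)
  write_genome(genomes$spike, paths$spike_genome)
  write_genes(genes, paths$genes)
  write_fastq(all_reads, paths$fastq)
  utils::write.table(samples[, c("name", "barcode")], paths$barcodes,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  truth <- list(spike_mass_fraction = config$spike_mass_fraction,
                seed = config$seed,
                config = unclass(config),
                samples = lapply(sims, `[[`, "truth"),
                genes = genes, spike_genes = spike_genes)
  write_truth(truth, paths$truth)
  invisible(list(paths = paths, truth = truth, genomes = genomes,
                 genes = genes, spike_genes = spike_genes))
}

#' Write / read a simulation truth record
#'
#' The truth record round-trips losslessly through JSON (full numeric
#' precision).
#'
#' @param truth Truth list as produced by [simulate_experiment()].
#' @param path JSON file.
#' @return `read_truth` returns the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  x$genes <- as.data.frame(x$genes, stringsAsFactors = FALSE)
  x$spike_genes <- as.data.frame(x$spike_genes, stringsAsFactors = FALSE)
  x
}
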