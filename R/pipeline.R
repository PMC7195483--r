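#' Validate a pipeline run configuration
#'
#' Accepts a YAML path or an equivalent nested list, merges parameter
#' defaults (1 barcode mismatch, 150 bp tag extension, 1500 bp TSS window,
#' 25 bp bins), checks every structural invariant, and reports all
#' violations together with their field paths.
#'
#' @param config YAML file path or a nested list with blocks `run`,
#'   `parameters`, `samples`, and exactly one of `simulate` or `input`.
#' @return The validated config (class `RunConfig`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    sc_check(file.exists(config), "sc_format_error",
             paste0("config file not found: ", config))
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) sc_error("sc_format_error",
                         paste0("cannot parse YAML config: ",
                                conditionMessage(e))))
  }
  bad <- character(0)
  note <- function(path, msg) bad <<- c(bad, sprintf("%s: %s", path, msg))

  defaults <- list(mismatch = 1L, extension = 150L, window = 1500L,
                   bin_size = 25L)
  p <- utils::modifyList(defaults, config$parameters %||% list())
  config$parameters <- p
  if (p$mismatch < 0) note("parameters.mismatch", "must be >= 0")
  if (p$extension <= 0) note("parameters.extension", "must be > 0")
  if (p$window <= 0 || p$bin_size <= 0 || p$window %% p$bin_size != 0)
    note("parameters.bin_size", "window must be a positive multiple of bin_size")

  if (is.null(config$run$output_dir)) note("run.output_dir", "is required")
  if (is.null(config$run$seed)) config$run$seed <- 1L

  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    note("simulate/input", "exactly one of the two blocks is required")
  if (has_input) {
    for (f in c("fastq", "exp_genome", "spike_genome", "genes"))
      if (is.null(config$input[[f]]))
        note(paste0("input.", f), "is required")
  }

  smp <- config$samples
  if (is.null(smp) || length(smp) == 0) {
    note("samples", "at least one sample is required")
  } else {
    df <- do.call(rbind, lapply(seq_along(smp), function(i) {
      s <- smp[[i]]
      data.frame(name = s$name %||% NA_character_,
                 barcode = s$barcode %||% NA_character_,
                 kind = s$kind %||% NA_character_,
                 condition = s$condition %||% s$name %||% NA_character_,
                 replicate = as.integer(s$replicate %||% 1L),
                 efficiency = as.numeric(s$efficiency %||% 1.0),
                 input_sample = s$input_sample %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
    if (anyNA(df$name) || anyDuplicated(df$name))
      note("samples.name", "must be present and unique")
    if (anyNA(df$barcode)) note("samples.barcode", "is required")
    else {
      if (anyDuplicated(df$barcode)) note("samples.barcode", "must be unique")
      if (length(unique(nchar(df$barcode))) != 1)
        note("samples.barcode", "must all have the same length")
    }
    if (!all(df$kind %in% c("IP", "input")))
      note("samples.kind", "must be 'IP' or 'input'")
    inputs <- df$name[df$kind == "input"]
    for (i in which(df$kind == "IP")) {
      if (is.na(df$input_sample[i]))
        note(sprintf("samples[%s].input_sample", df$name[i]), "is required")
      else if (!df$input_sample[i] %in% inputs)
        note(sprintf("samples[%s].input_sample", df$name[i]),
             sprintf("references '%s', which is not an input sample",
                     df$input_sample[i]))
    }
    config$sample_table <- df
  }
  if (length(bad))
    sc_error("sc_config_error",
             paste0("invalid run configuration:\n  ",
                    paste(bad, collapse = "\n  ")))
  class(config) <- "RunConfig"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_guard <- function(stage, sample, outdir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(outdir, sprintf("%s%s.failed", stage,
                        if (nzchar(sample)) paste0(".", sample) else ""))
    try(writeLines(conditionMessage(e), marker), silent = TRUE)
    sc_error("sc_stage_error",
             sprintf("stage '%s'%s failed: %s", stage,
                     if (nzchar(sample)) paste0(" (sample ", sample, ")")
                     else "", conditionMessage(e)))
  })
}

#' Run the full spike-in calibrated pipeline
#'
#' Orchestrates simulate (or ingest) -> demultiplex -> sequential exclusive
#' assignment -> normalization factors -> duplicate-filtered extension
#' pileups (raw, SPMR, spike-calibrated) -> TSS-anchored matrices, heatmap
#' orderings, anchor profiles and condition-difference matrices, writing
#' every artifact plus a JSON manifest with md5 checksums and the resolved
#' parameter set. A failing stage leaves a `.failed` marker named after the
#' stage and sample.
#'
#' @param config A `RunConfig` (or YAML path / list; validated first).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  out <- config$run$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  par <- config$parameters
  smp <- config$sample_table
  artifacts <- character(0)
  add_artifact <- function(p) artifacts <<- c(artifacts, p)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage_guard("simulate", "", out, {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$run$seed
      cfg <- do.call(sim_config, sim_args)
      simulate_experiment(cfg, smp[, c("name", "barcode", "kind",
                                       "efficiency")],
                          file.path(out, "sim"))
    })
    fastq <- sim$paths$fastq
    genomes <- sim$genomes
    genes <- sim$genes
    for (p in unlist(sim$paths)) add_artifact(p)
  } else {
    genomes <- stage_guard("ingest", "", out, list(
      experimental = read_genome(config$input$exp_genome, "experimental"),
      spike = read_genome(config$input$spike_genome, "spike")))
    genes <- stage_guard("ingest", "", out, read_genes(config$input$genes))
    fastq <- config$input$fastq
  }

  # --- demultiplex --------------------------------------------------------
  dm <- stage_guard("demux", "", out, {
    reads <- read_fastq(fastq)
    spec <- barcode_spec(stats::setNames(smp$barcode, smp$name))
    demultiplex(reads, spec, max_mismatch = par$mismatch)
  })
  demux_tsv <- file.path(out, "demux_counts.tsv")
  utils::write.table(dm$counts, demux_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_artifact(demux_tsv)

  # --- exclusive assignment ----------------------------------------------
  read_len <- nchar(dm$samples[[1]]$seq[1])
  idx_spike <- stage_guard("index", "spike", out,
                           build_index(genomes$spike, width = read_len - 1L))
  idx_exp <- stage_guard("index", "experimental", out,
                         build_index(genomes$experimental,
                                     width = read_len - 1L))
  aln_dir <- file.path(out, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  assignments <- list()
  for (nm in smp$name) {
    assignments[[nm]] <- stage_guard("assign", nm, out, {
      a <- assign_exclusive(dm$samples[[nm]], idx_spike, idx_exp, sample = nm)
      for (g in c("experimental", "spike")) {
        bed <- file.path(aln_dir, sprintf("%s.%s.bed", nm, g))
        write_alignments(a[[g]], bed)
        add_artifact(bed)
      }
      a
    })
  }
  rm(idx_spike, idx_exp, dm)   # indexes dominate memory; free before pileup
  gc(FALSE)
  counts_df <- do.call(rbind, lapply(smp$name, function(nm) {
    a <- assignments[[nm]]
    data.frame(sample = nm, n_spike = a$counts$n_spike,
               n_exp = a$counts$n_exp, n_dropped = a$stats$n_dropped,
               n_cross_mappers = a$stats$n_cross_mappers,
               stringsAsFactors = FALSE)
  }))
  counts_tsv <- file.path(out, "assignment_counts.tsv")
  utils::write.table(counts_df, counts_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_artifact(counts_tsv)

  # --- normalization factors ---------------------------------------------
  ip_names <- smp$name[smp$kind == "IP"]
  factors <- stage_guard("normalize", "", out, {
    fs <- lapply(ip_names, function(nm) {
      inp <- smp$input_sample[smp$name == nm]
      norm_factor(assignments[[inp]]$counts, assignments[[nm]]$counts)
    })
    names(fs) <- ip_names
    fs
  })
  factor_tsv <- file.path(out, "norm_factors.tsv")
  write_factor_report(factors,
                      lapply(ip_names, function(nm)
                        assignments[[smp$input_sample[smp$name == nm]]]$counts),
                      lapply(ip_names, function(nm) assignments[[nm]]$counts),
                      factor_tsv)
  add_artifact(factor_tsv)

  # --- pileup tracks ------------------------------------------------------
  trk_dir <- file.path(out, "tracks")
  dir.create(trk_dir, showWarnings = FALSE)
  exp_lens <- chrom_lengths(genomes$experimental)
  spike_lens <- chrom_lengths(genomes$spike)
  tracks <- list()
  for (nm in smp$name) {
    tracks[[nm]] <- stage_guard("pileup", nm, out, {
      ded <- deduplicate(assignments[[nm]]$experimental)
      raw <- extend_and_pileup(ded, exp_lens, extension = par$extension,
                               genome_label = "experimental")
      spmr <- spmr_scale(raw)
      res <- list(raw = raw, spmr = spmr)
      if (nm %in% ip_names)
        res$calibrated <- apply_factor(spmr, factors[[nm]])
      # spike-genome pileup kept as a QC artifact only
      sded <- deduplicate(assignments[[nm]]$spike)
      sraw <- extend_and_pileup(sded, spike_lens, extension = par$extension,
                                genome_label = "spike")
      for (kind in names(res)) {
        f <- file.path(trk_dir, sprintf("%s.%s.bedgraph", nm, kind))
        write_track(res[[kind]], f)
        add_artifact(f)
      }
      qc <- file.path(trk_dir, sprintf("%s.spike_raw.bedgraph", nm))
      write_track(sraw, qc)
      add_artifact(qc)
      # raw/SPMR tracks live on disk; only calibrated tracks feed matrices
      res[c("raw", "spmr")] <- NULL
      res
    })
    assignments[[nm]]$experimental <- NULL
    assignments[[nm]]$spike <- NULL
  }
  gc(FALSE)

  # --- metagene matrices and profiles ------------------------------------
  mat_dir <- file.path(out, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  conds <- unique(smp$condition[smp$kind == "IP"])
  ref_cond <- config$reference_condition %||% conds[1]
  matrices <- list()
  for (cond in conds) {
    matrices[[cond]] <- stage_guard("metagene", cond, out, {
      members <- smp$name[smp$kind == "IP" & smp$condition == cond]
      trk <- if (length(members) > 1)
        average_tracks(lapply(members, function(nm) tracks[[nm]]$calibrated))
      else tracks[[members]]$calibrated
      m <- signal_matrix(trk, genes, window = par$window,
                         bin_size = par$bin_size, sample = cond)
      f <- file.path(mat_dir, sprintf("%s.matrix.tsv", cond))
      export_matrix(m, f); add_artifact(f)
      prof <- anchor_profile(m)
      pf <- file.path(mat_dir, sprintf("%s.profile.tsv", cond))
      utils::write.table(
        data.frame(offset = prof$offsets, value = fmt_sig(prof$profile),
                   n = prof$n),
        pf, sep = "\t", quote = FALSE, row.names = FALSE)
      add_artifact(pf)
      m
    })
  }
  if (length(conds) >= 1 && ref_cond %in% names(matrices)) {
    for (cond in conds) {
      m_ord <- order_rows(matrices[[cond]], matrices[[ref_cond]])
      f <- file.path(mat_dir, sprintf("%s.ordered_by_%s.tsv", cond, ref_cond))
      export_matrix(m_ord, f); add_artifact(f)
    }
  }
  if (length(conds) >= 2) {
    for (i in seq_len(length(conds) - 1)) for (j in seq(i + 1, length(conds))) {
      d <- difference_matrix(matrices[[conds[j]]], matrices[[conds[i]]])
      f <- file.path(mat_dir, sprintf("%s_minus_%s.matrix.tsv",
                                      conds[j], conds[i]))
      export_matrix(d, f); add_artifact(f)
    }
  }

  # --- manifest -----------------------------------------------------------
  prefix <- paste0(out, "/")
  rel <- sort(unique(ifelse(startsWith(artifacts, prefix),
                            substring(artifacts, nchar(prefix) + 1L),
                            artifacts)))
  sums <- as.character(tools::md5sum(file.path(out, rel)))
  manifest <- list(
    parameters = par,
    seed = config$run$seed,
    samples = smp,
    counts = counts_df,
    factors = lapply(factors, function(f)
      list(sample = f$sample, p_input = f$p_input, p_ip = f$p_ip,
           factor = f$factor)),
    artifacts = data.frame(path = rel, md5 = sums, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  invisible(manifest)
}

#' Genome-wide gene-window signal ratio between two tracks
#'
#' Summarises each track as the mean value over all TSS-anchored gene
#' windows minus the mean over background bases (everything further than
#' `flank` bases upstream or `downstream` bases downstream of any TSS), and
#' returns the ratio of the two background-subtracted signals. This is the
#' quantity spike-in calibration is supposed to make comparable across
#' samples with different global ChIP efficiencies.
#'
#' @param num_track,den_track `CoverageTrack`s over the same genome.
#' @param genes Gene data.frame.
#' @param window Gene window size (bp downstream of the TSS).
#' @param flank Upstream exclusion around each TSS for the background (bp).
#' @param downstream Downstream exclusion for the background (bp).
#' @return List with `ratio` and the per-track signal and background means.
#' @export
global_signal_ratio <- function(num_track, den_track, genes, window = 1500L,
                                flank = 1500L, downstream = 3000L) {
  sc_check(identical(num_track$chrom_lengths, den_track$chrom_lengths),
           "sc_incompatible_error", "tracks cover different genomes")
  win_mask <- lapply(num_track$chrom_lengths, function(L) logical(L))
  bg_block <- lapply(num_track$chrom_lengths, function(L) logical(L))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; tss <- genes$tss[i]
    L <- num_track$chrom_lengths[[ch]]
    dirn <- if (genes$strand[i] == "+") 1L else -1L
    w <- tss + dirn * (0:(window - 1L))
    w <- w[w >= 0 & w < L]
    win_mask[[ch]][w + 1L] <- TRUE
    b <- (tss - flank):(tss + flank) # orientation-free core
    d <- tss + dirn * (0:downstream)
    b <- unique(c(b, d))
    b <- b[b >= 0 & b < L]
    bg_block[[ch]][b + 1L] <- TRUE
  }
  summarise <- function(track) {
    wvals <- unlist(lapply(names(win_mask), function(ch)
      track$values[[ch]][win_mask[[ch]]]), use.names = FALSE)
    bvals <- unlist(lapply(names(bg_block), function(ch)
      track$values[[ch]][!bg_block[[ch]]]), use.names = FALSE)
    c(signal = mean(wvals), background = mean(bvals))
  }
  a <- summarise(num_track); b <- summarise(den_track)
  list(ratio = (a[["signal"]] - a[["background"]]) /
               (b[["signal"]] - b[["background"]]),
       num_signal = a[["signal"]], num_background = a[["background"]],
       den_signal = b[["signal"]], den_background = b[["background"]])
}
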