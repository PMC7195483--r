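#' Exclusive per-genome read counts of a library
#'
#' Carrier of the normalization-factor inputs: how many reads of one
#' demultiplexed library were exclusively assigned to the spike genome and
#' to the experimental genome. Counts are taken at the assignment stage,
#' before pileup-stage duplicate removal.
#'
#' @param sample Sample name.
#' @param n_spike,n_exp Exclusive read counts (>= 0).
#' @return An object of class `LibraryCounts`.
#' @export
library_counts <- function(sample, n_spike, n_exp) {
  sc_check(is_count(n_spike) && n_spike >= 0, "sc_config_error",
           "n_spike must be a nonnegative count")
  sc_check(is_count(n_exp) && n_exp >= 0, "sc_config_error",
           "n_exp must be a nonnegative count")
  structure(list(sample = sample, n_spike = as.numeric(n_spike),
                 n_exp = as.numeric(n_exp)),
            class = "LibraryCounts")
}

#' Spike read proportion of a library
#'
#' @param counts A [library_counts()].
#' @return `n_spike / (n_spike + n_exp)`.
#' @export
spike_proportion <- function(counts) {
  total <- counts$n_spike + counts$n_exp
  if (!isTRUE(total > 0))
    sc_error("sc_degenerate_library",
             sprintf("library %s has zero assigned reads", counts$sample))
  counts$n_spike / total
}

#' Spike-in normalization factor
#'
#' The factor applied to an IP sample's SPMR track is the spike read
#' proportion of the matched input library divided by the square root of the
#' spike read proportion of the IP library (the square root compensating
#' the per-million SPMR scaling already applied to the track):
#' `factor = p_input / sqrt(p_ip)`.
#'
#' @param input_counts [library_counts()] of the input library.
#' @param ip_counts [library_counts()] of the IP library.
#' @return An object of class `NormFactor` with fields `sample`, `p_input`,
#'   `p_ip`, `factor`.
#' @export
norm_factor <- function(input_counts, ip_counts) {
  p_input <- spike_proportion(input_counts)
  p_ip <- spike_proportion(ip_counts)
  if (!isTRUE(p_ip > 0))
    sc_error("sc_degenerate_library", sprintf(
      "IP library %s has no spike reads: normalization factor undefined",
      ip_counts$sample))
  sc_check(p_input > 0 && p_input < 1, "sc_degenerate_library",
           sprintf("input library %s spike proportion %.4g is not in (0,1)",
                   input_counts$sample, p_input))
  sc_check(p_ip < 1, "sc_degenerate_library",
           sprintf("IP library %s contains only spike reads",
                   ip_counts$sample))
  structure(list(sample = ip_counts$sample, input_sample = input_counts$sample,
                 p_input = p_input, p_ip = p_ip,
                 factor = p_input / sqrt(p_ip)),
            class = "NormFactor")
}

#' @export
print.NormFactor <- function(x, ...) {
  cat(sprintf("NormFactor %s: p_input=%.5g p_ip=%.5g factor=%.5g\n",
              x$sample, x$p_input, x$p_ip, x$factor))
  invisible(x)
}

#' Apply a normalization factor to an SPMR track
#'
#' Multiplies every base value by the factor and marks the track
#' spike-calibrated. Applying a factor to a raw (pre-SPMR) track is a
#' provenance error; the input track is not modified.
#'
#' @param track An SPMR-scaled `CoverageTrack`.
#' @param f A [norm_factor()].
#' @return A spike-calibrated `CoverageTrack`.
#' @export
apply_factor <- function(track, f) {
  sc_check(inherits(f, "NormFactor"), "sc_config_error",
           "f must be a NormFactor")
  if (!identical(track$provenance, "SPMR"))
    sc_error("sc_provenance_error", sprintf(
      "normalization factors apply to SPMR tracks, not '%s'",
      track$provenance))
  track$values <- lapply(track$values, function(v) v * f$factor)
  track$provenance <- "spike-calibrated"
  track$norm_factor <- f$factor
  track
}

#' Write the normalization-factor audit table
#'
#' One row per IP sample with all four read counts, both proportions and
#' the factor, so the calibration is fully reproducible from the report.
#'
#' @param factors List of [norm_factor()] results.
#' @param input_counts,ip_counts Lists of [library_counts()] matched by
#'   position to `factors`.
#' @param path Output TSV.
#' @export
write_factor_report <- function(factors, input_counts, ip_counts, path) {
  df <- do.call(rbind, lapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    data.frame(sample = f$sample,
               n_spike_in = input_counts[[i]]$n_spike,
               n_exp_in = input_counts[[i]]$n_exp,
               n_spike_ip = ip_counts[[i]]$n_spike,
               n_exp_ip = ip_counts[[i]]$n_exp,
               p_input = f$p_input, p_ip = f$p_ip, factor = f$factor,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
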