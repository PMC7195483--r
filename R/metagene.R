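#' TSS-anchored signal matrix
#'
#' One row per gene, one column per bin of `bin_size` bases over a window of
#' `window` bases starting at the TSS and running into the gene body
#' (strand-oriented, so bin 0 always abuts the TSS in the direction of
#' transcription). The bin statistic is the mean of per-base track values,
#' keeping matrix values in the track's units regardless of bin size. Genes
#' whose window exceeds the chromosome bounds get all-`NA` rows (with a
#' warning) rather than being dropped, so row sets stay identical across
#' samples.
#'
#' @param track An SPMR or spike-calibrated `CoverageTrack`.
#' @param genes Gene data.frame (`id`, `chrom`, `tss`, `strand`).
#' @param window Window size in bases (default 1500).
#' @param bin_size Bin size in bases (default 25); must divide `window`.
#' @param sample Sample name recorded as the matrix source.
#' @return An object of class `SignalMatrix`.
#' @export
signal_matrix <- function(track, genes, window = 1500L, bin_size = 25L,
                          sample = "sample") {
  sc_check(track$provenance %in% c("SPMR", "spike-calibrated"),
           "sc_provenance_error",
           "signal matrices are built from SPMR or spike-calibrated tracks")
  sc_check(window %% bin_size == 0, "sc_config_error",
           "window must be divisible by bin_size")
  n_bins <- as.integer(window / bin_size)
  vals <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins,
                 dimnames = list(genes$id, (seq_len(n_bins) - 1L) * bin_size))
  n_skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    sc_check(ch %in% names(track$values), "sc_incompatible_error",
             sprintf("gene %s lies on unknown chromosome %s", genes$id[i], ch))
    L <- track$chrom_lengths[[ch]]
    tss <- genes$tss[i]
    pos <- if (genes$strand[i] == "+") tss + 0:(window - 1L)
           else tss - 0:(window - 1L)
    if (pos[1] < 0 || pos[1] >= L || pos[window] < 0 || pos[window] >= L) {
      n_skipped <- n_skipped + 1L
      next
    }
    v <- track$values[[ch]][pos + 1L]
    vals[i, ] <- colMeans(matrix(v, nrow = bin_size))
  }
  if (n_skipped > 0)
    warning(sprintf("%d gene window(s) exceed chromosome bounds; rows set NA",
                    n_skipped), call. = FALSE)
  structure(list(values = vals, bin_size = as.integer(bin_size),
                 n_bins = n_bins, window = as.integer(window),
                 source = list(sample = sample,
                               provenance = track$provenance),
                 ordering = "genomic"),
            class = "SignalMatrix")
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf(
    "SignalMatrix [%s, %s]: %d genes x %d bins (%d bp bins, %d bp window)\n",
    x$source$sample, x$source$provenance, nrow(x$values), x$n_bins,
    x$bin_size, x$window))
  invisible(x)
}

check_same_geneset <- function(a, b) {
  sc_check(setequal(rownames(a$values), rownames(b$values)),
           "sc_incompatible_error", "matrices cover different gene sets")
}

#' Order matrix rows by a reference matrix
#'
#' Rows are sorted by descending row mean of the reference matrix (the
#' heatmap convention of ranking genes by their signal in a chosen
#' condition); ties break by gene id. The ordering source is recorded.
#'
#' @param matrix,reference `SignalMatrix` objects over the same gene set.
#' @return `matrix` with rows reordered.
#' @export
order_rows <- function(matrix, reference) {
  check_same_geneset(matrix, reference)
  means <- rowMeans(reference$values, na.rm = TRUE)
  ids <- rownames(reference$values)
  ord <- ids[order(-means, ids, method = "radix")]
  matrix$values <- matrix$values[ord, , drop = FALSE]
  matrix$ordering <- sprintf("by row mean of %s (descending)",
                             reference$source$sample)
  matrix
}

#' Averaged metagene anchor profile
#'
#' Per-bin mean over all non-missing rows, with the number of contributing
#' rows per bin.
#'
#' @param matrix A `SignalMatrix` with at least one non-missing row.
#' @return List with `profile` (length `n_bins`), `n` (contributing rows per
#'   bin), `bin_size`, `offsets` (bin start offsets from the TSS).
#' @export
anchor_profile <- function(matrix) {
  ok <- rowSums(!is.na(matrix$values)) > 0
  if (!any(ok)) sc_error("sc_empty_matrix",
                         "all rows are missing; no profile to average")
  v <- matrix$values[ok, , drop = FALSE]
  list(profile = colMeans(v, na.rm = TRUE),
       n = colSums(!is.na(v)),
       bin_size = matrix$bin_size,
       offsets = (seq_len(matrix$n_bins) - 1L) * matrix$bin_size)
}

#' Condition difference matrix
#'
#' Elementwise `a - b` for two matrices with identical gene sets, row order
#' and bin geometry (e.g. mutant minus wild type on spike-calibrated
#' signal).
#'
#' @param a,b `SignalMatrix` objects.
#' @return A `SignalMatrix` of differences.
#' @export
difference_matrix <- function(a, b) {
  sc_check(identical(rownames(a$values), rownames(b$values)),
           "sc_incompatible_error",
           "difference requires identical gene sets in identical row order")
  sc_check(a$bin_size == b$bin_size && a$n_bins == b$n_bins &&
           a$window == b$window,
           "sc_incompatible_error", "difference requires identical bin geometry")
  out <- a
  out$values <- a$values - b$values
  out$source <- list(
    sample = sprintf("%s - %s", a$source$sample, b$source$sample),
    provenance = sprintf("difference(%s, %s)", a$source$provenance,
                         b$source$provenance))
  out
}

#' Export / import a signal matrix as TSV
#'
#' First column `gene_id`, header row of bin start offsets, values at 6
#' significant digits, missing rows as `NA`; a leading comment line carries
#' the geometry and source so the matrix round-trips.
#'
#' @param matrix A `SignalMatrix`.
#' @param path TSV file.
#' @return `read_matrix` returns the `SignalMatrix`.
#' @export
export_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# signal_matrix bin_size=%d window=%d sample=%s provenance=%s",
    matrix$bin_size, matrix$window, matrix$source$sample,
    matrix$source$provenance), con)
  offs <- (seq_len(matrix$n_bins) - 1L) * matrix$bin_size
  writeLines(paste(c("gene_id", offs), collapse = "\t"), con)
  v <- matrix$values
  for (i in seq_len(nrow(v))) {
    cells <- ifelse(is.na(v[i, ]), "NA", fmt_sig(signif(v[i, ], 6)))
    writeLines(paste(c(rownames(v)[i], cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname export_matrix
#' @export
read_matrix <- function(path) {
  sc_check(file.exists(path), "sc_format_error",
           sprintf("%s: no such matrix file", path))
  lines <- readLines(path)
  sc_check(length(lines) >= 2 && startsWith(lines[1], "# signal_matrix"),
           "sc_format_error",
           sprintf("%s: not a signal-matrix TSV", path))
  m <- regmatches(lines[1], regexec(
    "bin_size=(\\d+) window=(\\d+) sample=(.*) provenance=(.*)$",
    lines[1]))[[1]]
  bin_size <- as.integer(m[2]); window <- as.integer(m[3])
  tab <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1,
                           na.strings = "NA")
  vals <- as.matrix(tab)
  rownames(vals) <- rownames(tab)
  structure(list(values = vals, bin_size = bin_size,
                 n_bins = ncol(vals), window = window,
                 source = list(sample = m[4], provenance = m[5]),
                 ordering = "as-read"),
            class = "SignalMatrix")
}
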