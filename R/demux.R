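#' Barcode specification
#'
#' Validates a sample-to-barcode map. By default pairwise Hamming distance
#' must be at least 3, which with one allowed mismatch makes assignment
#' unambiguous (a read within distance 1 of two barcodes would force the
#' barcodes within distance 2 of each other). `min_dist` can be relaxed to
#' study the behaviour of closer barcode sets.
#'
#' @param entries Named character vector (names = sample names) or a
#'   data.frame with columns `name`, `barcode`.
#' @param min_dist Minimum pairwise Hamming distance to enforce.
#' @return An object of class `BarcodeSpec`.
#' @export
barcode_spec <- function(entries, min_dist = 3L) {
  if (is.data.frame(entries))
    entries <- stats::setNames(entries$barcode, entries$name)
  sc_check(length(entries) >= 1, "sc_config_error", "no barcodes given")
  sc_check(!is.null(names(entries)) && !anyDuplicated(names(entries)) &&
           all(nzchar(names(entries))),
           "sc_config_error", "sample names must be unique and non-empty")
  sc_check(all(grepl("^[ACGT]+$", entries)), "sc_config_error",
           "barcodes must be A/C/G/T strings")
  sc_check(length(unique(nchar(entries))) == 1, "sc_config_error",
           "barcodes must all have the same length")
  if (length(entries) > 1) {
    for (i in seq_len(length(entries) - 1))
      for (j in seq(i + 1, length(entries)))
        sc_check(hamming(entries[[i]], entries[[j]]) >= min_dist,
                 "sc_config_error",
                 sprintf("barcodes %s and %s are closer than Hamming %d",
                         names(entries)[i], names(entries)[j], min_dist))
  }
  structure(list(entries = entries, barcode_length = nchar(entries[[1]])),
            class = "BarcodeSpec")
}

#' Read a TSV barcode table
#' @param path Two-column TSV (`sample<TAB>barcode`), no header.
#' @param min_dist Passed to [barcode_spec()].
#' @return A `BarcodeSpec`.
#' @export
read_barcodes <- function(path, min_dist = 3L) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("name", "barcode"))
  barcode_spec(tab, min_dist = min_dist)
}

#' Demultiplex reads by in-line barcode
#'
#' A read is assigned to the unique barcode whose Hamming distance to the
#' read's leading bases is minimal and at most `max_mismatch`; the barcode
#' is trimmed from the assigned read. Reads matching no barcode within the
#' tolerance, or tied between two or more barcodes at the minimal distance,
#' are left untrimmed in the unassigned stream (a tie-break would silently
#' corrupt sample identity). N bases count as mismatches.
#'
#' @param reads Data.frame with `id`, `seq` and optionally `qual`.
#' @param spec A [barcode_spec()].
#' @param max_mismatch Maximum Hamming distance for assignment (default 1).
#' @return List with `samples` (named list of trimmed read data.frames),
#'   `unassigned` (untrimmed) and `counts` (data.frame `sample`, `n`).
#' @export
demultiplex <- function(reads, spec, max_mismatch = 1L) {
  sc_check(inherits(spec, "BarcodeSpec"), "sc_config_error",
           "spec must be a BarcodeSpec")
  B <- spec$barcode_length
  sc_check(all(nchar(reads$seq) > B), "sc_malformed_read",
           "read shorter than (or equal to) the barcode length")
  if (is.null(reads$qual)) reads$qual <- strrep("I", nchar(reads$seq))
  n <- nrow(reads)
  prefix <- substr(reads$seq, 1L, B)
  bcs <- spec$entries
  dist <- matrix(0L, nrow = n, ncol = length(bcs))
  for (k in seq_along(bcs)) {
    d <- integer(n)
    for (i in seq_len(B))
      d <- d + (substr(prefix, i, i) != substr(bcs[[k]], i, i))
    dist[, k] <- d
  }
  best <- do.call(pmin, lapply(seq_along(bcs), function(k) dist[, k]))
  n_best <- rowSums(dist == best)
  assigned <- best <= max_mismatch & n_best == 1L
  which_bc <- max.col(-dist, ties.method = "first")

  samples <- lapply(seq_along(bcs), function(k) {
    sel <- assigned & which_bc == k
    out <- reads[sel, , drop = FALSE]
    out$seq <- substr(out$seq, B + 1L, nchar(out$seq))
    out$qual <- substr(out$qual, B + 1L, nchar(out$qual))
    rownames(out) <- NULL
    out
  })
  names(samples) <- names(bcs)
  unassigned <- reads[!assigned, , drop = FALSE]
  rownames(unassigned) <- NULL
  counts <- data.frame(sample = c(names(bcs), "unassigned"),
                       n = c(vapply(samples, nrow, integer(1)),
                             nrow(unassigned)),
                       stringsAsFactors = FALSE)
  stopifnot(sum(counts$n) == n)  # partition property
  list(samples = samples, unassigned = unassigned, counts = counts)
}
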