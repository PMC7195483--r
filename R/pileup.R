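#' Coverage track container
#'
#' Per-base float signal over one genome with scaling provenance. The
#' provenance ladder is `raw` (fragment-extension pileup), `SPMR` (scaled to
#' signal per million reads) and `spike-calibrated` (SPMR multiplied by a
#' spike-in normalization factor).
#'
#' @param genome_label `"experimental"` or `"spike"`.
#' @param values Named list of per-chromosome numeric vectors (one value per
#'   base).
#' @param provenance One of `"raw"`, `"SPMR"`, `"spike-calibrated"`.
#' @param reads_used Number of (deduplicated) reads that built the pileup.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(genome_label, values,
                           provenance = c("raw", "SPMR", "spike-calibrated"),
                           reads_used = 0L) {
  provenance <- match.arg(provenance)
  sc_check(is.list(values) && !is.null(names(values)),
           "sc_config_error", "values must be a named list of vectors")
  sc_check(all(vapply(values, function(v) all(v >= 0), logical(1))),
           "sc_config_error", "coverage values must be nonnegative")
  structure(list(genome_label = genome_label, values = values,
                 chrom_lengths = lengths(values), provenance = provenance,
                 reads_used = reads_used),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack <%s, %s>: %d chrom(s), %s bp, %d reads used\n",
              x$genome_label, x$provenance, length(x$values),
              format(sum(x$chrom_lengths), big.mark = ","), x$reads_used))
  invisible(x)
}

# 0-based 5' position of each alignment record.
five_prime_pos <- function(aln) {
  ifelse(aln$strand == "+", aln$start, aln$start + aln$aligned_length - 1L)
}

#' Remove duplicate reads
#'
#' Keeps at most one record per (chromosome, 5' position, strand), where the
#' 5' position is the leftmost base for plus-strand reads and the rightmost
#' aligned base for minus-strand reads. Retention is deterministic: within a
#' key the record with the lexicographically smallest `read_id` survives.
#'
#' @param aln Alignment data.frame from one genome.
#' @return Deduplicated alignment data.frame.
#' @export
deduplicate <- function(aln) {
  if (nrow(aln) == 0) return(aln)
  fp <- five_prime_pos(aln)
  ord <- order(aln$chrom, fp, aln$strand, aln$read_id, method = "radix")
  aln <- aln[ord, , drop = FALSE]
  fp <- fp[ord]
  key <- paste(aln$chrom, fp, aln$strand, sep = "\r")
  out <- aln[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragment-extension pileup
#'
#' Each deduplicated read contributes +1 coverage over a half-open interval
#' of `extension` bases starting at its 5' end and running in the read's
#' direction (the computational reconstruction of the sequenced fragment):
#' plus-strand reads cover `[start, start + extension)`, minus-strand reads
#' `[five_prime - extension + 1, five_prime + 1)`. Intervals are truncated
#' at chromosome bounds.
#'
#' @param aln Deduplicated alignment data.frame (one genome).
#' @param chrom_lengths Named chromosome lengths of that genome.
#' @param extension Extension length in bases (default 150).
#' @param genome_label Label recorded on the track.
#' @return A raw `CoverageTrack` with `reads_used = nrow(aln)`.
#' @export
extend_and_pileup <- function(aln, chrom_lengths, extension = 150L,
                              genome_label = "experimental") {
  sc_check(is_count(extension) && extension > 0, "sc_config_error",
           "extension must be a positive count")
  sc_check(all(aln$chrom %in% names(chrom_lengths)), "sc_config_error",
           "alignment chromosome absent from chrom_lengths")
  fp <- five_prime_pos(aln)
  s0 <- ifelse(aln$strand == "+", fp, fp - extension + 1L)
  e0 <- s0 + extension  # half-open 0-based
  values <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    sel <- aln$chrom == ch
    if (!any(sel)) return(numeric(L))
    s <- pmax(s0[sel], 0L)
    e <- pmin(e0[sel], L)
    ok <- e > s
    if (!any(ok)) return(numeric(L))
    cov <- IRanges::coverage(IRanges::IRanges(s[ok] + 1L, e[ok]), width = L)
    as.numeric(cov)
  })
  names(values) <- names(chrom_lengths)
  coverage_track(genome_label, values, "raw", reads_used = nrow(aln))
}

#' Scale a raw track to signal per million reads (SPMR)
#'
#' Every base value is multiplied by `1e6 / reads_used`, where `reads_used`
#' is the deduplicated read count of this track's genome.
#'
#' @param track A raw `CoverageTrack` with `reads_used > 0`.
#' @return An SPMR `CoverageTrack`.
#' @export
spmr_scale <- function(track) {
  sc_check(identical(track$provenance, "raw"), "sc_provenance_error",
           "SPMR scaling applies to raw tracks")
  if (!isTRUE(track$reads_used > 0))
    sc_error("sc_empty_library", "cannot SPMR-scale a track built from 0 reads")
  k <- 1e6 / track$reads_used
  track$values <- lapply(track$values, function(v) v * k)
  track$provenance <- "SPMR"
  track
}

#' Average replicate tracks
#'
#' Per-base arithmetic mean of two or more tracks over the same genome with
#' identical provenance (e.g. two technical repeats before plotting).
#'
#' @param ... `CoverageTrack`s, or a single list of them.
#' @return A `CoverageTrack` with `reads_used` equal to the inputs' sum.
#' @export
average_tracks <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1 && !inherits(tracks[[1]], "CoverageTrack"))
    tracks <- tracks[[1]]
  sc_check(length(tracks) >= 2, "sc_config_error",
           "need at least two tracks to average")
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    sc_check(identical(t$genome_label, ref$genome_label) &&
             identical(t$chrom_lengths, ref$chrom_lengths),
             "sc_incompatible_error", "tracks cover different genomes")
    sc_check(identical(t$provenance, ref$provenance),
             "sc_incompatible_error", "tracks have different provenance")
  }
  n <- length(tracks)
  values <- lapply(names(ref$values), function(ch) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / n
  })
  names(values) <- names(ref$values)
  used <- sum(unlist(lapply(tracks, function(t) as.numeric(t$reads_used))))
  coverage_track(ref$genome_label, values, ref$provenance, reads_used = used)
}

track_header <- function(track, type) {
  sprintf(paste0('track type=%s description="provenance=%s;reads_used=%d;',
                 'genome=%s;lengths=%s"'),
          type, track$provenance, track$reads_used, track$genome_label,
          paste(sprintf("%s:%d", names(track$chrom_lengths),
                        track$chrom_lengths), collapse = ","))
}

#' Write a coverage track to bedGraph or wiggle
#'
#' bedGraph rows are 0-based half-open with run-length merging of equal
#' adjacent values (at the printed precision) and zero rows omitted; wiggle
#' output is `fixedStep` with 1-based start and step 1. Values are printed
#' at 6 significant digits, so `read_track(write_track(t))` reproduces
#' `signif(values, 6)` exactly. The track line carries provenance,
#' `reads_used` and chromosome lengths so the container round-trips.
#'
#' @param track A `CoverageTrack`.
#' @param path Output file.
#' @param format `"bedGraph"` or `"wiggle"`.
#' @export
write_track <- function(track, path, format = c("bedGraph", "wiggle")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bedGraph") {
    writeLines(track_header(track, "bedGraph"), con)
    for (ch in names(track$values)) {
      v <- signif(track$values[[ch]], 6)
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths  # 0-based
      keep <- r$values != 0
      if (!any(keep)) next
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         fmt_sig(r$values[keep])), con)
    }
  } else {
    writeLines(track_header(track, "wiggle_0"), con)
    for (ch in names(track$values)) {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", ch), con)
      writeLines(fmt_sig(signif(track$values[[ch]], 6)), con)
    }
  }
  invisible(path)
}

parse_track_header <- function(line, path) {
  m <- regmatches(line, regexec(
    'description="provenance=([^;]+);reads_used=(\\d+);genome=([^;]+);lengths=([^"]+)"',
    line))[[1]]
  sc_check(length(m) == 5, "sc_format_error",
           sprintf("%s line 1: missing or malformed track header", path))
  lens <- strsplit(m[5], ",")[[1]]
  parts <- strsplit(lens, ":")
  list(provenance = m[2], reads_used = as.integer(m[3]), genome = m[4],
       chrom_lengths = stats::setNames(
         as.integer(vapply(parts, `[`, character(1), 2)),
         vapply(parts, `[`, character(1), 1)))
}

#' Read a coverage track written by [write_track()]
#'
#' @param path bedGraph or wiggle file.
#' @return A `CoverageTrack`.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  sc_check(length(lines) >= 1, "sc_format_error",
           sprintf("%s: empty track file", path))
  hdr <- parse_track_header(lines[1], path)
  is_wig <- grepl("type=wiggle_0", lines[1])
  values <- lapply(hdr$chrom_lengths, numeric)
  if (is_wig) {
    ch <- NULL; at <- 0L
    for (i in seq_along(lines)[-1]) {
      ln <- lines[i]
      if (startsWith(ln, "fixedStep")) {
        m <- regmatches(ln, regexec(
          "fixedStep chrom=(\\S+) start=(\\d+) step=1", ln))[[1]]
        sc_check(length(m) == 3, "sc_format_error",
                 sprintf("%s line %d: malformed fixedStep header", path, i))
        ch <- m[2]; at <- as.integer(m[3]) - 1L
        sc_check(ch %in% names(values), "sc_format_error",
                 sprintf("%s line %d: unknown chromosome %s", path, i, ch))
      } else {
        v <- suppressWarnings(as.numeric(ln))
        sc_check(!is.null(ch) && !is.na(v), "sc_format_error",
                 sprintf("%s line %d: malformed wiggle value", path, i))
        values[[ch]][at + 1L] <- v
        at <- at + 1L
      }
    }
  } else {
    if (length(lines) > 1) {
      body <- lines[-1]
      parts <- strsplit(body, "\t", fixed = TRUE)
      bad <- which(lengths(parts) != 4)
      sc_check(length(bad) == 0, "sc_format_error",
               sprintf("%s line %d: malformed bedGraph row", path,
                       if (length(bad)) bad[1] + 1L else 0L))
      chs <- vapply(parts, `[`, character(1), 1)
      s <- as.integer(vapply(parts, `[`, character(1), 2))
      e <- as.integer(vapply(parts, `[`, character(1), 3))
      v <- as.numeric(vapply(parts, `[`, character(1), 4))
      sc_check(!anyNA(s) && !anyNA(e) && !anyNA(v) &&
               all(chs %in% names(values)),
               "sc_format_error",
               sprintf("%s: malformed bedGraph coordinates", path))
      for (i in seq_along(chs))
        values[[chs[i]]][(s[i] + 1L):e[i]] <- v[i]
    }
  }
  coverage_track(hdr$genome, values, hdr$provenance, hdr$reads_used)
}
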