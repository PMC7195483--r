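#' Build an exact-match substring index of a genome
#'
#' Enumerates every k-mer of the given width on both strands (minus-strand
#' hits are recorded at their leftmost plus-strand coordinate, as in SAM)
#' and keys them for O(log n) lookup, recording each k-mer's total number of
#' occurrences so multi-mapping queries are recognised. Queries of other
#' lengths (>= 20) fall back to a full Biostrings scan.
#'
#' @param genome A `Genome`.
#' @param width Indexed query width in bases; the internal aligner trims the
#'   first read base, so the default matches 50 bp reads.
#' @return An object of class `GenomeIndex`.
#' @export
build_index <- function(genome, width = 49L) {
  width <- as.integer(width)
  sc_check(width >= 20L, "sc_config_error", "index width must be >= 20")
  lens <- chrom_lengths(genome)
  parts <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    if (L < width) next
    n <- L - width + 1L
    fwd <- substring(genome$chroms[[ch]], 1:n, width:L)
    rc <- revcomp(genome$chroms[[ch]])
    rev <- substring(rc, 1:n, width:L)
    parts[[length(parts) + 1L]] <- data.table::data.table(
      kmer = fwd, chrom = ch, pos = 0:(n - 1L), strand = "+")
    parts[[length(parts) + 1L]] <- data.table::data.table(
      kmer = rev, chrom = ch, pos = L - (0:(n - 1L)) - width, strand = "-")
  }
  kmers <- data.table::rbindlist(parts)
  kmers[, n := .N, by = "kmer"]
  data.table::setkey(kmers, kmer)
  structure(list(width = width, kmers = kmers, chrom_lengths = lens,
                 label = genome$label, chroms = genome$chroms),
            class = "GenomeIndex")
}

#' Query an index for all exact hits of a sequence
#'
#' @param index A [build_index()] result.
#' @param seq Query sequence (length >= 20).
#' @return Data.frame of hits with `chrom`, `pos` (0-based leftmost),
#'   `strand`; zero rows if absent.
#' @export
query_index <- function(index, seq) {
  sc_check(nchar(seq) >= 20L, "sc_config_error", "query shorter than 20 bases")
  if (nchar(seq) == index$width) {
    hits <- index$kmers[data.table::J(seq), nomatch = NULL]
    return(as.data.frame(hits[, c("chrom", "pos", "strand")]))
  }
  # slow path for non-indexed widths: full scan on both strands
  out <- list()
  for (ch in names(index$chroms)) {
    subj <- Biostrings::DNAString(index$chroms[[ch]])
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(seq), subj)
    if (length(fwd))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = BiocGenerics::start(fwd) - 1L, strand = "+",
        stringsAsFactors = FALSE)
    rev <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)), subj)
    if (length(rev))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = BiocGenerics::start(rev) - 1L, strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

check_read_alphabet <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  sc_check(!any(bad), "sc_malformed_read",
           sprintf("%d read(s) contain characters outside A/C/G/T/N",
                   sum(bad)))
}

#' Align one read uniquely, excluding its first base
#'
#' The first base is removed (sequencer-specific error hotspot in the
#' emulated pipeline), the remainder is searched exactly on both strands,
#' and a placement is reported only when exactly one hit exists; zero hits
#' and multi-aligned reads both yield no placement.
#'
#' @param read Read sequence (length >= 21).
#' @param index A [build_index()] result.
#' @param read_id Identifier for the returned record.
#' @return One-row alignment data.frame (`read_id`, `genome_label`, `chrom`,
#'   `start`, `strand`, `aligned_length`) or `NULL` for no placement.
#' @export
align_unique <- function(read, index, read_id = "read") {
  sc_check(nchar(read) >= 21L, "sc_malformed_read",
           "read shorter than 21 bases")
  check_read_alphabet(read)
  trimmed <- substring(read, 2L)
  hits <- query_index(index, trimmed)
  if (nrow(hits) != 1L) return(NULL)
  data.frame(read_id = read_id, genome_label = index$label,
             chrom = hits$chrom, start = hits$pos, strand = hits$strand,
             aligned_length = nchar(trimmed), stringsAsFactors = FALSE)
}

# Bulk unique placement of equal-length trimmed sequences against an index.
# Returns a data.frame aligned with `trimmed`, with NA chrom where the read
# is unplaced, plus a status vector in {placed, multi, unmapped}.
align_bulk <- function(trimmed, index) {
  stopifnot(all(nchar(trimmed) == index$width))
  hit <- index$kmers[data.table::J(trimmed), mult = "first"]
  status <- rep("unmapped", length(trimmed))
  status[!is.na(hit$n) & hit$n == 1L] <- "placed"
  status[!is.na(hit$n) & hit$n > 1L] <- "multi"
  list(chrom = hit$chrom, pos = hit$pos, strand = hit$strand, status = status)
}

#' Sequential exclusive assignment of reads to two genomes
#'
#' Each read (first base excluded) is first aligned to the spike genome;
#' uniquely placed reads become spike records and never reach the second
#' pass. Remaining reads (unmapped or multi-mapped on spike) are aligned to
#' the experimental genome; uniquely placed ones become experimental
#' records; everything else is dropped. The returned counts are the
#' exclusive per-genome read totals that feed the normalization factor.
#'
#' @param reads Data.frame with `id` and `seq`.
#' @param spike_index Index of the spike genome.
#' @param exp_index Index of the experimental genome.
#' @param sample Sample name recorded in the counts.
#' @return List with `spike` and `experimental` alignment data.frames,
#'   `counts` (a [library_counts()]), and `stats` (drop and cross-mapper
#'   diagnostics).
#' @export
assign_exclusive <- function(reads, spike_index, exp_index,
                             sample = "sample") {
  sc_check(spike_index$label == "spike" && exp_index$label == "experimental",
           "sc_config_error", "indexes must be (spike, experimental)")
  check_read_alphabet(reads$seq)
  sc_check(all(nchar(reads$seq) >= 21L), "sc_malformed_read",
           "reads must be at least 21 bases")
  trimmed <- substring(reads$seq, 2L)
  mk <- function(ids, chrom, pos, strand, label, width) {
    data.frame(read_id = ids, genome_label = label, chrom = chrom,
               start = pos, strand = strand, aligned_length = width,
               stringsAsFactors = FALSE)
  }
  if (length(unique(nchar(trimmed))) == 1L &&
      nchar(trimmed[1]) == spike_index$width &&
      spike_index$width == exp_index$width) {
    sp <- align_bulk(trimmed, spike_index)
    sp_placed <- sp$status == "placed"
    spike_df <- mk(reads$id[sp_placed], sp$chrom[sp_placed],
                   sp$pos[sp_placed], sp$strand[sp_placed], "spike",
                   spike_index$width)
    rest <- which(!sp_placed)
    ex <- align_bulk(trimmed[rest], exp_index)
    ex_placed <- ex$status == "placed"
    exp_df <- mk(reads$id[rest][ex_placed], ex$chrom[ex_placed],
                 ex$pos[ex_placed], ex$strand[ex_placed], "experimental",
                 exp_index$width)
    n_multi_spike <- sum(sp$status == "multi")
    n_multi_exp <- sum(ex$status == "multi")
    cross <- sum(data.table::`%chin%`(trimmed[sp_placed],
                                      exp_index$kmers$kmer))
  } else {
    rec_sp <- rec_ex <- list()
    n_multi_spike <- n_multi_exp <- cross <- 0L
    for (i in seq_len(nrow(reads))) {
      r <- align_unique(reads$seq[i], spike_index, reads$id[i])
      if (!is.null(r)) {
        rec_sp[[length(rec_sp) + 1L]] <- r
        if (nrow(query_index(exp_index, substring(reads$seq[i], 2L))) > 0)
          cross <- cross + 1L
        next
      }
      if (nrow(query_index(spike_index, substring(reads$seq[i], 2L))) > 1)
        n_multi_spike <- n_multi_spike + 1L
      r <- align_unique(reads$seq[i], exp_index, reads$id[i])
      if (!is.null(r)) rec_ex[[length(rec_ex) + 1L]] <- r
      else if (nrow(query_index(exp_index, substring(reads$seq[i], 2L))) > 1)
        n_multi_exp <- n_multi_exp + 1L
    }
    empty <- mk(character(0), character(0), integer(0), character(0),
                "x", integer(0))[0, ]
    spike_df <- if (length(rec_sp)) do.call(rbind, rec_sp) else empty
    exp_df <- if (length(rec_ex)) do.call(rbind, rec_ex) else empty
  }
  counts <- library_counts(sample, n_spike = nrow(spike_df),
                           n_exp = nrow(exp_df))
  sc_check(counts$n_spike + counts$n_exp <= nrow(reads), "sc_config_error",
           "assigned more reads than were supplied")
  list(spike = spike_df, experimental = exp_df, counts = counts,
       stats = list(n_total = nrow(reads),
                    n_dropped = nrow(reads) - nrow(spike_df) - nrow(exp_df),
                    n_multi_spike = n_multi_spike, n_multi_exp = n_multi_exp,
                    n_cross_mappers = cross))
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    w <- 0L
    for (op in ops) {
      k <- substr(op, nchar(op), nchar(op))
      if (k %in% c("M", "D", "N", "=", "X"))
        w <- w + as.integer(substr(op, 1L, nchar(op) - 1L))
    }
    w
  }, integer(1), USE.NAMES = FALSE)
}

#' Ingest externally produced alignments (SAM/BAM or BED6)
#'
#' Entry point for real sequencing data aligned outside the package. SAM/BAM
#' records are filtered to mapped, primary, non-duplicate alignments
#' (via Rsamtools); BED6 records are taken as-is. Starts are converted to
#' 0-based coordinates and the reference-aligned length is taken from the
#' CIGAR (SAM) or the interval width (BED).
#'
#' @param path A `.sam`, `.bam` or `.bed` file.
#' @param genome_label `"experimental"` or `"spike"`.
#' @return Alignment data.frame (`read_id`, `genome_label`, `chrom`,
#'   `start`, `strand`, `aligned_length`).
#' @export
read_alignments <- function(path, genome_label) {
  genome_label <- match.arg(genome_label, c("experimental", "spike"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    bam <- path
    if (ext == "sam") {
      bam <- tryCatch(
        Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                         indexDestination = FALSE),
        error = function(e) sc_error("sc_format_error",
          paste0("cannot parse SAM file: ", conditionMessage(e))))
    }
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isDuplicate = FALSE,
                                   isSupplementaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(
      flag = flag, what = c("qname", "rname", "strand", "pos", "cigar"))
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    return(data.frame(read_id = x$qname, genome_label = genome_label,
                      chrom = as.character(x$rname), start = x$pos - 1L,
                      strand = as.character(x$strand),
                      aligned_length = cigar_ref_width(x$cigar),
                      stringsAsFactors = FALSE))
  }
  if (ext == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) sc_error("sc_format_error",
                     paste0("cannot parse BED file: ", conditionMessage(e))))
    st <- as.character(GenomicRanges::strand(gr))
    sc_check(all(st %in% c("+", "-")), "sc_format_error",
             "BED alignments must carry +/- strands")
    return(data.frame(read_id = gr$name, genome_label = genome_label,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L, strand = st,
                      aligned_length = GenomicRanges::width(gr),
                      stringsAsFactors = FALSE))
  }
  sc_error("sc_format_error",
           paste0("unrecognised alignment format: .", ext))
}

#' Write alignment records to BED6
#' @param aln Alignment data.frame.
#' @param path Output BED file.
#' @export
write_alignments <- function(aln, path) {
  gr <- GenomicRanges::GRanges(
    aln$chrom,
    IRanges::IRanges(aln$start + 1L, width = aln$aligned_length),
    strand = aln$strand)
  gr$name <- aln$read_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
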