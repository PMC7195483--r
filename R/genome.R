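#' Genome container
#'
#' A genome is a named set of chromosome sequences plus a label saying
#' whether it is the experimental genome or the exogenous spike-in genome.
#'
#' @param label `"experimental"` or `"spike"`.
#' @param chroms Named character vector of uppercase A/C/G/T sequences.
#' @return An object of class `Genome`.
#' @export
genome <- function(label, chroms) {
  label <- match.arg(label, c("experimental", "spike"))
  sc_check(length(chroms) > 0, "sc_config_error", "genome has no chromosomes")
  sc_check(!is.null(names(chroms)) && !anyDuplicated(names(chroms)),
           "sc_config_error", "chromosome names must be unique and non-empty")
  sc_check(all(nchar(chroms) > 0), "sc_config_error", "empty chromosome sequence")
  sc_check(!any(grepl("[^ACGT]", chroms)), "sc_config_error",
           "chromosome sequences must be uppercase A/C/G/T only")
  structure(list(label = label, chroms = chroms), class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome <%s>: %d chromosome(s), %s bp total\n",
              x$label, length(x$chroms),
              format(sum(nchar(x$chroms)), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g A `Genome`.
#' @return Named integer vector.
#' @export
chrom_lengths <- function(g) {
  stats::setNames(nchar(g$chroms), names(g$chroms))
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @param label Genome label (`"experimental"` or `"spike"`).
#' @return A `Genome`.
#' @export
read_genome <- function(path, label) {
  seqs <- Biostrings::readDNAStringSet(path)
  chroms <- stats::setNames(toupper(as.character(seqs)),
                            sub("\\s.*$", "", names(seqs)))
  genome(label, chroms)
}

#' Write a genome to FASTA
#' @param g A `Genome`.
#' @param path Output file.
#' @export
write_genome <- function(g, path) {
  x <- Biostrings::DNAStringSet(g$chroms)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read single-end reads from FASTQ
#'
#' @param path FASTQ file.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#' @param reads Data.frame with `id`, `seq`, `qual`.
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read gene annotations from BED6
#'
#' Genes are encoded as 1-bp BED6 features at the TSS (chrom, tss, tss+1,
#' id, score, strand; 0-based half-open starts).
#'
#' @param path BED file.
#' @return Data.frame with `id`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) sc_error("sc_format_error",
                   paste0("cannot parse BED gene file: ", conditionMessage(e))))
  df <- data.frame(id = gr$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   tss = GenomicRanges::start(gr) - 1L,
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  sc_check(all(df$strand %in% c("+", "-")), "sc_format_error",
           "gene BED records must carry +/- strands")
  sc_check(!anyDuplicated(df$id), "sc_format_error", "gene ids must be unique")
  df
}

#' Write gene annotations to BED6
#' @param genes Data.frame with `id`, `chrom`, `tss`, `strand`.
#' @param path Output file.
#' @export
write_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$tss + 1L, width = 1L),
                               strand = genes$strand)
  gr$name <- genes$id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
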