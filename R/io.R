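#' Write / read a genome FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(as_genome_chars(genome))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(dna)), sub("\\s.*$", "", names(dna)))
}

#' Write / read FASTQ (phred+33)
#'
#' @param reads data.frame with read_id, sequence, quality.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @return `read_fastq()` returns a data.frame (read_id, sequence, quality).
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(read_id = names(dna),
             sequence = as.character(dna),
             quality = as.character(S4Vectors::mcols(dna)$qualities),
             stringsAsFactors = FALSE)
}

#' Write / read gene models as GTF
#'
#' Internally the package uses 0-based half-open feature coordinates; on
#' disk GTF is 1-based inclusive. 3'UTR intervals are emitted as
#' `three_prime_utr` features.
#'
#' @param models feature data.frame (gene_id, chrom, strand, type in
#'   {exon, utr3}, start, end, exon_rank).
#' @param path output file.
#' @export
write_models_gtf <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand)
  S4Vectors::mcols(gr)$source <- "ipaseq"
  S4Vectors::mcols(gr)$type <- ifelse(models$type == "utr3",
                                      "three_prime_utr", models$type)
  S4Vectors::mcols(gr)$gene_id <- models$gene_id
  S4Vectors::mcols(gr)$exon_number <- models$exon_rank
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_models_gtf
#' @return `read_models_gtf()` returns the feature data.frame.
#' @export
read_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- S4Vectors::mcols(gr)$type %in% c("exon", "three_prime_utr")
  gr <- gr[keep]
  data.frame(
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = ifelse(S4Vectors::mcols(gr)$type == "three_prime_utr", "utr3",
                  "exon"),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    exon_rank = as.integer(S4Vectors::mcols(gr)$exon_number %||%
                             rep(NA_integer_, length(gr))),
    stringsAsFactors = FALSE)
}

#' Write truth sites as BED6
#'
#' name is `<gene>:<category>`, score is round(usage * 1000) in the given
#' condition, coordinates are the single cleavage base `[pos, pos+1)`.
#'
#' @param truth an `ipaseq_truth`.
#' @param path output file.
#' @param condition condition whose usage fills the score column.
#' @export
write_truth_bed <- function(truth, path, condition = truth$conditions[1]) {
  s <- truth$sites
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", s$chrom, s$cleavage_pos,
                   s$cleavage_pos + 1L, paste0(s$gene_id, ":", s$category),
                   round(1000 * s[[usage_col(condition)]]), s$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of exclusion intervals
#'
#' @param path BED file (at least 3 columns; 0-based half-open on disk, kept
#'   that way internally).
#' @param label exclusion-set label (e.g. "blacklist").
#' @return data.frame chrom, start, end, label.
#' @export
read_bed_intervals <- function(path, label = basename(path)) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   stop("failed to parse BED file ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   label = label, stringsAsFactors = FALSE)
  bad <- df$start >= df$end
  if (any(bad)) {
    stop("invalid interval (start >= end) in ", path, " at record ",
         which(bad)[1])
  }
  df
}

#' Load external alignments from SAM/BAM
#'
#' Reads aligned segments, drops unmapped records, and applies the mapping
#' quality filter. The number of MAPQ-filtered records is attached as the
#' `"n_low_mapq"` attribute.
#'
#' @param path SAM or BAM file.
#' @param min_mapq minimum retained mapping quality.
#' @return data.frame read_id, chrom, genome_strand, start, end (0-based
#'   half-open), mapq.
#' @export
load_alignments <- function(path, min_mapq = 10) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "mapq")))
  df <- data.frame(
    read_id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    genome_strand = as.character(GenomicAlignments::strand(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    mapq = S4Vectors::mcols(ga)$mapq,
    stringsAsFactors = FALSE)
  mapq <- ifelse(is.na(df$mapq), 0L, df$mapq)
  out <- df[mapq >= min_mapq, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_low_mapq") <- sum(mapq < min_mapq)
  out
}

#' Write a data.frame as TSV with stable formatting
#'
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write poly(A) sites as BED6
#'
#' @param sites site table (site_id, chrom, position, strand; counts ignored).
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  total <- round(rowSums(as.matrix(
    sites[, grep("^n_", names(sites)), drop = FALSE])))
  if (length(total) == 0) total <- rep(0L, nrow(sites))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom, sites$position,
                   sites$position + 1L, sites$site_id, total, sites$strand)
  writeLines(lines, path)
  invisible(path)
}
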