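# length of the common prefix of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1L]][seq_len(n)]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]][seq_len(n)]
  mism <- which(av != bv)
  if (length(mism) == 0L) n else mism[1L] - 1L
}

#' Resolve the cleavage position of one aligned read and classify it
#'
#' The insert is the reverse complement of the transcript 3' end, so the
#' transcript strand is opposite the insert's genomic strand and the
#' provisional cleavage position is the insert's 3'-most aligned base in
#' transcript orientation. The T-tail is then rescued against the genome:
#' walking outward from the insert-adjacent tail base, each tail base whose
#' transcript-sense identity equals the next genomic sense-strand base
#' downstream of the cleavage site (an A, for a tail T) is genome-templated;
#' every rescued base moves the cleavage position one base downstream.
#' Rescue stops at the first mismatch (or after `rescue_window` bases, or at
#' the contig end). The unmappable-T count is the number of T's left in the
#' unrescued part of the tail; reads with at least two unmappable T's are
#' poly(A)-site-supporting (PASS).
#'
#' @param trimmed list/row from [trim_and_extract_tail()] (needs `read_id`,
#'   `tail`, `tail_length`).
#' @param segment alignment of the insert: list/row with `chrom`,
#'   `genome_strand`, `start`, `end` (0-based half-open).
#' @param genome named character vector or DNAStringSet.
#' @param rescue_window bp of downstream genomic sequence examined.
#' @return a list with `read_id`, `chrom`, `transcript_strand`,
#'   `cleavage_pos` (0-based last transcribed base), `unmappable_t`,
#'   `rescued`, `pass` (logical) and, for non-PASS reads, `reason` in
#'   `"internal_priming"` / `"insufficient_tail"` / `"tailless"`.
#' @export
resolve_cleavage_and_classify <- function(trimmed, segment, genome,
                                          rescue_window = 20) {
  df <- classify_pass_reads(
    data.frame(read_id = trimmed$read_id, tail = trimmed$tail,
               tail_length = trimmed$tail_length,
               chrom = segment$chrom, genome_strand = segment$genome_strand,
               start = segment$start, end = segment$end,
               stringsAsFactors = FALSE),
    genome, rescue_window = rescue_window)
  as.list(df[1L, ])
}

#' Vectorised cleavage resolution and PASS classification
#'
#' @param aligned data.frame with columns read_id, tail, tail_length, chrom,
#'   genome_strand, start, end (one row per MAPQ-passing aligned read).
#' @inheritParams resolve_cleavage_and_classify
#' @return data.frame with read_id, chrom, transcript_strand, cleavage_pos,
#'   rescued, unmappable_t, pass, reason.
#' @export
classify_pass_reads <- function(aligned, genome, rescue_window = 20) {
  genome <- as_genome_chars(genome)
  n <- nrow(aligned)
  if (n == 0) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      transcript_strand = character(0),
                      cleavage_pos = integer(0), rescued = integer(0),
                      unmappable_t = integer(0), pass = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  ts <- ifelse(aligned$genome_strand == "+", "-", "+")
  prov <- ifelse(ts == "+", aligned$end - 1L, aligned$start)

  # genomic sense-strand sequence downstream of the provisional cleavage
  # site, read outward in transcript direction; clipped at contig ends.
  # Reads share few distinct cleavage positions, so extract per unique key.
  poskey <- paste(aligned$chrom, ts, prov, sep = "|")
  pu <- which(!duplicated(poskey))
  plus_u <- ts[pu] == "+"
  dwn_u <- character(length(pu))
  if (any(plus_u)) {
    i <- pu[plus_u]
    dwn_u[plus_u] <- genome_substr(genome, aligned$chrom[i], prov[i] + 1L,
                                   prov[i] + 1L + rescue_window)
  }
  if (any(!plus_u)) {
    i <- pu[!plus_u]
    dwn_u[!plus_u] <- sense_substr(genome, aligned$chrom[i],
                                   prov[i] - rescue_window, prov[i], "-")
  }
  dwn <- dwn_u[match(poskey, poskey[pu])]

  # tail in transcript-sense orientation, insert-adjacent base first
  tu <- which(!duplicated(aligned$tail))
  tail_sense_u <- ifelse(aligned$tail_length[tu] > 0,
                         revcomp(aligned$tail[tu]), "")
  tail_sense <- tail_sense_u[match(aligned$tail, aligned$tail[tu])]

  key <- paste(tail_sense, dwn, sep = "|")
  uq <- which(!duplicated(key))
  rescued_uq <- mapply(common_prefix_len, tail_sense[uq], dwn[uq],
                       USE.NAMES = FALSE)
  idx <- match(key, key[uq])
  rescued <- as.integer(rescued_uq[idx])
  remaining_uq <- substr(tail_sense[uq], rescued_uq + 1L,
                         aligned$tail_length[uq])
  # unmappable T's: tail A's (transcript sense) left unexplained by genome
  unmappable_uq <- nchar(remaining_uq) -
    nchar(gsub("A", "", remaining_uq, fixed = TRUE))
  unmappable <- unmappable_uq[idx]

  cleave <- ifelse(ts == "+", prov + rescued, prov - rescued)
  pass <- unmappable >= 2L
  reason <- ifelse(pass, NA_character_,
                   ifelse(aligned$tail_length == 0L, "tailless",
                          ifelse(rescued > 0L, "internal_priming",
                                 "insufficient_tail")))
  data.frame(read_id = aligned$read_id, chrom = aligned$chrom,
             transcript_strand = ts, cleavage_pos = as.integer(cleave),
             rescued = rescued, unmappable_t = as.integer(unmappable),
             pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Process one raw 3'-end-seq library to PASS reads
#'
#' Full read-level pipeline: UMI/tail trimming, insert length filter,
#' exact-match alignment, MAPQ filter, tail-rescue and PASS classification.
#' Every input read lands in exactly one partition of the run report.
#'
#' @param reads data.frame with read_id, sequence (e.g. from
#'   [simulate_threads_library()] or [read_fastq()]).
#' @param genome named character vector or DNAStringSet.
#' @param params a [pa_params()].
#' @param umi_length nt of UMI at the read start.
#' @param align_cache optional environment passed to [align_inserts()].
#' @return list with `pass` (data.frame read_id, chrom, strand,
#'   cleavage_pos, unmappable_t, library), `report` (named integer partition
#'   counts summing to the input count) and `library` (label, from the
#'   `"library"` attribute of `reads` if present).
#' @export
process_threads_library <- function(reads, genome, params = pa_params(),
                                    umi_length = 4, align_cache = NULL) {
  lib <- attr(reads, "library") %||% "library"
  trim <- trim_reads(reads, umi_length = umi_length,
                     min_insert = params$min_insert)
  tr <- trim$trimmed
  aln <- align_inserts(tr$insert, genome, cache = align_cache)
  unaligned <- is.na(aln$chrom)
  lowmapq <- !unaligned & aln$mapq < params$min_mapq

  keep <- !unaligned & !lowmapq
  cls <- classify_pass_reads(
    cbind(tr[keep, c("read_id", "tail", "tail_length"), drop = FALSE],
          aln[keep, c("chrom", "genome_strand", "start", "end"),
              drop = FALSE]),
    genome, rescue_window = params$rescue_window)

  pass <- cls[cls$pass, c("read_id", "chrom", "transcript_strand",
                          "cleavage_pos", "unmappable_t"), drop = FALSE]
  names(pass)[names(pass) == "transcript_strand"] <- "strand"
  pass$library <- lib
  rownames(pass) <- NULL

  report <- c(
    input = nrow(reads),
    trim_no_insert = sum(trim$rejected$reason == "no_insert"),
    trim_short_insert = sum(trim$rejected$reason == "short_insert"),
    unaligned = sum(unaligned),
    low_mapq = sum(lowmapq),
    non_pass_tailless = sum(!cls$pass & cls$reason == "tailless"),
    non_pass_internal_priming = sum(!cls$pass &
                                      cls$reason == "internal_priming"),
    non_pass_insufficient_tail = sum(!cls$pass &
                                       cls$reason == "insufficient_tail"),
    pass = sum(cls$pass))
  list(pass = pass, report = report, library = lib)
}
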