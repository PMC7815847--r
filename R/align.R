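#' Exact-match alignment of an insert against a genome
#'
#' A deliberately simple end-to-end aligner for testing and for the
#' synthetic world, whose inserts are exact genomic substrings: the insert
#' is searched as an exact full-length match on both strands of every
#' contig. A unique hit gets MAPQ 42; multiple hits get MAPQ 0 (and are
#' later removed by the MAPQ filter); no hit returns `NULL`. Real data
#' should instead be aligned externally and ingested with
#' [load_alignments()].
#'
#' @param insert character insert sequence (read orientation).
#' @param genome named character vector or DNAStringSet.
#' @return a list with chrom, genome_strand, start, end (0-based half-open),
#'   mapq, n_hits; or `NULL` if unmatched.
#' @export
naive_align <- function(insert, genome) {
  hits <- align_inserts(insert, genome)
  if (is.na(hits$chrom[1L])) return(NULL)
  as.list(hits[1L, c("chrom", "genome_strand", "start", "end", "mapq",
                     "n_hits")])
}

align_one <- function(ins, dna) {
  hit_chrom <- character(0); hit_strand <- character(0)
  hit_start <- integer(0)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") ins else revcomp(ins)
    mi <- Biostrings::vmatchPattern(pat, dna)
    nh <- S4Vectors::elementNROWS(mi)
    for (ci in which(nh > 0)) {
      ir <- mi[[ci]]
      hit_chrom <- c(hit_chrom, rep(names(dna)[ci], length(ir)))
      hit_strand <- c(hit_strand, rep(strand, length(ir)))
      hit_start <- c(hit_start, IRanges::start(ir) - 1L)
    }
  }
  n_hits <- length(hit_start)
  if (n_hits == 0) {
    data.frame(chrom = NA_character_, genome_strand = NA_character_,
               start = NA_integer_, end = NA_integer_, mapq = NA_integer_,
               n_hits = 0L, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = hit_chrom[1L], genome_strand = hit_strand[1L],
               start = hit_start[1L], end = hit_start[1L] + nchar(ins),
               mapq = if (n_hits == 1L) 42L else 0L,
               n_hits = n_hits, stringsAsFactors = FALSE)
  }
}

#' Align many inserts by exact match (vectorised, memoised)
#'
#' @param inserts character vector of insert sequences.
#' @param genome named character vector or DNAStringSet.
#' @param cache optional environment; alignment results are memoised there
#'   by insert sequence so repeated libraries over the same genome reuse
#'   work.
#' @return data.frame with one row per input insert: chrom, genome_strand,
#'   start, end, mapq, n_hits (`NA` chrom when the insert is absent from the
#'   genome).
#' @export
align_inserts <- function(inserts, genome, cache = NULL) {
  empty <- data.frame(chrom = character(0), genome_strand = character(0),
                      start = integer(0), end = integer(0), mapq = integer(0),
                      n_hits = integer(0), stringsAsFactors = FALSE)
  if (length(inserts) == 0) return(empty)
  dna <- if (is(genome, "DNAStringSet")) genome else
    Biostrings::DNAStringSet(as_genome_chars(genome))
  if (is.null(names(dna)) || any(names(dna) == "")) {
    stop("genome contigs must be named")
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  uq <- unique(inserts)
  todo <- uq[!vapply(uq, exists, logical(1), envir = cache, inherits = FALSE)]
  for (ins in todo) assign(ins, align_one(ins, dna), envir = cache)
  rows_uq <- do.call(rbind, lapply(uq, get, envir = cache, inherits = FALSE))
  rows <- rows_uq[match(inserts, uq), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
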