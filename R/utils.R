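#' @importFrom stats rbinom rlnorm runif setNames dbinom binom.test fisher.test
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' works on plain character vectors.
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Complement without reversal, for per-base strand flips.
complement_chars <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# Normalise a genome argument (named character vector or DNAStringSet) to a
# named character vector of uppercase contig sequences.
as_genome_chars <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("genome must be a named character vector or a DNAStringSet")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("genome contigs must be named")
  }
  out
}

# Extract genome substring, 0-based half-open [start, end), clipped to the
# contig. Returns "" when the clipped interval is empty.
genome_substr <- function(genome, chrom, start, end) {
  seqs <- genome[chrom]
  if (anyNA(seqs)) {
    stop("unknown contig: ", paste(unique(chrom[is.na(seqs)]), collapse = ", "))
  }
  len <- nchar(seqs)
  s <- pmax(start, 0L)
  e <- pmin(end, len)
  out <- character(length(s))
  ok <- s < e
  out[ok] <- substr(seqs[ok], s[ok] + 1L, e[ok])
  out
}

# Sense-strand sequence of [start, end) for a transcript on `strand`.
sense_substr <- function(genome, chrom, start, end, strand) {
  fwd <- genome_substr(genome, chrom, start, end)
  out <- fwd
  neg <- rep_len(strand == "-", length(fwd))
  if (any(neg)) out[neg] <- revcomp(fwd[neg])
  out
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("parameter '", name, "' must be a single number", call. = FALSE)
  }
  if (x < min || x > max) {
    stop("parameter '", name, "' must be in [", min, ", ", max, "], got ", x,
         call. = FALSE)
  }
  if (integer && x != as.integer(x)) {
    stop("parameter '", name, "' must be an integer, got ", x, call. = FALSE)
  }
  invisible(x)
}

# Deterministic per-library seed derived from a base seed; kept well below
# .Machine$integer.max for small base seeds.
derive_seed <- function(seed, condition_index, replicate_index, salt = 0L) {
  (as.integer(seed) %% 100000L) * 10000L +
    1009L * as.integer(condition_index) +
    101L * as.integer(replicate_index) + as.integer(salt)
}

random_dna <- function(n_char) {
  if (n_char <= 0) return("")
  paste(sample(DNA_BASES, n_char, replace = TRUE), collapse = "")
}

# n random fixed-width DNA strings, vectorised.
random_dna_vec <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
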