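#' Trim a raw 3'-end-seq read and extract its T-tail
#'
#' Removes `umi_length` leading bases as the UMI, then consumes the maximal
#' leading run of T's, allowing at most one embedded non-T base provided at
#' least one T follows it. The remaining bases are the insert; reads whose
#' insert is shorter than `min_insert` are rejected.
#'
#' @param read a list or one-row data.frame with `read_id` and `sequence`
#'   (and optionally `quality`).
#' @param umi_length nt removed from the read start.
#' @param min_insert minimum retained insert length (nt).
#' @return a list: either `status = "ok"` with fields `read_id`, `umi`,
#'   `tail_length`, `tail_non_t_offset` (0 = tail base adjacent to the
#'   insert; `NA` if the tail is all T), `insert`; or `status = "rejected"`
#'   with a `reason` of `"no_insert"` or `"short_insert"`.
#' @export
trim_and_extract_tail <- function(read, umi_length = 4, min_insert = 22) {
  df <- data.frame(read_id = read$read_id, sequence = read$sequence,
                   stringsAsFactors = FALSE)
  res <- trim_reads(df, umi_length = umi_length, min_insert = min_insert)
  if (nrow(res$trimmed) == 1L) {
    c(list(status = "ok"), as.list(res$trimmed[1L, ]))
  } else {
    list(status = "rejected", read_id = res$rejected$read_id[1L],
         reason = res$rejected$reason[1L])
  }
}

#' Trim a batch of reads (vectorised)
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @inheritParams trim_and_extract_tail
#' @return list with `trimmed` (read_id, umi, tail_length,
#'   tail_non_t_offset, insert) and `rejected` (read_id, reason).
#' @export
trim_reads <- function(reads, umi_length = 4, min_insert = 22) {
  stopifnot_scalar_number(umi_length, "umi_length", min = 0, integer = TRUE)
  stopifnot_scalar_number(min_insert, "min_insert", min = 1, integer = TRUE)
  seqs <- toupper(reads$sequence)
  if (any(nchar(seqs) == 0)) stop("empty read sequence")
  n <- length(seqs)
  no_insert <- nchar(seqs) < umi_length

  umi <- substr(seqs, 1L, umi_length)
  rest <- substr(seqs, umi_length + 1L, nchar(seqs))

  # maximal leading T-run with at most one embedded non-T followed by a T
  m <- regexpr("^T*(?:[ACGN]T+)?", rest, perl = TRUE)
  tl <- attr(m, "match.length")
  tl[no_insert] <- 0L
  tail_seq <- substr(rest, 1L, tl)
  insert <- substr(rest, tl + 1L, nchar(rest))

  nt <- regexpr("[^T]", tail_seq)
  offset <- ifelse(nt > 0, tl - as.integer(nt), NA_integer_)

  short <- !no_insert & nchar(insert) < min_insert
  keep <- !no_insert & !short
  list(
    trimmed = data.frame(
      read_id = reads$read_id[keep],
      umi = umi[keep],
      tail_length = tl[keep],
      tail = tail_seq[keep],
      tail_non_t_offset = offset[keep],
      insert = insert[keep],
      stringsAsFactors = FALSE),
    rejected = data.frame(
      read_id = reads$read_id[!keep],
      reason = ifelse(no_insert[!keep], "no_insert", "short_insert"),
      stringsAsFactors = FALSE))
}
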