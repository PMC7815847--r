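reads_gr <- function(read_positions) {
  GenomicRanges::GRanges(
    seqnames = read_positions$chrom,
    ranges = IRanges::IRanges(start = read_positions$start + 1L,
                              end = read_positions$end),
    strand = read_positions$strand)
}

#' Strand-specific RNA-seq window counts around poly(A) sites
#'
#' For each site, counts reads overlapping the validation window
#' `[position - w, position + w]` (w = `window_halfwidth`), plus two
#' disjoint w-wide flanks in transcript orientation: the upstream flank
#' ends at (and includes) the cleavage base, the downstream flank starts
#' immediately after it. A read counts toward a window when its half-open
#' interval overlaps it; only reads on the site's transcript strand count.
#' Replicates of a condition are expected pooled in `read_positions`.
#'
#' @param read_positions data.frame chrom, strand, start, end (0-based
#'   half-open), optionally `condition`; rows without a condition column
#'   are treated as one unnamed condition.
#' @param sites site table.
#' @param params a [pa_params()].
#' @return data.frame site_id, condition, window_count, upstream_count,
#'   downstream_count.
#' @export
count_site_windows <- function(read_positions, sites, params = pa_params()) {
  w <- params$window_halfwidth
  if (is.null(read_positions$condition)) {
    read_positions$condition <- rep("all", nrow(read_positions))
  }
  if (nrow(read_positions) == 0) {
    return(data.frame(site_id = sites$site_id,
                      condition = rep("all", nrow(sites)),
                      window_count = integer(nrow(sites)),
                      upstream_count = integer(nrow(sites)),
                      downstream_count = integer(nrow(sites)),
                      stringsAsFactors = FALSE))
  }
  plus <- sites$strand == "+"
  win <- function(start, end) {
    GenomicRanges::GRanges(seqnames = sites$chrom,
                           ranges = IRanges::IRanges(start = start + 1L,
                                                     end = end),
                           strand = sites$strand)
  }
  p <- sites$position
  # whole validation window [pos - w, pos + w] inclusive
  g_window <- win(p - w, p + w + 1L)
  # upstream flank: w bases ending at the cleavage base, transcript sense
  g_up <- win(ifelse(plus, p - w + 1L, p), ifelse(plus, p + 1L, p + w))
  # downstream flank: w bases starting after the cleavage base
  g_dn <- win(ifelse(plus, p + 1L, p - w), ifelse(plus, p + w + 1L, p))

  out <- lapply(split(read_positions, read_positions$condition),
                function(rp) {
    gr <- reads_gr(rp)
    data.frame(site_id = sites$site_id, condition = rp$condition[1],
               window_count = GenomicRanges::countOverlaps(g_window, gr),
               upstream_count = GenomicRanges::countOverlaps(g_up, gr),
               downstream_count = GenomicRanges::countOverlaps(g_dn, gr),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(site_id = character(0), condition = character(0),
                      window_count = integer(0), upstream_count = integer(0),
                      downstream_count = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Per-site window log2 fold change
#'
#' `log2((B * s + pseudocount) / (A + pseudocount))` where `s` scales B to
#' A's library size (total mapped reads).
#'
#' @param counts_a,counts_b numeric window counts, aligned per site.
#' @param pseudocount added to both counts.
#' @param lib_size_a,lib_size_b total mapped reads of each library; equal
#'   by default.
#' @return numeric vector of log2 fold changes.
#' @export
window_log2fc <- function(counts_a, counts_b, pseudocount = 1,
                          lib_size_a = 1, lib_size_b = 1) {
  sf <- lib_size_a / lib_size_b
  log2((counts_b * sf + pseudocount) / (counts_a + pseudocount))
}

#' Gene-level RNA-seq counts by union-exon overlap
#'
#' A read counts toward a gene when it overlaps any exon of the gene on the
#' matching strand; reads overlapping exons of two or more genes are
#' discarded as ambiguous.
#'
#' @param read_positions data.frame chrom, strand, start, end, optionally
#'   `condition`.
#' @param models feature data.frame.
#' @return data.frame gene_id, condition, count (zero rows included for
#'   genes without reads).
#' @export
gene_counts <- function(read_positions, models) {
  ex <- models[models$type == "exon", , drop = FALSE]
  genes <- unique(models$gene_id)
  if (is.null(read_positions$condition)) {
    read_positions$condition <- rep("all", nrow(read_positions))
  }
  conds <- unique(read_positions$condition)
  if (length(conds) == 0) conds <- "all"
  base <- expand.grid(gene_id = genes, condition = conds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$count <- 0
  if (nrow(read_positions) == 0 || nrow(ex) == 0) return(base)
  gr_ex <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  gr_rd <- reads_gr(read_positions)
  hits <- GenomicRanges::findOverlaps(gr_rd, gr_ex)
  qh <- S4Vectors::queryHits(hits)
  gene_hit <- ex$gene_id[S4Vectors::subjectHits(hits)]
  ngenes <- tapply(gene_hit, qh, function(g) length(unique(g)))
  uniq_reads <- as.integer(names(ngenes)[ngenes == 1L])
  gene_of <- tapply(gene_hit, qh, `[`, 1L)[as.character(uniq_reads)]
  cond_of <- read_positions$condition[uniq_reads]
  if (length(uniq_reads) > 0) {
    tab <- table(paste(gene_of, cond_of, sep = "\r"))
    key <- paste(base$gene_id, base$condition, sep = "\r")
    add <- as.integer(tab[key])
    base$count <- ifelse(is.na(add), 0L, add)
  }
  base
}
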