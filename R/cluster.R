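#' Cluster PASS-read cleavage positions into poly(A) sites
#'
#' Single-linkage clustering per contig and transcript strand: sorted
#' cleavage positions are chained while consecutive gaps are at most
#' `merge_window` nt. The representative position of a cluster is the
#' position carrying the most reads (the mode); ties break toward the
#' 5'-most position in transcript orientation. Per-library counts are
#' summed over the cluster.
#'
#' @param pass_reads data.frame with chrom, strand, cleavage_pos, library
#'   (e.g. pooled `pass` tables from [process_threads_library()]).
#' @param merge_window nt.
#' @return site table: site_id, chrom, strand, position, cluster_start,
#'   cluster_end (0-based half-open span of observed positions), n_total,
#'   and one `n_<library>` column per library; ordered by (chrom, position,
#'   strand).
#' @export
cluster_ends <- function(pass_reads, merge_window = 24) {
  libs <- sort(unique(pass_reads$library))
  empty <- data.frame(site_id = character(0), chrom = character(0),
                      strand = character(0), position = integer(0),
                      cluster_start = integer(0), cluster_end = integer(0),
                      n_total = numeric(0), stringsAsFactors = FALSE)
  for (l in libs) empty[[paste0("n_", l)]] <- numeric(0)
  if (nrow(pass_reads) == 0) return(empty)

  # collapse to per-position, per-library counts
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(pass_reads))),
    by = list(chrom = pass_reads$chrom, strand = pass_reads$strand,
              cleavage_pos = pass_reads$cleavage_pos,
              library = pass_reads$library),
    FUN = sum)

  out <- list()
  for (grp in split(agg, paste(agg$chrom, agg$strand))) {
    pos_tot <- rowsum(grp$count, grp$cleavage_pos)
    positions <- as.integer(rownames(pos_tot))
    ord <- order(positions)
    positions <- positions[ord]
    totals <- pos_tot[ord, 1]
    cl <- cumsum(c(1L, as.integer(diff(positions) > merge_window)))
    strand <- grp$strand[1L]
    for (ci in unique(cl)) {
      sel <- cl == ci
      p <- positions[sel]; tt <- totals[sel]
      best <- which(tt == max(tt))
      rep_pos <- if (strand == "+") p[best[1L]] else p[best[length(best)]]
      row <- data.frame(chrom = grp$chrom[1L], strand = strand,
                        position = rep_pos,
                        cluster_start = min(p), cluster_end = max(p) + 1L,
                        n_total = sum(tt), stringsAsFactors = FALSE)
      in_cl <- grp$cleavage_pos %in% p
      libcnt <- rowsum(grp$count[in_cl], grp$library[in_cl])
      for (l in libs) {
        row[[paste0("n_", l)]] <-
          if (l %in% rownames(libcnt)) libcnt[l, 1] else 0
      }
      out[[length(out) + 1L]] <- row
    }
  }
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$chrom, sites$position, sites$strand), ,
                 drop = FALSE]
  sites <- cbind(site_id = sprintf("PAS%05d", seq_len(nrow(sites))), sites,
                 stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  sites
}

# names of count columns and their library labels
count_cols <- function(sites) {
  cols <- grep("^n_(.+_r[0-9]+)$", names(sites), value = TRUE)
  setNames(cols, sub("^n_", "", cols))
}

# parse library labels "<condition>_r<rep>" into a data.frame
parse_libraries <- function(labels) {
  m <- regmatches(labels, regexec("^(.*)_r([0-9]+)$", labels))
  bad <- lengths(m) != 3
  if (any(bad)) stop("unparseable library label: ", labels[bad][1])
  data.frame(library = labels,
             condition = vapply(m, `[`, character(1), 2L),
             replicate = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}
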