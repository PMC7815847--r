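# --- gene-model helpers ------------------------------------------------------

#' Gene spans and derived introns
#'
#' The span of a gene is `[min exon start, max exon end)`; introns are the
#' gaps between its sorted exons.
#'
#' @param models feature data.frame (see [build_toy_world()] /
#'   [read_models_gtf()]).
#' @return data.frame gene_id, chrom, strand, start, end.
#' @export
gene_spans <- function(models) {
  ex <- models[models$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' @rdname gene_spans
#' @return `gene_introns()` returns data.frame gene_id, chrom, strand,
#'   start, end, one row per intron.
#' @export
gene_introns <- function(models) {
  ex <- models[models$type == "exon", , drop = FALSE]
  out <- lapply(split(ex, ex$gene_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1],
               start = g$end[-nrow(g)], end = g$start[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[out$start < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

sites_gr <- function(sites, stranded = TRUE) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position + 1L, width = 1L),
    strand = if (stranded) sites$strand else "*")
}

intervals_gr <- function(df, stranded = FALSE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (stranded && !is.null(df$strand)) df$strand else "*")
}

# --- exclusion intervals -----------------------------------------------------

#' Remove sites falling in exclusion intervals
#'
#' A site is flagged (and removed) when its representative cleavage base
#' lies in any interval of any exclusion set (blacklist, retrotransposons,
#' miRNA, snoRNA, ...). Overlap is strand-agnostic and half-open on the
#' single-base site interval; a site hit by several sets records all their
#' labels but is removed once.
#'
#' @param sites site table from [cluster_ends()].
#' @param interval_sets a data.frame (chrom, start, end, label) or a list of
#'   them, e.g. from [read_bed_intervals()].
#' @return list with `sites` (retained), `removed` (site_id, reason =
#'   comma-joined labels) and `by_label` (named hit counts).
#' @export
apply_exclusion_filters <- function(sites, interval_sets) {
  if (is.data.frame(interval_sets)) interval_sets <- list(interval_sets)
  iv <- do.call(rbind, interval_sets)
  if (is.null(iv) || nrow(iv) == 0 || nrow(sites) == 0) {
    return(list(sites = sites,
                removed = data.frame(site_id = character(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE),
                by_label = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(sites_gr(sites, stranded = FALSE),
                                      intervals_gr(iv),
                                      ignore.strand = TRUE)
  lab_by_site <- split(iv$label[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
  flagged <- as.integer(names(lab_by_site))
  reason <- vapply(lab_by_site, function(l) paste(sort(unique(l)),
                                                  collapse = ","),
                   character(1))
  keep <- setdiff(seq_len(nrow(sites)), flagged)
  list(
    sites = sites[keep, , drop = FALSE],
    removed = data.frame(site_id = sites$site_id[flagged], reason = reason,
                         stringsAsFactors = FALSE),
    by_label = table(iv$label[S4Vectors::subjectHits(hits)]))
}

# --- gene assignment ---------------------------------------------------------

#' Assign each site to a gene
#'
#' A site is assigned by overlap of its cleavage base with strand-matched
#' gene spans: no overlap removes it as intergenic, overlap with two or more
#' genes removes it as multi-gene, a single overlap assigns the gene.
#'
#' @param sites site table.
#' @param models feature data.frame.
#' @return list with `sites` (retained, with `gene_id`) and `removed`
#'   (site_id, reason in "intergenic" / "multiple_genes").
#' @export
assign_genes <- function(sites, models) {
  spans <- gene_spans(models)
  ng <- integer(nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  if (nrow(sites) > 0 && nrow(spans) > 0) {
    hits <- GenomicRanges::findOverlaps(sites_gr(sites),
                                        intervals_gr(spans, stranded = TRUE))
    qh <- S4Vectors::queryHits(hits)
    tab <- table(qh)
    ng[as.integer(names(tab))] <- as.integer(tab)
    single <- as.integer(names(tab)[tab == 1L])
    gene[single] <- spans$gene_id[S4Vectors::subjectHits(hits)[
      match(single, qh)]]
  }
  keep <- ng == 1L
  out <- sites[keep, , drop = FALSE]
  out$gene_id <- gene[keep]
  list(sites = out,
       removed = data.frame(
         site_id = sites$site_id[!keep],
         reason = ifelse(ng[!keep] == 0L, "intergenic", "multiple_genes"),
         stringsAsFactors = FALSE))
}

# --- category annotation -----------------------------------------------------

#' Annotate site categories with intron priority
#'
#' A site inside any intron of its gene is an intron site, regardless of
#' overlapping UTR annotation of sibling transcripts; otherwise a site in
#' the 3'UTR is a utr3 site; anything else inside the gene is an exon site.
#'
#' @param sites site table with `gene_id`.
#' @param models feature data.frame.
#' @return `sites` with a `category` column.
#' @export
annotate_category <- function(sites, models) {
  if (nrow(sites) == 0) {
    sites$category <- character(0)
    return(sites)
  }
  gr <- sites_gr(sites)
  in_set <- function(iv) {
    res <- logical(nrow(sites))
    if (nrow(iv) == 0) return(res)
    hits <- GenomicRanges::findOverlaps(gr, intervals_gr(iv, stranded = TRUE))
    same_gene <- sites$gene_id[S4Vectors::queryHits(hits)] ==
      iv$gene_id[S4Vectors::subjectHits(hits)]
    res[unique(S4Vectors::queryHits(hits)[same_gene])] <- TRUE
    res
  }
  in_intron <- in_set(gene_introns(models))
  in_utr3 <- in_set(models[models$type == "utr3", , drop = FALSE])
  spans <- gene_spans(models)
  span_idx <- match(sites$gene_id, spans$gene_id)
  inside <- !is.na(span_idx) & sites$position >= spans$start[span_idx] &
    sites$position < spans$end[span_idx]
  if (any(!inside)) {
    stop("site outside its assigned gene span: ",
         sites$site_id[!inside][1], " (annotation defect)")
  }
  sites$category <- ifelse(in_intron, "intron",
                           ifelse(in_utr3, "utr3", "exon"))
  sites
}

#' Re-annotate sole sites of single-site genes as 3'UTR
#'
#' A gene represented by exactly one retained site almost always uses its
#' canonical 3'UTR site, so that site's category is set to utr3 regardless
#' of its interval-derived label. Idempotent.
#'
#' @param sites site table with `gene_id` and `category`.
#' @return `sites` with adjusted categories; attribute `"adjusted_from"`
#'   holds the count of adjustments split by prior category.
#' @export
reannotate_single_site_genes <- function(sites) {
  if (nrow(sites) == 0) {
    attr(sites, "adjusted_from") <- integer(0)
    return(sites)
  }
  n_by_gene <- table(sites$gene_id)
  lone <- sites$gene_id %in% names(n_by_gene)[n_by_gene == 1L]
  adjust <- lone & sites$category != "utr3"
  adjusted_from <- table(sites$category[adjust])
  sites$category[adjust] <- "utr3"
  attr(sites, "adjusted_from") <- adjusted_from
  sites
}

#' Remove sites ambiguous between overlapping genes
#'
#' A retained site whose position is covered by the spans of two or more
#' genes in the full (pre-filter) annotation cannot be attributed
#' unambiguously, even when only one of those genes survived earlier
#' filters, and is removed.
#'
#' @param sites site table with `gene_id`.
#' @param models_full the complete feature annotation.
#' @return list with `sites` and `removed` (reason "ambiguous_overlap").
#' @export
remove_ambiguous_overlaps <- function(sites, models_full) {
  spans <- gene_spans(models_full)
  ng <- integer(nrow(sites))
  if (nrow(sites) > 0 && nrow(spans) > 0) {
    hits <- GenomicRanges::findOverlaps(sites_gr(sites),
                                        intervals_gr(spans, stranded = TRUE))
    tab <- table(S4Vectors::queryHits(hits))
    ng[as.integer(names(tab))] <- as.integer(tab)
  }
  keep <- ng < 2L
  list(sites = sites[keep, , drop = FALSE],
       removed = data.frame(site_id = sites$site_id[!keep],
                            reason = rep("ambiguous_overlap", sum(!keep)),
                            stringsAsFactors = FALSE))
}

# --- robustness filters ------------------------------------------------------

#' Expression and robustness filters on sites
#'
#' Retains sites that pass all of: (1) the host gene is expressed (RNA-seq
#' count at least `min_gene_rnaseq` in at least one condition; genes absent
#' from the RNA-seq table count 0), (2) the summed 3'-end-seq counts over
#' the replicates of at least one condition reach `min_replicate_sum`, and
#' (3) the fraction of poly(A)-site usage reaches `min_fpu` in at least one
#' library. A site failing several criteria is booked under the first.
#'
#' @param sites site table with `gene_id` and per-library counts.
#' @param rnaseq_gene_counts data.frame gene_id, condition, count.
#' @param params a [pa_params()].
#' @return list with `sites`, `removed` (site_id, reason in
#'   "gene_not_expressed" / "low_replicate_sum" / "low_fpu") and
#'   `missing_genes` (gene ids absent from the RNA-seq table).
#' @export
apply_robustness_filters <- function(sites, rnaseq_gene_counts,
                                     params = pa_params()) {
  empty_removed <- data.frame(site_id = character(0), reason = character(0),
                              stringsAsFactors = FALSE)
  if (nrow(sites) == 0) {
    return(list(sites = sites, removed = empty_removed,
                missing_genes = character(0)))
  }
  # (1) gene expression
  gmax <- tapply(rnaseq_gene_counts$count, rnaseq_gene_counts$gene_id, max)
  gene_expr <- unname(gmax[sites$gene_id])
  missing <- unique(sites$gene_id[is.na(gene_expr)])
  gene_expr[is.na(gene_expr)] <- 0
  ok1 <- gene_expr >= params$min_gene_rnaseq

  # (2) replicate-sum per condition
  cc <- count_cols(sites)
  libinfo <- parse_libraries(names(cc))
  cond_sum <- sapply(unique(libinfo$condition), function(cd) {
    cols <- cc[libinfo$condition == cd]
    rowSums(sites[, cols, drop = FALSE])
  })
  cond_sum <- matrix(cond_sum, nrow = nrow(sites))
  ok2 <- apply(cond_sum, 1L, max) >= params$min_replicate_sum

  # (3) FPU in at least one library
  fpu <- compute_fpu(sites)
  fmax <- tapply(fpu$fpu, fpu$site_id, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  fmax <- unname(fmax[sites$site_id])
  ok3 <- !is.na(fmax) & fmax >= params$min_fpu

  keep <- ok1 & ok2 & ok3
  reason <- ifelse(!ok1, "gene_not_expressed",
                   ifelse(!ok2, "low_replicate_sum", "low_fpu"))
  list(sites = sites[keep, , drop = FALSE],
       removed = data.frame(site_id = sites$site_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE),
       missing_genes = missing)
}

# --- poly(A) signal scan -----------------------------------------------------

#' Scan sites for the AATAAA polyadenylation signal
#'
#' Extracts transcript-sense sequence around each site
#' (`position +/- motif_extension`, clipped at contig ends), counts the
#' sites whose 40 bp immediately upstream of the cleavage base contain
#' AATAAA, and reports a one-sided binomial enrichment p-value against the
#' chance hit rate of a random hexamer in a window of that length under the
#' observed base composition.
#'
#' @param sites site table.
#' @param genome named character vector or DNAStringSet.
#' @param params a [pa_params()].
#' @return list with `fraction` (NA when there are no sites), `p_value`,
#'   `n_sites`, `n_hits`, `null_rate`.
#' @export
hexamer_scan <- function(sites, genome, params = pa_params()) {
  if (nrow(sites) == 0) {
    return(list(fraction = NA_real_, p_value = 1, n_sites = 0L, n_hits = 0L,
                null_rate = NA_real_))
  }
  genome <- as_genome_chars(genome)
  ext <- params$motif_extension
  plus <- sites$strand == "+"
  ctx <- character(nrow(sites))
  up40 <- character(nrow(sites))
  if (any(plus)) {
    ctx[plus] <- genome_substr(genome, sites$chrom[plus],
                               sites$position[plus] - ext,
                               sites$position[plus] + ext + 1L)
    up40[plus] <- genome_substr(genome, sites$chrom[plus],
                                sites$position[plus] - 40L,
                                sites$position[plus])
  }
  if (any(!plus)) {
    ctx[!plus] <- sense_substr(genome, sites$chrom[!plus],
                               sites$position[!plus] - ext,
                               sites$position[!plus] + ext + 1L, "-")
    up40[!plus] <- sense_substr(genome, sites$chrom[!plus],
                                sites$position[!plus] + 1L,
                                sites$position[!plus] + 41L, "-")
  }
  hit <- grepl("AATAAA", up40, fixed = TRUE)

  comp <- table(factor(strsplit(paste(ctx, collapse = ""), "")[[1]],
                       levels = DNA_BASES))
  freq <- comp / sum(comp)
  p_hex <- unname(freq["A"]^5 * freq["T"])
  win_positions <- max(nchar(up40)) - 5L
  null_rate <- 1 - (1 - p_hex)^max(win_positions, 0L)
  pv <- stats::binom.test(sum(hit), length(hit), p = null_rate,
                          alternative = "greater")$p.value
  list(fraction = mean(hit), p_value = pv, n_sites = nrow(sites),
       n_hits = sum(hit), null_rate = null_rate)
}
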