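#' Compute the fraction of poly(A)-site usage (FPU)
#'
#' Per library, a site's FPU is its read count divided by the summed counts
#' of all sites of the same gene. Because it is a within-gene fraction, FPU
#' is internally normalised within each library and comparable across
#' libraries without depth scaling. Genes with zero total in a library
#' yield `NA` for all their sites in that library.
#'
#' @param sites site table with `gene_id` and per-library `n_<library>`
#'   count columns.
#' @return long data.frame: site_id, gene_id, library, condition, replicate,
#'   count, gene_total, fpu.
#' @export
compute_fpu <- function(sites) {
  cc <- count_cols(sites)
  if (nrow(sites) > 0 && length(cc) == 0) {
    stop("no per-library count columns (n_<condition>_r<rep>) found")
  }
  libinfo <- parse_libraries(names(cc))
  out <- lapply(seq_along(cc), function(i) {
    cnt <- sites[[cc[i]]]
    if (any(cnt < 0)) stop("negative counts in column ", cc[i])
    gt <- tapply(cnt, sites$gene_id, sum)[sites$gene_id]
    data.frame(site_id = sites$site_id, gene_id = sites$gene_id,
               library = libinfo$library[i],
               condition = libinfo$condition[i],
               replicate = libinfo$replicate[i],
               count = cnt, gene_total = as.numeric(gt),
               fpu = ifelse(gt > 0, cnt / gt, NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(site_id = character(0), gene_id = character(0),
               library = character(0), condition = character(0),
               replicate = integer(0), count = numeric(0),
               gene_total = numeric(0), fpu = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Differential poly(A)-site usage between two conditions
#'
#' The operative statistic is the FPU fold change: mean FPU across the
#' replicates of condition B (epsilon-floored) over condition A. As the
#' accompanying significance measure, a two-sided Fisher exact test is run
#' on the 2x2 table of pooled site counts versus pooled rest-of-gene counts
#' in the two conditions.
#'
#' @param records FPU records from [compute_fpu()].
#' @param cond_a,cond_b condition names; fold changes are B over A.
#' @param epsilon floor added to mean FPUs before the ratio.
#' @return data.frame per site: site_id, gene_id, mean_fpu_a, mean_fpu_b,
#'   fc_threads, p_value, direction ("up" = higher usage in B),
#'   one_condition (gene silent in one condition's libraries).
#' @export
differential_site_usage <- function(records, cond_a, cond_b,
                                    epsilon = 1e-4) {
  for (cd in c(cond_a, cond_b)) {
    if (!cd %in% records$condition) stop("condition absent: ", cd)
  }
  a <- records[records$condition == cond_a, , drop = FALSE]
  b <- records[records$condition == cond_b, , drop = FALSE]
  ids <- unique(records$site_id)
  agg <- function(x, f, v) {
    r <- tapply(x[[v]], x$site_id, f)
    as.numeric(r[ids])
  }
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  ma <- agg(a, mean_na, "fpu"); mb <- agg(b, mean_na, "fpu")
  sa <- agg(a, sum, "count"); sb <- agg(b, sum, "count")
  ga <- agg(a, sum, "gene_total"); gb <- agg(b, sum, "gene_total")
  one_cond <- is.na(ma) | is.na(mb)
  ma0 <- ifelse(is.na(ma), 0, ma); mb0 <- ifelse(is.na(mb), 0, mb)
  fc <- (mb0 + epsilon) / (ma0 + epsilon)
  pv <- vapply(seq_along(ids), function(i) {
    m <- matrix(c(sa[i], ga[i] - sa[i], sb[i], gb[i] - sb[i]), nrow = 2)
    if (any(is.na(m)) || any(m < 0) || sum(m) == 0) return(NA_real_)
    stats::fisher.test(round(m))$p.value
  }, numeric(1))
  gid <- records$gene_id[match(ids, records$site_id)]
  data.frame(site_id = ids, gene_id = gid,
             mean_fpu_a = ma, mean_fpu_b = mb,
             fc_threads = fc, p_value = pv,
             direction = ifelse(fc >= 1, "up", "down"),
             one_condition = one_cond, stringsAsFactors = FALSE)
}

#' Call differentially used intronic poly(A) sites
#'
#' A site is called when it is intronic, its 3'-end-seq FPU fold change
#' reaches `fc_ipa_threads` (in either direction), the RNA-seq window fold
#' change at the site reaches `fc_rnaseq` in the same direction, and the
#' RNA-seq flank counts of the higher-usage condition show more reads
#' upstream than downstream of the site. Per-criterion booleans are
#' retained for reporting. Sites without window counts are marked
#' unevaluable and excluded (counted in the `"n_unevaluable"` attribute).
#'
#' @param diff output of [differential_site_usage()].
#' @param sites site table with `category` (and the same site ids).
#' @param windows window counts from [count_site_windows()], pooled per
#'   condition, for both conditions.
#' @param params a [pa_params()].
#' @param cond_a,cond_b condition names (B over A, matching `diff`).
#' @param lib_sizes optional named vector of total mapped RNA-seq reads per
#'   condition, used to depth-scale window counts before the fold change;
#'   equal sizes assumed when omitted.
#' @return data.frame of calls with fold changes, per-criterion flags
#'   (crit_intron, crit_threads, crit_rnaseq, crit_updown), upstream/
#'   downstream counts, direction, and `passed`.
#' @export
call_differential_ipa <- function(diff, sites, windows, params = pa_params(),
                                  cond_a, cond_b, lib_sizes = NULL) {
  wa <- windows[windows$condition == cond_a, , drop = FALSE]
  wb <- windows[windows$condition == cond_b, , drop = FALSE]
  ia <- match(diff$site_id, wa$site_id)
  ib <- match(diff$site_id, wb$site_id)
  unevaluable <- is.na(ia) | is.na(ib)

  sf <- 1
  if (!is.null(lib_sizes)) sf <- lib_sizes[[cond_a]] / lib_sizes[[cond_b]]
  ps <- params$pseudocount
  fc_rnaseq <- (wb$window_count[ib] * sf + ps) / (wa$window_count[ia] + ps)

  cat_ <- sites$category[match(diff$site_id, sites$site_id)]
  up <- diff$fc_threads >= 1
  hi_up <- ifelse(up, wb$upstream_count[ib], wa$upstream_count[ia])
  hi_dn <- ifelse(up, wb$downstream_count[ib], wa$downstream_count[ia])

  crit_intron <- !is.na(cat_) & cat_ == "intron"
  crit_threads <- diff$fc_threads >= params$fc_ipa_threads |
    diff$fc_threads <= 1 / params$fc_ipa_threads
  crit_rnaseq <- ifelse(up, fc_rnaseq >= params$fc_rnaseq,
                        fc_rnaseq <= 1 / params$fc_rnaseq)
  crit_updown <- hi_up > hi_dn

  out <- data.frame(
    site_id = diff$site_id, gene_id = diff$gene_id, category = cat_,
    mean_fpu_a = diff$mean_fpu_a, mean_fpu_b = diff$mean_fpu_b,
    fc_threads = diff$fc_threads, p_value = diff$p_value,
    fc_rnaseq = fc_rnaseq, direction = diff$direction,
    upstream_count = hi_up, downstream_count = hi_dn,
    crit_intron = crit_intron, crit_threads = crit_threads,
    crit_rnaseq = crit_rnaseq, crit_updown = crit_updown,
    stringsAsFactors = FALSE)
  out$passed <- crit_intron & crit_threads & crit_rnaseq & crit_updown
  out <- out[!unevaluable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unevaluable") <- sum(unevaluable)
  out
}

#' Intersect differential calls with knockdown response
#'
#' Retains calls whose knockdown-versus-control FPU fold change reaches
#' `fc_cpsf` in the same direction as the differentiation call. Sites
#' missing from the knockdown libraries are excluded and counted.
#'
#' @param calls passed calls from [call_differential_ipa()].
#' @param knockdown_records FPU records of the knockdown experiment
#'   ([compute_fpu()] on the control/knockdown count table).
#' @param params a [pa_params()].
#' @param cond_ctrl,cond_kd condition names of the knockdown contrast.
#' @return the retained subset of `calls`, with `fc_knockdown`; attributes
#'   `"n_missing"` (calls absent from the knockdown data) and
#'   `"n_discordant"`.
#' @export
cpsf_dependence <- function(calls, knockdown_records, params = pa_params(),
                            cond_ctrl = "CTRL", cond_kd = "KD") {
  kd <- differential_site_usage(knockdown_records, cond_ctrl, cond_kd,
                                epsilon = params$epsilon)
  idx <- match(calls$site_id, kd$site_id)
  missing <- is.na(idx)
  fc_kd <- kd$fc_threads[idx]
  same_dir <- (calls$direction == "up" & fc_kd >= params$fc_cpsf) |
    (calls$direction == "down" & fc_kd <= 1 / params$fc_cpsf)
  keep <- !missing & same_dir
  out <- calls[keep, , drop = FALSE]
  out$fc_knockdown <- fc_kd[keep]
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(missing)
  attr(out, "n_discordant") <- sum(!missing & !same_dir)
  out
}

#' 3'UTR distal-usage index
#'
#' For genes with two or more 3'UTR sites, the distal fraction is the
#' pooled count at the 3'-most site divided by the summed 3'UTR counts of
#' the gene, per condition. The fold change of the distal fraction (B over
#' A, epsilon-floored) classifies each gene as lengthened
#' (fc > `fc_distal`), shortened (fc < 1/`fc_distal`) or unchanged.
#'
#' @param sites site table with `gene_id`, `category` and per-library
#'   counts.
#' @param cond_a,cond_b condition names.
#' @param params a [pa_params()].
#' @return data.frame gene_id, n_utr3_sites, distal_site, distal_frac_a,
#'   distal_frac_b, fc, classification; genes with fewer than two 3'UTR
#'   sites are skipped and counted in attribute `"n_skipped"`.
#' @export
distal_usage_index <- function(sites, cond_a, cond_b, params = pa_params()) {
  utr <- sites[sites$category == "utr3", , drop = FALSE]
  cc <- count_cols(sites)
  libinfo <- parse_libraries(names(cc))
  pool <- function(df, cond) {
    cols <- cc[libinfo$condition == cond]
    rowSums(df[, cols, drop = FALSE])
  }
  genes <- split(utr, utr$gene_id)
  n_skipped <- sum(vapply(genes, nrow, integer(1)) < 2)
  rows <- lapply(genes, function(g) {
    if (nrow(g) < 2) return(NULL)
    distal <- if (g$strand[1] == "+") which.max(g$position) else
      which.min(g$position)
    ca <- pool(g, cond_a); cb <- pool(g, cond_b)
    fa <- if (sum(ca) > 0) ca[distal] / sum(ca) else NA_real_
    fb <- if (sum(cb) > 0) cb[distal] / sum(cb) else NA_real_
    eps <- params$epsilon
    fc <- (ifelse(is.na(fb), 0, fb) + eps) / (ifelse(is.na(fa), 0, fa) + eps)
    data.frame(gene_id = g$gene_id[1], n_utr3_sites = nrow(g),
               distal_site = g$site_id[distal],
               distal_frac_a = fa, distal_frac_b = fb, fc = fc,
               classification = if (fc > params$fc_distal) "lengthened"
               else if (fc < 1 / params$fc_distal) "shortened"
               else "unchanged",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_utr3_sites = integer(0),
                      distal_site = character(0), distal_frac_a = numeric(0),
                      distal_frac_b = numeric(0), fc = numeric(0),
                      classification = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Intersect two differential-expression tables
#'
#' Returns the genes passing the fold-change and p-value thresholds in both
#' externally produced tables with consistent direction, plus Venn counts.
#'
#' @param table_a,table_b data.frames with columns gene_id, fold_change,
#'   p_value.
#' @param fc_min minimum fold change (or its reciprocal for downregulation).
#' @param p_max maximum p-value.
#' @return list with `genes`, `n_a`, `n_b`, `n_shared`.
#' @export
intersect_de_lists <- function(table_a, table_b, fc_min = 2, p_max = 0.05) {
  need <- c("gene_id", "fold_change", "p_value")
  for (tb in list(a = table_a, b = table_b)) {
    miss <- setdiff(need, names(tb))
    if (length(miss) > 0) {
      stop("DE table lacks column(s): ", paste(miss, collapse = ", "),
           "; found: ", paste(names(tb), collapse = ", "))
    }
  }
  passes <- function(tb) {
    tb[(tb$fold_change >= fc_min | tb$fold_change <= 1 / fc_min) &
         tb$p_value < p_max, , drop = FALSE]
  }
  pa <- passes(table_a); pb <- passes(table_b)
  shared <- intersect(pa$gene_id, pb$gene_id)
  dir_a <- pa$fold_change[match(shared, pa$gene_id)] >= 1
  dir_b <- pb$fold_change[match(shared, pb$gene_id)] >= 1
  genes <- shared[dir_a == dir_b]
  list(genes = genes, n_a = nrow(pa), n_b = nrow(pb),
       n_shared = length(genes))
}

#' Count PASS reads at an existing site table
#'
#' Assigns each PASS read to the nearest site on the same contig and
#' strand, provided it lies within `window` nt; used to quantify additional
#' libraries (e.g. a knockdown pair) at sites called from the primary
#' contrast.
#'
#' @param sites site table.
#' @param pass_reads PASS reads (chrom, strand, cleavage_pos, library).
#' @param window maximum distance from the representative site position.
#' @return `sites` with one new `n_<library>` column per library in
#'   `pass_reads`.
#' @export
quantify_sites <- function(sites, pass_reads, window = 24) {
  libs <- sort(unique(pass_reads$library))
  for (l in libs) sites[[paste0("n_", l)]] <- 0
  if (nrow(sites) == 0 || nrow(pass_reads) == 0) return(sites)
  key_s <- paste(sites$chrom, sites$strand)
  key_r <- paste(pass_reads$chrom, pass_reads$strand)
  for (k in unique(key_r)) {
    si <- which(key_s == k)
    if (length(si) == 0) next
    ri <- which(key_r == k)
    ord <- order(sites$position[si])
    sp <- sites$position[si][ord]
    pos <- pass_reads$cleavage_pos[ri]
    left <- findInterval(pos, sp)
    dl <- ifelse(left >= 1L, pos - sp[pmax(left, 1L)], Inf)
    du <- ifelse(left < length(sp), sp[pmin(left + 1L, length(sp))] - pos,
                 Inf)
    pick <- ifelse(du < dl, left + 1L, left)
    dist <- pmin(dl, du)
    ok <- dist <= window
    tgt <- si[ord][pick]
    for (l in libs) {
      sel <- ok & pass_reads$library[ri] == l
      if (any(sel)) {
        add <- table(tgt[sel])
        col <- paste0("n_", l)
        idx <- as.integer(names(add))
        sites[[col]][idx] <- sites[[col]][idx] + as.integer(add)
      }
    }
  }
  sites
}
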