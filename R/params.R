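#' Analysis parameter set
#'
#' Single home for every numeric threshold used by the pipeline. Defaults are
#' the values used throughout the package documentation; all are overridable.
#'
#' @param merge_window nt; cleavage positions closer than this are merged into
#'   one poly(A) site by single-linkage clustering.
#' @param min_gene_rnaseq minimum RNA-seq gene count (in at least one
#'   condition) for a gene to count as expressed.
#' @param min_replicate_sum minimum summed 3'-end-seq count across the
#'   replicates of at least one condition for a site to be retained.
#' @param min_fpu minimum fraction of poly(A)-site usage in at least one
#'   library for a site to be retained.
#' @param window_halfwidth bp; half-width of the RNA-seq validation window
#'   around a site, and width of each upstream/downstream flank.
#' @param fc_ipa_threads minimum 3'-end-seq FPU fold change (either direction)
#'   for a differential intronic poly(A) call.
#' @param fc_rnaseq minimum same-direction RNA-seq window fold change for a
#'   differential call.
#' @param fc_cpsf minimum same-direction knockdown FPU fold change for a call
#'   to count as knockdown-dependent.
#' @param fc_distal minimum distal-usage-fraction fold change for a gene to be
#'   classified as 3'UTR lengthened/shortened.
#' @param motif_extension bp extracted on each side of a site for motif
#'   scanning.
#' @param min_mapq minimum mapping quality of retained alignments.
#' @param min_insert nt; reads whose insert is shorter after trimming are
#'   dropped.
#' @param rescue_window bp of genomic sequence downstream of the cleavage site
#'   examined when rescuing tail bases as genome-templated.
#' @param epsilon floor added to usage fractions before forming fold changes.
#' @param pseudocount added to window counts before forming RNA-seq fold
#'   changes.
#' @return a named list of class `ipaseq_params`.
#' @export
pa_params <- function(merge_window = 24,
                      min_gene_rnaseq = 5,
                      min_replicate_sum = 10,
                      min_fpu = 0.10,
                      window_halfwidth = 100,
                      fc_ipa_threads = 2.0,
                      fc_rnaseq = 1.5,
                      fc_cpsf = 1.5,
                      fc_distal = 1.5,
                      motif_extension = 200,
                      min_mapq = 10,
                      min_insert = 22,
                      rescue_window = 20,
                      epsilon = 1e-4,
                      pseudocount = 1) {
  p <- list(merge_window = merge_window,
            min_gene_rnaseq = min_gene_rnaseq,
            min_replicate_sum = min_replicate_sum,
            min_fpu = min_fpu,
            window_halfwidth = window_halfwidth,
            fc_ipa_threads = fc_ipa_threads,
            fc_rnaseq = fc_rnaseq,
            fc_cpsf = fc_cpsf,
            fc_distal = fc_distal,
            motif_extension = motif_extension,
            min_mapq = min_mapq,
            min_insert = min_insert,
            rescue_window = rescue_window,
            epsilon = epsilon,
            pseudocount = pseudocount)
  for (nm in names(p)) stopifnot_scalar_number(p[[nm]], nm, min = 0)
  for (nm in c("merge_window", "min_replicate_sum", "window_halfwidth",
               "fc_ipa_threads", "fc_rnaseq", "fc_cpsf", "fc_distal",
               "motif_extension", "min_insert", "rescue_window")) {
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be positive")
  }
  if (p$min_fpu <= 0 || p$min_fpu > 1) {
    stop("parameter 'min_fpu' must be in (0, 1]")
  }
  structure(p, class = "ipaseq_params")
}
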