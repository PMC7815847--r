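#' Run the full intronic-polyadenylation pipeline
#'
#' Ties the stages together in the fixed order: per-library read processing
#' to PASS reads, single-linkage clustering, exclusion-interval filtering,
#' gene assignment, expression/robustness filtering, category annotation
#' with intron priority, single-site re-annotation, ambiguous-overlap
#' removal, FPU quantification, differential intronic-site calling with
#' RNA-seq window validation, and 3'UTR distal-usage classification.
#'
#' @param libraries named list of read data.frames (read_id, sequence);
#'   names are library labels `<condition>_r<rep>`.
#' @param genome named character vector or DNAStringSet.
#' @param models feature data.frame.
#' @param rnaseq RNA-seq read positions (chrom, strand, start, end) with a
#'   `condition` column, replicates pooled.
#' @param exclusion_sets optional list of interval data.frames
#'   (chrom, start, end, label).
#' @param params a [pa_params()].
#' @param conditions two condition names; fold changes are second over
#'   first.
#' @param umi_length nt of UMI at the read start.
#' @param align_cache optional environment for [align_inserts()] memoising.
#' @return a list of class `ipaseq_run`: `sites` (final table with gene,
#'   category and counts), `fpu`, `diff`, `calls`, `distal`, `hexamer`,
#'   `read_reports` (per library), `stages` (bookkeeping), `params`,
#'   `conditions`.
#' @export
run_ipa_pipeline <- function(libraries, genome, models, rnaseq,
                             exclusion_sets = list(),
                             params = pa_params(),
                             conditions = c("UD", "DF"),
                             umi_length = 4,
                             align_cache = NULL) {
  if (is.null(names(libraries)) || any(names(libraries) == "")) {
    stop("'libraries' must be a named list (<condition>_r<rep>)")
  }
  libconds <- parse_libraries(names(libraries))$condition
  if (!all(conditions %in% libconds)) {
    stop("need libraries for both conditions: ",
         paste(conditions, collapse = ", "))
  }

  read_reports <- list()
  pass_list <- list()
  for (lib in names(libraries)) {
    reads <- libraries[[lib]]
    attr(reads, "library") <- lib
    pr <- process_threads_library(reads, genome, params,
                                  umi_length = umi_length,
                                  align_cache = align_cache)
    read_reports[[lib]] <- pr$report
    pass_list[[lib]] <- pr$pass
  }
  pass <- do.call(rbind, pass_list)

  stages <- list()
  log_stage <- function(name, input, retained, removed) {
    stages[[name]] <<- list(
      input = input, retained = retained,
      removed = if (nrow(removed) > 0) table(removed$reason) else
        integer(0))
  }

  sites <- cluster_ends(pass, merge_window = params$merge_window)
  stages[["clustering"]] <- list(input = nrow(pass), retained = nrow(sites),
                                 removed = integer(0))

  ex <- apply_exclusion_filters(sites, exclusion_sets)
  log_stage("exclusion", nrow(sites), nrow(ex$sites), ex$removed)

  ga <- assign_genes(ex$sites, models)
  log_stage("gene_assignment", nrow(ex$sites), nrow(ga$sites), ga$removed)

  gcounts <- gene_counts(rnaseq, models)
  rf <- apply_robustness_filters(ga$sites, gcounts, params)
  log_stage("robustness", nrow(ga$sites), nrow(rf$sites), rf$removed)

  ann <- annotate_category(rf$sites, models)
  ann <- reannotate_single_site_genes(ann)

  am <- remove_ambiguous_overlaps(ann, models)
  log_stage("ambiguous_overlap", nrow(ann), nrow(am$sites), am$removed)
  final <- am$sites

  fpu <- compute_fpu(final)
  diff <- differential_site_usage(fpu, conditions[1], conditions[2],
                                  epsilon = params$epsilon)
  windows <- count_site_windows(rnaseq, final, params)
  calls <- call_differential_ipa(diff, final, windows, params,
                                 cond_a = conditions[1],
                                 cond_b = conditions[2])
  distal <- distal_usage_index(final, conditions[1], conditions[2], params)
  hex <- hexamer_scan(final, genome, params)

  structure(list(sites = final, fpu = fpu, diff = diff, windows = windows,
                 calls = calls, distal = distal, hexamer = hex,
                 read_reports = read_reports, stages = stages,
                 params = params, conditions = conditions,
                 adjusted_from = attr(ann, "adjusted_from")),
            class = "ipaseq_run")
}

#' Summarise a pipeline run
#'
#' Machine-readable bookkeeping of a run: partition counts of every read
#' and site stage, per-category site counts, differential-call counts split
#' by direction with recomputed percentages, distal-usage class counts, and
#' the thresholds applied.
#'
#' @param run an `ipaseq_run` from [run_ipa_pipeline()].
#' @return a nested list, JSON-ready.
#' @export
summarize_run <- function(run) {
  sites <- run$sites
  calls <- run$calls[run$calls$passed, , drop = FALSE]
  n_up <- sum(calls$direction == "up")
  n_dn <- sum(calls$direction == "down")
  n_calls <- nrow(calls)
  pct <- function(k, n) if (n > 0) round(100 * k / n, 1) else NA_real_
  complete <- nrow(sites) > 0
  list(
    complete = complete,
    reads = lapply(run$read_reports, as.list),
    stages = lapply(run$stages, function(s) {
      list(input = s$input, retained = s$retained,
           removed = as.list(s$removed))
    }),
    sites = list(
      total = nrow(sites),
      by_category = as.list(table(sites$category)),
      genes = length(unique(sites$gene_id)),
      single_site_reannotated = as.list(run$adjusted_from %||% integer(0))),
    differential_ipa = list(
      total = n_calls, up = n_up, down = n_dn,
      pct_up = pct(n_up, n_calls), pct_down = pct(n_dn, n_calls),
      unevaluable = attr(run$calls, "n_unevaluable") %||% 0L),
    distal_usage = list(
      eligible_genes = nrow(run$distal),
      by_class = as.list(table(run$distal$classification)),
      skipped_single_site = attr(run$distal, "n_skipped") %||% 0L),
    hexamer = run$hexamer[c("fraction", "p_value", "n_sites", "n_hits")],
    params = unclass(run$params),
    conditions = run$conditions)
}

#' Write the run report and stage tables to disk
#'
#' Emits `summary.json` plus deterministic TSV/BED artifacts: the final
#' site table, FPU matrix, differential calls with per-criterion flags,
#' distal-usage table and site BED.
#'
#' @param run an `ipaseq_run`.
#' @param dir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summarize_run(run)
  jsonlite::write_json(s, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  ord <- order(run$sites$chrom, run$sites$position, run$sites$strand)
  write_tsv(run$sites[ord, , drop = FALSE], file.path(dir, "sites.tsv"))
  write_sites_bed(run$sites[ord, , drop = FALSE],
                  file.path(dir, "sites.bed"))
  write_tsv(run$fpu, file.path(dir, "fpu.tsv"))
  write_tsv(run$calls, file.path(dir, "differential_ipa.tsv"))
  write_tsv(run$distal, file.path(dir, "distal_usage.tsv"))
  invisible(s)
}
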