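# Shared small synthetic world used across test files. Built once per test
# run; 40 genes x 8,000 reads keeps each file fast while leaving every gene
# class (intronic site, two 3'UTR sites, planted shifts) represented.

tw_config <- function(...) {
  sim_config(n_genes = 40, reads_per_library = 8000, seed = 101, ...)
}

.tw_env <- new.env(parent = emptyenv())

toy_world <- function() {
  if (is.null(.tw_env$world)) .tw_env$world <- build_toy_world(tw_config())
  .tw_env$world
}

toy_libraries <- function() {
  if (is.null(.tw_env$libs)) {
    w <- toy_world()
    cfg <- tw_config()
    libs <- list()
    for (cd in c("UD", "DF")) {
      for (r in 1:2) {
        libs[[paste0(cd, "_r", r)]] <-
          simulate_threads_library(w$genome, w$truth, cd, cfg, r)
      }
    }
    .tw_env$libs <- libs
  }
  .tw_env$libs
}

toy_rnaseq <- function(depth = 40000) {
  if (is.null(.tw_env$rna)) {
    w <- toy_world()
    rna <- NULL
    for (cd in c("UD", "DF")) {
      rp <- simulate_rnaseq_library(w$models, w$truth, cd, depth,
                                    seed = 500 + match(cd, c("UD", "DF")))
      rp$condition <- cd
      rna <- rbind(rna, rp)
    }
    .tw_env$rna <- rna
  }
  .tw_env$rna
}

.tw_cache <- new.env(parent = emptyenv())

toy_run <- function() {
  if (is.null(.tw_env$run)) {
    w <- toy_world()
    .tw_env$run <- run_ipa_pipeline(toy_libraries(), w$genome, w$models,
                                    toy_rnaseq(), align_cache = .tw_cache)
  }
  .tw_env$run
}

# distance from each truth site to the nearest called site on the same
# contig and strand (NA when none exists)
truth_match_dist <- function(sites, truth_sites) {
  vapply(seq_len(nrow(truth_sites)), function(i) {
    sel <- sites$chrom == truth_sites$chrom[i] &
      sites$strand == truth_sites$strand[i]
    if (!any(sel)) return(NA_real_)
    min(abs(sites$position[sel] - truth_sites$cleavage_pos[i]))
  }, numeric(1))
}

# independent single-linkage oracle used by the clustering tests
brute_force_clusters <- function(positions, window = 24) {
  positions <- sort(unique(positions))
  if (length(positions) == 0) return(list())
  groups <- list(positions[1])
  for (p in positions[-1]) {
    last <- groups[[length(groups)]]
    if (p - max(last) <= window) {
      groups[[length(groups)]] <- c(last, p)
    } else {
      groups[[length(groups) + 1]] <- p
    }
  }
  groups
}

# minimal PASS-read table builder
pass_df <- function(pos, strand = "+", lib = "UD_r1", chrom = "chr1") {
  n <- length(pos)
  data.frame(read_id = sprintf("r%d", seq_len(n)),
             chrom = rep_len(chrom, n), strand = rep_len(strand, n),
             cleavage_pos = pos, library = rep_len(lib, n),
             stringsAsFactors = FALSE)
}

# site table builder for unit tests: positions/categories/counts supplied
# directly, count columns named n_<cond>_r<rep>
make_sites <- function(gene_id, position, strand = "+", category = NULL,
                       chrom = "chr1", counts = list()) {
  n <- length(position)
  df <- data.frame(site_id = sprintf("S%03d", seq_len(n)),
                   chrom = rep_len(chrom, n), strand = rep_len(strand, n),
                   position = position,
                   gene_id = rep_len(gene_id, n), stringsAsFactors = FALSE)
  if (!is.null(category)) df$category <- category
  for (nm in names(counts)) df[[paste0("n_", nm)]] <- counts[[nm]]
  df
}
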