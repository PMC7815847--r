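#' Simulator configuration
#'
#' Parameters of the synthetic two-condition 3'-end-sequencing experiment.
#' The defaults describe the study design the package's end-to-end tests run
#' under: 200 three-exon genes, two conditions ("UD" undifferentiated-like
#' reference, "DF" differentiated-like contrast), two replicates per
#' condition, 50,000 reads per library.
#'
#' @param n_genes number of simulated genes.
#' @param gene_length_range bp; total gene length is drawn uniformly from
#'   this interval.
#' @param replicates_per_condition replicates per condition.
#' @param reads_per_library 3'-end-seq reads emitted per library.
#' @param tail_length_distribution probabilities over residual poly(A)-tail
#'   lengths 2..30 nt (read-borne T's). Default: 2 + Binomial(28, 0.25),
#'   mean 9 nt.
#' @param non_t_error_prob probability that a simulated tail carries one
#'   non-T base (never at the insert-adjacent terminal position).
#' @param internal_priming_fraction fraction of reads generated at
#'   internal-priming decoy positions over genomic A-runs.
#' @param umi_length nt of random unique molecular identifier at the read
#'   start.
#' @param insert_length nt of transcript sequence (reverse-complemented) at
#'   the read end; must be at least 22 so planted reads survive the
#'   length filter.
#' @param seed integer; every random draw of the world and of each library is
#'   derived from it.
#' @param conditions two condition names; fold changes are reported as
#'   second over first.
#' @param frac_ipa_genes fraction of genes carrying one intronic site (in
#'   intron 1) in addition to their 3'UTR site(s).
#' @param frac_two_utr3 fraction of genes with two 3'UTR sites
#'   (proximal + distal).
#' @param frac_ipa_differential fraction of intronic sites whose usage
#'   changes between conditions.
#' @param ipa_usage_high,ipa_usage_low usage fractions of a differential
#'   intronic site in its high and low condition (default 0.6 vs 0.2, a
#'   3-fold usage change).
#' @param ipa_usage_flat usage of non-differential intronic sites.
#' @param frac_utr3_shift fraction of two-3'UTR-site genes whose distal
#'   usage shifts between conditions.
#' @param utr3_distal_high,utr3_distal_low distal share of the 3'UTR mass in
#'   the shifted high/low condition (non-shifted genes use 0.5).
#' @param knockdown if `TRUE`, two additional conditions "CTRL" and "KD" are
#'   planted: CTRL mirrors the first condition; in KD a fraction
#'   `frac_kd_responsive` of the differential intronic sites shift in the
#'   same direction as in the second condition.
#' @param frac_kd_responsive see `knockdown`.
#' @param n_decoys number of internal-priming decoy positions (half plus,
#'   half minus strand) planted over 30-nt genomic A-runs.
#' @param n_contigs number of contigs the genes are distributed over.
#' @param spacer_length bp of random intergenic sequence between planted
#'   units.
#' @return a validated list of class `ipaseq_sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       gene_length_range = c(1500, 2700),
                       replicates_per_condition = 2,
                       reads_per_library = 50000,
                       tail_length_distribution = dbinom(0:28, 28, 0.25),
                       non_t_error_prob = 0.1,
                       internal_priming_fraction = 0.05,
                       umi_length = 4,
                       insert_length = 40,
                       seed = 1,
                       conditions = c("UD", "DF"),
                       frac_ipa_genes = 0.5,
                       frac_two_utr3 = 0.5,
                       frac_ipa_differential = 0.4,
                       ipa_usage_high = 0.6,
                       ipa_usage_low = 0.2,
                       ipa_usage_flat = 0.3,
                       frac_utr3_shift = 0.3,
                       utr3_distal_high = 0.7,
                       utr3_distal_low = 0.3,
                       knockdown = FALSE,
                       frac_kd_responsive = 0.4,
                       n_decoys = 40,
                       n_contigs = 4,
                       spacer_length = 300) {
  cfg <- as.list(environment())
  stopifnot_scalar_number(n_genes, "n_genes", min = 0, integer = TRUE)
  if (!is.numeric(gene_length_range) || length(gene_length_range) != 2L ||
      gene_length_range[1] > gene_length_range[2] ||
      gene_length_range[1] < 600) {
    stop("parameter 'gene_length_range' must be an increasing bp interval with lower bound >= 600")
  }
  stopifnot_scalar_number(replicates_per_condition, "replicates_per_condition",
                          min = 1, integer = TRUE)
  stopifnot_scalar_number(reads_per_library, "reads_per_library", min = 0,
                          integer = TRUE)
  if (!is.numeric(tail_length_distribution) ||
      length(tail_length_distribution) != 29L ||
      any(tail_length_distribution < 0) ||
      sum(tail_length_distribution) <= 0) {
    stop("parameter 'tail_length_distribution' must be 29 non-negative weights over tail lengths 2..30")
  }
  for (nm in c("non_t_error_prob", "internal_priming_fraction",
               "frac_ipa_genes", "frac_two_utr3", "frac_ipa_differential",
               "ipa_usage_high", "ipa_usage_low", "ipa_usage_flat",
               "frac_utr3_shift", "utr3_distal_high", "utr3_distal_low",
               "frac_kd_responsive")) {
    stopifnot_scalar_number(cfg[[nm]], nm, min = 0, max = 1)
  }
  stopifnot_scalar_number(umi_length, "umi_length", min = 0, integer = TRUE)
  stopifnot_scalar_number(insert_length, "insert_length", min = 22,
                          integer = TRUE)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  stopifnot_scalar_number(n_decoys, "n_decoys", min = 0, integer = TRUE)
  stopifnot_scalar_number(n_contigs, "n_contigs", min = 1, integer = TRUE)
  stopifnot_scalar_number(spacer_length, "spacer_length", min = 50,
                          integer = TRUE)
  if (length(conditions) != 2L || anyDuplicated(conditions) ||
      any(grepl("[^A-Za-z0-9]", conditions))) {
    stop("parameter 'conditions' must be two distinct alphanumeric names")
  }
  cfg$tail_length_distribution <-
    tail_length_distribution / sum(tail_length_distribution)
  structure(cfg, class = "ipaseq_sim_config")
}

DECOY_RUN_LENGTH <- 30L
DECOY_FLANK <- 60L

#' Build a toy genome with planted poly(A) sites
#'
#' Generates a random genome, three-exon gene models, a ground-truth set of
#' cleavage sites with per-condition usage fractions, and internal-priming
#' decoy positions sitting immediately upstream of 30-nt genomic A-runs.
#' Every planted site has the AATAAA hexamer planted 12-40 bp upstream in
#' transcript orientation. Fully deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with elements `genome` (named character vector of contig
#'   sequences), `models` (feature data.frame: gene_id, chrom, strand, type
#'   in {exon, utr3}, start, end, 0-based half-open, exon_rank in transcript
#'   order), and `truth` (class `ipaseq_truth`: `sites`, `decoys`,
#'   `gene_expression`, `conditions`).
#' @export
build_toy_world <- function(config = sim_config()) {
  if (!inherits(config, "ipaseq_sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_genes
  conds <- config$conditions
  if (config$knockdown) conds <- c(conds, "CTRL", "KD")

  # --- per-gene structure in sense coordinates -------------------------------
  L <- if (n > 0) {
    round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
  } else integer(0)
  # intron 1 is kept wide so that an intronic site and its +/- flanking
  # validation windows fit inside it without touching neighbouring exons
  e1 <- round(0.12 * L); i1 <- round(0.30 * L)
  e2 <- round(0.08 * L); i2 <- round(0.10 * L)
  e3 <- L - e1 - i1 - e2 - i2
  u3 <- round(0.60 * e3)

  has_ipa  <- runif(n) < config$frac_ipa_genes
  two_utr3 <- runif(n) < config$frac_two_utr3
  ipa_diff <- has_ipa & runif(n) < config$frac_ipa_differential
  ipa_down <- runif(n) < 0.5   # differential direction: usage lower in cond 2
  u3_shift <- two_utr3 & runif(n) < config$frac_utr3_shift
  u3_longer <- runif(n) < 0.5  # shift direction: distal share up in cond 2

  gene_ids <- sprintf("g%04d", seq_len(n))
  strands <- rep(c("+", "-"), length.out = n)

  # sense-coordinate site positions
  pos_distal <- L - sample(15:60, n, replace = TRUE)
  pos_prox <- pos_distal - sample(80:200, n, replace = TRUE)
  ipa_margin <- pmax(40L, pmin(160L, i1 %/% 3L))
  pos_ipa <- e1 + ipa_margin +
    vapply(pmax(i1 - 2L * ipa_margin, 1L), function(w) sample.int(w, 1L),
           integer(1))

  # --- gene sense sequences with planted hexamers ----------------------------
  build_gene_seq <- function(g) {
    s <- random_dna(L[g])
    sites <- c(pos_distal[g],
               if (two_utr3[g]) pos_prox[g],
               if (has_ipa[g]) pos_ipa[g])
    for (p in sites) {
      d <- sample(12:40, 1)
      substr(s, p - d + 1L, p - d + 6L) <- "AATAAA"
      # keep the base immediately downstream of the cleavage site non-A so
      # the planted coordinate stays identifiable under tail rescue
      if (p + 2L <= L[g] && substr(s, p + 2L, p + 2L) == "A") {
        substr(s, p + 2L, p + 2L) <- "C"
      }
    }
    s
  }
  gene_seq <- vapply(seq_len(n), build_gene_seq, character(1))

  # --- decoy blocks ----------------------------------------------------------
  nd <- config$n_decoys
  decoy_strand <- rep(c("+", "-"), length.out = nd)
  decoy_seq <- vapply(seq_len(nd), function(i) {
    paste0(random_dna(DECOY_FLANK), strrep("A", DECOY_RUN_LENGTH),
           random_dna(DECOY_FLANK))
  }, character(1))

  # --- assemble contigs ------------------------------------------------------
  contigs <- sprintf("chr%d", seq_len(config$n_contigs))
  units <- data.frame(
    kind = c(rep("gene", n), rep("decoy", nd)),
    idx = c(seq_len(n), seq_len(nd)),
    stringsAsFactors = FALSE)
  if (nrow(units) > 0) {
    units <- units[sample.int(nrow(units)), , drop = FALSE]
    units$contig <- rep(contigs, length.out = nrow(units))
  } else {
    units$contig <- character(0)
  }

  offsets <- integer(nrow(units))
  genome <- setNames(character(length(contigs)), contigs)
  for (ct in contigs) {
    sel <- which(units$contig == ct)
    pieces <- character(0)
    at <- 0L
    for (k in sel) {
      spacer <- random_dna(config$spacer_length)
      piece <- if (units$kind[k] == "gene") {
        g <- units$idx[k]
        if (strands[g] == "+") gene_seq[g] else revcomp(gene_seq[g])
      } else {
        i <- units$idx[k]
        if (decoy_strand[i] == "+") decoy_seq[i] else revcomp(decoy_seq[i])
      }
      offsets[k] <- at + config$spacer_length
      at <- at + config$spacer_length + nchar(piece)
      pieces <- c(pieces, spacer, piece)
    }
    genome[ct] <- paste0(paste(pieces, collapse = ""),
                         random_dna(config$spacer_length))
  }

  gene_offset <- gene_chrom <- NULL
  if (n > 0) {
    gi <- units$kind == "gene"
    ord <- order(units$idx[gi])
    gene_offset <- offsets[gi][ord]
    gene_chrom <- units$contig[gi][ord]
  }

  # sense coordinate -> genomic 0-based
  g2g <- function(g, p) {
    if (strands[g] == "+") gene_offset[g] + p else gene_offset[g] + L[g] - 1L - p
  }
  # sense half-open interval [a, b) -> genomic half-open
  iv2g <- function(g, a, b) {
    if (strands[g] == "+") c(gene_offset[g] + a, gene_offset[g] + b)
    else c(gene_offset[g] + L[g] - b, gene_offset[g] + L[g] - a)
  }

  # --- gene models -----------------------------------------------------------
  models_list <- vector("list", n)
  for (g in seq_len(n)) {
    sense_feats <- list(
      c(0L, e1[g], 1L), c(e1[g] + i1[g], e1[g] + i1[g] + e2[g], 2L),
      c(L[g] - e3[g], L[g], 3L))
    rows <- lapply(sense_feats, function(f) {
      iv <- iv2g(g, f[1], f[2])
      data.frame(gene_id = gene_ids[g], chrom = gene_chrom[g],
                 strand = strands[g], type = "exon",
                 start = iv[1], end = iv[2], exon_rank = f[3],
                 stringsAsFactors = FALSE)
    })
    uiv <- iv2g(g, L[g] - u3[g], L[g])
    rows <- c(rows, list(data.frame(gene_id = gene_ids[g],
                                    chrom = gene_chrom[g],
                                    strand = strands[g], type = "utr3",
                                    start = uiv[1], end = uiv[2],
                                    exon_rank = NA_integer_,
                                    stringsAsFactors = FALSE)))
    models_list[[g]] <- do.call(rbind, rows)
  }
  models <- if (n > 0) do.call(rbind, models_list) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), type = character(0),
               start = integer(0), end = integer(0),
               exon_rank = integer(0), stringsAsFactors = FALSE)

  # --- truth sites with usage fractions --------------------------------------
  site_rows <- list()
  for (g in seq_len(n)) {
    u_ipa <- if (!has_ipa[g]) setNames(rep(0, length(conds)), conds) else {
      base <- if (!ipa_diff[g]) {
        setNames(rep(config$ipa_usage_flat, 2), config$conditions)
      } else if (ipa_down[g]) {
        setNames(c(config$ipa_usage_high, config$ipa_usage_low),
                 config$conditions)
      } else {
        setNames(c(config$ipa_usage_low, config$ipa_usage_high),
                 config$conditions)
      }
      out <- base
      if (config$knockdown) {
        kd_resp <- ipa_diff[g] && runif(1) < config$frac_kd_responsive
        out <- c(base, CTRL = unname(base[1]),
                 KD = unname(if (kd_resp) base[2] else base[1]))
      }
      out[conds]
    }
    rest <- 1 - u_ipa
    distal_share <- if (!two_utr3[g]) setNames(rep(1, length(conds)), conds)
    else if (!u3_shift[g]) setNames(rep(0.5, length(conds)), conds)
    else {
      sh <- if (u3_longer[g]) c(config$utr3_distal_low, config$utr3_distal_high)
            else c(config$utr3_distal_high, config$utr3_distal_low)
      out <- setNames(sh, config$conditions)
      if (config$knockdown) out <- c(out, CTRL = out[[1]], KD = out[[1]])
      out[conds]
    }

    add_site <- function(p, category, usage) {
      df <- data.frame(gene_id = gene_ids[g], chrom = gene_chrom[g],
                       strand = strands[g], cleavage_pos = g2g(g, p),
                       category = category, stringsAsFactors = FALSE)
      for (cd in conds) df[[paste0("usage_", cd)]] <- unname(usage[cd])
      df
    }
    site_rows <- c(site_rows,
                   list(add_site(pos_distal[g], "utr3", rest * distal_share)),
                   if (two_utr3[g])
                     list(add_site(pos_prox[g], "utr3",
                                   rest * (1 - distal_share))),
                   if (has_ipa[g]) list(add_site(pos_ipa[g], "intron", u_ipa)))
  }
  sites <- if (length(site_rows) > 0) do.call(rbind, site_rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), cleavage_pos = integer(0),
               category = character(0), stringsAsFactors = FALSE)
  if (nrow(sites) > 0) {
    sites$site_id <- sprintf("ts%04d", seq_len(nrow(sites)))
    sites <- sites[, c("site_id", setdiff(names(sites), "site_id"))]
  } else {
    sites$site_id <- character(0)
    for (cd in conds) sites[[paste0("usage_", cd)]] <- numeric(0)
  }

  # --- decoy coordinates -----------------------------------------------------
  if (nd > 0) {
    di <- units$kind == "decoy"
    ordd <- order(units$idx[di])
    d_off <- offsets[di][ordd]
    d_chrom <- units$contig[di][ordd]
    block_len <- 2L * DECOY_FLANK + DECOY_RUN_LENGTH
    d_pos <- ifelse(decoy_strand == "+",
                    d_off + DECOY_FLANK - 1L,          # last base before A-run
                    d_off + block_len - DECOY_FLANK)   # first base after T-run
    decoys <- data.frame(chrom = d_chrom, strand = decoy_strand,
                         position = d_pos, stringsAsFactors = FALSE)
  } else {
    decoys <- data.frame(chrom = character(0), strand = character(0),
                         position = integer(0), stringsAsFactors = FALSE)
  }

  expr <- if (n > 0) {
    a <- rlnorm(n, meanlog = 0, sdlog = 0.7)
    a / sum(a)
  } else numeric(0)
  gene_expression <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (cd in conds) gene_expression[[paste0("abundance_", cd)]] <- expr

  truth <- structure(list(sites = sites, decoys = decoys,
                          gene_expression = gene_expression,
                          conditions = conds),
                     class = "ipaseq_truth")
  list(genome = genome, models = models, truth = truth)
}

usage_col <- function(condition) paste0("usage_", condition)

# insert sequence (read orientation) for cleavage at `pos` on `strand`:
# reverse complement of the `len` transcript bases ending at the cleavage
# site. For minus-strand transcripts this is simply the plus-strand genomic
# sequence starting at pos.
site_insert <- function(genome, chrom, pos, strand, len) {
  plus <- strand == "+"
  out <- character(length(pos))
  if (any(plus)) {
    out[plus] <- revcomp(genome_substr(genome, chrom[plus],
                                       pos[plus] - len + 1L, pos[plus] + 1L))
  }
  if (any(!plus)) {
    out[!plus] <- genome_substr(genome, chrom[!plus], pos[!plus],
                                pos[!plus] + len)
  }
  out
}

#' Simulate one 3'-end-sequencing library
#'
#' Emits reads laid out as UMI + residual T-tail + reverse complement of the
#' transcript 3' end. Site choice is multinomial over gene abundance times
#' per-condition usage fraction; a configurable fraction of reads is instead
#' generated at internal-priming decoy positions with tails fully templated
#' by the downstream genomic A-run. A tail carries at most one non-T base,
#' never at its insert-adjacent terminal position.
#'
#' @param genome,truth from [build_toy_world()].
#' @param condition condition name present in the truth set.
#' @param config the [sim_config()] used to build the world.
#' @param replicate_index 1-based replicate number (enters the derived seed).
#' @return data.frame with columns read_id, sequence, quality (phred+33,
#'   constant "I"); attribute `"library"` holds the library label
#'   `<condition>_r<replicate>`.
#' @export
simulate_threads_library <- function(genome, truth, condition, config,
                                     replicate_index = 1) {
  genome <- as_genome_chars(genome)
  if (!condition %in% truth$conditions) {
    stop("unknown condition '", condition, "'; truth has: ",
         paste(truth$conditions, collapse = ", "))
  }
  lib <- paste0(condition, "_r", replicate_index)
  n <- config$reads_per_library
  empty <- data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE)
  attr(empty, "library") <- lib
  if (n == 0) return(empty)

  set.seed(derive_seed(config$seed, match(condition, truth$conditions),
                       replicate_index, salt = 1L))
  sites <- truth$sites
  nd_avail <- nrow(truth$decoys)
  n_decoy <- if (nd_avail > 0) round(n * config$internal_priming_fraction) else 0L
  n_true <- n - n_decoy

  expr <- truth$gene_expression[[paste0("abundance_", condition)]]
  names(expr) <- truth$gene_expression$gene_id
  w <- expr[sites$gene_id] * sites[[usage_col(condition)]]

  rows <- list()
  if (n_true > 0 && nrow(sites) > 0 && sum(w) > 0) {
    pick <- sample.int(nrow(sites), n_true, replace = TRUE, prob = w)
    len <- sample(2:30, n_true, replace = TRUE,
                  prob = config$tail_length_distribution)
    tails <- strrep("T", len)
    err <- runif(n_true) < config$non_t_error_prob & len >= 2
    if (any(err)) {
      # error offset counted from the insert-adjacent end; never offset 0
      off <- 1L + floor(runif(sum(err)) * (len[err] - 1L))
      idx <- len[err] - off  # 1-based index in read orientation
      bad <- sample(c("A", "C", "G"), sum(err), replace = TRUE)
      te <- tails[err]
      substr(te, idx, idx) <- bad
      tails[err] <- te
    }
    ins_by_site <- site_insert(genome, sites$chrom, sites$cleavage_pos,
                               sites$strand, config$insert_length)
    rows$true <- data.frame(
      origin = sites$site_id[pick],
      tail = tails,
      insert = ins_by_site[pick],
      stringsAsFactors = FALSE)
  }
  if (n_decoy > 0) {
    dk <- sample.int(nd_avail, n_decoy, replace = TRUE)
    dlen <- pmin(sample(2:30, n_decoy, replace = TRUE,
                        prob = config$tail_length_distribution),
                 DECOY_RUN_LENGTH)
    dins <- site_insert(genome, truth$decoys$chrom, truth$decoys$position,
                        truth$decoys$strand, config$insert_length)
    rows$decoy <- data.frame(
      origin = sprintf("decoy%03d", dk),
      tail = strrep("T", dlen),
      insert = dins[dk],
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, rows)
  if (is.null(reads) || nrow(reads) == 0) return(empty)
  umi <- random_dna_vec(nrow(reads), config$umi_length)
  seqs <- paste0(umi, reads$tail, reads$insert)
  out <- data.frame(
    read_id = sprintf("%s:%07d:%s", lib, seq_len(nrow(reads)), reads$origin),
    sequence = seqs,
    quality = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE)
  attr(out, "library") <- lib
  out
}

# Genomic blocks of the isoform terminating at each truth site: all exonic
# sequence upstream of the cleavage site plus, for intronic sites, the
# retained intron portion up to the cleavage position.
isoform_blocks <- function(models, truth) {
  sites <- truth$sites
  out <- vector("list", nrow(sites))
  ex_all <- models[models$type == "exon", , drop = FALSE]
  for (i in seq_len(nrow(sites))) {
    gid <- sites$gene_id[i]
    ex <- ex_all[ex_all$gene_id == gid, , drop = FALSE]
    strand <- sites$strand[i]
    # order exons in transcript (sense) direction
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    pos <- sites$cleavage_pos[i]
    blocks <- list()
    for (k in seq_len(nrow(ex))) {
      s <- ex$start[k]; e <- ex$end[k]
      inside <- pos >= s && pos < e
      if (inside) {
        if (strand == "+") e <- pos + 1L else s <- pos
        blocks[[length(blocks) + 1L]] <- c(s, e)
        break
      }
      upstream_exon <- if (strand == "+") e <= pos else s > pos
      if (!upstream_exon) {
        # cleavage lies in the intron preceding this exon: retain intron
        prev_e <- blocks[[length(blocks)]]
        if (strand == "+") {
          blocks[[length(blocks) + 1L]] <- c(prev_e[2], pos + 1L)
        } else {
          blocks[[length(blocks) + 1L]] <- c(pos, prev_e[1])
        }
        break
      }
      blocks[[length(blocks) + 1L]] <- c(s, e)
    }
    bm <- do.call(rbind, blocks)
    out[[i]] <- data.frame(site_id = sites$site_id[i], gene_id = gid,
                           chrom = sites$chrom[i], strand = strand,
                           start = bm[, 1], end = bm[, 2],
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(site_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Simulate a strand-specific RNA-seq library
#'
#' Draws single-end read positions uniformly (per base) along the expressed
#' isoforms of every gene. Each planted cleavage site defines one isoform
#' that terminates there (intronic isoforms retain intron sequence up to the
#' cleavage position); isoform weights are gene abundance times usage
#' fraction, so coverage drops downstream of a used site.
#'
#' @param models,truth from [build_toy_world()].
#' @param condition condition name present in the truth set.
#' @param n_reads number of read positions to draw.
#' @param seed integer seed.
#' @param read_length bp; reads are truncated at isoform block boundaries.
#' @return data.frame with columns chrom, strand, start, end (0-based
#'   half-open) and gene_id.
#' @export
simulate_rnaseq_library <- function(models, truth, condition, n_reads,
                                    seed = 1, read_length = 50) {
  stopifnot_scalar_number(n_reads, "n_reads", min = 0, integer = TRUE)
  if (!condition %in% truth$conditions) {
    stop("unknown condition '", condition, "'")
  }
  empty <- data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  if (n_reads == 0 || nrow(truth$sites) == 0) return(empty)
  set.seed(as.integer(seed))
  blocks <- isoform_blocks(models, truth)
  expr <- truth$gene_expression[[paste0("abundance_", condition)]]
  names(expr) <- truth$gene_expression$gene_id
  usage <- truth$sites[[usage_col(condition)]]
  names(usage) <- truth$sites$site_id
  wt <- expr[blocks$gene_id] * usage[blocks$site_id] *
    (blocks$end - blocks$start)
  if (sum(wt) <= 0) return(empty)
  pick <- sample.int(nrow(blocks), n_reads, replace = TRUE, prob = wt)
  b <- blocks[pick, , drop = FALSE]
  start <- b$start + floor(runif(n_reads) * (b$end - b$start))
  end <- pmin(start + read_length, b$end)
  data.frame(chrom = b$chrom, strand = b$strand, start = as.integer(start),
             end = as.integer(end), gene_id = b$gene_id,
             stringsAsFactors = FALSE)
}
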