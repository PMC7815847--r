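test_that("tail trimming follows the single-mismatch scanning rule", {
  ins30 <- paste0("ACGCA", strrep("GACCA", 5))  # 30 nt, starts non-T
  r <- function(seq) list(read_id = "r1", sequence = seq)

  # plain tail: UMI + 5 T + insert
  t1 <- trim_and_extract_tail(r(paste0("ACGT", "TTTTT", ins30)),
                              umi_length = 4, min_insert = 22)
  expect_equal(t1$status, "ok")
  expect_equal(t1$umi, "ACGT")
  expect_equal(t1$tail_length, 5)
  expect_true(is.na(t1$tail_non_t_offset))
  expect_equal(t1$insert, ins30)

  # one embedded non-T followed by T's is part of the tail
  t2 <- trim_and_extract_tail(r(paste0("ACGT", "TTATT", ins30)))
  expect_equal(t2$tail_length, 5)
  expect_equal(t2$tail, "TTATT")
  expect_equal(t2$tail_non_t_offset, 2)  # 0 = insert-adjacent base
  expect_equal(t2$insert, ins30)

  # a non-T not followed by a T ends the tail and stays in the insert
  t3 <- trim_and_extract_tail(r(paste0("ACGT", "TTT", "A", ins30)))
  expect_equal(t3$tail_length, 3)
  expect_equal(t3$insert, paste0("A", ins30))

  # a second non-T ends the tail
  t4 <- trim_and_extract_tail(r(paste0("ACGT", "TTATTA", ins30)))
  expect_equal(t4$tail, "TTATT")
  expect_equal(t4$insert, paste0("A", ins30))

  # short insert after trimming is rejected
  t5 <- trim_and_extract_tail(r(paste0("ACGT", "TTTTT", "ACGCAGGGCA")))
  expect_equal(t5$status, "rejected")
  expect_equal(t5$reason, "short_insert")
  t6 <- trim_and_extract_tail(r("ACG"), umi_length = 4)
  expect_equal(t6$reason, "no_insert")

  # tailless read is retained with tail_length 0
  t7 <- trim_and_extract_tail(r(paste0("ACGT", ins30)))
  expect_equal(t7$status, "ok")
  expect_equal(t7$tail_length, 0)
})

test_that("exact aligner reports strand, coordinates and multiplicity", {
  core <- "GATTACACCGGTTAACCGGATCCGATCCA"  # 29 nt unique
  dup <- "TTGACCATGGACCATGGACCTTG"        # planted twice
  genome <- c(chrA = paste0("CCGCA", core, "AAGGC", dup, "CCTA"),
              chrB = paste0("GGTAC", dup, "TTACG"))

  # insert equal to the reverse complement of a unique substring
  hit <- naive_align(revcomp(core), genome)
  expect_equal(hit$genome_strand, "-")
  expect_equal(hit$chrom, "chrA")
  expect_equal(hit$start, 5)
  expect_equal(hit$end, 5 + nchar(core))
  expect_equal(hit$mapq, 42)

  # duplicated insert maps with mapq 0
  multi <- naive_align(dup, genome)
  expect_equal(multi$mapq, 0)
  expect_equal(multi$n_hits, 2)

  # absent insert
  expect_null(naive_align(strrep("ACGTC", 6), genome))
})

test_that("SAM ingestion applies the MAPQ and mapped-only filters", {
  sam <- tempfile(fileext = ".sam")
  seq10 <- "ACGTACGTAC"
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:1000",
    paste("keep10", 0, "chr1", 101, 10, "10M", "*", 0, 0, seq10, "*",
          sep = "\t"),
    paste("drop9", 16, "chr1", 201, 9, "10M", "*", 0, 0, seq10, "*",
          sep = "\t"),
    paste("unmapped", 4, "*", 0, 0, "*", "*", 0, 0, seq10, "*", sep = "\t")),
    sam)
  aln <- load_alignments(sam, min_mapq = 10)
  expect_equal(aln$read_id, "keep10")
  expect_equal(aln$start, 100)  # 0-based
  expect_equal(aln$end, 110)
  expect_equal(attr(aln, "n_low_mapq"), 1)

  # empty file with valid header
  sam2 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000"), sam2)
  expect_equal(nrow(load_alignments(sam2)), 0)
})

test_that("tail rescue against downstream genomic A-runs is exact", {
  # plus-strand transcript: insert aligned on the genome minus strand
  left <- "CCATG"
  ins <- "GGATCCGATTACAGGCATTACCGGAAT"  # 27 nt
  mk_genome <- function(downstream) {
    c(chrT = paste0(left, ins, downstream, "GGCCGGCGG"))
  }
  seg <- list(chrom = "chrT", genome_strand = "+", start = 5,
              end = 5 + nchar(ins))
  trm <- function(tail) list(read_id = "x", tail = tail,
                             tail_length = nchar(tail))
  # NB: transcript strand is opposite the insert's genome strand, so this
  # segment is a minus-strand transcript; cleavage = start, downstream =
  # upstream-in-genome. Use a plus-strand transcript instead: align the
  # reverse complement of the insert.
  seg_minus <- list(chrom = "chrT", genome_strand = "-", start = 5,
                    end = 5 + nchar(ins))

  # tail of 6 T's, downstream genomic bases "CG...": nothing rescued, PASS
  g <- mk_genome("CGTTAA")
  r1 <- resolve_cleavage_and_classify(trm("TTTTTT"), seg_minus, g)
  expect_equal(r1$transcript_strand, "+")
  expect_equal(r1$cleavage_pos, 5 + nchar(ins) - 1)
  expect_equal(r1$rescued, 0)
  expect_equal(r1$unmappable_t, 6)
  expect_true(r1$pass)

  # tail of 2 T's over downstream "AA": fully rescued, internal priming,
  # cleavage moves 2 bases downstream
  g2 <- mk_genome("AACGGT")
  r2 <- resolve_cleavage_and_classify(trm("TT"), seg_minus, g2)
  expect_equal(r2$rescued, 2)
  expect_equal(r2$unmappable_t, 0)
  expect_false(r2$pass)
  expect_equal(r2$reason, "internal_priming")
  expect_equal(r2$cleavage_pos, 5 + nchar(ins) - 1 + 2)

  # tail of 1 T, no genomic A: insufficient tail
  r3 <- resolve_cleavage_and_classify(trm("T"), seg_minus, mk_genome("CCGG"))
  expect_equal(r3$unmappable_t, 1)
  expect_equal(r3$reason, "insufficient_tail")

  # unrescued non-T terminates rescue and does not count as unmappable:
  # tail TTATT (read orientation), downstream "AA" rescues the two
  # insert-adjacent T's, the A (sense T) mismatches, two T's remain
  r4 <- resolve_cleavage_and_classify(trm("TTATT"), seg_minus,
                                      mk_genome("AACCGG"))
  expect_equal(r4$rescued, 2)
  expect_equal(r4$unmappable_t, 2)
  expect_true(r4$pass)

  # rescued non-T: tail TTGTT over downstream "AACAA" — the sense C of the
  # read G matches, rescue continues through all five bases
  r5 <- resolve_cleavage_and_classify(trm("TTGTT"), seg_minus,
                                      mk_genome("AACAAGG"))
  expect_equal(r5$rescued, 5)
  expect_equal(r5$unmappable_t, 0)
  expect_equal(r5$reason, "internal_priming")

  # tailless reads can never be PASS
  r6 <- resolve_cleavage_and_classify(trm(""), seg_minus, mk_genome("CCGG"))
  expect_equal(r6$reason, "tailless")

  # minus-strand transcript: cleavage at segment start, downstream reads
  # leftward as complement; genomic "TT" immediately left of the insert
  # rescues a 2-T tail
  gm <- c(chrT = paste0("CGA", "TT", ins, "GGCC"))
  segp <- list(chrom = "chrT", genome_strand = "+", start = 5,
               end = 5 + nchar(ins))
  rm1 <- resolve_cleavage_and_classify(trm("TT"), segp, gm)
  expect_equal(rm1$transcript_strand, "-")
  expect_equal(rm1$rescued, 2)
  expect_equal(rm1$cleavage_pos, 3)  # moved 2 downstream (leftward)
  expect_equal(rm1$reason, "internal_priming")

  # rescue truncates at the contig boundary instead of erroring
  gshort <- c(chrT = paste0(left, ins))
  r7 <- resolve_cleavage_and_classify(trm("TTTT"), seg_minus, gshort,
                                      rescue_window = 20)
  expect_equal(r7$rescued, 0)
  expect_equal(r7$unmappable_t, 4)
})

test_that("rescue is monotone in the rescue window", {
  set.seed(42)
  ins <- "GGATCCGATTACAGGCATTACCGGAAT"
  for (i in 1:25) {
    dwn <- paste(sample(c("A", "A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
    g <- c(chrT = paste0("CCATG", ins, dwn))
    tail <- paste(sample(c("T", "T", "T", "A"), sample(1:8, 1),
                         replace = TRUE), collapse = "")
    seg <- list(chrom = "chrT", genome_strand = "-", start = 5,
                end = 5 + nchar(ins))
    trm <- list(read_id = "x", tail = tail, tail_length = nchar(tail))
    u <- vapply(c(0, 5, 10, 20), function(wn) {
      resolve_cleavage_and_classify(trm, seg, g, rescue_window = wn)$unmappable_t
    }, numeric(1))
    expect_true(all(diff(u) <= 0))
  }
})

test_that("clean simulated reads recover their planted cleavage site exactly", {
  cfg <- sim_config(n_genes = 12, reads_per_library = 1500, seed = 31,
                    non_t_error_prob = 0, internal_priming_fraction = 0)
  w <- build_toy_world(cfg)
  lib <- simulate_threads_library(w$genome, w$truth, "UD", cfg, 1)
  pr <- process_threads_library(lib, w$genome, pa_params())
  expect_equal(sum(pr$report[-1]), pr$report[["input"]])
  origin <- sub("^.*:", "", pr$pass$read_id)
  tr <- w$truth$sites[match(origin, w$truth$sites$site_id), ]
  expect_equal(pr$pass$cleavage_pos, tr$cleavage_pos)
  expect_equal(pr$pass$strand, tr$strand)
})

test_that("decoy internal-priming reads are never PASS", {
  w <- toy_world()
  libs <- toy_libraries()
  for (lib in libs[c("UD_r1", "DF_r2")]) {
    pr <- process_threads_library(lib, w$genome, pa_params(),
                                  align_cache = .tw_cache)
    expect_equal(sum(pr$report[-1]), pr$report[["input"]])
    origin <- sub("^.*:", "", pr$pass$read_id)
    expect_false(any(grepl("^decoy", origin)))
    n_decoy_in <- sum(grepl("decoy", lib$read_id))
    expect_gte(pr$report[["non_pass_internal_priming"]], n_decoy_in * 0.9)
  }
})
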