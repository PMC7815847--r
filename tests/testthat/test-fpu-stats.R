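random_count_sites <- function(n_genes = 8, max_sites = 4,
                               libs = c("UD_r1", "UD_r2", "DF_r1", "DF_r2")) {
  gene_id <- unlist(lapply(seq_len(n_genes), function(g) {
    rep(sprintf("g%02d", g), sample(1:max_sites, 1))
  }))
  counts <- lapply(setNames(libs, libs), function(l) {
    rpois(length(gene_id), lambda = sample(c(0, 5, 50), length(gene_id),
                                           replace = TRUE))
  })
  make_sites(gene_id, seq_along(gene_id) * 100, counts = counts)
}

test_that("FPU is the within-gene count fraction, NA for silent genes", {
  s <- make_sites(c("g1", "g2", "g2"), c(1, 2, 3),
                  counts = list(UD_r1 = c(17, 30, 70),
                                DF_r1 = c(5, 0, 0)))
  f <- compute_fpu(s)
  ud <- f[f$library == "UD_r1", ]
  expect_equal(ud$fpu, c(1.0, 0.3, 0.7))
  df <- f[f$library == "DF_r1", ]
  expect_equal(df$fpu, c(1.0, NA, NA))  # g2 silent in DF_r1 only
  expect_error(compute_fpu(make_sites("g", 1, counts = list(UD_r1 = -1))),
               "negative")
})

test_that("FPU sums to one per gene per library and ignores library scaling", {
  set.seed(11)
  for (i in 1:40) {
    s <- random_count_sites()
    f <- compute_fpu(s)
    sums <- tapply(f$fpu, paste(f$gene_id, f$library), sum)
    expect_true(all(is.na(sums) | abs(sums - 1) < 1e-9))

    s2 <- s
    s2$n_UD_r1 <- s2$n_UD_r1 * 7.5  # depth scaling of one library
    f2 <- compute_fpu(s2)
    expect_equal(f2$fpu, f$fpu)
  }
})

test_that("differential usage reproduces the exact-test oracle", {
  s <- make_sites(c("g1", "g1"), c(1, 2),
                  counts = list(UD_r1 = c(10, 90), DF_r1 = c(40, 60)))
  d <- differential_site_usage(compute_fpu(s), "UD", "DF")
  # fc on epsilon-floored mean FPU: (0.4 + 1e-4)/(0.1 + 1e-4)
  expect_equal(d$fc_threads[1], (0.4 + 1e-4) / (0.1 + 1e-4))
  expect_lt(d$p_value[1], 0.01)

  # identical counts: fc 1, p 1
  s0 <- make_sites(c("g1", "g1"), c(1, 2),
                   counts = list(UD_r1 = c(30, 70), DF_r1 = c(30, 70)))
  d0 <- differential_site_usage(compute_fpu(s0), "UD", "DF")
  expect_equal(d0$fc_threads, c(1, 1))
  expect_equal(d0$p_value, c(1, 1))

  # independent full-enumeration oracle for the 2x2 exact test on small
  # tables: P(table) under the hypergeometric law, two-sided by summing
  # probabilities <= observed
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    x <- max(0, k - n):min(k, m)
    p <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
    sum(p[p <= p[x == a] * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:30) {
    tot_a <- sample(5:25, 1); tot_b <- sample(5:25, 1)
    sa <- sample(0:tot_a, 1); sb <- sample(0:tot_b, 1)
    s <- make_sites(c("gx", "gx"), c(1, 2),
                    counts = list(A_r1 = c(sa, tot_a - sa),
                                  B_r1 = c(sb, tot_b - sb)))
    d <- differential_site_usage(compute_fpu(s), "A", "B")
    expect_equal(d$p_value[1],
                 enum_fisher(sa, tot_a - sa, sb, tot_b - sb),
                 tolerance = 1e-8)
  }

  # gene expressed in only one condition is epsilon-floored and flagged
  s1 <- make_sites(c("g1", "g1"), c(1, 2),
                   counts = list(UD_r1 = c(0, 0), DF_r1 = c(20, 20)))
  d1 <- differential_site_usage(compute_fpu(s1), "UD", "DF")
  expect_true(all(d1$one_condition))
  expect_true(all(is.finite(d1$fc_threads)))
})

test_that("differential IpA calls require all four criteria", {
  diff <- data.frame(site_id = c("S1", "S2", "S3"),
                     gene_id = c("g1", "g2", "g3"),
                     mean_fpu_a = c(0.6, 0.6, 0.2),
                     mean_fpu_b = c(0.2, 0.2, 0.6),
                     fc_threads = c(1 / 3, 1 / 3, 3),
                     p_value = c(0.001, 0.001, 0.001),
                     direction = c("down", "down", "up"),
                     one_condition = FALSE, stringsAsFactors = FALSE)
  sites <- make_sites(c("g1", "g2", "g3"), 1:3,
                      category = c("intron", "intron", "utr3"))
  sites$site_id <- c("S1", "S2", "S3")
  windows <- rbind(
    data.frame(site_id = c("S1", "S2", "S3"), condition = "UD",
               window_count = c(90, 90, 30), upstream_count = c(50, 10, 20),
               downstream_count = c(5, 40, 2)),
    data.frame(site_id = c("S1", "S2", "S3"), condition = "DF",
               window_count = c(30, 75, 90), upstream_count = c(20, 30, 60),
               downstream_count = c(2, 20, 5)))
  calls <- call_differential_ipa(diff, sites, windows, pa_params(),
                                 cond_a = "UD", cond_b = "DF")
  # S1: all criteria pass, direction down (checked in the higher-FPU UD)
  expect_true(calls$passed[calls$site_id == "S1"])
  # S2: RNA-seq fold change 75/90 is not <= 1/1.5 -> fails crit_rnaseq;
  # its upstream/downstream comes from UD and also fails
  expect_false(calls$passed[calls$site_id == "S2"])
  expect_false(calls$crit_rnaseq[calls$site_id == "S2"])
  # S3: fc_threads 3 and RNA-seq 3 but not intronic
  s3 <- calls[calls$site_id == "S3", ]
  expect_false(s3$passed)
  expect_false(s3$crit_intron)
  expect_true(s3$crit_threads & s3$crit_rnaseq)

  # missing window counts mark the call unevaluable
  calls2 <- call_differential_ipa(diff, sites, windows[windows$site_id !=
                                                         "S1", ],
                                  pa_params(), "UD", "DF")
  expect_equal(attr(calls2, "n_unevaluable"), 1)
  expect_false("S1" %in% calls2$site_id)
})

test_that("knockdown dependence keeps same-direction responders", {
  calls <- data.frame(site_id = c("S1", "S2", "S3"),
                      direction = c("down", "down", "up"),
                      passed = TRUE, stringsAsFactors = FALSE)
  kd <- make_sites(c("g1", "g1", "g2", "g2", "g3", "g3"),
                   1:6, counts = list(
                     CTRL_r1 = c(60, 40, 60, 40, 20, 80),
                     KD_r1 = c(30, 70, 80, 20, 60, 40)))
  kd$site_id <- c("S1", "o1", "S2", "o2", "S3", "o3")
  dep <- cpsf_dependence(calls, compute_fpu(kd), pa_params())
  # S1: 0.6 -> 0.3, down 2x, same direction as the call -> retained
  # S2: 0.6 -> 0.8, up, discordant with "down" -> dropped
  # S3: 0.2 -> 0.6, up 3x, same direction -> retained
  expect_setequal(dep$site_id, c("S1", "S3"))
  expect_equal(attr(dep, "n_discordant"), 1)

  calls2 <- rbind(calls, data.frame(site_id = "S9", direction = "down",
                                    passed = TRUE))
  dep2 <- cpsf_dependence(calls2, compute_fpu(kd), pa_params())
  expect_equal(attr(dep2, "n_missing"), 1)
})

test_that("planted knockdown responders are recovered from a simulated design", {
  cfg <- sim_config(n_genes = 60, reads_per_library = 20000, seed = 71,
                    knockdown = TRUE, frac_ipa_differential = 0.6)
  w <- build_toy_world(cfg)
  cache <- new.env(parent = emptyenv())
  pass <- NULL
  for (cd in c("UD", "DF", "CTRL", "KD")) {
    for (r in 1:2) {
      lib <- simulate_threads_library(w$genome, w$truth, cd, cfg, r)
      pr <- process_threads_library(lib, w$genome, pa_params(),
                                    align_cache = cache)
      pass <- rbind(pass, pr$pass)
    }
  }
  main <- pass[grepl("^(UD|DF)_", pass$library), ]
  sites <- cluster_ends(main)
  ga <- assign_genes(sites, w$models)
  ann <- annotate_category(ga$sites, w$models)
  kd_sites <- quantify_sites(
    ann[, !grepl("^n_", names(ann))],
    pass[grepl("^(CTRL|KD)_", pass$library), ])

  fpu <- compute_fpu(ann)
  diff <- differential_site_usage(fpu, "UD", "DF")
  # evaluate dependence on the truth-matched differential intronic sites
  tr <- w$truth$sites
  tr_diff <- tr[tr$category == "intron" & abs(tr$usage_UD - tr$usage_DF) >
                  0.1, ]
  idx <- vapply(seq_len(nrow(tr_diff)), function(i) {
    sel <- which(ann$chrom == tr_diff$chrom[i] &
                   ann$strand == tr_diff$strand[i])
    sel[which.min(abs(ann$position[sel] - tr_diff$cleavage_pos[i]))]
  }, integer(1))
  calls <- data.frame(site_id = ann$site_id[idx],
                      direction = diff$direction[match(ann$site_id[idx],
                                                       diff$site_id)],
                      stringsAsFactors = FALSE)
  dep <- cpsf_dependence(calls, compute_fpu(kd_sites), pa_params())
  predicted <- calls$site_id %in% dep$site_id
  truth_resp <- abs(tr_diff$usage_KD - tr_diff$usage_CTRL) > 0.1
  expect_gte(mean(predicted == truth_resp), 0.9)
})

test_that("distal usage index classifies 3'UTR shifts by fold change", {
  # distal fractions 0.2 vs 0.5 -> fc 2.5 -> lengthened
  s <- make_sites(c("gA", "gA"), c(100, 300), category = "utr3",
                  counts = list(UD_r1 = c(80, 20), DF_r1 = c(50, 50)))
  d <- distal_usage_index(s, "UD", "DF")
  expect_equal(d$distal_site, "S002")
  expect_equal(d$distal_frac_a, 0.2)
  expect_equal(d$distal_frac_b, 0.5)
  expect_equal(d$classification, "lengthened")

  # equal fractions: unchanged; minus strand picks the lowest coordinate
  s2 <- make_sites(c("gA", "gA"), c(100, 300), strand = "-",
                   category = "utr3",
                   counts = list(UD_r1 = c(30, 70), DF_r1 = c(30, 70)))
  d2 <- distal_usage_index(s2, "UD", "DF")
  expect_equal(d2$distal_site, "S001")
  expect_equal(d2$classification, "unchanged")

  # genes with a single 3'UTR site are skipped and counted
  s3 <- make_sites(c("gA", "gA", "gB"), c(1, 2, 3), category = "utr3",
                   counts = list(UD_r1 = c(1, 1, 5), DF_r1 = c(1, 1, 5)))
  d3 <- distal_usage_index(s3, "UD", "DF")
  expect_equal(d3$gene_id, "gA")
  expect_equal(attr(d3, "n_skipped"), 1)
})

test_that("DE-table intersection enforces thresholds and direction", {
  ta <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   fold_change = c(3, 0.3, 2.5, 4, 1.2),
                   p_value = c(0.01, 0.02, 0.03, 0.06, 0.01))
  tb <- data.frame(gene_id = c("g1", "g2", "g3", "g6"),
                   fold_change = c(2.8, 0.4, 0.35, 9),
                   p_value = c(0.001, 0.04, 0.01, 0.001))
  res <- intersect_de_lists(ta, tb)
  # g1: up in both; g2: down in both; g3: discordant; g4: p 0.06 in a;
  # g5: fc too small
  expect_setequal(res$genes, c("g1", "g2"))
  expect_equal(res$n_shared, 2)

  expect_equal(intersect_de_lists(ta[1:2, ], tb[4, , drop = FALSE])$n_shared,
               0)
  expect_error(intersect_de_lists(ta, tb[, 1:2]), "p_value")
})
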