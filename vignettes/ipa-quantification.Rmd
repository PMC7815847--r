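---
title: "Quantifying intronic polyadenylation from 3'-end sequencing"
author: "ipaseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intronic polyadenylation from 3'-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

3'-end sequencing protocols of the 3'READS+ family read the mRNA 3' end
inward: after poly(A) selection and tail trimming, each sequenced fragment
carries a residual stretch of T's (the reverse complement of the remaining
poly(A) tail) followed by the reverse complement of the transcript's last
bases. The residual T's are the evidence that the molecule was genuinely
polyadenylated at that position rather than internally primed on an A-rich
genomic stretch. `ipaseq` implements the full analysis path from such reads
to biological conclusions:

1. **PASS reads** — trimming, alignment, and certification of reads whose
   tails cannot be explained by downstream genomic A's;
2. **poly(A) sites** — single-linkage clustering of cleavage positions,
   exclusion and robustness filtering, gene assignment, and category
   annotation (intron / 3'UTR / other exon) with intron priority;
3. **FPU** — the fraction of poly(A)-site usage, a within-gene count
   fraction that is internally normalised per library;
4. **differential intronic polyadenylation (IpA)** — fold-change-driven
   calls cross-validated against strand-specific RNA-seq coverage around
   each site;
5. **knockdown dependence** — intersection of differential calls with a
   control/knockdown contrast by same-direction fold change;
6. **3'UTR distal usage** — lengthening/shortening classification for genes
   with two or more 3'UTR sites.

Everything is exercised end to end on synthetic data with planted ground
truth, so each stage's behaviour is verifiable without any external
download.

## Read model and PASS classification

A raw read is modelled as

```
[UMI, 4 nt][residual T-tail, with at most one non-T base][revcomp of transcript 3' end]
```

The 5' adapter is assumed already removed, as after demultiplexing; the UMI
stands in for the four random nucleotides that head the insert. Trimming
removes the UMI, then consumes the maximal leading run of T's, allowing one
embedded non-T provided at least one T follows it. Inserts shorter than
`min_insert = 22` nt are discarded.

After alignment (an external aligner via SAM/BAM, or the built-in
exact-match aligner for synthetic genomes), the transcript strand is
opposite the insert's genomic strand and the provisional cleavage position
is the insert's 3'-most aligned base. The tail is then *rescued* against
the genome: walking outward from the insert-adjacent tail base, each tail
base whose transcript-sense identity matches the next genomic base
downstream of the cleavage site is treated as genome-templated, and the
cleavage position advances one base downstream. Rescue stops at the first
mismatch, after `rescue_window = 20` bases, or at a contig end. A read is
**PASS** when at least two tail T's remain unexplained by the genome.

Two interpretation points deserve note:

* The rescue walk starts at the insert-adjacent end of the tail. Only that
  end abuts the genome, so the alternative reading (starting at the far
  end) cannot correspond to contiguous genomic sequence.
* A tail's single non-T base is rescued exactly like a T when it matches
  the corresponding genomic base; when it does not match it terminates the
  rescue and is *not* counted as an unmappable T (it is not a T).
* Reads with an empty tail are carried through alignment but can never be
  PASS; they are reported as `tailless`.

Every input read lands in exactly one partition of the run report
(`trim_no_insert`, `trim_short_insert`, `unaligned`, `low_mapq`,
`non_pass_*`, `pass`), and the partition sums to the input count — this
conservation is property-tested.

## Site calling

PASS cleavage positions are clustered per contig and transcript strand by
single linkage: sorted positions chain while consecutive gaps are at most
`merge_window = 24` nt. The representative position is the modal position
(most reads); ties break toward the 5'-most position in transcript
orientation. The mode is robust to the one-to-two-base micro-heterogeneity
that tail rescue can introduce, and the deterministic tie-break keeps runs
reproducible.

Filters then run in a fixed order, each recording its removals:

1. **exclusion intervals** (blacklist, retrotransposons, miRNA, snoRNA
   BEDs) — a site whose representative base falls in any interval is
   removed once, with all hitting labels recorded;
2. **gene assignment** — by strand-matched overlap with gene spans
   (`[min exon start, max exon end)`); sites in zero genes or in two or
   more genes are removed;
3. **robustness** — the host gene needs an RNA-seq count of at least 5 in
   one condition, the site needs a summed replicate count of at least 10 in
   one condition, and an FPU of at least 10% in one library;
4. **category annotation** — intron first, then 3'UTR, else exon. Intron
   priority prevents previously uncharacterised intronic sites from being
   absorbed into UTR annotation by sibling transcripts;
5. **single-site re-annotation** — the sole site of a single-site gene is
   set to `utr3` regardless of its interval label (idempotent);
6. **ambiguous-overlap removal** — a site covered by two or more gene spans
   of the *full* annotation is removed even when only one of those genes
   survived the expression filters, because its reads cannot be attributed.

The gene span deliberately uses exon extremes with no promoter or
downstream padding; it is the simplest defensible rule and is configurable
upstream by editing the models table.

## FPU and differential calls

For each site and library, FPU = site count / summed counts of all sites in
the same gene. Being a within-gene fraction it is internally normalised:
scaling a library's counts by any constant leaves every FPU unchanged,
which sidesteps cross-library normalisation entirely (property-tested on
random count matrices).

Differential usage between conditions A and B is driven by the FPU fold
change `(mean FPU_B + eps) / (mean FPU_A + eps)` with `eps = 1e-4`;
replicates are combined by the mean. As the accompanying significance
measure we run a two-sided Fisher exact test on the 2x2 table of pooled
site counts versus pooled rest-of-gene counts in the two conditions. A
negative-binomial count model applied to usage fractions is statistically
ambiguous; the calls here are threshold-driven, the exact test simply
orders sites by evidence, and its p-values are verified against a full
hypergeometric enumeration in the tests.

A site becomes a **differential IpA call** when all four criteria hold:

* it is intronic;
* the FPU fold change reaches 2 (in either direction);
* the RNA-seq fold change of read counts in the site's ±100 bp window
  reaches 1.5 in the same direction (pseudocount 1, library-size scaling by
  total mapped reads — neither is prescribed by the protocol, both are
  configurable);
* the RNA-seq flanks of the higher-usage condition show more reads in the
  100 bp upstream of the cleavage base (inclusive) than in the 100 bp
  after it. The window orientation follows the transcript strand; the
  choice of the higher-usage condition makes the criterion evaluable for
  sites that are silent in one condition.

Per-criterion booleans are retained so a failed call shows which criterion
failed. Knockdown dependence then keeps calls whose control-versus-knockdown
FPU fold change reaches 1.5 in the same direction as the differentiation
call.

For 3'UTR shortening/lengthening, genes with two or more 3'UTR sites
contribute a distal fraction per condition — pooled counts at the 3'-most
site over pooled 3'UTR counts — and the fold change of that fraction
classifies the gene (`lengthened` above 1.5, `shortened` below 1/1.5).

## The synthetic world

`build_toy_world()` generates, deterministically per seed:

* three-exon genes (default 200, 1.5–2.7 kb) on both strands of several
  contigs, with intron 1 made wide (30% of the gene) so an intronic site
  and its ±100 bp validation windows fit inside it;
* one distal 3'UTR site per gene; half the genes get a proximal 3'UTR site
  (distal share 0.5, or 0.3/0.7 for the ~30% of them with a planted
  shift); half the genes get one intronic site in intron 1 (usage 0.3, or
  0.6 versus 0.2 — a three-fold change — for the ~40% planted as
  differential, split evenly between directions);
* the AATAAA hexamer planted 12–40 bp upstream (transcript sense) of every
  site, which the motif scan must find in all of them;
* internal-priming decoys: positions immediately upstream of planted 30-nt
  A-runs, half on each strand, whose reads carry fully genome-templated
  tails and must never become PASS;
* matched RNA-seq positions drawn per-base-uniformly along the isoform
  implied by each site (an intronic isoform retains intron sequence up to
  its cleavage position), with isoform weights = gene abundance x usage.
  Coverage therefore drops after a used site, which is what the window
  validation measures.

Reads are emitted as UMI + T-tail (lengths 2 + Binomial(28, 0.25), mean
9 nt; one non-T error with probability 0.1, never at the insert-adjacent
position) + 40 nt insert. Two generator choices keep the planted coordinate
identifiable: the base immediately downstream of every planted site is
forced non-A (otherwise tail rescue would — correctly, per the method —
shift the cleavage assignment downstream), and the single tail error never
sits at the insert-adjacent position (which keeps the rescue rule
unambiguous for testing). Real data has neither property; on real data
cleavage positions adjacent to genomic A's are genuinely ambiguous and the
rescue rule resolves them downstream, which the clustering then absorbs.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate — includes sequencing errors in the insert, multi-isoform
splicing, paired ends, soft-clipped or gapped alignments, library-specific
biases, and quality-score realism. The built-in aligner is exact-match with
a declared MAPQ dialect (42 unique / 0 multiple); real pipelines should
align externally and ingest SAM/BAM.

## Problem sizes and numerical choices

The default test and acceptance configuration is 200 genes, two conditions
x two replicates x 50,000 3'-end reads, and 100,000 RNA-seq positions per
condition; detection power is measured over 20 stochastic library
replicates on a fixed world, and the null false-call rate over three
replicates of a world with no planted differences. The unit-test world is
40 genes x 8,000 reads. At these depths a planted three-fold usage change
is detected in well over 90% of replicates while null worlds yield no
calls.

Other numerical details, all in `pa_params()`: epsilon floor `1e-4` on
usage fractions; pseudocount 1 on window counts; MAPQ threshold 10; rescue
window 20 bp; merge window 24 nt; motif context ±200 bp with the AATAAA
search confined to the 40 bp upstream of cleavage, and a one-sided binomial
enrichment p-value against the hexamer hit rate expected from the observed
base composition.

## Limitations

* The exact-test p-value is a ranking device, not a calibrated
  replicate-aware error rate; calls are threshold-driven by design.
* Gene spans ignore promoters/extensions, so sites just outside annotated
  exon extremes are `intergenic`.
* The ambiguous-overlap rule removes sites conservatively whenever gene
  spans overlap, even if expression filters could in principle
  disambiguate.
* `quantify_sites()` assigns knockdown reads to the nearest primary site
  within the merge window; sites private to the knockdown libraries are
  ignored by construction.

## A minimal session

```{r example}
library(ipaseq)

cfg <- sim_config(n_genes = 40, reads_per_library = 8000, seed = 101)
w <- build_toy_world(cfg)

libs <- list()
for (cd in c("UD", "DF")) {
  for (r in 1:2) {
    libs[[paste0(cd, "_r", r)]] <-
      simulate_threads_library(w$genome, w$truth, cd, cfg, r)
  }
}
rna <- do.call(rbind, lapply(c("UD", "DF"), function(cd) {
  rp <- simulate_rnaseq_library(w$models, w$truth, cd, 40000,
                                seed = 500 + match(cd, c("UD", "DF")))
  rp$condition <- cd
  rp
}))

run <- run_ipa_pipeline(libs, w$genome, w$models, rna)
summary <- summarize_run(run)
write_report(run, "ipaseq_out")
```
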