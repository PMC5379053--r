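# tecrm — transposable-element cis-regulatory module analysis

`tecrm` is an R package for discovering and characterizing *cis*-regulatory
modules encoded by transposable elements (TEs). Young LTR retroelement
subfamilies can carry a module of pluripotency transcription-factor binding
sites (Esrrb + Klf4 + Sox2, "EKS") that makes individual copies behave as
embryonic-stem-cell enhancers; because a subfamily expands from one
ancestral element, a single insertion event can deposit the same regulatory
logic at many loci. The package is aimed at regulatory-genomics analysts who
want the complete desk-scale pipeline around this phenomenon, with every
stage testable against simulated data with known ground truth.

## What it computes

- **Site clustering** — ChIP-seq peaks (extended to 200 bp about their
  center) and motif hits are reduced to reference points and chained into
  clusters when consecutive points lie within 100 bp; a cluster with *i*
  distinct TFs marks each TE it overlaps (≥ 1 bp) as bound by *i* TFs.
- **Subfamily enrichment** — for subfamily *j* and occupancy *i*, the
  base-2 log odds ratio of the 2×2 table (k, N_j − k, K_i − k,
  N − N_j − K_i + k) with Haldane–Anscombe correction on zero cells, plus
  the exact hypergeometric upper tail P(X ≥ k), X ~ Hypergeom(N, K_i, N_j).
  LOR ≥ 6 reads as ≥ 64-fold enrichment; rows need ≥ 10 bound elements.
- **Motif tools** — PWM scanning with patser-style exact p-values from a
  discretized convolution of per-column score distributions; per-position
  information content IC_l = 2 + Σ_b p_bl log2 p_bl; EKS-module detection;
  mutagenesis design at the highest-IC positions with least-informative
  replacements and a no-new-motif rescan check.
- **TE dating** — Jukes–Cantor correction K = −(3/4) ln(1 − 4p/3) of
  consensus divergence, and paired-LTR insertion dating T = d/(2r) with
  greedy ≤ 7-kb pairing and alignment-based divergence, at the mouse–rat
  rate bounds (1.2% and 0.05% per site per Myr).
- **Epigenomic metaprofiles** — reads-per-million coverage in 50-bp bins
  across 3-kb TE-centered windows, averaged by occupancy category (0 / 1 /
  2+ TFs).
- **Reporter quantification** — luciferase fold changes over the empty
  vector (enhancer > 2, strong > 10), barcoded-reporter (CRE-seq/MPRA)
  cDNA/DNA expression over basal constructs, mutant-vs-wild-type effects
  with Welch t-tests, and qPCR 2^(−ΔΔCt) relative expression.
- **Synthetic data** — a generator that plants TE copies mutated from a
  consensus, EKS modules in a chosen subfamily, LTR pairs diverged from a
  known insertion time, coverage enrichment and reporter fold changes, all
  with ground-truth tables.

## Worked example

Simulate the default study conditions — a 5-Mb genome, six LTR subfamilies
of 100 copies, EKS modules planted in half the copies of `simLTR1`, 100 LTR
pairs inserted 13 Myr ago — and ask which subfamily is enriched for
multi-TF binding:

```r
library(tecrm)

cfg  <- sim_config(seed = 1)
sim  <- simulate_genome(cfg)
peaks <- simulate_peaks(sim, background_rate = 10, seed = 2)

sites    <- tf_sites(peaks[, c("chrom", "start", "end", "tf")], "peak")
clusters <- cluster_sites(sites, gap = 100)
n_tfs    <- assign_clusters_to_tes(sim$annotation, clusters)
enr      <- enrichment_scan(n_tfs, sim$annotation, lor_threshold = 1.5)
enr[enr$flagged, c("repName", "i", "k", "N_j", "K_i", "N", "lor", "pvalue")]
#>    repName  i  k N_j K_i   N   lor    pvalue
#> 16 simLTR1  3 50 100  51 800 9.449 4.896e-50
#> 37 simLTR1 2+ 50 100  51 800 9.449 4.896e-50
```

Exactly the planted subfamily is flagged: 50 of its 100 copies are bound by
3 TFs (`k`/`N_j`), versus 51 such TEs genome-wide (`K_i`) among 800
annotated copies (`N`) — a 2^9.4 ≈ 700-fold odds enrichment. Dating the
planted proviruses recovers the 13-Myr insertion at the slow rate bound:

```r
ltrs  <- sim$annotation[sim$annotation$repName == "simERV-LTR", ]
pairs <- pair_ltrs(ltrs, max_span = 7000)
pairs$d <- vapply(seq_len(nrow(pairs)), function(i) {
  g <- sim$genome[[pairs$chrom[i]]]
  ltr_divergence(
    as.character(Biostrings::subseq(g, pairs$start5[i] + 1, pairs$end5[i])),
    as.character(Biostrings::subseq(g, pairs$start3[i] + 1, pairs$end3[i])))
}, numeric(1))
subfamily_age_summary(data.frame(repName = "simERV", d = pairs$d))
#>   repName rate_label n_pairs     q25  median     q75
#> 1  simERV       fast     100  0.4167  0.5556  0.6944
#> 2  simERV       slow     100 10.0000 13.3333 16.6667
```

`run_pipeline(list(seed = 1), "out/")` chains all stages (simulate →
cluster → enrich → scan → age → profile → reporter), writes one TSV per
stage and a `manifest.json` that reproduces the run bit-identically.

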