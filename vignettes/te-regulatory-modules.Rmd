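---
title: "Methods: TE-encoded cis-regulatory module analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-encoded cis-regulatory module analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Transposable elements (TEs) replicate through a genome and can carry
regulatory sequence with them. When a TE subfamily's ancestral element
contained binding sites for several transcription factors (TFs), its
expansion deposits the same *cis*-regulatory module — a co-occurring set of
TF-binding sites that jointly drive expression — at many loci at once. In
mouse embryonic stem cells, certain young LTR retroelement subfamilies carry
a module of Esrrb, Klf4 and Sox2 (EKS) binding sites and behave as
ESC-specific enhancers.

`tecrm` implements the complete desk-scale analysis around this phenomenon:
finding TEs that carry clusters of TF-binding sites, quantifying which
subfamilies are enriched for them, dating those subfamilies, profiling their
chromatin signature, quantifying their regulatory potential from reporter
assays, and designing motif-disrupting mutations. Every stage can be run
against a bundled synthetic-data generator whose ground truth is known, so
the statistical machinery is testable end to end without any downloads.

# Models and procedures

## Site clustering and TE assignment

TF-binding sites are reduced to a single reference point: the peak center
`floor((start + end) / 2)` for ChIP-seq peaks, the motif start for predicted
motifs. Peaks are first extended symmetrically to 200 bp around their
center, clipping at chromosome bounds without re-centering (edge windows may
be shorter and are flagged). Sites are then chained per chromosome by
single linkage: consecutive reference points at most 100 bp apart join one
cluster. The 100-bp rule is taken boundary-inclusive (distance of exactly
100 joins); the alternative strict reading differs only on a measure-zero
set of configurations and the choice is surfaced as the `gap` argument.

A cluster with `i` distinct TF names marks every TE it overlaps by at least
1 bp (half-open interval semantics, as in `intersectBed`) as "bound by `i`
TFs"; a TE touched by several clusters takes the maximum `i`, the
conservative monotone summary of a per-TE property. Whether overlap should
instead require a member site inside the TE is not determined by the source
procedure; the ≥1-bp span-overlap rule is our reading, and the brute-force
invariant test pins its exact semantics.

## Subfamily enrichment

For subfamily `j` and occupancy bin `i` (1–5 exactly, plus a "2+"
aggregate), with `k` bound subfamily copies, `N_j` subfamily copies, `K_i`
bound TEs genome-wide and `N` annotated TEs total, enrichment is the base-2
log odds ratio of the 2×2 table `(k, N_j − k, K_i − k, N − N_j − K_i + k)`.
Base 2 makes the scale read in folds (LOR 6 = 64-fold). Zero cells get the
Haldane–Anscombe 0.5 correction on all four cells, keeping estimates finite;
corrected rows are identifiable because `k`, `N_j`, `K_i`, `N` are emitted
alongside. Significance is the exact hypergeometric upper tail
`P(X ≥ k)`, `X ~ Hypergeom(N, K_i, N_j)` — the universe is all annotated TE
copies, matching the odds-ratio framing. Rows need at least 10 bound
elements to be reportable, and flagging requires `LOR ≥ 4.5` and
`p < 0.001` by default (the 64-fold tier `LOR ≥ 6` is also surfaced). Raw
p-values carry the decision, as in the source analysis; a Benjamini–Hochberg
column is emitted as clearly supplementary output.

## Motif scanning with exact p-values

Motifs are position probability matrices with a background model (uniform by
default). Scores are log odds in bits, `log2((p + c) / (bg + c))` with
pseudocount `c = 0.01` guarding `−Inf`; information content for ranking
positions uses the raw probabilities (`IC_l = 2 + Σ p log2 p`), reflecting
the matrix as given. The null score distribution is computed exactly by
convolving per-column score distributions on a 0.01-bit grid; the scan
threshold at `p = 0.001` is the smallest attainable score whose tail
probability is ≤ p. This reproduces patser-style exact p-values without
enumerating `4^L` windows; the test suite proves the convolution identical
to full enumeration for `L ≤ 6` and bounds the discretization artifact by
the bin width. "Matching the consensus" is operationalized as agreement at
every majority-base position (column maximum > 0.5), a determinate reading
of an otherwise unspecified criterion.

An EKS module is called in an element when Esrrb, Klf4 and Sox2 each have at
least one hit starting within the upstream fraction (default the 5′ half,
strand-aware) of the element.

## Mutagenesis design

Motif-disrupting mutations are placed at the `max_mutations = 4`
highest-information-content positions (ties leftmost) and substitute the
least probable base of the column (ties alphabetical; if the site already
carries it, the next-least). All tie-breaks are stated, so designs are
deterministic. A design is verified by rescanning the mutated sequence
against the whole motif library: any hit overlapping a mutated position that
was absent at the same offset/strand/TF in the original fails the design.
This in-house rescan replaces an external motif-comparison tool and tests
the property actually required — that the substitutions do not create a new
binding site.

## TE dating

Two estimators. (1) Consensus divergence: a copy's observed divergence `p`
to its subfamily consensus is corrected to substitutions per site with the
Jukes–Cantor formula `K = −(3/4) ln(1 − 4p/3)`, undefined at the saturation
point `p = 0.75`. (2) Paired-LTR dating: the two LTRs flanking a provirus
are identical at insertion and evolve independently afterwards, so their
divergence `d` accrues at twice the per-lineage rate and the insertion time
is `T = d / (2r)`. Candidate pairs are adjacent same-subfamily, same-strand
copies within 7 kb, paired greedily closest-first with each copy used once.
Divergence comes from a global alignment (match +1, mismatch −1, gap open
−4, gap extend −1): mismatches over aligned non-gap columns. The raw
p-distance feeds `T` — at the divergences where paired-LTR dating is
meaningful (`2rT ≲ 0.05`) the JC correction is below the sampling noise —
and per-subfamily summaries are reported at both mouse–rat rate bounds,
1.2% and 0.05% per site per Myr, as box-plot statistics.

## Epigenomic metaprofiles

Coverage is averaged in 50-bp bins across 3-kb windows centered on the TE
midpoint (60 bins), scaled to reads per million by the track's library
size — the minimal standard reading of "normalized read density"; tracks
that are already ratios (e.g. methylation) can skip normalization. Windows
are unstranded. Bins truncated by chromosome ends are excluded from the
category mean and reflected in the per-bin `n`. TEs are grouped as 0, 1, or
2+ bound TFs and averaged element-wise per category.

## Reporter quantification

Luciferase: expression is the firefly/renilla ratio; technical replicates
average within an experiment, experiments average into the construct value,
and the fold change divides by the empty-vector value computed identically.
Fold change > 2 classifies an enhancer, > 10 a strong enhancer. The
reported sd is across experiment-level fold changes, and zero-renilla
records are dropped with a warning.

CRE-seq (barcoded MPRA): per barcode and replicate, expression is
`(cDNA + 0.5) / (DNA + 0.5)`; barcodes with DNA depth < 10 are excluded.
Both constants guard division by zero and low-depth noise, are not dictated
by the source procedure, and are exposed as arguments. A construct's
expression is the mean over retained barcode-replicate ratios; its fold
change divides by the mean basal-construct expression (mean, not median —
the basal set is a designed homogeneous pool). Mutant effects are the
mutant/wild-type fold-change ratio with a Welch two-sided t-test on
replicate-level expressions; Welch rather than pooled because equal
variances are not guaranteed across constructs.

qPCR: `ΔCt = Ct_target − Ct_reference` per condition,
`ΔΔCt = ΔCt_mut − ΔCt_wt`, relative expression `2^(−ΔΔCt)`. The negative
exponent is required for a deletion that reduces expression to come out
below 1; the frequently seen "2^ΔΔCt" notation is a sign convention
difference, documented on the function.

# The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_genome()` and its
companions generate every pipeline input with ground truth:

- **Genome and TE copies.** A uniform-random background genome (default one
  5-Mb chromosome) hosts six LTR-like subfamilies of 100 copies each. Each
  copy is its subfamily's 300-bp consensus with i.i.d. per-site
  substitutions at rate 0.05, uniform over the three alternative bases —
  the generative counterpart of the Jukes–Cantor model used by the dating
  estimators. Copies are placed uniformly without overlap by rejection
  sampling (1,000 retries, then a capacity error). Realized divergence per
  copy is recorded in the annotation (`milliDiv`).
- **Planted modules.** Half the copies of one subfamily carry one exact
  best-scoring site per module PWM (Esrrb, Klf4, Sox2, in order) in the
  upstream half of the element, strand-aware. Peak tables place one
  deterministic peak on every planted site plus seeded uniform background
  peaks (default in the pipeline: 10 per Mb per TF).
- **LTR pairs.** 100 proviruses inserted 13 Myr ago at 5e-4 substitutions
  per site per Myr: each pair starts identical and the two 300-bp LTRs
  mutate independently with per-site probability `rT`, separated by a
  6.5-kb internal span. Proviruses are placed before the small copies and
  with a 7-kb exclusion guard around each — otherwise greedy
  nearest-neighbour pairing could chain LTRs of two adjacent insertions and
  the planted truth would be ambiguous, and late placement of 7.4-kb blocks
  into a fragmented genome fails spuriously.
- **Coverage.** Per-base Poisson depth at background mean 20, multiplied by
  5 over module carriers; the library size is the track total.
- **Reporter data.** Per barcode (8) and replicate (3), DNA ~
  Poisson(1,000) and cDNA ~ Poisson(depth × basal × fold change ×
  log-normal noise, sdlog 0.1); luciferase firefly/renilla pairs share the
  same planted fold changes (wild type 4×, mutants 1.2× = 0.3 of wild type,
  negative control 1×). The 10% log-normal dispersion is a typical
  between-replicate spread for a well-behaved reporter experiment; the
  planted 4× wild type sits inside the enhancer tier without straddling it.

Identical config and seed reproduce every output byte-for-byte; the
generator restores the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no indels or nested insertions (divergence is
substitution-only), no sequencing reads (coverage is per-base intensity, not
mapped fragments with mappability artifacts), no CpG-aware methylation, no
chromatin-driven covariance between marks, uniform base composition, and TE
placement independent of genes. Recovery results certify the estimators and
their wiring, not robustness to alignment artifacts or compositional biases
of real genomes.

# Numerical choices and degenerate inputs

- Score discretization 0.01 bits; the threshold search uses attainable
  (positive-probability) bins only. A PWM identical to the background has no
  attainable threshold and returns `Inf` with a warning; `p = 1` returns the
  minimum attainable score.
- Windows containing any non-ACGT base are skipped during scanning.
- Jukes–Cantor rejects `p ≥ 0.75`; antiparallel LTR input yields `d` near
  0.75 and a warning to re-orient.
- All-uniform PWMs are "undesignable" for mutagenesis and error out rather
  than emitting a vacuous plan.
- Coordinates are 0-based half-open (BED convention) everywhere internally;
  rmsk `genoStart` is treated as 0-based. Peak centers of even-width peaks
  use `floor`.
- Empty categories, empty subfamilies and all-excluded constructs are
  omitted or reported `NA` with warnings, never silently dropped.

# Problem sizes used by the test suite

Unit tests run on 1e5–3e5-bp genomes with 10–30 copies per subfamily; the
quantitative recovery suite uses the full study conditions (5-Mb genome,
6 × 100 copies, 20 independent seeds for enrichment, dating and reporter
recovery, 100 LTR pairs, sequencing depth 1,000). These sizes are the
package's chosen operating point: large enough that binomial/Poisson noise
is well inside the asserted bounds, small enough to iterate quickly.

# Known limitations

- Cross-species presence/absence dating (homology search across genomes) is
  out of scope; only divergence-based estimators are implemented.
- The bundled motif library is synthetic (see `inst/extdata/pwms_synthetic`);
  analyses of real data should load curated JASPAR matrices via
  `read_jaspar()`.
- `mutant_effect`'s t-test uses replicate-level means (n = replicates);
  with very few replicates its power rests on the barcode averaging.
- The enrichment universe is TE copies; alternative universes (e.g. cluster
  regions) would change `K_i` and are not implemented.
- No strand-aware clustering and no re-centering of clipped peak windows.
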