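---
title: "Methods: miRNA-mRNA differential co-expression and rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA differential co-expression and rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirewire)
```

This vignette is the package's account of its statistical machinery: the
models behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical corner cases. The motivating design is a
two-condition bulk study — peripheral white blood cells from fertile (FH)
and subfertile (SFH) heifers, 7 vs 7 small-RNA libraries and 7 vs 6 mRNA
libraries from the same animals — but nothing in the code is specific to
that system beyond the FH/SFH labels.

## Expression QC and normalization

Counts per million are computed per sample as `counts / total * 1e6`.
Two filters run before anything else: features with zero counts in every
sample are dropped, and a feature is then kept only if its CPM is at
least `min_cpm` (default 1) in at least `min_frac` (default 0.5) of all
samples, both groups pooled. The boundary is inclusive — a feature at
CPM ≥ 1 in exactly half the samples survives — matching the
"expressed in at least half" convention of count-based QC. CPM for the
filter is computed once, from the column totals of the matrix being
filtered; `prevalence_filter()` accepts explicit `lib_sizes` so a derived
matrix can be filtered against the original totals, under which the
filter is idempotent. No between-sample normalization beyond library size
(no TMM) is applied; the differential-expression stage has its own
median-of-ratios factors.

## Differential expression

The test is a deliberately transparent re-implementation of the standard
negative-binomial skeleton:

* **Size factors** — median-of-ratios: features with no zero count form a
  geometric-mean pseudo-reference, and a sample's factor is the median of
  its count-to-reference ratios (median taken on the ratio scale).
* **Dispersion** — per-feature method of moments on normalized counts,
  using `Var(count/sf) ≈ mu·mean(1/sf) + alpha·mu²` with the pooled
  within-group variance, scaled by `(n1+n2)/(n1+n2−2)` and floored at
  1e-8. The scale factor is a small-sample correction: the plug-in
  dispersion is noisy at 7 samples per group, and without the correction
  the Wald test runs about 40% above nominal size. With it, the empirical
  size at p ≤ 0.05 is ≈ 0.055 and the null p-value distribution is
  uniform to within a Kolmogorov–Smirnov distance of ≈ 0.03 (both
  measured in the test suite at n = 2000–5000 null features).
* **Wald statistic** — on `log2fc = log2(mean_SFH / mean_FH)` with a
  delta-method standard error and a two-sided normal p-value. Group means
  carry a `(sum + 0.5)/n` pseudo-count guard; a feature entirely zero in
  one group is flagged and its log2fc clamped to ±30.

No shrinkage toward a dispersion trend, no independent filtering, no
outlier handling: the DEMI call thresholds the raw p-value at 0.05 and
|log2FC| at 0.5 (both inclusive), so the adjusted p (reported as
Benjamini–Hochberg for reference) plays no role in the call. "Up" means
higher in the SFH group.

## Seed-site prediction

The seed is miRNA nucleotides 2–7 (5'→3'); a site is the reverse
complement of the seed in the UTR. Classes follow the canonical-site
hierarchy — 8mer (seed match + Watson–Crick match to miRNA nt 8 on the
site's 5' flank + A opposite nt 1 on the 3' flank), 7mer-m8, 7mer-A1,
6mer — with G:U wobble not accepted in the seed match, and every locus
reported once under its best class. Coordinates are 1-based inclusive on
the given strand, `utr_start` being the site's 5'-most nucleotide.
Context++ scoring is not re-implemented (it is a trained regression over
conservation and accessibility features); TargetScan-format tables can be
ingested instead, filtered at cumulative weighted context++ ≤ −0.4
(per-gene scores, as in TargetScan's gene-level export), and the scanner
provides a self-contained substitute for synthetic runs.

## PCIT networks

For every unordered trio (x, y, z), first-order partial correlations

$$r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}{\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}$$

define a local tolerance ε, the mean absolute ratio of partial to direct
correlation over the trio's three rotations; an edge (x, y) is eliminated
when some z satisfies both |r_xy| < ε|r_xz| and |r_xy| < ε|r_yz|.
Numerical conventions: a trio containing a perfect pairwise correlation
(|r| = 1) is skipped and counted (the partials are undefined there), and
a zero direct correlation contributes 0 to ε rather than infinity — an
absent association should not license eliminating others. The O(n³) trio
loop is C++ (about 7×10⁷ trios for the 757-node scale of a real run, well
under a minute); the test suite holds it to exact agreement with a pure-R
exhaustive triple loop on 30-node matrices.

Correlations are Pearson on raw CPM over the condition's samples, using
only samples with both miRNA and mRNA profiles (7 in FH, 6 in SFH at the
default design). Network edges are PCIT-significant pairs with |r| > 0.6
that involve at least one miRNA; gene–gene pairs are recorded in the full
dump but not returned as edges. A per-edge correlation t-test p-value is
reported for reference but does not gate edges — the r-threshold plus
PCIT survival is the gate.

## Connectivity and rewiring

Standardized connectivity is degree over the maximum degree within that
network, so each network's hub sits at K = 1. DK = K_SFH − K_FH is
z-scored over the union node universe (a node absent from one network has
degree 0 there); |z| ≥ 1.96 is significant, directed as gain (DK > 0) or
loss with SFH as the reference. Genes and miRNAs are z-scored jointly.

The rewiring score treats each node's two condition-specific weighted
neighbor vectors (edge r if present, else 0, over the union neighbor set)
as two states; Dn is their mean distance from the centroid — with two
states, half the Euclidean gap — and the degree-corrected variant divides
by the union degree (floored at 1 for isolated nodes). Dn is zero exactly
when the weighted neighborhoods agree, and symmetric in the group labels.
Exact numeric parity with the DyNet Cytoscape plug-in is not a contract;
the score is re-derived from the centroid-distance idea.

**Limitation worth stating plainly:** at 6–7 samples per condition the
null distribution of Pearson r is wide — P(|r| > 0.6) is roughly 0.15 at
n = 7 and 0.21 at n = 6 — so every node in a small network acquires a few
condition-specific chance edges that look like rewiring. In simulations
at the default design, planted rewired genes land in the top decile of
degree-corrected Dn only about half the time; the per-pair edge recovery
of planted couplings, by contrast, is ≈ 0.95–1.0. Rankings of
degree-corrected Dn at this sample size should be read as suggestive, not
as a calibrated statistic. (The per-node top-decile rate averaged over
replicates is the recovery metric we report; with only a handful of
planted rewired nodes it is the stable summary.)

## Duplex minimum free energy

An intermolecular-only dynamic program: base pairs form between the miRNA
and an antiparallel target window, with no intramolecular structure.
Watson–Crick and G:U pairs are allowed; consecutive pairs score
Turner-style nearest-neighbor stack energies; interruptions score
length-dependent bulge/internal-loop penalties (internal loops add a
capped asymmetry term, `min(3.0, 0.6·|l1−l2|)` kcal/mol); one duplex
initiation penalty (4.09 kcal/mol) applies per duplex. Loop lengths are
capped at 15 per side — beyond that, extension is never favorable given
the penalty slope. The parameter table ships as documented plain text
(`extdata/duplex_energy_params.txt`) and its nearest-neighbor symmetry
`E(p1,p2) = E(rev p2, rev p1)` is asserted at load. Simplifications
relative to full folding engines: no terminal-AU penalty, no dangling
ends, no special 1×1/2×2 internal-loop tables, no per-site p-value model.
The mfe is the minimum over all target positions, clamped to 0 when no
stable duplex exists. Genes with multiple transcripts get the arithmetic
mean of per-transcript mfe, and the affinity call is strict:
gene-average mfe < −20 kcal/mol (an average of exactly −20 fails).

One consequence of the Turner parameters: a perfectly complementary
duplex of 14 nt is *not* guaranteed to clear −20 kcal/mol — AU-rich
14-mers fall short (the weakest stack is −0.9 kcal/mol). At mature-miRNA
length (21–22 nt) full complements always clear it.

## Enrichment

Upper-tail hypergeometric per term (`P(X ≥ overlap)` with the supplied
annotation as the background universe), Holm's step-down correction with
significance at 0.05, and term de-duplication by Cohen's kappa on the
2×2 membership tables: terms with κ ≥ 0.4 are joined and clusters are
connected components, each represented by its lowest-p member. Full
ClueGO-style term fusion and cluster-level aggregate p-values are not
reproduced — clustering here only de-duplicates labels.

## The synthetic-data generator

The generator's defaults are the study conditions: 341 miRNAs × (7 FH +
7 SFH), 741 genes × (7 FH + 6 SFH, mirroring the dropped SFH mRNA
sample), NB counts with dispersion 0.1, log-normal(0, 0.2) library-size
factors, 16 planted DEMIs with |log2FC| uniform on [0.5, 2] (the lower
bound equals the DEMI threshold so planted effects are detectable in
expectation), and uniformly random UTR lengths of 500–2000 nt.

Design choices that were genuinely open:

* **Coupling through realized expression.** A planted target's latent
  log2-abundance in an active condition is
  `log2(baseline) − slope·z + noise`, where z is the planted miRNA's
  *realized* log2-CPM standardized within that condition's samples and
  the default slope is 2. Coupling to the realized profile (rather than
  to an extra shared latent) keeps the miRNA marginal exactly NB and
  means the target tracks what the miRNA actually did in each library.
  Base-2 exponentiation keeps the dynamic range at `2^±(2·z)` — on the
  raw-CPM scale, where the networks correlate, a natural-base version
  produced such long tails that planted correlations degraded.
* **One planted target per DE miRNA** (`n_target_genes = 16`). The
  generator does not model target-specific regulation, so several targets
  of one miRNA would share the same latent up to small noise —
  correlating at 0.95–0.99, which is degenerate input that partial
  correlation rightly prunes. One target per miRNA keeps planted pairs
  identifiable and the planted structure honest.
* **Rewired fraction 0.15.** Rewired pairs are active in one condition
  only; their genes are the planted rewired nodes. The fraction is kept
  small so the planted rewired set fits within a decile of the network
  node universe, the scale on which rewiring recovery is defined.
* **Sequence generation by segment-wise rejection.** UTRs are built in
  ~120-nt segments; a segment is redrawn (cap 1000, then an error naming
  the offending miRNA) while it creates any 6mer-or-better match to a
  planted seed. The acceptance window carries only 5 context characters,
  so a hit must overlap the new segment — whole-sequence rejection at
  2 kb against 16 seeds has acceptance probability ≈ 4×10⁻⁴ and is not
  viable. Planted sites are written at recorded positions with flanks
  guarded so the recorded class is exactly the best class at that locus.
  Decoy UTRs are generated for 50 genes (plus the 16 targets), emulating
  partial prediction coverage rather than sequences for all 741 genes.
* **Pathways.** One term of 15 genes holds 10 planted targets; 25 decoy
  terms are uniform draws from the 741-gene universe.

What the generator does **not** emulate: isomiR structure, conservation,
3'-compensatory or ORF sites, correlated library composition, batch
effects, or any gene–gene regulatory structure beyond the planted
miRNA couplings. Passing the recovery tests therefore shows the pipeline
recovers the planted signal under idealized independence assumptions — it
does not certify behavior on real data with correlated backgrounds.

## Problem sizes and determinism

The test suite and the acceptance script run the generator at the default
study scale (341 × 14 and 741 × 13) for pipeline-level checks, 20
simulation replicates for recovery rates, 2000 null and 200 planted
features for the DE operating characteristics, 50 random 30-node matrices
against the PCIT oracle, 1000 random trios against matrix inversion, and
10,000 random 1-kb UTRs against the sliding-window scanner oracle — sizes
chosen so each property is measured with comfortable margins while the
whole suite stays quick. All randomness flows from explicit seeds;
`run_pipeline()` with a fixed seed produces byte-identical stage outputs,
and the config hash recorded in the manifest changes exactly when a
threshold or input changes.
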