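---
title: "Modeling CRISPR/Cas9 off-target effects with moffr"
author: "moffr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CRISPR/Cas9 off-target effects with moffr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moffr)
```

# The problem

SpCas9 cleaves genomic sites that resemble, but do not exactly match, the
20-nt guide (crRNA) spacer. How strongly a mismatched site is cut depends
on three separable factors:

1. an **individual mismatch effect** (IME) set by the identity and
   position of each mismatch — the M1 matrix, a 12 × 20 table indexed by
   the rX:dY pairing (crRNA base X against the base Y on the
   complementary target DNA strand) and the protospacer position, counted
   PAM-proximal = 1;
2. a **guide-intrinsic mismatch tolerance** (GMT): some guides tolerate
   *any* mismatch better than others, independent of mismatch context;
3. an **"epistasis-like" combinatorial effect** of multiple mismatches:
   the joint effect of two mismatches is usually *smaller* than the
   product of their individual effects, quantified by a symmetric 20 × 20
   matrix of pairwise factors $\delta_{ij} \le 1$ (the M2 matrix).

moffr implements the full measurement-and-modeling stack around these
quantities: the dual-target synthetic screen that measures relative
cleavage rates, the statistical decomposition that separates the three
factors, a sequence-based GMT predictor, a kinetic model of R-loop
formation that rationalizes the combinatorial rules, and the MOFF scores
that put everything back together to predict off-target activity.

# The dual-target measurement model

A dual-target construct carries an off-target and an on-target
protospacer in tandem on one amplicon, so the on-target cleavage rate is
an internal control. Each sequenced read is classified into one of five
editing outcomes $C = (c_1..c_5)$: wt+wt, indel at the off-target only,
indel at the on-target only, indels at both, or a large deletion. The
unobserved cleavage states $S = (s_1..s_4)$ (no cleavage, off only, on
only, both) generate outcomes through a 4 × 5 row-stochastic transition
matrix $P$:

$$C = P^\top S + \varepsilon .$$

Structural zeros constrain $P$: the off-only state can only produce the
off-indel category; the on-only state produces the on-indel category or a
large deletion; the both state produces double indels or a large
deletion. The first row (background noise and PCR artifacts) is free.
Category labels follow the construct's left-to-right layout — `indel_wt`
means an indel at the left (off-target) site — which is the only labeling
consistent with those structural zeros.

$P$ is estimated from PAM controls: constructs whose two identical
protospacers are silenced per-target by replacing NGG with NTT. The
NTT+NTT group estimates the noise row directly; NGG+NTT and NTT+NGG are
two-component mixtures (noise + state) solved explicitly; the NGG+NGG
group mixes all four states (either target can escape cleavage) and row 4
is solved by linear equations given rows 1–3, with negative solutions
clipped and rows renormalized.

Given $P$, per-construct states are inferred by non-negative least
squares, $\min_{S \ge 0} \lVert P^\top S - C\rVert^2$ (Lawson–Hanson via
`pracma::lsqnonneg`), and the off-on ratio is

$$r = \frac{s_2 + s_4}{s_3 + s_4},$$

with pairs failing a minimum of 100 on-target-edited reads filtered out
and logs computed as $\log(r + c)$, $c = 0.01$, matching the assay's
dynamic range of roughly 0.02–1. Natural logarithms are used everywhere
in the package (the log base is a convention; thresholds such as the
MOFF-aggregate cutoff of 1 are interpreted on this scale).

## Read processing choices

Merged reads are assigned to constructs only on an exact match of the
10-nt barcode 1 and the last 10 nt of barcode 2; reads are assumed
trimmed to the amplicon so both keys sit at fixed offsets. The
inter-barcode region is then aligned to the designed amplicon with an
affine-gap aligner (match +2, mismatch −2, gap open 8, gap extend 1; a
gap of length $L$ costs $8 + L$). Classification uses a *global*
(end-anchored) alignment: the amplicon ends are anchored by the barcodes
that produced the assignment, and a local alignment would clip, rather
than gap, a >32-bp deletion that leaves only a short flank — making the
large-deletion category unreachable. The package also exposes the plain
Smith–Waterman local alignment (`alignLocal()`), which the tests verify
against an exhaustive dynamic-programming oracle.

A read is a large deletion if any single deletion exceeds 32 bp
(configurable); otherwise indels are tested in a 10-bp window centered on
each cut site, taken as the canonical blunt cut 3 bp 5′ of the PAM. An
insertion reported at boundary $b$ is counted against the window over the
interval $[b, b+L]$: tandem-duplication insertions (the most common Cas9
+1/+n products) align ambiguously and can be placed anywhere within one
copy of the duplicated sequence. Inversions between the two cut sites are
not modeled.

# Decomposition

For 1-MM observations the model is additive in logs,
$\log(r_{ij}+c) = \log m_j + \log g_i + \varepsilon$, fit by full-batch
gradient descent on the least-squares objective (`fitM1Gmt()`; with unit
step size the block updates are exact alternating least squares, and the
tests confirm equality with the closed-form two-way solution on a fully
crossed design). The multiplicative gauge freedom ($m \to \alpha m$,
$g \to g/\alpha$) is fixed by centering $\log g$ to mean zero, so M1 is
the effect for a guide of average tolerance; the fit is unweighted (read
depths are not used as weights). Disconnected guide/mismatch-type
observation graphs leave the gauge ambiguous across components and
trigger a warning.

Pairwise combinatorial effects use the closed-form least-squares
estimator
$\hat\delta_{ij} = \sum_k x y z \,/\, \sum_k (yz)^2$
on linear-scale ratios, where $x$ is a 2-MM ratio and $y, z$ its two
1-MM parents (the nested 1/2/3-MM library design guarantees the parents
exist). Cells pool the five neighboring position pairs
$(i,j), (i,j\pm1), (i\pm1,j)$, clipped at positions 1 and 20; empty pools
are flagged missing and delta indices run 1..20 (a position 0 has no
protospacer meaning). `computeRcs()` provides the complementary
observed/expected co-occurrence score for detected off-target sites,
averaged per guide.

# Predicting GMT from sequence

Guides are encoded either as a 4 × 20 one-hot mononucleotide array or a
16 × 19 one-hot dinucleotide array (row order AT, AC, AG, AA, TT, TA, TG,
TC, CC, CA, CG, CT, GG, GA, GT, GC). The GMT regressor is a minimal
convolutional network: `k` kernels (default 3) spanning all 16 encoding
rows with width one position pair, followed by a dense layer onto a
single output neuron, trained on log-GMT with mean-squared-error loss by
full-batch gradient descent. The model is linear in its factorized
weights, which keeps it identifiable at the ~1,400-guide training scale
and makes the kernel-derived dinucleotide weights directly comparable to
stacking energies. A step that increases the loss is reverted and the
learning rate halved, which stabilizes the jointly trained factors.
Defaults: 5-fold cross-validation (a folds argument accommodates 10),
1,500 epochs, learning rate 0.05, all randomness seeded. Targets are on
the log scale, matching the additive decomposition that produced them.

# The kinetic model

Cleavage is modeled as a nearest-neighbor random walk over the states
unbound → PAM-bound → hybrid length 1..20 → cleaved, with the two ends
absorbing. PAM binding lowers the free energy by 5 $k_BT$; each matched
hybrid base pair lowers it by 0.25 $k_BT$; a mismatch raises it by
4 $k_BT$ when isolated and by 3 $k_BT$ when it extends an existing bubble
(a maximal run of consecutive mismatches). Hop rates are Arrhenius,
$k_{i\to j} = \exp(-\max(0, G_j - G_i))$, which satisfy detailed balance
to machine precision; the final cleavage step is taken barrierless. The
splitting probability of cleaving before unbinding is solved exactly by
first-step analysis (a tridiagonal linear system), and a jump-chain Monte
Carlo simulator provides an independent stochastic check. The
model-predicted combinatorial effect is

$$\delta^{model}_{ij} = \frac{P(i,j)\,P(\varnothing)}{P(i)\,P(j)},$$

which reproduces the observed rules: strong epistasis for seed-region
pairs, near-independence when a mismatch sits at position 19/20, and —
aggregating over positions so the position trend does not confound the
distance trend — adjacent mismatches (one 2-nt bubble) are milder than
pairs separated by 1–6 nt (two 1-nt bubbles). In the zero-cost limit the
heatmap collapses to 1 only up to the small residual effect of a costless
mismatch still forgoing its 0.25 $k_BT$ match gain; the implementation
keeps the mismatch step at exactly the stated cost rather than cost
minus match gain, because the isolated-mismatch step height (+4 $k_BT$)
is the anchored quantity.

Sequence-based landscapes accumulate dinucleotide stacking-energy
differences (DNA:DNA minus RNA:DNA). The built-in `defaultEnergyTable()`
is a **synthetic toy table** whose only designed property is that GC-rich
steps favour the hybrid; published nearest-neighbor parameter sets are
not redistributed and can be supplied as JSON via `readEnergyTable()`.

# MOFF scores

For a guide and a site with $k$ mismatches,

$$S_{MOFF} = \sum_{i=1}^{k} \log s_i
  + \frac{2}{k} \sum_{i<j} \log \delta_{ij}
  + k \log s_{GMT},$$

the log predicted off-on ratio. The pairwise sum runs over each unordered
pair once. A perfect match scores 0; $k = 2$ adds a single
$\log\delta$; for $k = 3$ the construction equals the geometric mean of
the three sequential orderings of adding a third mismatch, and the $2/k$
coefficient extends this by induction. Missing $\delta$ entries impute to
1. With $\delta \equiv 1$ and $s_{GMT} \equiv 1$ the score reduces
exactly to the product of M1 entries — the marginally independent model
that MOFF generalizes.

`moffAggregate()` scans both strands for NGG-adjacent 20-mers within 6
mismatches (NAG optionally) and reports the natural log of the summed
predicted ratios over all off-target sites; perfect-match sites are
excluded as on-targets, and a guide with no candidate site is floored at
$\log c$. DNA/RNA bulges are not modeled.

`moffAllele()` designs allele-discriminating guides for a 1-bp variant:
seed guides perfectly match the mutant allele and cover the variant; all
single-mismatch variants of each seed (those not recreating the wildtype
base) are scored against both alleles on the ratio scale
$e^{S_{MOFF}}$, where the efficiency threshold (mutant ratio > 0.5) and
selectivity threshold (wildtype/mutant < 0.2) are meaningful; candidates
are ranked by ascending selectivity ratio.

# Synthetic data and what passing tests show

Every generator is a pure function of (parameters, seed) and ships its
ground truth. Defaults reflect the screen conditions the package models: guides are i.i.d.
uniform with the thymine-homopolymer filter; 1-MM ratios follow
$m_j g_i$ with lognormal noise ($\sigma = 0.2$ for recovery
experiments); 2-MM ratios follow $y z \delta$; the dynamic range can be
clipped to 0.02–1. M1 truth has a seed/non-seed position trend (means
0.1 and 0.5 with lognormal jitter), GMT spread is $\sigma_{\log g} =
0.5$, and the delta truth varies smoothly with position so that the
neighborhood-pooled estimator remains consistent. Reads are simulated at
depth $10^4$ per construct for the end-to-end checks, with small indels
(geometric lengths truncated at 15 nt, deletions 60%, insertions as
templated duplications) inside the cut windows and 33–80-nt large
deletions spanning from the off-target cut; insertions are templated
both because that is the dominant Cas9 repair outcome and because it
keeps alignment memoization effective. The recovery tests use 1,438
guides with three 1-MM observations each and a 28-construct
dual-target + 16-construct control read simulation — sizes chosen so
the whole suite runs comfortably on a laptop while matching the study's
parameter scale where it matters (the number of guides and observations
per parameter).

Synthetic data emulate barcode demultiplexing, outcome classification
and the generative decomposition model; they do not emulate PCR
amplification bias, lentiviral integration effects, base-quality errors,
chromatin context, or bulge-containing off-targets. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not performance on real screens.

# Numerical and design choices

* **Barcodes** are sampled uniformly (seeded) from a shortened GF(4)
  Hamming code, giving a guaranteed minimum pairwise Hamming distance of
  3 at linear cost; barcode pairs are unique across a library.
* **Primer/linker constants** are fixed, GC-balanced, and free of GG/CC
  dinucleotides so no construct gains an accidental NGG PAM.
* **Mismatch draws** in the library designer use three distinct
  positions per guide (required for the nested 2-MM/3-MM scheme), with
  the alternative base uniform — mismatch categories are not stratified
  by region.
* **NNLS** uniqueness holds for full-rank $P^\top$; the zero count
  vector maps to the zero state vector.
* **Convergence**: the decomposition stops when the relative objective
  change falls below $10^{-10}$; delta cells with empty pools are
  missing, and missing deltas impute to 1 at scoring time.
* **PAM controls**: one pooled transition matrix is estimated across all
  controls rather than per construct.
* **Cut site**: between protospacer positions 3 and 4 counted from the
  PAM (the canonical blunt cut); the 10-bp windows are centered there
  (±5) and configurable.
* **Large-deletion threshold**: 32 bp, configurable.

# Known limitations

The GMT regressor is linear in its factorized weights; it cannot express
interactions between distant dinucleotides. The kinetic chain uses a
single attempt rate and barrierless cleavage from the full hybrid, so
absolute cleavage probabilities are illustrative — only contrasts
(ratios such as $\delta^{model}$) are interpreted. Off-target scanning
is Hamming-only (no bulges) and NGG/NAG-only. The allele module assumes
a single-nucleotide difference between alleles.

# A worked example

```{r example, eval = FALSE}
set.seed(1)
guides <- simulateGuides(6, seed = 1)
lib <- designDualTargetLibrary(guides, seed = 2)
m1 <- simulateM1(seed = 3)
gmt <- simulateGmt(guides, seed = 4)
tab <- simulateOffOnTable(guides, m1, gmt, simulateDelta(), sigma = 0.1,
                          seed = 5)
fit <- fitM1Gmt(tab$obs1)
head(fit$gmt)
```

The README shows the full pipeline, including read simulation,
classification and MOFF scoring, with the numbers it prints.
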