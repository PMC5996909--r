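---
title: "Methods: motif-level analysis of the EIF4A3 5'UTR repeat locus"
author: "repeatlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-level analysis of the EIF4A3 5'UTR repeat locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatlens)
```

# The locus and the data model

The *EIF4A3* 5′UTR carries a tandem array of three repeat units — CA18
(18 nt), CACA20 and CGCA20 (20 nt each) — that share the 10-nt head
`TCGGCAGCGG` and differ only in their central nucleotides. Because every
motif ends in `GG` and starts with `T`, motif boundaries in a valid array
can only occur at `GG|TC` junctions, which makes the tiling of any sequence
composed purely of these motifs *unique*. An allele is therefore fully
described by its ordered motif list (plus any non-motif insertion segment),
and the package's central object, `AlleleStructure`, stores exactly that.
All downstream analyses — classification, recombination, expression
modelling, CpG accounting — operate at motif granularity.

Two clinically motivated thresholds define the allele taxonomy: control
alleles carry up to 12 repeats of CA18/CACA20, patients carry 14–16 repeats
enriched in the disease-associated CGCA20 motif, and the syndrome is
recessive. `classifyAllele` exposes the pathogenic-candidate threshold
(default 14 repeats plus at least one CGCA20) as a parameter because the
13-repeat zone was observed in neither group: a 13-repeat CGCA20-bearing
allele is classified by the configurable threshold, and cohort summaries
count it in an explicit "indeterminate zone" field rather than silently
assigning disease relevance. A 17-repeat CGCA20-rich allele found in
heterozygosis in an unaffected carrier is classified pathogenic-candidate,
consistent with the recessive model.

## Decomposition

`decomposeSequence` is an anchored scan with backtracking: at each offset it
tries every motif (longest first) and recurses. Although tiling is provably
unique for the default alphabet, backtracking keeps the decomposer correct
for user-supplied alphabets where greedy longest-match can fail. With
`allowInsertions`, non-motif segments of up to 20 nt (the observed atypical
population alleles carry 12- and 20-nt segments) are admitted between
motifs; insertion segments are retained verbatim, never aligned to motifs,
and insertion-bearing alleles are excluded from recombination and
expression modelling. Sequences are handled in the orientation in which the
motifs are written; because the genomic strand convention of an arbitrary
input is not fixed, `autoOrient = TRUE` also tries the reverse complement
and keeps whichever orientation tiles.

# Heterozygote deconvolution

Diploid amplicons sequenced in one Sanger read produce a mixed signal. We
model it at sequence level: `superpose` left-aligns the two amplicons at
the sequencing-primer (5′) side and emits, per position, the IUPAC union of
the bases present; beyond the shorter amplicon the longer allele alone
determines the code. Shared primer-side and distal flanks (30 nt each in
the synthetic generator) are part of the amplicon, so after the frame shift
introduced by a length difference, the shorter allele's 3′ flank
superposes against the longer allele's repeat region — exactly the regime
in which mixed traces become hard to read by eye.

`deconvolve` inverts this forward model exactly. A depth-first search
enumerates every motif tiling whose bases are compatible with the IUPAC
constraint at each position (pruned by the per-position compatibility, with
an optional mismatch budget ≤ 2 to mimic base-calling noise; default 0,
exact); compatible tilings are then paired, and each pair is scored by
re-running the forward model. All zero-mismatch pairs are reported, ranked
by mismatch count and then lexicographically by nomenclature.

Phase ambiguity is intrinsic to a union signal: when two motif slots are
heterozygous, swapping which allele carries which motif leaves the union
unchanged, so several allele pairs can be exactly consistent with one mixed
read. The package enumerates these ties rather than hiding them — on
random 2–12-repeat heterozygotes roughly half to two thirds of superpositions
admit more than one zero-mismatch pair, while the generating pair is always
among them (soundness is asserted over 200 random heterozygotes in the
tests). This mirrors why the original analysts validated mixed-sequence
genotypes by cloning and sequencing alleles separately; the measured
ambiguity rate is reported but has no published counterpart to compare
against.

# Unequal crossing-over and allele origins

Observed alleles are mosaics of whole motifs, so recombination is modelled
with motif-granular breakpoints in the register imposed by the shared
motif head; sub-motif breakpoints would create repeat units never observed
at the locus. `unequalCrossover` splices `p1[0:b1]` onto `p2[b2:]` and vice
versa; total motif count is conserved, and the exchange is unequal when
`b1 != b2`. There is deliberately no replication-slippage or stepwise
mutation mode: the locus is transgenerationally stable, in contrast to
dynamic-mutation repeat disorders, and the model makes unequal exchange the
only mutational force so that its consequences can be studied in isolation.

`evolvePopulation` embeds this event in a Wright–Fisher population of
constant diploid size: each transmitted allele is, with probability
`crossoverRate`, a crossover product of the parent's two homologs, with the
(b1, b2, product) choice uniform over misaligned pairings whose product
size lies in a viable range of 2–20 motifs (the observed range 2–17 plus
headroom). With `crossoverRate = 0` the allele spectrum changes only by
drift, matching the observed stability as a model property.
`derivationDistance` runs a breadth-first search over crossover products of
a pool (and accumulated products) to find the minimal number of events
deriving a target allele — the origin hypothesis for pathogenic alleles
made executable. The search is exponential in depth and is bounded at a few
events (tests plant and recover 0-, 1- and 2-event constructions); no
recombination rate or ancestral pool is known for the real locus, so
simulator outputs are properties of the model, not historical estimates.

# Haplotypes and linkage disequilibrium

Five SNPs flank the repeat locus in plus-strand order
rs11150824 – rs2289534 – (repeat) – rs3829612 – rs10782008 – rs12943620.
`emPhase` is a standard EM over exhaustive haplotype-pair expansions of
unphased genotypes (at most 8 loci), with the repeat locus entering as a
categorical allele. Initialization is uniform, so runs are deterministic;
convergence is declared at a log-likelihood change below 1e-8 with a
1000-iteration cap, the log-likelihood is asserted non-decreasing on every
run, missing genotypes are marginalized per individual, and ties in the
most probable phase break toward the pair whose first haplotype has higher
frequency. `dPrime` implements D = pAB − pA·pB and D′ = |D|/Dmax with the
standard bound; a monomorphic locus raises an error rather than returning
zero, since LD is undefined there. The published weak-LD summary does not
state which marker pair it refers to, so `pairwiseDprime` reports all
pairwise values and their maximum rather than guessing.

Real-cohort haplotype identities are not reproducible — the underlying
cohort was never deposited — so the module reproduces the *method*, and the
synthetic generator provides the weak-LD regime (below) plus planted
shared-haplotype scenarios to exercise the carrier-origin logic.

# Reporter expression

Per well, the firefly/Renilla ratio is normalized between the negative
(0%) and positive (100%) control means:
`percent = 100 (r − r_neg) / (r_pos − r_neg)`. Replicate wells are averaged
per construct; when several independent experiments are present the
default normalizes within each experiment before averaging across them
(whether the original assays pooled or per-experiment normalized is
unstated, so both modes exist behind a flag). Standard errors are
propagated from experimental replicate variance only, controls treated as
fixed. Reported percents round to 2 decimals, matching the precision of
the printed activities (22.45, 19.69, 17.8, 11.96).

`perMotifEffect` reproduces the field convention used for the printed
pairwise comparisons: the activity difference between two
comparable-composition constructs is divided by the *total* number of
motifs added and attributed to the dominant added motif type. Between the
4- and 10-repeat constructs (6 motifs added) this gives 2.76% and 0.46%
per CACA20; between the 12- and 16-repeat constructs (4 motifs added:
three CGCA20 and one CACA20) it gives 5.84% and 1.46% "per CGCA20" —
the convention attributes the whole difference to the dominant type even
though one added motif is CACA20. `fitMotifModel` is offered as the
principled alternative: least squares of percent on per-type motif counts,
with a rank check naming collinear designs and leave-one-out refits for
stability. The two agree exactly when only one motif type is added and
noise is zero. Note the consequence of the convention: a generator planting
per-type betas of −0.46/−1.46 yields a 12-vs-16 delta of 4.84 (= 0.46 +
3×1.46), not 5.84; the printed 5.84 is a property of the measured
activities, not of any per-type linear model.

Group comparisons use one-way ANOVA with Tukey HSD at alpha 0.05, via the
standard `stats::aov`/`TukeyHSD` machinery.

# Bisulfite methylation

`bisulfiteConvert` models the chemistry forward: non-CpG cytosines convert
C→T with the conversion efficiency; CpG cytosines convert only when
unmethylated (also subject to efficiency). Only the top (motif-sense)
strand is modelled and CpG methylation is treated as symmetric — clones of
PCR products do not track strand. `filterClones` aligns each clone globally
to the unconverted reference (match +1, mismatch −1, gap −2; the reference
tool's internal scoring is unpublished) and applies the four published
thresholds exactly: conversion ≥ 95%, identity ≥ 90%, N at cytosine
positions ≤ 20%, gap fraction ≤ 20%; every violated threshold is recorded.
Identity is computed over gap-free, N-free columns and treats a C/T
difference at *any* reference cytosine as the bisulfite-expected change
rather than a mismatch. This choice matters: at the 1.7–2.8% methylation
levels seen at this locus, nearly every CpG cytosine legitimately reads T,
and counting those as mismatches would push every valid clone below the
90% identity threshold — a convention under which the published analysis
could not have retained any clones.

Quantification counts, over kept clones, the fraction with a retained C per
CpG site and globally (the global fraction equals the call-count-weighted
mean of the per-CpG fractions). Note that a methylated *call* arises either
from true methylation or from a conversion failure at an unmethylated CpG,
so the expected call rate is `p + (1 − p)(1 − efficiency)`; recovery tests
compare against this quantity, not the raw methylation probability. Group
comparison defaults to pooling methylated/unmethylated calls per group into
a single 2×2 Fisher exact test (matching a global low-methylation
comparison); whether the original test was pooled or per-CpG is ambiguous,
so a per-CpG mode with Bonferroni correction is also provided.
`fisherExact2x2` computes the two-sided p-value by the point-probability
method (summing hypergeometric probabilities not exceeding that of the
observed table, relative tie tolerance 1e-7) and is tested against full
margin-fixed enumeration to 1e-12.

# The synthetic generator

No raw data were deposited for the study this package operationalizes, so
the generator is first-class: it emulates the study conditions and plants
ground truth sufficient to score every recovery test without regeneration.

* **Cohort** (`generateCohort`): 380 individuals by default, allele pairs
  drawn under Hardy–Weinberg (an inbreeding knob exists, default 0, because
  families at a recessive locus are consanguinity-prone) from a *stylized*
  spectrum: repeat counts 2–17, modal 7- and 8-repeat alleles at 25.46% and
  23.21%, the most common allele `4xCACA20+CA18+CACA20+CA18`, one
  single-motif-type allele, and 1% of alleles carrying CGCA20 within 11+
  repeat alleles, including a 17-repeat allele with 14 CGCA20. Exact
  per-allele population counts were published only as a figure, so the
  spectrum is configuration labelled "stylized", not a claim about the
  cohort. Heterozygote amplicons are emitted through `superpose` with fixed
  30-nt flanks.
* **SNP haplotypes**: the default distribution covers all 32 haplotypes of
  the 5-SNP panel, built as the product of per-SNP allele frequencies
  (0.30–0.50 alternate) tilted by a fixed adjacent-marker interaction
  (eps = 0.30) and renormalized; its maximum pairwise D′ is 0.34, inside
  the weak-LD regime (D′ < 0.48), and `cohortSpec` validates any
  user-supplied distribution against that bound. A note on design: a
  distribution supported on only four haplotypes cannot keep all ten SNP
  pairs below complete LD (four rows cannot realize all four gametes for
  every pair of five columns), so the weak-LD default uses the full
  32-haplotype support, and the small 4-haplotype panels used in EM
  recovery tests make no claim about pairwise D′.
* **Luciferase plates** (`generateLuciferaseDataset`): per-construct true
  percents follow intercept + Σ beta × count with per-motif betas
  defaulting to the pairwise estimates (−0.46 for CA18/CACA20, −1.46 for
  CGCA20) and intercept 24.29 (so the 4-repeat construct sits at 22.45%);
  per-well Gaussian noise on the percent scale is inverted through the
  normalization formula to firefly counts; controls are exact, so zero
  noise reproduces planted percents to machine precision. Wells implying
  percents outside (−20, 120) are flagged and their ratios floored at a
  small positive value.
* **Bisulfite clones** (`generateBisulfiteDataset`): per-CpG states drawn at
  the planted probabilities (defaults emulate the 1.7%/2.8% regime, 10
  clones per sample, conversion efficiency 0.995), plus deterministic
  planted filter violations — one clone each at conversion 0.90, ~14%
  mismatch, 25% N-at-C, or a 25% deletion — each tripping exactly its own
  threshold.

What the generator does **not** emulate: chromatogram traces and peak
heights (sequence-level IUPAC presence/absence only), luminometer noise
beyond Gaussian, plate/batch effects, strand-specific methylation, and any
real LD structure beyond the tilted-product model. Passing recovery tests
therefore demonstrates correctness of the algorithms under the stated
generative model, not performance on raw Sanger traces.

# Numerical choices and problem sizes

Determinism: every stochastic component takes an integer seed; the
pipeline derives per-stage seeds from one master seed, and regeneration is
byte-identical under the same spec and seed. Degenerate inputs raise
errors rather than silent defaults (monomorphic loci in LD, missing
controls or positive ≤ negative in normalization, zero kept clones,
rank-deficient expression designs, out-of-range breakpoints). Tie-breaks
are stated: deconvolution candidates sort by mismatches then nomenclature;
EM phase ties prefer the higher-frequency haplotype; Fisher ties use the
standard 1e-7 relative tolerance.

The shipped tests and acceptance script use problem sizes chosen to
exercise each property well past its noise floor while staying desk-scale:
1000 random alleles for the round-trip property, 200 heterozygotes for
deconvolution soundness, 100 and 10,000 individuals for EM recovery
(±0.05 and ±0.01), 12 wells per construct for beta recovery (±0.5 at noise
sd 1), 6–7 samples × 10 clones for the methylation regime, and 2-event
derivation searches over small pools.

# Known limitations

* Deconvolution assumes both alleles share the configured flanks and a
  common 5′ alignment; it does not model trace quality, indels within
  motifs, or somatic mosaicism.
* `derivationDistance` is exact only within its event bound and becomes
  expensive beyond 2–3 events.
* EM phasing enumerates haplotype pairs exhaustively and is limited to 8
  loci; it is not a scalable phaser.
* The crossover simulator has no mutation, selection or coalescent
  machinery; it tests reachability and stability, not allele ages.
* Real-cohort figures (the 43-allele catalogue, 85% heterozygosity, the
  published haplotype sharing, the 1.7%/2.8% methylation) derive from
  undeposited data and are reproduced only as regimes/properties of the
  synthetic model, never as numeric targets.
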