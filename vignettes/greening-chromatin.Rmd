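---
title: "Methods: temporal chromatin dynamics and the methylation-to-acetylation switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal chromatin dynamics and the methylation-to-acetylation switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenswitch)
```

# The experimental design this package models

A dark-grown, photosynthetically inactive plant cell culture is moved into
constant light and sampled at four timepoints — Dark, Day1, Day4, Day7 —
by which point functional chloroplasts have formed. At each timepoint,
ChIP-seq profiles four histone modifications (H3K4me3 and H3K27ac for
active chromatin, H3K27me3 for Polycomb-repressed chromatin, H3K9me2 for
silenced repeats), together with a total-H3 ChIP and an input-chromatin
control, in two biological replicates. The scientific question is which
genomic regions change chromatin state at which transition, and in
particular whether photosynthesis-associated genes undergo a switch: loss
of H3K27me3 in mid-course (Day1 to Day4) followed by a late gain of
H3K27ac (Day4 to Day7).

# Consensus region curation

Peak calling against two different controls (input and H3) yields two
peak lists per sample; a peak supported under both controls is far less
likely to be a nucleosome-density artefact. `conserve_dual_control()`
keeps the input-controlled peaks that overlap (at least 1 bp) any
H3-controlled peak. Two conventions here were genuinely open and are
package decisions:

- *Conservation direction.* The input-controlled list is the reference
  (its coordinates survive); the H3-controlled list acts only as a
  filter. Input-controlled calls are the field-standard primary call.
- *Replicate handling.* Peaks from both replicates are pooled before
  conservation; `strict_replicates = TRUE` additionally requires a
  conserved peak to overlap a conserved peak from another replicate.
  Pooling is the default because a replicate-agreement rule is a
  stricter criterion than the underlying experiment imposes.

Narrow peaks (H3K27ac, H3K4me3) are then re-centred to ±250 bp around
their called summit — a fixed-width window makes count comparisons across
timepoints well defined — while broad peaks (H3K27me3, H3K9me2) keep
their called coordinates: a "summit" of a broad domain is not a
meaningful anchor. The union over all marks and timepoints is merged
(`gap = 0`, so touching intervals join) into disjoint consensus regions
with stable ids (`CR000001`, ...). All coordinates are 0-based half-open
internally; GFF3 input is converted on read. Strand is carried but
ignored by overlap operations. Every interval operation sorts its output
(chromosome, start, end) so results are reproducible run to run.

# The differential statistic

For a modification sample with counts $c_{PTM}$ and its paired H3 sample
$c_{H3}$ at the same timepoint and replicate, the per-region statistic is

$$ r = \log_2\frac{c_{PTM} + 0.5}{s_{PTM}} - \log_2\frac{c_{H3} + 0.5}{s_{H3}} $$

with $s$ per-sample size factors. Dividing by H3 normalizes for
nucleosome occupancy: a region whose H3 density halves while its
per-nucleosome acetylation is unchanged shows no change in $r$ (this is a
tested invariant). The pseudocount 0.5 keeps zero counts finite; at the
simulated depths it perturbs $r$ by under 2%.

Size factors are median-of-ratios (each sample's median ratio to the
per-region geometric mean over samples, rescaled to geometric mean 1),
falling back to library sizes when fewer than 10 regions have positive
counts everywhere. Median-of-ratios anchors on the *typical* region, so
it assumes most consensus regions are not changing between any two
samples — see the simulator notes below for why that assumption is part
of the generator's design.

For a transition $t_1 \to t_2$ the effect is
$\Delta = \bar r_{t_2} - \bar r_{t_1}$ (means over replicates), and the
test is a moderated Wald test: the pooled per-region variance $s^2_g$
(residual df $d = n_1 + n_2 - 2$, i.e. 2 at two replicates) is shrunk
toward a prior $s_0^2$ with weight $d_0$,

$$ \tilde s^2_g = \frac{d\, s^2_g + d_0\, s_0^2}{d + d_0},\qquad
   t_g = \frac{\Delta_g}{\sqrt{\tilde s^2_g (1/n_1 + 1/n_2)}}, $$

referred two-sided to a $t$ distribution with $d + d_0$ degrees of
freedom. By default the prior weight is **estimated** from the data
(`shrink_df = "auto"`): under a scaled-F model the variance of
$\log s^2_g$ in excess of $\psi'(d/2)$ determines $d_0$ (the moment
estimator of Smyth 2004, solved by trigamma inversion), and when the
observed log-variances are no more dispersed than chi-squared sampling
noise allows, $d_0 = \infty$ and the test becomes a known-variance z
test. This matters enormously at two replicates: a fixed small prior
weight forces a heavy-tailed reference distribution even when thousands
of regions demonstrate that variances are homogeneous, roughly halving
per-transition detection at the simulated conditions. A fixed numeric
`shrink_df` reproduces the constant-weight variant.

Regions are called differentially enriched at `fdr <= 0.05` (BH within
each mark × transition family — per-family adjustment matches how the
per-transition counts are reported) and `|log2fc| >= 1` (fold > 2), both
boundaries inclusive.

# Trajectories, the switch set, enrichment

`classify_profiles()` is a pure function of the status triples: labels
are systematic (`"down.ns.up"` etc.), with one field-named alias —
`Profile5` = H3K27ac with `(ns, ns, up)`, regions acetylated only at the
final transition. `switch_overlap()` builds the switch gene set at the
gene level: any annotated region with an H3K27me3 "down" at Day1:Day4
plus any region with an H3K27ac "up" at Day4:Day7 qualifies a gene, and
supporting region ids are kept as provenance. Region-to-gene annotation
takes every gene whose body extended 1 kb upstream (strand-aware)
overlaps the region — all matches are retained, with no nearest-gene
collapse, because promoter-proximal peaks legitimately regulate more
than one neighbouring locus.

Term over-representation is the one-sided hypergeometric tail
$P(X \ge k)$ for $k$ term genes among $n$ selected from a universe of
$N$ containing $K$, with the enrichment ratio
$(100k/n) / (100K/N)$ ("% found vs % expected") and Bonferroni
correction by default (BH by flag). The source analysis names both an
over-representation tool and a rank-sum test for its enrichment display;
those cannot describe a single procedure, so the standard ORA
computation is implemented and the discrepancy noted rather than
guessed at. Term maps are taken as given — no ontology-graph
propagation.

# ChIP-qPCR and expression

The qPCR chain mirrors the bench protocol exactly: percent-input of the
modification divided by percent-input of H3 per locus
(`chip_ratio()`); division by the geometric mean of two control loci
chosen for constant signal (`normalize_to_controls()` — afterwards the
two controls multiply to exactly 1, a tested invariant); relativization
to a reference condition (`relativize()`). The chain is invariant to any
plate-level rescaling of a condition's percent-input values. Expression
uses plain ΔCt against the arithmetic mean of two reference-gene Cts
(equal to the geometric mean on the linear $2^{-Ct}$ scale); primer
efficiencies are fixed at 2. Group comparisons use Welch's t test;
`meta_qpcr()` averages normalized per-locus profiles with SEM across
loci. A helper converts raw Ct to percent input given the input
fraction, which the protocol leaves unstated — it is a parameter.

# Phenotyping

Pigments: absorbances at 470/652/665 nm are blanked with A750 and
divided by the 0.58 microplate pathlength factor; chlorophylls follow
the printed linear combinations and carotenoids
$(1000\,A_{470c} - 1.63\,ChlA - 104.96\,ChlB)/221$. The /221 divisor is
applied to the whole numerator: this reproduces the standard
methanol-extract carotenoid equation, whereas dividing only the last
term yields physically absurd values. Negative corrected absorbances
(blank above signal) are clamped to zero with a warning. Per-mg values
use 0.5 ml extract per 25 mg fresh weight by default, overridable per
record. Greening: the score is 255 minus the mean grey of a
cotyledon ROI on the 8-bit green channel. Both Tukey (all pairs) and
Dunnett (versus control) post-hoc tests are provided after one-way
ANOVA, since both appear in the source analyses for different figures;
no default claim is made about which fits a given experiment — Tukey is
the function default, Dunnett by argument.

# What the simulator emulates — and what it does not

`simulate_chipseq()` reproduces the design, not the genome: regions of
500 bp tiled on a toy genome with 1200 bp gaps, one gene per region,
negative-binomial counts (variance $\mu + \phi\mu^2$, $\phi$ = 0.05 by
default) at mean depth 50, per-sample depth scales drawn from
(0.75, 1.25), two replicates. Six temporal classes are planted via
per-class templates; crucially the templates are defined **on the
H3-normalized ratio scale** ($\mu_{PTM} = depth \times ratio \times
h3density$), so `effect_log2fc` is exactly the planted effect on the
scale the test measures even where H3 occupancy itself changes (switch
regions lose 30% H3 from Day4; profile5 regions are at 60% H3
throughout, matching their described low nucleosome density). Peak call
lists are emitted wherever the planted ratio is at least 2-fold over
background, in both control variants, with a configurable probability
(default 0.05) that the H3-controlled list misses a peak.

Two generator defaults encode statistical realism rather than
convenience:

- *Class fractions* (constitutive 0.40, null 0.35, dark-specific 0.08,
  silenced-repeat 0.07, switch 0.06, profile5 0.04): stable peaks must
  dominate the consensus set, as they do in real chromatin, because
  median-of-ratios normalization anchors on the median region — if the
  majority of a sample's consensus regions were differential, the size
  factor would absorb the signal and bias every fold change.
- *Region gap 1200 bp*: the toy intergenic spacing exceeds the 1 kb
  promoter-annotation window, so each region annotates to exactly one
  gene, as region-gene assignment should behave at realistic gene
  spacing.

The simulator does not emulate read-level artefacts (mappability, GC,
duplicate reads), peak-width variation, overlapping genes, or
correlated replicates. Passing tests therefore demonstrate the
statistical machinery — calibration, recovery, invariances — not
robustness to alignment-level noise in real data.

The companion generators are exact inverses of their analyses where
noise is zero: `simulate_qpcr()` (lognormal noise on percent-input;
planted treatment effect at photosynthesis loci), `simulate_absorbance()`
(solves the 2×2 chlorophyll system and the carotenoid equation for
corrected absorbances; the inverse map is nonnegative for any
nonnegative concentrations, so only negative requests are rejected) and
`simulate_seedling_image()` (rectangular cotyledon ROIs on a light
background). All generators are pure functions of their seed.

# Numerical choices and problem sizes

Tolerances: exact rational cases (qPCR chain, enrichment p, interval
operations) are checked to 1e-12; pigment round-trips to 1e-6; the
worked chlorophyll value to 1e-3 (the precision it is usually quoted
at). Trigamma inversion for the shrinkage prior uses `uniroot` at
tolerance 1e-10, treating estimated prior df above 1e6 as infinite.
Degenerate inputs: an all-zero sample is an error naming the sample;
a zero standard error with a zero effect gives p = 1; empty fragment
sets give zero coverage.

Validation throughout the package and its checks runs at 1000 regions
(the calibration and recovery simulations; 20 and 10 seeds
respectively), with interval-algebra comparisons against per-base and
all-pairs brute-force oracles on 10 kb toy chromosomes. These sizes give
binomial standard errors of about 0.7% on the calibration fractions
while keeping the full suite quick on a laptop.

# Known limitations

- With two replicates, per-region variance information is almost nil;
  the test's validity leans on the empirical-Bayes homogeneity
  assumption. Under the simulated conditions an oracle z test with known
  variances caps per-transition sensitivity near 0.8 at the stated
  depth and dispersion — the information limit is
  $\mathrm{var}(\log_2 r) \ge 2\phi/\ln^2 2$ per replicate regardless of
  sequencing depth — and a gene must pass two independent transitions to
  enter the switch set, so switch-set sensitivity sits well below the
  per-transition value at these settings. The acceptance script reports
  the realized values.
- The consensus stage discards regions with no conserved peak anywhere,
  so truly null regions never reach testing in the end-to-end pipeline;
  calibration is checked on the full simulated region set instead.
- The enrichment module tests terms independently; correlated terms
  (shared genes) are corrected conservatively by Bonferroni.
- Greening ROIs are taken as given; no segmentation or scanner
  calibration is attempted.
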