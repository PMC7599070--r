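---
title: "Identifying phosphatase holoenzyme substrates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying phosphatase holoenzyme substrates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphatr)
```

PP1 is a promiscuous serine/threonine phosphatase whose specificity is
conferred by PP1-interacting proteins (PIPs). `phosphatr` implements the
quantitative workflow for establishing a PIP/PP1 holoenzyme's substrate
repertoire: candidate discovery by SILAC phosphoproteomics, sequence-context
analysis, biochemical validation by single-timepoint kinetics, binding
analysis by biolayer interferometry (BLI), and in-vivo confirmation by TMT
phosphoproteomics in knockout versus wild-type cells. This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the method description leaves room.

## SILAC dephosphorylation score

Three cell lines — (1) expressing the constitutively active holoenzyme
cofactor, (2) a PP1-binding-deficient control, (3) empty vector — are
compared pairwise in heavy/light SILAC mixes, in both labelling orientations.
For each localized phosphosite the four control/active ratios are combined as

$$\log_2 \mathrm{score} = \tfrac14\left[\log_2\tfrac{2^H}{1^L}
 + \log_2\tfrac{3^H}{1^L} + \log_2\tfrac{2^L}{1^H}
 + \log_2\tfrac{3^L}{1^H}\right],$$

the log of the geometric mean, so the score is multiplicative in the ratios
and symmetric under exchanging the two labelling orientations (both are
tested properties). A site dephosphorylated by the holoenzyme loses phospho
signal only in condition 1, making all four ratios large.

**Missing data.** The printed formula assumes all four ratios; real SILAC
site tables are sparse. The default policy (`"strict"`) scores only
complete cases. The `"balanced"` policy scores the mean of the available
log-ratios provided at least `min_ratios` (default 2) are present *and* both
labelling orientations contribute, which guards against heavy/light label
bias masquerading as dephosphorylation. Sites failing the policy are flagged
unscored, never silently dropped. Candidates are sites with score
strictly above 2.5 (the threshold at which the acidic/hydrophobic sequence
bias emerges), sorted with lexicographic tie-breaks for determinism.

**Orientation convention.** Ratios are stored as control/active throughout;
columns supplied in the opposite orientation are inverted once, at
design-mapping time, so no downstream code needs to know.

A localization-probability filter is available (`filter_localization()`,
class-I style, default cutoff 0.75) but is not applied anywhere by default,
since the upstream analysis did not state one.

## Annotation enrichment

Terms annotate proteins while scores attach to sites, so site scores are
first aggregated per protein — by `max` by default (a protein is a substrate
if any site is; `mean` is available). Each term with at least `min_size = 5`
scored members is tested by a Mann–Whitney rank comparison of member versus
non-member scores. We report the rank-biserial enrichment score
$s = 2U/(n_1 n_2) - 1 \in [-1, 1]$, where $U$ counts member-greater pairs
with ties as 1/2. P-values use the exact Mann–Whitney distribution when
$n_1 n_2 \le 400$ and the data are tie-free, and the normal approximation
with tie and continuity correction otherwise (exact enumeration under ties is
not well defined in the standard test). BH step-up correction is applied
across all tested terms; the headline filtered view uses the strict
inequalities mean score > 1 and q < 0.02. No ontology-graph propagation is
performed: annotation sets are taken as given.

## Motif analysis

The sequence context of candidates is summarised as a positional frequency
matrix over windows of halfwidth 7 (covering the informative −3 to +8 range),
with terminal pad characters excluded from counts and each position
normalised by its own non-pad count. The candidate-versus-all contrast is a
log2 ratio of pseudocounted frequencies, with the pseudocount (default 0.5)
applied on the count scale before renormalisation so sparse foregrounds do
not explode.

The scanner implements the core motif **S/T-x(2–3)-ϕ-L**: target S/T, a 2–3
residue spacer, a hydrophobic residue, then leucine. Choices made here:

- ϕ = {L, I, V, M, F}. L/I/V dominate the observed +4/+5 enrichment; M and F
  are included as conventional aliphatic/aromatic hydrophobics; W is excluded
  because tryptophan substitutions on peptide arrays raise binding
  nonspecifically and are uninterpretable.
- The terminal position requires L by default ("leucine preferred at the
  distal position"); `relax_terminal = TRUE` accepts any ϕ there, for
  stretched substrates like afadin whose only hydrophobic anchor is at +4.
- When both spacers match, the spacer-3 register is reported as primary
  (`"canonical"`, the preferred +4/+5 register) and the spacer-2 alternative
  recorded in `also_spacer`.
- Positions are 1-based, matching residue notation like S455.

The scanner is verified against an exhaustive position-by-spacer oracle on
1,000 seeded random sequences and is shift-equivariant by construction.

## Single-timepoint Michaelis–Menten kinetics

The plate assay reads product (phosphate) once, after $t = 15$ min, across a
1.5-fold dilution series from 1 mM peptide (16 steps; in-well concentrations
are scaled by 40/50 for the enzyme addition). Absorbance converts to
phosphate through a linear standard curve (negative values clamp to zero with
a warning count). The model is

$$P = t\,E\,\frac{(k_{cat}/K_M)\,C}{C/K_M + 1},$$

with $C$ the *initial* substrate concentration held constant over the
window. Substrate depletion is deliberately not corrected — the reference
analysis fits the same equation — so fits where product approaches $C$ at low
concentrations are biased low; the caveat stands for both.

**Fitting.** For fixed $K_M$ the model is linear in the efficiency, so the
conditional least-squares efficiency has a closed form and the whole fit
reduces to a deterministic 1-D minimisation over $\log_{10} K_M$ (coarse
400-point grid from $\min(C)/10^3$ to $10^4\max(C)$, then golden-section
refinement). This replaces multi-start nonlinear least squares: it optimises
the identical objective, cannot be trapped by a bad start, needs no random
restarts, and recovers noise-free parameters to better than $10^{-4}$
relative (tested). The same trick fits the pNPP normalisation hyperbola and
the BLI steady-state isotherm.

**Reliability flag.** When $K_M$ exceeds the assay range only the ratio
$k_{cat}/K_M$ is identified (the linear regime). `km_reliable` is `FALSE`
when the fitted $K_M$ exceeds $\max(C)$ or its 95% profile-likelihood
interval (F-threshold on the profiled SSE) spans more than one decade. There
is no published numeric rule for the "could not be reliably determined"
annotation; these two conditions capture both failure modes (out of range,
and flat likelihood) and the thresholds are stated so users can tighten them.

**Units.** 1 U of enzyme releases 15 µM phosphate in 15 min from 125 µM
standard peptide, so activity is $p_{15}/15$ and kcat is per-unit. The
specificity constant is reported on the conventional µM·min⁻¹·U⁻¹ scale;
dimensionally it is per µM substrate at the linear limit, and both readings
are noted in the fit object documentation rather than silently resolving the
ambiguity.

## BLI binding

Sensorgrams follow the 1:1 Langmuir model: association
$R(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})$ with
$R_{eq} = R_{max}C/(C + K_d)$, dissociation exponential with rate $k_{off}$.
Steady-state fitting uses exact $R_{eq}$ values when supplied, or the mean of
the last 5% of association samples when extracting from traces. Kinetic
fitting is a global 2-D Nelder–Mead over $(\log k_{on}, \log k_{off})$ with
$R_{max}$ conditionally linear, started from a log-linear dissociation
regression; on noise-free traces it agrees with steady-state $K_d$ to 0.1%.
Mass-transport limitation is not modelled, matching the instrument software's
1:1 analysis.

The fixture table stores the wild-type PP1-binding peptide ($K_d$ 10.4 nM)
and its interface mutants as fold reductions versus wild type. Only $K_d$
values are measurements; on-rates are a synthetic convention
($k_{on} = 10^5\ \mathrm{M^{-1}s^{-1}}$, typical for peptide–protein
interactions) with $k_{off} = k_{on}K_d$. Fold values that are only bounds
(">300", ">10", ">50") carry `bound_flag = TRUE` and are excluded from
equality-style checks. Fixture concentration grids are 8 log-spaced points
bracketing each fixture's own $K_d$ ($K_d/30$ to $30K_d$): the weak mutants
sit far outside any fixed 0.1–10 µM window, and an unbracketed isotherm
leaves $K_d$ unidentified.

## TMT differential analysis

Matrices are normalised per sample column to mean 0, SD 1 over present
values (missing entries preserved, never imputed). The "Z-score across
columns" phrasing of the upstream description is ambiguous; per-sample
standardisation is the reading that makes deltas comparable across samples,
and is the one implemented. Treatment deltas (DMSO − CD by default) are
computed within each (replicate, region, MS-mode) block — unpaired blocks are
skipped with a warning — then pooled across regions and MS modes, giving one
delta vector per genotype per site. The differential Z-score is
$\overline{\Delta_{WT}} - \overline{\Delta_{KO}}$, tested with the Welch
unequal-variance t-test (the stated "two-sample t-test" does not fix the
variance assumption; Welch is the safer default and a pooled-variance flag
exists). Hits require $p < \alpha$ *and* positive differential Z-score —
CD-induced dephosphorylation present only when the holoenzyme is intact — with
a signless mode available. No multiple-testing correction is applied by
default, mirroring the plain t-test thresholding of the upstream analysis;
`bh_fdr()` can be applied to the p column when wanted.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (parameters, seed); a top-level seed
fans out to per-generator child seeds by stable string hashing, so adding a
generator never perturbs another's output. Defaults encode the study
conditions:

- `gen_proteome`: uniform background residues; each substrate protein gets
  one planted S-centred window with basic residues at −3..−1, an L-doublet at
  +4/+5 and acidic residues at +6..+8 — the observed substrate context.
- `gen_silac`: planted sites centred at a log2 effect of 3 (scores ≈ 8,
  comfortably above the 2.5 candidate threshold, as observed for the top
  substrates), others at 0, with lognormal per-ratio noise of 0.3 log2 units
  (a typical SILAC ratio CV). 500 sites, 20 substrates.
- `gen_tmt`: 2 genotypes × DMSO/CD × 2 replicates × 2 regions × 2 MS modes
  (16 samples, 8 delta blocks per genotype, matching the pooled design);
  planted effect 1.5 Z-units on wild-type CD samples only; Gaussian sample
  noise SD 0.5; 2,000 sites, 20 planted.
- `gen_assay_plate` / `gen_sensorgrams`: exact model curves plus optional
  Gaussian readout noise.

These fixtures emulate effect structure, noise scale and design layout. They
do **not** emulate missingness patterns, peptide-level multiplicity,
batch/channel effects, ratio compression (TMT co-isolation), or correlated
noise across sites. Passing recovery tests therefore demonstrates that the
statistical machinery is correct and well calibrated under the stated
conditions — not that real datasets of this size will yield the same recall.

## Problem sizes and numerical choices

The test suite runs the SILAC recovery at 500 sites / 20 substrates, the TMT
recovery at 2,000 sites / 20 planted, the null-calibration checks at 10,000
Welch tests and 500 random terms, and the scanner oracle at 1,000 sequences
of length 50 — sizes chosen so each property is measured with useful
precision while the whole suite stays fast on a laptop. Degenerate inputs
are handled explicitly: saturated steady-state isotherms flag $K_d$
unidentifiable, constant TMT columns are an error naming the sample,
all-zero product vectors are an error, sub-threshold concentration spans
warn. Ties in candidate ranking break lexicographically; ties in rank tests
count 1/2 and switch the p-value path to the corrected normal approximation.

## Known limitations

- Single-timepoint kinetics cannot separate $k_{cat}$ and $K_M$ when
  $K_M \gg \max(C)$; the fit reports the efficiency and flags $K_M$ —
  progress-curve analysis would be needed to do better.
- The enrichment module tests flat annotation sets; GO graph propagation is
  out of scope and should be done upstream if wanted.
- The stretched-motif definition (spacer 2) requires the terminal L by
  default; the relaxed flag exists because the distal preference of
  +4-anchored substrates is not settled.
- The TMT module assumes the block design is known and complete; it skips,
  rather than models, unpaired blocks.
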