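---
title: "From comparative genomics to thermal stability: the acp3U analysis workflow"
author: "tRNAcp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From comparative genomics to thermal stability: the acp3U analysis workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAcp)
```

## The scientific problem

3-(3-amino-3-carboxypropyl)uridine (acp3U) is a conserved tRNA modification
in which an aminocarboxypropyl group, donated by S-adenosylmethionine, is
attached to the N3 atom of uridine — the Watson–Crick face — so the
modified base can no longer pair. In bacteria acp3U sits at Sprinzl
position 47 in the variable loop; in eukaryotes it occurs at positions 20
and 20a of the D-loop, with the dihydrouridine counterpart acp3D appearing
at the same positions in some tRNAs. Identifying the
aminocarboxypropyltransferases responsible and characterizing the
modification involves a chain of computational steps that this package
implements as reusable, tested components:

1. **Phylogenetic profiling** — intersect ortholog-group presence/absence
   across genomes with a measured modification phenotype to shortlist
   candidate genes, then filter by functional annotation and rank by
   protein-domain content.
2. **Oligonucleotide mass spectrometry** — digest a (modified) tRNA in
   silico with RNase T1, compute exact monoisotopic masses and negative-ion
   m/z values of the fragments, predict CID product-ion series, match
   observed peak lists within ppm tolerances, and quantify modification
   stoichiometry from extracted-ion-chromatogram areas.
3. **Misincorporation signatures** — predict acp3U sites from tRNA-seq
   pileups via the apparent U-to-C conversion that the N3-acp group causes
   during reverse transcription.
4. **Thermal stability** — simulate two-state UV melting curves and
   estimate melting temperatures from the inflection point, quantifying the
   stabilization a single acp3U confers.
5. **Phenotype statistics** — the small descriptive statistics of colony
   morphology, motility and mutator assays.

Every stage can run on seeded synthetic data, so the full pipeline is
testable offline.

## The modification alphabet and Sprinzl numbering

Modifications are registry entries (`defaultRegistry()`): a code, a parent
base, an elemental-composition delta and its monoisotopic mass, plus two
behavioural flags — whether the code blocks Watson–Crick pairing and, for
G-derived codes, whether it blocks RNase T1 cleavage. All masses in the
package are derived from elemental composition with monoisotopic atomic
masses, so there is a single source of truth; the registry ships acp3U
(+C4H7NO2, +101.0477 Da), dihydrouridine (+H2, +2.0157 Da) and acp3D
(+C4H9NO2, +103.0633 Da — dihydrouridine plus the acp group), among others.
The registry is an editable TSV under `extdata`, so new codes need no code
changes; unknown codes are always an error, never silently passed.

Modified sequences are written as plain letters with bracketed codes
(`"AC[acp3U]CAG"`); parsing and serialization are exact inverses. Sprinzl
labels are **strings**, never integers, because insertion labels (20a, 20b,
e11–e17) are not numeric. Label assignment is deterministic from a
cloverleaf annotation — an *input*, not a prediction; secondary-structure
prediction is out of scope. The canonical 76-residue cloverleaf (segments
9/17/17/5/28) yields labels "1"–"76"; up to two extra D-loop residues are
labeled "20a"/"20b" after "20" (where the modification occurs in mammals
and plants), and up to seven extra variable-loop residues are labeled
"e11"–"e17" between "47" and "48", so "47" is always the first
variable-loop position after "46". Class II (long-variable-arm) tRNAs are
rejected rather than mislabeled.

```{r sprinzl}
s <- parseModifiedSequence(paste(rep("A", 77), collapse = ""))
s <- assignSprinzl(s, canonicalCloverleaf(dInsert = 1))
sprinzlMap(s)[19:23]
```

## The profiling screen

`screenCandidates()` implements the strict Venn intersection: a group
passes iff it is present in **every** positive-phenotype taxon and absent
in **every** negative one; unknown-phenotype taxa are ignored, because only
organisms with a measured modification status carry information. Presence
means at least one member gene in that taxon — paralog counts are
deliberately ignored. `scoreProfiles()` generalizes this to the fraction of
labeled taxa where presence matches phenotype; strict passers score exactly
1. `filterByAnnotation()` keeps candidates whose reference-taxon gene has
the kept function class (typically "unknown"), and `rankByDomain()` sorts
candidates carrying preferred domain tags (e.g. the uncharacterized DTW
domain) first, breaking ties lexicographically so the ordering is
deterministic.

Because published ortholog databases change between snapshots, the
package's correctness claims rest on synthetic and toy data, not on
reproducing historical candidate counts. `buildRBHOrthologs()` provides a
reciprocal-best-hit, single-linkage ortholog builder — a documented
simplification of database clustering — so screens can be built from raw
pairwise similarity scores.

The synthetic profile generator plants one group exactly co-distributed
with the phenotype among Bernoulli(1/2) decoy profiles, with 3 positive and
5 negative taxa by default (one modification-positive reference organism
plus two positive protist-like taxa against five negative bacteria-like
taxa — the screening geometry of the discovery setting). A decoy passes the
strict screen with probability $(1/2)^8/(1-(1/2)^8)$ (profiles are
resampled if empty), which the tests check against binomial 99% intervals.

## Masses, digestion and CID series

RNase T1 cleaves 3′ of guanosine, leaving a 2′,3′-cyclic phosphate that
hydrolyzes to a linear 3′-phosphate, with a 5′-OH on the downstream
product. The default fragment chemistry is therefore 5′-OH / 3′-linear
phosphate, with a cyclic-phosphate option (`threePrime =
"cyclicPhosphate"`); the parent's own 3′-terminal fragment keeps 3′-OH.
G residues whose modification blocks T1 (2′-O-methylguanosine) are not
cleaved; base methylations such as m7G are non-blocking by default. Only
monoisotopic masses are computed (Orbitrap-class instruments); average-mass
mode is omitted.

A fragment's neutral mass is the sum of nucleoside-monophosphate residue
masses (plus modification deltas) minus one water per phosphodiester bond,
with terminal corrections; negative-mode ions are $(M - z \cdot 1.007276)/z$.
The acp3U47-containing T1 hexamer of the shipped fixture
(composition A2 C2 G1 acp3U1) gives the workflow's reference value:

```{r hexamer}
M <- neutralMass("AC[acp3U]CAG")
c(neutral_mass = round(M, 4), mz_3minus = round(mzForMass(M, 3), 2))
```

CID product ions cover the commonly observed RNA series c, y, w, a and
a−B (the a ion minus its 3′-terminal nucleobase; a base modification such
as the acp group leaves with its base). The b/d/x/z series are derivable by
complementarity but not emitted. The identities
$c_i + y_{n-i} = a_i + w_{n-i} = M + \mathrm{H_2O}$ hold to 1e-4 Da and are
enforced by property tests against an independent elemental-composition
oracle. Peak matching assigns each observed peak to the nearest theoretical
m/z within a ppm tolerance, at most one assignment per peak, ties broken by
smaller ppm error then lower theoretical m/z — determinism over cleverness.

Two normalization rules quantify stoichiometry: at the fragment level,
modified intensity over the sum of modified and unmodified forms of the
same fragment (`fragmentModFraction()`); at the nucleoside level, modified
peak area over the unmodified reference nucleoside's area
(`nucleosideModLevel()`), with XIC areas from trapezoidal integration. A
knockout sample shows up as a zero modified-fragment fraction. Isotope
overlap between, e.g., acp3D- and acp3U-containing fragments is **not**
corrected; peak areas are taken at face value, a documented approximation.

## The misincorporation caller

The acp group on N3 blocks base pairing, and reverse transcriptase reads a
modified U predominantly as C. For each pileup column the misincorporation
rate is $1 - n_\mathrm{ref}/\mathrm{coverage}$, with deletions counted as
misincorporation but never as the dominant mismatch base. A column is a
candidate acp3U site iff the reference is U, coverage ≥ 50, rate ≥ 0.1, and
C is the strict plurality among non-reference bases. The thresholds are
package defaults — no published values exist for this reanalysis — and are
fully configurable; raising the rate threshold is a monotone filter (never
adds candidates). At the default thresholds, a null column with a 1%
error rate and coverage ≥ 200 is called with probability below 1e-6
(binomial tail), so genome-scale false calls are negligible. Input is a
pre-computed pileup TSV; alignment is out of scope.

## Melting curves and Tm estimation

Curves are simulated from a two-state van't Hoff model: the unfolded
fraction is $f(T) = K/(1+K)$ with
$K = \exp[-(\Delta H/R)(1/T - 1/T_m)]$ in kelvin, and absorbance
interpolates between linear folded and unfolded baselines (hyperchromicity:
the unfolded plateau is at least the folded one). $f(T_m) = 1/2$ exactly.
ΔH is the van't Hoff enthalpy in kJ/mol (default 200, a typical value for
a folded tRNA transition); the acquisition grid is 25–90 °C at 0.5 °C
steps, mirroring a standard 0.5 °C/min UV melting ramp. The reference
construct midpoints are 70.0 °C (acp3U47-modified) and 66.7 °C
(unmodified), a 3.3 °C stabilization that rounds to the headline 3 °C.

`estimateTmInflection()` returns the temperature of maximum first
derivative, with three numerical choices that matter:

* **Derivative coordinate.** The derivative is taken against inverse
  absolute temperature ($dA/dT \cdot T_K^2$). In plain $dA/dT$ the
  two-state derivative maximum sits $\approx RT_m^2/\Delta H$ *below* the
  midpoint (0.3 °C at ΔH = 200 kJ/mol — larger than the estimator's error
  budget); in the $1/T$ coordinate the transition is exactly symmetric
  about $1/T_m$, so the maximum is the midpoint.
* **Peak refinement.** The grid maximum (localized on a re-smoothed
  derivative so noise bumps cannot capture it) is refined by a quadratic
  vertex fit over the contiguous points above 70% of the peak, again in
  the $1/T$ coordinate. Averaging over the peak top keeps the vertex
  stable under noise; the default Savitzky–Golay smoothing is an 11-point,
  degree-3 window.
* **Baseline handling.** With `baselineCorrect = TRUE` (default) a
  provisional two-state sigmoid — parameterized from the first derivative
  pass itself — is subtracted to expose the baseline trend, which is then
  fitted as the midline of the pre- and post-transition baselines (falling
  back to a single trend line when a plateau is not spanned). Subtracting
  the midline makes the residual slope error cancel at the midpoint to
  first order. Both corrected and raw modes are available because the
  choice cannot be read off an instrument trace.

Noise-free recovery is within 0.1 °C for ΔH ∈ [100, 400] kJ/mol when the
grid spans the transition (tested at Tm 55–65 °C on the 25–90 °C grid; a
ΔH = 100 kJ/mol transition centred at 70 °C leaves the upper plateau
outside the window and accuracy degrades to ~0.15 °C). Under Gaussian
absorbance noise the mean absolute error over seeded replicates is within
0.3 °C at σ = 0.5% of the transition amplitude and 0.5 °C at σ = 1%.
The estimate is invariant to affine rescaling of absorbance, and curves
with no transition raise a typed condition rather than returning a number.

```{r melt}
pair <- genMeltingCurves()        # reference conditions, noise-free
c(tm_modified = estimateTmInflection(pair$modified),
  tm_unmodified = estimateTmInflection(pair$unmodified),
  delta = deltaTm(pair$modified, pair$unmodified))
```

## Phenotype statistics

`smallColonyFrequency()` and `mutationRate()` are plate-count ratios with
dilution and volume corrections; the mutation "rate" is a per-plating
resistant-CFU frequency, as in a ratio-of-plates mutator assay — *not* a
Luria–Delbrück fluctuation estimate, which would require parallel-culture
modeling out of scope here. `replicateSummary()` is mean ± sample SD, and
`twoSampleT()` wraps the classical Student's t test with one extra
contract: two zero-variance groups with equal means return t = 0, p = 1.

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure* each stage assumes:
co-distributed presence profiles with Bernoulli decoys; cloverleaf-valid
random tRNAs with modifications planted at requested Sprinzl labels;
theoretical ions jittered by Gaussian ppm noise with log-normal intensities
and uniform decoys; binomial C-biased misincorporation over Poisson
coverage; two-state melting curves with Gaussian absorbance noise. They do
**not** emulate biological sequence composition (the random tRNAs are
structurally valid but not real genes — the shipped tRNA-Met-like fixture
is likewise a constructed, clearly labeled synthetic stand-in), nor
chromatographic peak shapes, isotope envelopes, alignment artifacts,
context-dependent RT errors, or multi-state unfolding. Passing tests
therefore demonstrate the correctness of the computations under their
stated models, not robustness to every pathology of real instrument data.

Each generator draws from a single RNG stream keyed by its seed and
restores the caller's RNG state, so outputs are byte-reproducible and test
isolation is preserved. Problem sizes used by the test suite — up to 1000
profile decoys, 20-sequence tRNA cohorts at 500x coverage, 100-replicate
melting studies, 1000 random sequences for the mass oracle — were chosen as
the smallest sizes at which the binomial calibration checks have power.

## Running the whole pipeline

`runPipeline()` binds the stages (screen → digest/match/quantify → callsig
→ melt → pheno) through one declarative config; every stage writes
plain-text outputs, and the YAML report embeds the package version and a
config hash. `defaultPipelineConfig()` runs entirely on synthetic data:

```{r pipeline, eval = FALSE}
report <- runPipeline(defaultPipelineConfig(seed = 1))
report$screen$top_candidate   # the planted gene
report$melt$delta_tm          # ~3.3 degC
```

A thin command-line wrapper (`inst/scripts/trnacp`) exposes the same
operations as subcommands for shell use.

## Known limitations

* Class II tRNAs (long variable arms beyond e17) and D-arms shorter than
  canonical are rejected, not modeled.
* No isotope-envelope deconvolution or overlap correction in
  quantification.
* The RBH ortholog builder is single-linkage over reciprocal best hits — a
  stand-in for full orthology clustering, adequate for screen testing.
* The melting model is strictly two-state; multi-state unfolding and
  magnesium dependence are out of scope.
* Historical database-dependent candidate counts are not reproducible and
  are not targets.
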