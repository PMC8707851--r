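---
title: "Integrated multi-method community analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated multi-method community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxconsensus)
```

## The problem

When one seawater community is profiled by five classification methods
— Kaiju against NCBI-nr, Kaiju against a marine-specific database,
Kraken2 and Bracken against a k-mer database, and 16S amplicon
sequencing against SILVA — the five answers disagree substantially: the
fraction of classifiable reads spans 20–90%, proportions of individual
genera differ several-fold, and whole genera vanish when a reference
database lacks them. None of the methods is a gold standard. This
package treats each method as a biased observation of the same latent
community, integrates the observations (rank consensus, multiple
co-inertia analysis), anchors relative abundances to absolute qPCR
quantities, and — because real data carry no ground truth — validates
every estimator on synthetic communities where the truth is known.

## Rank consensus

For each sample and method, the top-`n` taxa are ranked `n`..1 with the
highest value on the most abundant taxon; everything outside the list
ranks 0, encoding "not prominent". Zeros deliberately enter the
per-taxon average over methods: a taxon that only one method considers
prominent should have a low consensus rank. When a profile holds fewer
than `n` taxa, the most abundant still receives rank `n` — rank value
expresses prominence, not list position. Ties in proportion break
lexicographically by taxon name, purely for reproducibility. The
default `n` is 20 at the phylum level (Proteobacteria resolved to
classes) and 50 for pooled genus lists. "Top 50 across all samples" is
computed per method by scoring each genus with its **maximum**
proportion over samples (`topGenera(stat = "max")`); the maximum
preserves treatment-specific dominants that peak in a single sample,
whereas the mean (also available) dilutes them.

## Compositional treatment

Proportions are compositional, so sample clustering operates on
centered log-ratio transformed data: `clr(p) = log((p + δ)/g)` with `g`
the geometric mean of the shifted parts. The pseudocount default,
δ = half the smallest nonzero proportion in the matrix, is the standard
zero replacement; it only matters for taxa a method reported as absent.
Clustering uses Euclidean distance with Ward linkage via `hclust`
method `"ward.D2"`, the variant that applies Ward's criterion to
unsquared Euclidean distances.

## Multiple co-inertia analysis

`mciaFit()` implements MCoA from scratch. Each table is preprocessed —
by default the non-symmetric correspondence weighting for non-negative
data (relative frequencies, row profiles centered by the column
marginal, then exact column centering), alternatively plain
center-and-scale — and scaled to total inertia 1 so no method dominates
by dispersion alone. Axis f maximizes the sum over tables of squared
covariances between a table score $X_k u_k$ (unit-norm loading) and a
common unit-variance reference score $v$; the solution is the leading
eigenvector of $\sum_k X_k X_k^\top$, the maximum is the eigenvalue
$\lambda_f$, and the per-table squared covariances (pseudo-eigenvalues)
sum to $\lambda_f$ exactly. Between axes we deflate by projecting the
reference-score direction out of every table's row space. A common
alternative deflates each table by its own loading direction; we chose
score-space deflation because it guarantees exactly uncorrelated global
scores across axes for any K (the two coincide at K = 1, where the
analysis reduces to PCA of the preprocessed table — a property the test
suite exploits as an oracle, together with a brute-force grid search
over loading angles on toy tables). Two axes are retained by default;
the RV coefficient matrix of the preprocessed tables quantifies
pairwise method concordance.

## Window-of-linearity qPCR quantification

The amplification model is logistic:
$F_c = base + drift\cdot c + F_{max} N_0 E^c / (F_{max} + N_0(E^c-1)) + \varepsilon$,
whose pre-plateau phase is exactly exponential with per-cycle
efficiency E — the regime a window-of-linearity fit assumes.
`windowOfLinearity()` proceeds per well:

* **Baseline**: estimated from early cycles (default 3–8, shrunk when
  amplification takes off early), as a *constant* unless the early
  drift is statistically unambiguous (|slope| > 4 standard errors).
  Extrapolating a noise-fitted baseline slope 20 cycles into the
  exponential phase is the single largest error source we observed, so
  the sloped model must earn its keep. The constant is then adjusted
  over a grid of offsets (±5 noise SD, plus zero for baseline-free
  traces), selected purely by window R².
* **Plateau compensation**: the exponential template is recovered from
  the saturating signal by $\tilde s = s/(1 - s/\hat F)$, with the
  plateau $\hat F$ estimated from the logistic step map
  ($1/s_{c+1}$ linear in $1/s_c$). "No compensation" is always a
  candidate and wins exact exponentials outright. Without this step the
  usable log-linear region at realistic noise (1% of plateau) spans
  fewer cycles than the window, and the fitted efficiency is biased
  low.
* **Window**: among runs of 4–6 consecutive cycles above the noise
  floor (3 noise SD) and below 90% of the (compensated) maximum, the
  fit maximizes a weighted R² of $\log_{10}\tilde s$ vs cycle; weights
  undo the noise amplification of the log and plateau transforms.
  Windows are scored by (passes the R² floor, default 0.99) × width
  first, then R², so a wide clean window beats a narrow noise-overfit
  one; slopes outside efficiency 1.05–2.3 are ineligible.
* **Efficiency and N0**: the reported efficiency averages the window
  slope with the step-map slope (two estimates that coincide on exact
  curves and have roughly complementary error); N0 anchors the fitted
  line at the window center, $N_0 = F(c^*)/E^{c^*}$.

`quantify()` pools wells per target: well efficiencies further than
0.05 from the target median are excluded from the assay mean (the cut
widens, flagged, if it would leave fewer than two standards), a common
quantification threshold $F_q$ (geometric mean of window-midpoint
fluorescence) gives comparable per-well $C_q$, and the per-cycle ratio
is **calibrated on the dilution series itself** by regressing
$\log_{10}(\text{known copies})$ on $C_q$ — with 8 standards over 6.6
decades this is far more precise than any per-well slope and removes
the coupling between efficiency error and the $C_q$ distance to a
standard. Sample copies are the fold difference to each standard point
combined in the log domain (a geometric mean; the arithmetic mean is
systematically inflated by the heavy right tail of ratio errors).
Copies per mL follow the volumetric chain elution/template/filtered
water, default 100 µL / 1 µL / 900 mL. Replicates are averaged; sample
wells excluded only as efficiency outliers are still quantified.
No-template controls that amplify raise a contamination flag.

Derived quantities: 16S_tot = B16S + A16S; archaea% = 100·A16S/16S_tot;
genus% = 100·genus/B16S. Estimated absolute abundance of
hydrocarbon-degrader genera is the profile's HDO fraction times the
**bacterial** 16S abundance — the bacterial anchor (not 16S_tot) is the
one consistent with published worked values, and it is an argument, not
a constant.

## MAGs, genes, depletion

RPKG = reads/(gene length in kb × genome equivalents) is linear in
reads and inverse-linear in genome equivalents; compound groups
(aliphatic / MAH / PAH / various) are summed per sample. All boundary
rules are strict as printed: a gene cluster is present in a MAG only
when *more* than half its components are registered; good quality means
completeness *above* 50 **and** contamination *below* 10; ANI ≥ 95%
(inclusive) defines same-organism pairs, closed by single linkage into
organisms — a pairwise "same organism" relation has connected
components as its natural closure, and missing ANI pairs count as below
threshold. Depletion is 100(1 − c_t/c_0) with the biodegradation
contribution the live-minus-sterile difference (non-positive values
flagged); ring-class aggregation sums concentrations before the ratio,
which equals depletion of the sums.

## What the synthetic generators emulate — and what they do not

The generators mirror an Arctic-seawater oil microcosm design: SW
(untreated), SWO (oil) and SWOB (oil + nutrients) at 0/4/8 months in
duplicate, a 53-genus marine catalog, total abundance starting at
1.2×10⁶ 16S copies/mL with archaea at 15.5%, and treatment fold
changes of 2.5–4.4 (SW/SWO) and 69/103-fold (SWOB) — values chosen to
match the scale of published biostimulation experiments. Blooms encode
the observed succession (Pseudomonas/Oleispira/Marinomonas at four
months yielding to Cycloclasticus/Paraperlucidibaca at eight, over a
persistently elevated degrader guild) as multiples of the *mean*
baseline share, so a bloom of 40 means "forty-fold a typical genus",
stable across seeds. Replicate noise is mean-one log-normal
(sdlog 0.15), keeping fold changes exact in expectation; disabling
noise makes them exact.

The five default bias models are calibrated loosely to the discrepancy
scale seen in published multi-method comparisons and remain fully
user-configurable: every method carries its own fixed genus-level
log-normal bias (sdlog 0.4–0.7) so that *no* method is near-truth;
named factors put the k-mer methods highest on Pseudomonas (×5), the
protein-level methods highest on Cycloclasticus (×3–5); the marine and
Standard-k-mer databases lack specific genera entirely; and the
amplicon model adds 16S copy numbers (1–10), phylum-structured primer
bias (Gammaproteobacteria ×0.35, Bacteroidetes ×4), fourteen genera
unresolved at the genus level, a PCR-competition flattening exponent
(0.65) and per-sample run noise (sdlog 0.4). The last two exist because
a fixed multiplicative bias barely changes the between-sample
configuration that the RV coefficient measures; only
composition-dependent and run-level distortion reproduces the observed
pattern in which amplicon data correlate visibly less with shotgun
methods (RV ≈ 0.5–0.85) than shotgun methods do with each other
(RV ≈ 0.8–0.9).

Not emulated: read-level sequences (no FASTQ), sequencer error
profiles, chimeras, taxonomy-tree disagreements between databases, and
classifier confusion between related genera (false positives come from
a fixed catalog of names absent from the truth, at 1–3 reads). Passing
tests therefore demonstrate that the estimators recover truth under
*these* bias mechanisms, not that any real classifier behaves exactly
like its namesake model.

Every generator draws from its own RNG stream seeded by (global seed,
operation name), so adding one generator to a workflow never perturbs
another's output, and all outputs are byte-identical under a fixed
seed.

## Numerical choices and degenerate inputs

Proportions renormalize to sum 1 (tolerance 1e-9) after every filter.
Readers signal a classed `emptyProfileError` when nothing remains after
eukaryote/unassignable removal, and name the offending line on
malformed rows. A flat qPCR trace (rise below 10 noise SD) signals
no-amplification; wells below the R² floor are excluded, not guessed.
MCIA refuses more axes than the rank of the joint operator; RV is
clamped to [0, 1] against rounding. Synthetic plates auto-dilute
samples above 10⁷ copies/reaction in decade steps (recorded in the
metadata and undone during quantification), because an undiluted 10⁹
trace saturates before any window exists — exactly why laboratories
dilute.

## Problem sizes

The test suite and the acceptance script run the full synthetic
pipeline at 53 genera × 13 samples × 5 methods with 10⁵ reads per
sample (2×10⁴ in the smoke tests), 5 qPCR targets × 36 wells × 40
cycles, 46 genes, and 19 MAGs; recovery medians use 50 seeded
replicates for qPCR and 20 for the consensus-dominance property. These
sizes give stable medians for every recovery check while a complete
run stays under a minute on one core.

## Known limitations

Genus matching is exact-string after an optional synonym table; no
taxonomy-tree reconciliation is attempted. The bundled
hydrocarbon-degrader database and gene-cluster definitions are reduced
working sets covering the genera and clusters prominent in marine oil
degradation — both are pluggable TSVs and should be replaced with a
complete compilation for production use. The window-of-linearity
implementation targets SYBR-style single-plex curves; melt curves and
fixed-threshold Cq calling are out of scope. MCIA significance testing
and plotting are left to dedicated packages.
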