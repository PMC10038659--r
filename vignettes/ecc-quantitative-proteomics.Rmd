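---
title: "Quantitative proteomics of muscle excitation-contraction coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative proteomics of muscle ECC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccquant)
```

## Scope

`eccquant` implements a two-route quantitative proteomics workflow for
skeletal-muscle studies of excitation-contraction coupling (ECC):

* **Relative quantification** from isobaric TMT 10-plex reporter-ion
  intensities, with empirical-Bayes moderated t-statistics and
  Benjamini-Hochberg FDR control, to compare two genotypes (here: wild-type
  vs a double-heterozygous *Ryr1*-mutant, "dHT") across 5 + 5 channels.
* **Absolute quantification** of low-abundance ECC proteins (RyR1,
  DHPR&alpha;1s, Stim1, Orai1, ...) by parallel-reaction-monitoring
  stable-isotope dilution (PRM/SID), expressed in µmol per kg wet tissue,
  plus an iBAQ-based calibration curve that extrapolates absolute amounts to
  proteins quantified only in the discovery data.

Downstream, the package derives oligomer-aware complex concentrations (RyR1
is a homotetramer, Orai1 a hexamer), pairwise molar stoichiometries,
cross-muscle percentages, and the fractional occupancy of the
DHPR&alpha;1s-Stac3 interaction site. A seeded synthetic-data generator
reproduces the statistical structure that these stages assume, so every
stage is testable without raw mass-spectrometry files.

Out of scope by design: spectral search and identification FDR,
chromatographic fractionation, mzML parsing, protein-group parsimony (groups
are assumed resolved upstream), and pathway-enrichment services.

## The TMT model

Each peptide-spectrum match (PSM) carries ten reporter intensities. The
generator's intensity model for PSM row $p$ in channel $c$ is

$$ I_{pc} = A_{g(p),\,\mathrm{cond}(c)} \cdot e_p \cdot l_c \cdot
\varepsilon_{pc}, $$

where $A$ is the protein-by-condition abundance, $e_p$ a log-normal peptide
ionization efficiency **fixed per peptide across channels**, $l_c$ a
channel loading factor and $\varepsilon$ multiplicative log-normal reporter
noise. Fixing $e_p$ across channels is the minimal model under which
summation-based protein roll-up is unbiased for between-channel ratios: the
per-peptide efficiency cancels exactly in any channel ratio. Log-normal
reporter noise makes log2 protein intensities (approximately) normal, the
distributional assumption behind the moderated t-test; the suite's
null-simulation check (uniform p-values, controlled false positives) probes
exactly this chain.

The analysis stages mirror the standard reporter-ion workflow:

1. `correct_reporters()` — isotope-impurity deconvolution, solving
   `impurity %*% corrected = observed` per row. The impurity matrix is
   config-supplied and defaults to the identity, since label-lot impurity
   tables are instrument metadata the pipeline cannot invent. Negative
   solutions are clipped to zero and counted.
2. `normalize_channels()` — global normalization equalizing total reporter
   intensity across the ten channels (factors reported; grand total
   conserved). This assumes the bulk of the proteome is unchanged; the
   synthetic designs used in tests therefore include an unchanged background
   proteome around the spiked proteins.
3. `rollup_proteins()` — summation per protein and channel, distinct-peptide
   counts, and iBAQ (summed intensity over the number of theoretically
   observable peptides: fully tryptic, 0 missed cleavages, length 7-30 —
   the standard iBAQ convention).
4. `moderated_t()` / `differential_abundance()` — see below.
5. `filter_significant()` — the study filter: q < 0.05, an abundance change
   of at least 0.20-fold (ratio ≤ 0.80 or ≥ 1.20; this reading matches the
   smallest reported significant changes, 0.77-0.79 and 1.23), and at least
   2 distinct peptides.

### Moderated t-statistics

For protein $g$, on log2 intensities: $\Delta_g$ is the condition-mean
difference, $s^2_g$ the pooled within-condition variance on
$d_g = n_1 + n_2 - 2$ degrees of freedom. The prior $(d_0, s_0^2)$ is
estimated by moment matching on the log sample variances: with
$e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$, $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}$ (Newton
inversion of the trigamma function) and $s_0^2$ follows from the mean of
$e$. The posterior variance is
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$, the statistic
$\tilde t_g = \Delta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ with
$d_0 + d_g$ degrees of freedom, and the reported ratio is $2^{\Delta_g}$.

Numerical and degenerate-input choices:

* If the spread of log variances is no larger than expected from sampling
  alone (or fewer than two positive variances exist, e.g. exact-replicate
  data), the prior degrees of freedom are infinite and all proteins share
  the common variance; $d_0 = 0$ (user-suppliable) recovers the ordinary
  pooled t-test. Both limits are exercised in tests, and the full fit is
  cross-checked against an independent empirical-Bayes implementation.
* Proteins with any non-positive channel intensity are excluded from
  testing with a reported count — the log transform is undefined there.
* p-values are two-sided; BH ties are resolved by the stable ordering of
  `stats::p.adjust`. Testing happens at the summed-protein level (summation
  precedes testing in the workflow this package reproduces).

## The PRM/SID model and the unit chain

Heavy reference peptides are spiked at $S$ fmol per µg of total endogenous
peptide ($S = 10$ by default). A light/heavy area ratio $r$ then means
$r \cdot S$ fmol of analyte per µg peptide, and with a tissue peptide yield
of $Y$ µg peptide per mg wet tissue,

$$ C \;[\mu\mathrm{mol/kg\ wet\ weight}] = r \cdot S \cdot Y \cdot 10^{-3}. $$

The yield $Y$ is a required, explicit parameter: the wet-tissue-to-peptide
conversion underlying published µmol/kg values is never derivable from the
ratios themselves. The default $Y = 64.5$ makes the worked example clean:
$r = 2$, $S = 10$ maps to exactly 1.29 µmol/kg, the reference RyR1 monomer
concentration in wild-type EDL.

Per sample, peptide-level values are summarized by the median of
log-transformed ratios, back-transformed — identical to the linear-scale
median for an odd peptide count and robust to single-transition outliers
(exercised in tests with a 100x outlier). `tic_normalize()` first rescales
each sample's ratios by reference TIC / sample TIC, the reference being the
mean TIC across samples; the mean of the *reciprocal* factors is exactly 1
by construction. A protein with no quantifiable peptide (non-positive heavy
areas), or a measured concentration of zero, is reported **not detected**
rather than zero — mirroring Orai1 in soleus muscle, which sits below the
detection level of the measurement.

### Calibration curve

`fit_calibration()` regresses log2 absolute concentration on log2 iBAQ over
the anchor proteins quantified by both routes (ordinary least squares;
$R^2 = 1 - SS_{res}/SS_{tot}$). `extrapolate()` maps new log2-iBAQ values
through the line; queries outside the anchors' x-range are computed but
flagged `out_of_domain` rather than refused, since the intended use is
precisely for proteins chosen to lie inside the linear domain and a hard
refusal would hide boundary cases from the caller.

## Stoichiometry and occupancy

`complex_concentration()` divides monomer concentrations by the oligomer
subunit count (RyR1 k = 4, Orai1 k = 6). `stoich_ratio()` forms molar
ratios in two labelled modes:

* `full_precision` — ratios of unrounded values; satisfies
  `ratio(a,b) * ratio(b,a) = 1`.
* `as_printed` — inputs first rounded to the 2 decimals at which
  concentration tables are printed, ratio reported to 3 significant digits.
  This mode exists because published ratio tables are computed from the
  rounded concentration entries: the Stim1/Orai1-hexamer ratio in EDL is
  23.0 from printed values (0.46/0.02) but ~25.1 at full precision
  (0.46/(0.11/6)). Both modes are exposed and recorded per row.
  Rounding follows the exact binary value as decimal printing does
  (0.86/4 is stored below 0.215 and rounds to 0.21); base `round()`'s
  half-to-even decimal convention would disagree with tabulated values.

`fractional_occupancy()` is the single-site Langmuir isotherm
$C/(C + K_d)$. µmol/kg wet weight is equated with µM through a configurable
tissue density (default 1 kg/L) — the comparison of a per-mass concentration
with a dissociation constant requires this conversion even though it is
usually left implicit. With Stac3 between 0.15 and 0.62 µmol/kg and
$K_d \in [2, 10]$ µM, occupancy stays below 50% in all muscles and both
genotypes, the bound the acceptance suite asserts. A cooperative or
multi-site model is deliberately not offered.

`build_stoichiometry_report()` emits one row per protein pair and
condition; "not detected" members yield `-` entries (soleus Stim1/Orai1)
instead of silent omission. The test suite regenerates the full published
ratio grid from the reference concentration table and — importantly — flags
the two extraocular-muscle rows (Stac3/Cacna1s and Jsrp1/Cacna1s) whose
published values are arithmetically inconsistent with the concentration
table (the value pattern suggests a row swap); those four cells are
asserted to *mismatch*, not forced to agree.

## What the generator emulates — and what it does not

`simulate_tmt()` and `simulate_prm()` reproduce: per-peptide ionization
efficiencies (log-normal, $\sigma = 1$ on the log scale, the magnitude of
peptide-to-peptide response spread seen in shotgun data), reporter noise
(log-normal, CV 0.10 — a typical reporter-ion CV after fractionation),
channel loading factors, a six-protein calibration mix in a geometric
series across channels (the published mix composition is not tabulated, so
amounts are explicit config rather than claims about the original), spike
ratio structure with peptide-level CV 0.10, per-sample TIC drift (CV 0.05)
that the TIC normalization can invert, and uniform-at-random PSM
missingness (no mechanism is specified for real data; default rate 0).

Two deliberate distributional choices: TMT reporter noise is log-normal so
that log2 intensities are exactly normal (the moderated-t model); PRM
peak-area and TIC-drift noise are symmetric Gaussian-multiplicative
(mean 1, SD = CV), the family under which the median-based protein summary
is mean-unbiased — pairing a skewed noise law with a median estimator would
build a small systematic bias into the generator itself and conflate it
with estimator error in the recovery checks.

Not emulated: fragment spectra, retention time, identification errors,
protein-group ambiguity, interference/ratio-compression beyond what the
impurity matrix models, and correlated (structured) missingness. Passing
tests therefore validate the statistical pipeline under its stated
assumptions; they do not certify behavior under co-isolation interference
or informative missingness found in real TMT data.

Synthetic carrier sequences for the nine ECC proteins concatenate the
proteotypic target peptides and pad them with random tryptic peptides to
realistic peptide counts (the real RyR1 is ~5000 residues); sequences and
the five non-measured peptide sets (Stac3, Jsrp1, Asph, Trdn, Jph1) are
labelled synthetic in the documentation.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; identical
configurations give byte-identical tables, and `run_pipeline()` writes a
manifest plus `#`-commented TSV headers (version, parameters, seed) so a
fixed-seed run regenerates identical files. The test suite uses problem
sizes chosen to make the statistical checks sharp yet quick: 1000-protein
null and spike simulations over 5 and 20 seeds for calibration of the
differential stage, 200 replicate PRM experiments for parameter recovery
(the scale at which a 2-standard-error band is a demanding check), and a
60-120-protein background for end-to-end runs. `scripts/acceptance.R`
recomputes the headline RyR1 recovery (200 replicates) from an installed
copy of the package.

## Known limitations

* The impurity matrix defaults to identity; real deconvolution needs the
  label lot's certificate of analysis.
* Global channel normalization biases ratios when a large fraction of total
  intensity genuinely changes; the package reports factors so users can
  inspect this, but does not attempt robust (e.g. trimmed) normalization.
* iBAQ from a handful of peptides is noisy; calibration anchored on few
  low-peptide proteins can yield unstable slopes. The fit reports $R^2$ and
  the domain precisely so such fits are visible.
* Occupancy assumes total ≈ free ligand concentration; at receptor
  concentrations comparable to $K_d$ this overestimates occupancy slightly,
  which is conservative for the "below 50%" bound.
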