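---
title: "Methods: proteome-wide MR and colocalization screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR and colocalization screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protscreen)
```

# The screening problem

Observational protein–disease associations are vulnerable to confounding
and reverse causation. Two-sample Mendelian randomization sidesteps both by
using *cis* protein quantitative trait loci (pQTLs) as instruments: a
variant near the protein-coding gene that robustly shifts circulating
protein levels can, under the instrumental-variable assumptions, identify
the causal effect of the protein on disease risk from two independent sets
of GWAS summary statistics. `protscreen` implements the full screen —
instrument selection, harmonization, estimation, directionality checks,
disease GWAS meta-analysis, colocalization, and a multi-criterion decision
rule across two proteomic platforms — plus a generator of synthetic GWAS
summary statistics with known causal architecture used to validate every
stage.

The MR assumptions are: (1) the variant is associated with the exposure;
(2) no confounders of the variant–outcome association; (3) the variant
affects the outcome only through the exposure. Restricting to *cis*
instruments limits horizontal pleiotropy (violations of assumption 3) but
cannot exclude it; the decision rule therefore demands cross-platform
consistency, Steiger support, reverse-MR nullity and, at the strongest
tier, colocalization evidence.

# Pipeline stages

## Instrument selection

Candidates are variants with p below the platform threshold *and* within
`cis_window_bp` of the transcription start site (1-based, fully closed
intervals throughout). Defaults follow the conventions of the two large
plasma-proteome GWAS the presets emulate: 1.8e-9 for a deCODE/SomaScan-like
platform and 1.7e-11 for a UKB/Olink-like one, both with a 1 Mb cis window.
A 1 Mb region is opened around each candidate (interpreted as a ±500 kb
flank; the flank is configurable because "a 1 Mb region was defined around
each SNP" is ambiguous between total width and flank), overlapping regions
are merged starting from the lowest-p SNP, candidates in LD r² ≥ 0.8
collapse into one region, and the lowest-p SNP of the final region is the
single sentinel. Ties in p are broken toward the lower genomic position so
selection is deterministic. An MHC-style interval can be declared
(`selection_config(mhc = ...)`) and is treated as a single region; no
default coordinates are assumed.

Disease instruments come from greedy clumping: repeatedly keep the
lowest-p SNP passing 5e-8 and discard SNPs with r² > 0.001 within a 10 kb
window of it; when nothing passes, a relaxed 5e-7 pass is used and the
resulting reverse-MR estimates carry a `relaxed_threshold` flag (they are
falsification probes, not causal estimates). When LD for a pair is
unavailable the pair is treated as uncorrelated, with a warning —
permissive, so instruments are not silently discarded. Note that the
distance window bounds the *reach* of the r² test: two SNPs 50 kb apart are
both retained regardless of LD. That is the documented behaviour of
distance-windowed clumping, and also its limitation — see "Known
limitations".

## Harmonization

Outcome records are aligned to the exposure's effect allele: identical
pairs pass directly; swapped pairs negate the outcome beta and complement
the frequency; complement-strand pairs are strand-flipped first. For
palindromic pairs (A/T, C/G) allele labels cannot identify the strand, so
alignment is inferred from allele frequency — only when both records' MAF
is below 0.3; otherwise the pair is dropped as `ambiguous_palindrome`. The
bound is applied uniformly to proxies and non-proxies. Finally the pair is
oriented so the exposure beta is non-negative: forward estimates are per
exposure-*increasing* normalized-SD unit, and odds ratios exponentiate the
log-odds estimate.

Sentinels missing from the outcome are replaced by the best LD proxy with
r² ≥ 0.8 (ties broken by genomic proximity). The sign of r carries the
allele mapping: a negative-r proxy has its beta negated and frequency
complemented before standing in. The exposure statistics remain those of
the original sentinel, and the proxy's own EAF is used on the outcome side
(standard two-sample MR convention). Variants are matched by rsid;
position+allele matching is deliberately out of scope.

## Estimation

With one instrument the Wald ratio β = β_y/β_x is used, with the
first-order delta SE se_y/|β_x|. The second-order term is omitted because
cis-pQTL instruments in this setting are strong (F in the hundreds; the
example screens produce F ≈ 400–800), making the correction negligible.
With k ≥ 2 instruments the IVW estimate is the weighted regression of β_y
on β_x through the origin with weights 1/se_y²; Cochran's Q feeds a
multiplicative random-effects scale φ = max(1, √(Q/(k−1))), so the
reported SE never drops below the fixed-effect SE. 95% CIs use the fixed
multiplier 1.959964.

## Steiger directionality and the liability scale

The Steiger test compares instrument-explained variance on the two sides:
per-SNP R² (the formula in the README) summed over instruments, with the
case-control outcome side converted to the liability scale by the standard
threshold-model transformation

r²_liab = r²_obs · K²(1−K)² / (z²·P(1−P)),

where K is population prevalence, P the sample case fraction and z the
standard normal density at the threshold Φ⁻¹(1−K). The transformation is a
design choice — the procedure it supports names prevalence but no formula —
and the implementation is validated against numerical simulation of the
threshold model. The p-value compares Fisher-transformed correlations √r²
at the two sample sizes. A strict inequality defines `direction_true`, so
an exact tie resolves to `FALSE`. Single-SNP Steiger cannot separate causal
from pleiotropic models; results carry `single_snp = TRUE` and the decision
engine uses them only jointly with bidirectional consistency. For pooled
outcomes the prevalence is the logit-scale fixed-effect pooling of
study-population prevalences weighted by effective sample size
(`weighted_prevalence()`).

## Disease GWAS meta-analysis

Per study, genomic control computes λ = median((β/se)²)/0.4549, floors it
at 1, and (when λ > 1) inflates SEs by √λ and recomputes p-values; λ from
fewer than 100 variants is unreliable and forced to 1 with a warning.
Genomic control is applied per input study, before pooling, matching the
documented recommendation of SE-weighted ("STDERR") meta-analysis. The SE
weighting (rather than sample-size z weighting) is deliberate: downstream
MR needs pooled betas and SEs, not just z-scores. Shared variants are
allele-aligned with the harmonization rules, pooled by inverse variance,
and variants present in only one study are dropped — heterogeneity is
undefined for them. The heterogeneity filter removes het p ≤ 0.05
*inclusive*.

## Colocalization

Per-variant evidence is the Wakefield log approximate Bayes factor
lABF = ½[ln(V/(V+W)) + z²·W/(V+W)], with prior effect SD 0.15 for
quantitative and 0.2 (log-odds) for binary traits — the cited framework's
convention; only the configuration priors p1 = p2 = 1e-6, p12 = 1e-7 are
inherited from the screen's published calibration. The five posterior
hypothesis probabilities are computed under the single-causal-variant
assumption entirely in log space (log-sum-exp; verified stable to |z| =
200), and H3's ΣBF₁ΣBF₂ − Σ(BF₁BF₂) term uses a log-difference, returning
exactly zero probability for a one-SNP region. Windows of 125 kb, 250 kb,
500 kb and 1 Mb total span are centered on the sentinel (a flank
interpretation is available via `window_mode = "flank"`); the 1 Mb window
is the main analysis and the smaller ones probe window-size sensitivity. A
window with no shared variants is reported empty rather than failing.
Variants lacking finite beta, SE or EAF are excluded before ABF
computation. Posterior vectors sum to 1 within 1e-9, and the implementation
agrees with exhaustive configuration enumeration within 1e-10 on regions of
up to 8 SNPs.

Caution on small windows: when the two traits' causal variants are
distinct but linked, a window too small to contain the second causal
variant sees only its LD shadow and can report high h4. This is why the
main analysis uses the largest window and why agreement across windows
(the `consistent` attribute) matters.

## Decision engine

`assign_tier()` is a pure function of the four criteria and the maximum h4
across windows: missing forward results → `not_shared`; discordant forward
directions → `inconsistent`; concordant but failing CIs, Steiger or
reverse nullity → `suggestive`; all four criteria → `consistent_candidate`,
upgraded to `colocalized_candidate` when max h4 > 0.8 (strict). "No
evidence for a reverse effect" is operationalized as every computed
reverse-MR 95% CI overlapping zero; a protein with no extractable reverse
instruments passes the criterion vacuously (recorded as not assessable).

One pipeline-level design choice deserves emphasis: disease instruments
that fall inside the evaluated protein's own cis window are excluded from
that protein's reverse MR. Under a shared causal variant the protein's own
pQTL is genome-wide significant for the disease; "instrumenting" the
disease with it and testing against the same protein is circular and would
flag every true positive as reverse-causal. Reverse MR asks whether disease
liability moves the protein through *other* susceptibility loci.

The pipeline draws no random numbers, so a rerun on the same inputs is
byte-identical. No multiple-testing correction is applied — the screen
looks for cross-platform consistency rather than p-value thresholds — and
none of MR-Egger, weighted-median or mode estimators are offered: with a
single cis-SNP per protein they are undefined.

# The synthetic-data generator

## What it emulates

`simulate_ld_panel()` draws haplotypes from a latent Gaussian
autoregressive process thresholded per SNP at MAF-matching quantiles. Two
refinements make the LD realistic and the `ld_rho` parameter honest.
First, MAFs follow a slowly varying reflected random walk inside
`[maf_low, maf_high]` rather than independent draws: the correlation of
two 0/1 variants is capped by their frequency mismatch, so high LD between
neighbours requires similar frequencies, as in real haplotypes. Second,
thresholding attenuates correlation (a latent 0.9 yields binary r ≈
0.55–0.7 under naive thresholding), so the latent coefficient of each
adjacent pair is calibrated numerically until the realized haplotype-scale
correlation matches `ld_rho`. Adjacent LD then concentrates near the
requested value.

`simulate_scenario()` builds four independent cohorts over one cis region
— two protein "platform" cohorts and two disease cohorts — under five
architectures: shared causal variant, distinct causal variants,
horizontal pleiotropy, reverse causation, and the global null. The protein
is X = Σ aⱼgⱼ + ε, standardized to unit variance, so `a` is in SD units.
Disease arises from a liability threshold model with a *standard logistic*
residual: L = γX + Σ δⱼgⱼ + Logistic(0,1), D = 1{L > qlogis(1−K)}. The
logistic residual is deliberate: it makes γ exactly the log-odds effect of
one protein SD on disease, so per-SNP logistic regression — and hence the
Wald ratio — targets γ directly (rare-outcome non-collapsibility is
negligible at the prevalences used). Under a probit residual the marginal
log-odds would be γ times the Mills ratio at the threshold (≈2.7 at
K = 0.01) and "recovering γ" would be ill-posed. Summary statistics come
from closed-form per-SNP OLS (protein) and a vectorized Newton–Raphson
per-SNP logistic solver (disease), both validated against `lm()`/`glm()`.

`simulate_screen()` scales this to a proteome screen: every protein owns a
cis region on its own chromosome with cis effect `a = 0.3`; two platform
cohorts measure all proteins; two disease cohorts contribute GWAS spanning
all regions plus a dedicated susceptibility region whose SNPs act directly
on liability and become the reverse-MR instruments. The susceptibility
region has low internal LD (`ld_rho_disease = 0.3`) so its two planted
signals are effectively independent loci — the situation distance-windowed
clumping assumes. The cis regions are dense (`ld_rho = 0.92`) so proxy
lookup can rescue sentinels lost to the heterogeneity filter.

Default study conditions: per-cohort n = 20,000 for single-region
scenarios with prevalence K = 0.01 (200 expected cases — the smallest
count giving stable logistic estimates at desk scale; a warning fires below
50), γ = 0.3 and a = 0.3 for the shared-causal preset; reverse causation
uses δ = 0.7 on liability and 0.5 from standardized liability to protein;
pleiotropy adds δ = 0.15 at the instrument SNP, which biases the Wald
ratio by ≈ δ/a — the quantitative reason the screen's consistency and
colocalization checks exist. Screens default to n = 10,000 per cohort,
K = 0.05 and γ = 1.2 for causal proteins, sized so both platforms detect
true effects while the whole screen runs in about a minute.

## What it does not emulate

Single-region scenarios only; no genome-wide polygenicity, no imputation
noise, no population stratification (so genomic control hovers at its
floor), no assay-specific measurement structure beyond independent noise
per platform, and desk-scale prevalences (1–5%) rather than the ~1e-5 of a
rare malignancy — the liability transformation is exercised across that
range by unit tests, but passing simulations say nothing about, e.g.,
case-ascertainment artifacts in real registries. Passing the recovery
tests demonstrates estimator correctness under the stated model, not
robustness to real-data pathologies.

## Correlated forward analyses

In the screen, platform A is tested against the two-cohort meta-analysis
and platform B against cohort 2 alone (mirroring the pairing that avoids
exposure/outcome sample overlap). The two forward estimates therefore
share cohort-2 outcome noise and are positively correlated; "both CIs
exclude zero in the same direction" is less stringent than the square of
one platform's error rate. This is a property of the emulated design
itself, and the simulated false-positive behaviour of the screen reflects
it.

# Numerical choices

- All posterior and Bayes-factor arithmetic in log space; `log1p`-based
  log-difference for H3; posteriors renormalized only through the
  log-sum-exp denominator.
- λ floored at 1; MRE φ floored at 1; CI multiplier fixed at 1.959964.
- Deterministic tie-breaks: minimum p then minimum position (selection,
  clumping); highest r² then nearest position (proxies); Steiger ties
  resolve to `direction_true = FALSE`.
- Validation is total: every input row is kept or counted once in the drop
  report, with a fixed order of reason checks.
- Degenerate inputs: β_x = 0 is a degenerate-instrument error; one-SNP
  IVW is a usage error (callers fall back to the Wald ratio); empty clump
  results and empty coloc windows are valid outputs, not errors.
- Text output uses `%.17g` so write→read→write round-trips are
  byte-identical.
- The z-vs-p consistency check is off by default (mixed-model GWAS
  p-values need not match the Wald z) and, when enabled, uses a 10%
  relative tolerance on the z scale.
- Genome build is opaque metadata; the caller is responsible for
  consistency across inputs.

# Problem sizes used by the test suite

Unit tests run on regions of 2–21 SNPs with cohorts of up to 20,000.
The property batteries use 500 shared-causal and 500 null replicates
(n = 20,000, 5 SNPs), 200 replicates each for the shared/distinct
colocalization and reverse-causation checks, five 1,000-variant null
meta-analyses for heterogeneity-filter calibration, and a 20-protein
screen with two planted causal proteins. These sizes were chosen so the
full suite completes in a few minutes on one CPU while keeping Monte-Carlo
error well inside the asserted bands.

# Known limitations

- Single-causal-variant colocalization: no multi-signal (SuSiE-style)
  decomposition and no LD-aware fine-mapping; a secondary causal variant
  in the region degrades h4.
- Distance-windowed clumping retains correlated SNPs that lie outside the
  window; IVW then overstates precision. The screen mitigates this by
  construction (independent susceptibility loci), real analyses should
  prefer wider windows or LD-aware pruning when instruments multiply.
- Reverse MR at relaxed thresholds is a falsification probe only.
- rsid-based matching assumes consistent variant naming across inputs.
- The decision rule is a screen, not an estimator of effect size: tiers
  are sensitive to the 0.8 h4 bound and the 95% CI convention exactly as
  documented, and no error control across proteins is attempted.
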