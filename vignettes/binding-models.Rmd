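---
title: "Equilibrium models of NF-kB dimer binding to kappa-B DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium models of NF-kB dimer binding to kappa-B DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappabind)
library(dplyr)
```

kappabind models the equilibrium interaction of an NF-kB-type protein
dimer with kappa-B DNA at three levels: discrete one- and two-site
binding with ligand depletion, a finite one-dimensional lattice
(footprint) model for multi-dimer stoichiometries on tandem promoter
segments, and the fluorescence anisotropy readout that connects site
occupancies to the measured signal. A synthetic-data generator and a
global least-squares fitting layer close the loop, so the whole analysis
is testable by parameter recovery. Small SAXS utilities (Guinier fit,
Kratky transform, excluded-volume polymer scaling) support the
compactness side of the analysis.

## Discrete-site equilibria with ligand depletion

Anisotropy titrations use labeled DNA at 5 nM, comparable to the
low-nanomolar dissociation constants of specific kappa-B sites, so free
and total protein cannot be identified. For a single site the complex
concentration is the physically valid root of the mass-balance
quadratic,

$$c = \tfrac{1}{2}\left[(P_0 + D_0 + K_d) -
  \sqrt{(P_0 + D_0 + K_d)^2 - 4 P_0 D_0}\right],$$

evaluated internally in the cancellation-free form
$2 P_0 D_0 / (s + \sqrt{s^2 - 4 P_0 D_0})$. For weak nonspecific binding
(hundreds of nM to uM) depletion of a 5 nM probe is negligible and the
Langmuir fraction $x/(x + K_d)$ is used instead; which regime applies is
an explicit choice (`isotherm = "quadratic"` vs `"hyperbolic"`), mirroring
how such titrations are analyzed in practice.

For two discrete sites on the same molecule the species
$D_{00}, D_{10}, D_{01}, D_{11}$ carry statistical weights $1$, $P/K_1$,
$P/K_2$ and $\omega P^2/(K_1 K_2)$ relative to free DNA, where $P$ is
free protein and $\omega$ the cooperativity factor ($\omega = 1$:
independent sites). Total-protein conservation

$$P + D_0\,\frac{P/K_1 + P/K_2 + 2\omega P^2/(K_1K_2)}
  {1 + P/K_1 + P/K_2 + \omega P^2/(K_1K_2)} = P_0$$

is strictly increasing in $P$, so it has exactly one root in
$[0, P_0]$. Multiplying out gives a cubic whose relevant root
`two_site_species()` finds with `polyroot()` and polishes with Newton
steps on the conservation function to about $10^{-12}$ relative; a
bracketed `uniroot()` on $[0, P_0]$ is the fallback and serves as the
independent oracle in the test-suite. Conservation of DNA and protein
holds to $10^{-9}$ relative everywhere, and the tests assert this as an
invariant rather than a spot check. Cooperativity is kept as a
first-class parameter precisely so that "no cooperativity" is a model
*selection* result, not an assumption.

```{r two-site}
two_site_species(250, 250, binding_params(kd1 = 1.7))
```

At equimolar protein and DNA with two equal tight sites this reproduces
the 1:2:1 free : singly bound : doubly bound pattern seen in gel-shift
band intensities (singly:doubly $\approx 2$).

## The finite-lattice footprint model

Gel shifts on tandem promoter segments resolve DNA bound by more dimers
than there are kappa-B sites, which discrete-site models cannot
represent. `species_distribution()` treats the DNA as a lattice of $L$
bp on which each dimer occludes a fixed footprint (default 10 bp). A
placement is *specific* only when exactly registered on a site interval
(with that site's $K_d$); every other fully-on-lattice start position is
*nonspecific* with a single uniform constant. Exclusion is hard-core
only. The occupancy-resolved partition function
$Z(P) = \sum_n a_n P^n$ is built by a transfer-matrix (sequential)
recursion over lattice positions in $O(L \cdot n_\max)$, and the free
protein is again the unique root of conservation, now summed over all
DNA species, so `competition_distribution()` gets the shared-pool
competition experiment for free. An exhaustive recursion over placement
sets (`enumerate_configurations()`, guarded to 200 bp) provides the
independent combinatorial oracle; both paths agree to $10^{-8}$ on all
lattices up to 40 bp in the tests.

Geometry fixtures (`kb_constructs()`) encode the printed segment
lengths rather than reconstructed sequences: 33 bp with two identical
10 bp sites separated by 4 bp, and 59 bp with two distinct sites
separated by 19 bp. Site placement on the 33 bp segment is chosen so
that scrambling site 1 leaves a 16 bp and scrambling site 2 a 21 bp
contiguous nonspecific stretch, the quantities that control whether a
third dimer can bind without displacing a specific one. The stated 3 bp
flanks of the anisotropy duplexes are arithmetically inconsistent with
those segment lengths, so the anisotropy geometries are separate
fixtures (30 and 45 bp) with exact 3 bp flanks. Hairpins are modeled as
their duplex stems with the CCCCC loop as a non-binding spacer.

## Anisotropy readout

Anisotropy is computed from polarized intensities as
$r = (I_{VV} - G I_{VH}) / (I_{VV} + 2 G I_{VH})$ with instrument
G-factor 0.67 by default. A variant with $-2G$ in the denominator
circulates in legacy spreadsheets; it produces $r > 1$ and a divergence
at $I_{VV} = 2 G I_{VH}$, so the standard total-intensity form is the
default and the variant sits behind `printed_form = TRUE`.

A 5' fluorophore reports binding only at sites whose nearest edge lies
within 3 bp (`proximity_cutoff`); the dependence on distance is sharp
enough that a binary weight is used rather than a smooth decay. With
3 bp flanks this makes forward- and reverse-labeled strands clean
single-site reporters of site 1 and site 2 of a tandem construct. The
predicted signal is `baseline + amplitude * weighted occupancy`, with
amplitude and baseline per curve: labeling efficiency varies between
DNA preparations, so these are nuisance parameters, never shared.

## Fitting, model selection, statistics

`fit_single_site()` and `fit_global_two_site()` use Levenberg-Marquardt
least squares (minpack.lm) with $K_d$ parameterized on the log scale —
strict positivity plus scale-free search — from five log-spaced starting
values spanning the concentration range (cost tolerance $10^{-10}$).
Global fits share the thermodynamic parameters across all curves while
each curve keeps its own amplitude and baseline. A fit is flagged
non-converged instead of raising when the optimizer stalls or when the
amplitude is statistically indistinguishable from zero (a flat curve
leaves $K_d$ unidentifiable). Replicates are fit independently and then
summarized as mean and SEM (`aggregate_replicates()`), matching the
mean-plus-SEM convention for reported constants; pooling replicates into
one fit is possible by passing all curves at once but is not the
default.

Model choice between `equal_kd`, `distinct_kd` and `cooperative` uses
small-sample-corrected AIC on the global fit, ties going to fewer
parameters. Two numerical choices matter. First, the RSS entering AICc
is floored at $(10^{-7}\,\mathrm{sd}(y))^2 n$: below that level the
candidates differ only by rounding error, which the log-RSS term would
otherwise amplify arbitrarily, and the parsimony penalty should decide.
Second, like any AIC-type criterion this one overfits with small
probability on finite noisy data; the distinct-vs-equal decision on
curves generated at 1.7/10 nM truths is nonetheless correct in well
over 90% of seeds, which the acceptance tests check directly.
Cooperativity is only identifiable away from the depletion-dominated
regime (where stoichiometric binding masks curve shape), so the
cooperative-recovery tests run at a 50 nM site, where $\omega$ changes
the curve shape visibly.

Group comparisons of per-replicate $K_d$ values use a two-tailed Welch
t-test on the linear $K_d$ scale, with a label-permutation test as a
distribution-free cross-check; exactly identical groups return $p = 1$
directly since the t statistic is undefined at zero pooled variance.

## The synthetic-data generator

`generate_titration()` adds i.i.d. Gaussian noise (default
$\sigma = 0.003$ anisotropy units, chosen so three-replicate SEMs are
comparable to those typical of plate-reader titrations) to the exact
model signal on a series of 12 log-spaced concentrations plus a zero
point, spanning 0.1 nM to 2 uM by default (1 nM to 10 uM or 50 uM for
the weak nonspecific constants, so the titration brackets the $K_d$).
Labeled DNA defaults to 5 nM, i.e. 10 nM sites for tandem duplexes.
Replicate $r$ draws its noise under seed
$100 \times \text{base} + r$, making every data set reproducible from
one integer while replicates stay independent. `generate_emsa()`
produces band-fraction tables over the 0 to 2000 nM gel series at
250 nM DNA, with optional truncated-Gaussian fractional noise
renormalized per lane.

What the generator emulates — and what it does not. It reproduces the
noise magnitude, replicate structure, concentration design and
depletion regime of the titrations, and the stoichiometry patterns of
the gels. It does not model sequence-dependent affinity within a site
class, fluorophore photophysics, pipetting (concentration) error,
baseline drift, or gel-quantification artifacts; parameter recovery
under the generator therefore demonstrates correctness and
identifiability of the analysis, not robustness to every systematic
error a real experiment can contain.

## SAXS utilities

`guinier_fit()` fits $\ln I$ against $q^2$ by weighted linear
regression, starting from the lowest usable $q$ and truncating the
upper end iteratively until $q_{\max} R_g \le 1.3$ (the conventional
validity limit; configurable). Up to three leading points are dropped
only when that improves the fit $r^2$, which absorbs beam-smeared
points. The exact q-window used by any given beamline pipeline is not
standardized, so the window and $q_{\max} R_g$ are reported with the
result. `kratky()` is the pointwise transform $q^2 I(q)$ with no
smoothing. `polymer_rg()` evaluates the excluded-volume scaling law
$R_g = 1.927\,\text{Å} \times N^{0.598}$; for a 218-residue disordered
chain it gives the ~48 Å fully-expanded reference value against which a
measured ~27 Å indicates a compact ensemble.

```{r saxs}
glance(guinier_fit(synthetic_guinier_profile(27.3, i0 = 100)))
polymer_rg(218)
```

## Problem sizes and limitations

The bundled tests and the acceptance script run entirely on synthetic
data at the scale of the experiments they emulate: 13-point titrations
in 3 replicates, lattices up to 59 bp (enumeration cross-checks up to
40 bp), 50-seed selection-rate simulations, 100-seed bias checks.
These sizes were chosen as the smallest at which the stochastic
properties stabilize.

Known limitations: specific binding requires exact registration on the
site (no partial-overlap intermediate affinity); nonspecific DNA is
homogeneous (one constant); no steric penalty beyond hard-core
exclusion between adjacently bound dimers; no kinetic (time-resolved)
binding; no heteroscedastic error model in the fits; and the indirect
Fourier transform side of SAXS analysis (P(r), D_max) is out of scope.
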