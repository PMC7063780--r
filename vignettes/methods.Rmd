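---
title: "Models and methods behind thermoflux"
author: "thermoflux maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoflux)
```

`thermoflux` analyses adaptive-laboratory-evolution (ALE) experiments in
cellulolytic thermophiles: it connects fermentation phenotypes measured in
chemostats and high-solids batch reactors to the mutations that lineages of
engineered, evolved strains accumulate.  This vignette explains each model
and procedure, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Chemostat flux accounting

At steady state in a chemostat the specific growth rate equals the dilution
rate $D$ (h$^{-1}$) and every product leaves the reactor at

$$q_i = D \, C_i \, V \quad [\mathrm{mmol/h}],$$

with $C_i$ the steady-state concentration (mM) and $V$ the working volume
(L; default 0.3, dilution rate default 0.1 h$^{-1}$, ten-hour residence
time).  Multiplying by the product's carbon number gives carbon fluxes in
mmol C-atoms/h, the unit used for phenotype clustering.  Fluxes are
per-reactor by default (matching how such heatmaps are usually drawn); a
`per_liter` flag removes the volume factor.  The cell pellet is treated as
one more carbon stream, pellet C (g/L) converted at 12.011 g/mol.

**Carbon recovery** is the percentage of consumed substrate carbon found in
products, pellet carbon, and optionally CO$_2$.  CO$_2$ is rarely measured
in these fermentations, so it is *inferred* stoichiometrically from each
product's formation pathway: one CO$_2$ per acetyl-CoA-derived product
(ethanol, acetate), two per isobutanol, one per 2,3-butanediol and valine,
none for the glycolytic products (lactate, pyruvate, formate) or the other
amino acids.  These coefficients live in the metabolite registry
(`metabolite_registry()`) where they can be inspected or replaced.  Both
recovery modes (with and without inferred CO$_2$) are available;
CO$_2$-inclusive is the default because recoveries excluding it
systematically undershoot.

**Electron balance.**  Each registry entry carries a degree of reduction
$\gamma = 4C + H - 2O - 3N$ (available electrons per molecule, ammonia-level
nitrogen); NADH and reduced ferredoxin count two electrons each.
`electron_balance()` returns the product-minus-reactant electron residual of
a fermentation equation: homoethanol fermentation
(glucose $\to$ 2 ethanol + 2 CO$_2$) balances exactly, while the acetate
pathway (glucose $\to$ 2 acetate + 2 CO$_2$) is 8 electrons short, closed by
2 NADH + 2 Fd$_{red}$ — the bookkeeping behind the observation that acetate
flux must be accompanied by reduced co-products.

**C:N ratio.**  Pellet carbon and nitrogen are both proxies for biomass and
vanish together with it, so their relationship is a proportionality through
the origin.  `cn_slope()` therefore fits the least-squares line *without*
an intercept by default; this also avoids the attenuation that independent
measurement noise on the regressor inflicts on an intercept fit at the
small sample sizes typical of a loading titration (an intercept option is
exposed).  The default biomass composition is 3.35 g C/g N.

**Growth rates.**  $\mu_{max}$ is estimated by scanning all contiguous
windows of at least 5 points for log-linearity ($R^2 \ge 0.99$) and taking
the steepest qualifying slope — the definition of a *maximum* specific
growth rate, and robust against windows that leak into the transition to
stationary phase (a longest-window rule dilutes the slope there).  When no
window qualifies (e.g. a flat series) the fit reports failure rather than a
number.

**Ethanol yield** is expressed against a theoretical maximum of 4 mol
ethanol per mol cellobiose (2 per hexose unit); a parameter switches to a
glucose-equivalent basis (2 per mol).

## Phenotype clustering

`select_products()` keeps the products that carry more than 3 % of the
total carbon flux in at least one strain (per-strain, any-strain rule — a
product that matters for a single phenotype is retained).
`cluster_strains()` performs agglomerative clustering with average linkage
on Euclidean distances over the raw carbon-flux matrix, for strains and for
products, and cuts the strain tree into $k = 3$ groups by default (three
fermentation phenotypes: wild-type-like acetate producers, pta-deletion
pyruvate/amino-acid overflow, evolved high-ethanol).  Fluxes are *not*
standardised before clustering — the profiles are in a common physical unit
and the dominant streams should dominate the metric — but a
`scale_fluxes` flag exists.  Rows are sorted by strain id before
clustering and labels renumbered by first appearance, so the partition is
invariant to input order; the full dendrogram is always returned (and
exportable as Newick) so other cuts remain inspectable.  The implementation
is `stats::hclust`; the test suite checks it against a brute-force
$O(n^3)$ average-linkage oracle.

## Mutation provenance

Strain pedigrees are rooted trees (`pedigree()` rejects multiple roots,
multiple parents and cycles).  A mutation is **inherited** when present in
the pedigree parent at DNA allele fraction $\ge$ 0.35 and an **origin**
mutation otherwise; the root strain's mutations are all origin.  The
presence threshold sits deliberately below 0.5 so a mixed parental
population still transmits "presence"; parental signal in the 0.05–0.35
band is annotated (`low_freq_in_parent`) but not counted, keeping the
origin/inherited dichotomy crisp while making carry-over visible.
Insertion elements are matched across strains by (disrupted gene, element
family) when that information is present, since independent insertions of
the same family rarely share exact coordinates.

**Upstream mutations** are linked to a gene when they fall within 500 bp
5′ of its strand-aware start (window inclusive) and inside no annotated
coding region; the nearest qualifying gene wins.  **Convergence**: genes
collecting $\ge 2$ origin mutations (in-gene or linked-upstream; inherited
copies excluded so each evolutionary event counts once) are reported with
their strains.  **Subpopulation takeovers** are mutations at DNA allele
fraction in $[0.05, 0.5)$ but RNA allele fraction $\ge 0.9$: the genome
sequencing saw a minority population, the RNA (sampled later) an
essentially fixed one.

## Merodiploid locus genotyping

Unmarked gene deletion goes through a single-crossover (merodiploid)
intermediate: the marker cassette integrated between two copies of the
downstream homology region.  The locus model encodes expected copy numbers
per genotype over the segments (upstream flank, target 5′ region,
downstream homology, cassette): wild type $\{1,1,1,0\}$, clean deletion
$\{1,0,1,0\}$, merodiploid $\{1,0,2,1\}$.  Evidence consumed:

* per-segment **relative depth** (segment median / genome-wide median),
  invariant to global depth scaling;
* **junction read pairs** with one mate unambiguous in the cassette and
  one in the locus;
* **in-silico PCR** amplicon sizes on genotype templates (exact primer
  matching on both strands, nearest-downstream pairing; mismatch-tolerant
  matching is unnecessary for genotype discrimination and would cost
  determinism).

The caller requires the target 5′ segment to be effectively absent
(relative depth $\le 0.05$), the homology region near 2× (merodiploid) or
1× (clean deletion) within a tolerance of 0.4, and at least 2 junction
pairs for integration (0 for a clean deletion); anything else is
*ambiguous* rather than forced into a class.  The tolerance and junction
minimum are package choices — the underlying evidence in such studies is
qualitative — and both are exposed as arguments.  On simulated Poisson
coverage the caller's confusion matrix is diagonal with < 2 % error at
50× depth (tested over ~1000 simulated loci).

## Expression linkage

RPKM is counts $\times 10^9 / (\text{gene length} \times \text{library
total})$.  For each upstream origin mutation the target gene's replicate
RPKM values in the mutated strain are compared against the pedigree parent:
the fold change is the ratio of replicate means, and the p-value a
two-sided Welch (unequal-variance) $t$ test on $\log_2(\mathrm{RPKM}+1)$.
The source study reports p-values without naming its test; Welch-on-logs is
a standard, assumption-light choice for 3–4 replicates of positive,
right-skewed data, and exact reproduction of the study's p-values is not
claimed.  The pseudocount of 1 keeps zero-RPKM replicates finite and is
negligible at the expression levels tested.  Significance is
Bonferroni-corrected over the family of tested upstream mutations
($p \le \alpha/m$; $m$ defaults to the number of tests, the study's family
was 22).  Libraries with compressed dynamic range are excluded by passing a
QC blacklist upstream (dropping columns), not auto-detected.  Full
differential-expression machinery (dispersion shrinkage etc.) is
deliberately out of scope: the question is a targeted two-group comparison
per planted mutation.

## Solubilization kinetics

Residual cellulose in high-solids batch fermentations is fitted with a
decreasing four-parameter logistic

$$f(t) = A + \frac{B - A}{1 + e^{k (t - t_0)}},$$

with floor $A$ and plateau $B$ in g glucose equivalents/L, steepness $k$
(h$^{-1}$) and inflection $t_0$ (h).  "Sigmoidal" admits several families;
the logistic is the simplest symmetric one and its rate maximum is
analytic: $-f'(t)$ peaks at $t_0$ with value $k(B-A)/4$.  Fitting uses
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) from up to 10
deterministic data-driven starts ($B$ from the first value, $A$ from the
minimum, $t_0$ from the steepest finite difference, $k$ from that slope,
each varied over a small grid) keeping the lowest-RSS converged fit with
$B > A$, $k > 0$; if no start converges the failure is reported, never a
fabricated parameter set.  The fit is scale-equivariant in the response and
recovers noiseless logistic data to $10^{-6}$.  Extent of solubilization is
the first-minus-last value of the (replicate-averaged) series;
`rate_vs_growth_timing()` compares $t_0$ with the pellet-nitrogen peak to
flag whether the rate maximum precedes peak cell density.  Cellulose is
converted to glucose equivalents by the hydration factor 180/162, exposed
rather than silently assumed.

## The synthetic-data generator

`scenario_config()` fixes the ground truth; all generators are
deterministic given the configuration (each derives its RNG stream from the
seed).  The defaults *are* the study conditions wherever those are stated:
a 3-lineage pedigree of 16 strains; chemostats at $D = 0.1$ h$^{-1}$,
$V = 0.3$ L on 5 g/L cellobiose, duplicate reactors sampled twice;
wild-type-like strains producing ~17 mM acetate with ethanol in a ~1:1
molar ratio; evolved strains at ~50 % of the theoretical ethanol yield and
the adhE-point-mutant reintroduction strain at 45 %; pellet composition
3.35 g C/g N; four replicate expression libraries (three for strains
emulating a dropped library); high-solids logistic truths calibrated to a
largest extent of 109.2 g gluc eq/L and a highest maximum rate of
3.19 g gluc eq/L/h, with the cell peak 15 h after the inflection; 5 %
measurement CV (3 % for residual cellulose).  Where the study states no
value, standard positive-noise models were chosen once: lognormal for
concentrations, Poisson for coverage, gamma–Poisson for counts
(dispersion 0.005).

Deliberate simplifications, and what they mean for interpreting green
tests:

* The genome is synthetic — 100 kb, 50 uniformly spaced 1.2-kb genes —
  so all coordinate logic runs at desk scale; nothing about real genome
  content is modelled.
* Background mutations are placed on *neutral* positions (neither genic
  nor within any 500-bp upstream window), so gene-level convergence and
  upstream linkage carry planted signal only.  Real data have genic
  background hits; passing recovery tests therefore demonstrate the
  bookkeeping is correct, not that convergence detection is specific under
  a realistic genic mutation load.
* Default chemostat records carry realistic (< 100 %) carbon recovery,
  because product titers anchored to the study's levels do not close the
  balance at full substrate consumption; a `closed_balance` mode instead
  sets the feed to exactly match accounted carbon and is used to verify
  that fully balanced records recover 100 %.
* The high-solids endpoint table is a labelled synthetic stand-in: product
  titers are anchored to reported values and the pellet-carbon column is
  solved so each strain's recovery equals its reported value (94.2/78.5/
  77.9/71.5 %).  Recomputing those recoveries exercises the full
  accounting path but is a consistency check of the calibration, not an
  independent measurement.
* Mutation reversion (a merodiploid subpopulation re-emerging in a
  descendant) is not generated spontaneously; determinism of the planted
  truth takes precedence.  The subpopulation signature itself (low DNA,
  high RNA allele fraction) is planted explicitly.
* No reads, alignments or library-QC artefacts are simulated; the package
  consumes alignment-derived evidence (depth tracks, junction counts,
  allele fractions) by design.

## Numerical and interface choices

* Coordinates are 1-based, closed, everywhere (the R/Bioconductor
  convention; VCF and GFF3 agree).
* Ties in clustering are broken by sorting strains lexicographically
  before `hclust`; distances in these data are continuous so exact ties do
  not otherwise arise.
* Test problem sizes — 20-point titrations, ~1000 simulated loci, 100
  random pedigrees, 100 kinetic fits, 1000 null test families — were chosen
  as the smallest sizes at which the Monte-Carlo assertions are stable.
* `validate_inputs()` returns structured diagnostics instead of raising on
  content problems, so a pipeline driver can report all of them at once.

## Known limitations

Intracellular flux estimation (MFA/FBA), hydrogen partial-pressure
modelling, variant calling from reads, structural-variant discovery beyond
the modelled locus, dispersion-shrinkage differential expression and
cluster-number selection statistics are all out of scope.  The Bonferroni
family size must be supplied when the tested family is larger than the
links that survived filtering — the package cannot know how many tests an
analyst intended.
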