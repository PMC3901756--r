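---
title: "Profiling marker informativeness over time: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling marker informativeness over time: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopi)
```

# The question the package answers

Given a concatenated multi-marker alignment, a rooted ultrametric tree
with branch lengths in Ma, and a partition scheme (genes, and codon
positions within protein-coding genes), `phylopi` asks: *which
partition is expected to contribute phylogenetic signal at which time
depth?* The answer drives marker choice — a fragment that is superb for
a Neogene radiation may be saturated noise for a Cretaceous split.

# Models and procedure

## Per-site rates on a fixed time tree

Each alignment column gets its own substitution rate $\lambda$
(substitutions/site/Ma), estimated by maximizing the column's
likelihood on the fixed tree with Felsenstein's pruning algorithm. The
substitution model is JC69 with uniform root frequencies. This is a
deliberate choice: with the tree fixed and the site treated in
isolation, JC69 leaves $\lambda$ as the single free parameter, so the
estimate is a pure rate summary uncontaminated by per-site nuisance
parameters that a 4-to-6-taxon column pattern could never inform
anyway. Robustness to this simplification is checked by simulating
under HKY85 with strongly unequal base frequencies and verifying that
rate *orderings* across partitions survive estimation (they do; the
absolute rate of deeply saturated AT-rich partitions is compressed,
which only flattens — never reorders — the classes; see the test
suite). A TSV reader (`read_rate_table()`) accepts externally produced
rates in the same layout, so rates from other estimators can be
substituted.

Numerical details that matter:

- The likelihood is maximized on $[0, \lambda_{\max}]$ with
  $\lambda_{\max} = 20/T$ ($T$ = root age): ~20 expected root-to-tip
  changes, far beyond saturation. The per-site profile likelihood can
  be bimodal — an interior mode plus a plateau near $\lambda_{\max}$
  where the column pattern is explained as pure noise — so Brent's
  method is always started inside a bracket found by a coarse
  log-spaced grid scan. All columns are optimized simultaneously by a
  vectorized golden-section refinement (one pruning pass per iteration
  over an $n_{\text{sites}} \times 4$ partial-likelihood matrix),
  which keeps a 6095-column, 40-taxon matrix under a few seconds.
- Partial likelihoods are renormalized at every internal node (log-scale
  accumulator), so deep trees cannot underflow.
- Gaps, `?`, `N` and all IUPAC ambiguity codes are missing data
  everywhere in the package: a missing tip contributes a partial vector
  of ones. Constant, all-missing and single-taxon columns get
  $\hat\lambda = 0$ with a boundary flag instead of `NA`, so partition
  sums over sites stay defined.
- $\hat\lambda$ is scale-equivariant (tree in units of $c\cdot$Ma
  $\Leftrightarrow$ rates divided by $c$) and invariant to taxon order;
  both are property-tested.

## Informativeness profiles

A site of rate $\lambda$ contributes, at time depth $t$,

$$\rho_{\text{orig}}(t;\lambda) = 16\lambda^2 t e^{-4\lambda t}, \qquad
  \rho_{\text{mod}}(t;\lambda) = \lambda t e^{-4\lambda t}.$$

The first (original) form is normalized to unit area over
$t \in (0,\infty)$, which compares profile *shapes* but scales each
site by its own rate: fast sites tower over slow ones at all depths.
The modified form drops the $16\lambda$ normalizing factor. This is the
form with the behavior expected of an absolute signal measure: peak
height is the constant $e^{-1}/4$ for every rate, peaks are lower and
more extended, and the curves of two rates cross exactly once, at
$t_x = \ln(\lambda_f/\lambda_s)/(4(\lambda_f-\lambda_s))$, beyond which
the slower site wins. (Dropping the whole $16\lambda^2$ factor instead
would make slow sites dominate at *all* depths, contradicting every
qualitative behavior the profiles are meant to display, so the package
commits to the $\lambda t e^{-4\lambda t}$ reading; `pi_rho()` is the
single place the form lives, so an alternative is a one-line swap.)
Both forms peak at $t^\ast = 1/(4\lambda)$.

Partition profiles are sums of $\rho$ over the partition's sites; the
`average_modified` variant divides the modified sum by partition length
$L$, giving informativeness per aligned base — the comparison to use
across fragments of very different length (a 2 kb fragment beats a
0.4 kb fragment in total signal merely by being long). The default time
grid is 512 evenly spaced points on $(0, T]$; sites whose rate sits at
the $\lambda_{\max}$ boundary are included (their $\rho$ is
negligible at any relevant $t$).

## Saturation tables

Saturation is diagnosed non-parametrically: for every taxon pair and
partition, the uncorrected p-distance (proportion of differing sites
among pairwise-complete positions) is plotted against the patristic
distance on the reference tree. Pairwise deletion is used rather than
complete cases because fragment-level missingness would otherwise
discard most pairs. The per-partition summary is an OLS slope,
intercept and Pearson r — saturation reading is fundamentally visual
(a plateau), and no bespoke saturation index is invented. Under JC the
expected p-distance at tree distance $d$ is
$\tfrac34(1-e^{-4\lambda d/3})$, with ceiling $\tfrac34$; under
unequal base frequencies the ceiling drops to $1-\sum_i \pi_i^2$,
which is why the AT-rich simulated mitochondrial partitions plateau
near 0.67 rather than 0.75. Which reference tree to use (combined-data
tree vs single-gene tree) is an analysis choice; the function takes the
tree as an explicit argument rather than guessing.

## Site classification

Ignoring missing symbols, a column is *conserved* (≤ 1 state),
*parsimony-informative* (≥ 2 states each in ≥ 2 taxa) or *variable but
uninformative* (variation only in singletons). "Variable" is reported
*including* the parsimony-informative sites, so
`n_conserved + n_variable = n_sites`; the output header documents this
convention. Ambiguity codes count as missing, not as partial states —
the simplest defensible rule, and consistent with their treatment
everywhere else in the package.

## Calibration priors

A fossil gives a hard minimum age (`offset`); the exceedance above it
is modeled as lognormal or exponential. The lognormal is parameterized
by the *real-space* mean and standard deviation of the exceedance,
mapped to log-scale parameters by $\sigma^2 = \ln(1+s^2/m^2)$,
$\mu = \ln m - \sigma^2/2$. With offset 34 Ma, mean 7, sd 5 this yields
a median of 39.70 Ma and a 2.5% quantile of 35.62 Ma — matching the
kind of "median ≈ 40 Ma, lower bound ≈ 36 Ma" summaries reported for
such priors, which is precisely why the real-space reading of
mean/sd was adopted (a log-space reading cannot reproduce that median).
The computed 97.5% quantile is 54.05 Ma; quantiles, CDF and Monte-Carlo
sampling are all closed-form/standard and round-trip-tested. Values are
reported to 0.01 Ma, rounded to integer Ma only in human-readable
summaries.

# The synthetic-data generator

Because the real data the package targets are external downloads, the
simulator is a first-class module generating matrices with the same
*structure*:

- **Tree**: Yule topology on 40 tips, node heights rescaled so the root
  is exactly 110 Ma. Pure-birth is the simplest ultrametric generator;
  topological realism is irrelevant to the math being tested.
- **Fragments**: eight fragments of 2008, 821, 684, 671, 670, 466, 447
  and 328 bp (total 6095), six of them protein-coding and split into
  codon-position partitions with genuine `\3` column interleaving, two
  ribosomal.
- **Rates**: eight rate classes (per site per Ma) — mito 3rd 0.030,
  nuclear 3rd 0.008, 16S 0.004, 28S 0.0018, mito 1st 0.00085, nuclear
  1st 0.0004, mito 2nd 0.0002, nuclear 2nd 0.0001 — drawn per site from
  a gamma law (shape 2 at third positions, 4 at first/second, 1 for
  ribosomal). The constants were fixed once, by design: mitochondrial
  3rd positions exceed 2 expected substitutions/site root-to-tip
  (deeply saturated), first/second positions stay below 0.2
  (unsaturated), nuclear 3rd positions peak near
  $1/(4\cdot0.008) \approx 31$ Ma, and adjacent classes are at least a
  factor ~2 apart so that class orderings are statistically recoverable
  from partitions of a few hundred sites. They live in
  `fixture_config()`, not in code paths.
- **Model**: HKY85 with AT-rich frequencies and high $\kappa$ for
  mitochondrial fragments, milder values for nuclear — deliberately
  *not* the JC model the estimator assumes, so end-to-end tests exercise
  model mismatch.
- **Missingness**: each (taxon, fragment) cell is independently blanked
  with probability 0.11 — fragment-level, not site-level, emulating
  specimens whose fragment failed to amplify.
- **Determinism**: every simulation function takes an integer seed and
  isolates the RNG (`withr::with_seed`), leaving session RNG state
  untouched; the same seed reproduces FASTA output byte-for-byte.

What the simulator does *not* emulate: indels (the real CAD fragment
contains a short indel region), base-composition heterogeneity across
lineages, selection/codon structure beyond position-specific rates, and
topological realism. Passing tests therefore demonstrate correctness of
the estimators and profile algebra under a controlled generating
process — not that any particular real dataset will show these exact
numbers.

# Problem sizes and runtime

The shipped test-and-validation conditions are the reference-structure
defaults above: 40 tips × 6095 sites for the end-to-end fixture
(rate estimation ≈ 2 s), 50 tips × 500 sites for gamma-rate recovery,
24 tips × 600 sites for saturation checks, and 4–6-tip trees for the
brute-force likelihood enumeration oracle ($4^{n_{\text{internal}}}$
terms). These sizes make the full suite run in well under a minute
while leaving each statistical check several standard errors of
headroom.

# Open design choices, resolved

- **Unrooted input trees** (basal trifurcation) are accepted and
  treated as rooted at that node, with a warning — refusing them would
  reject many published consensus trees for no mathematical reason.
- **Non-ultrametric trees** warn rather than fail in rate and
  informativeness operations: slight depth jitter from dating software
  output is common and harmless, while a hard error would force users
  to re-ultrametricize needlessly. Saturation tables accept any tree by
  design.
- **Profiles are reported per partition as supplied** — if gene ×
  codon-position subsets are wanted, the scheme should enumerate them
  (as the fixture's does); the package does not silently cross
  partitions with codon positions.
- **Rates are absolute** (per Ma) since branch lengths are in Ma; no
  per-partition relative-rate scaler is introduced. External relative
  rates can still be injected via the rate-table reader if a user
  prefers that convention.

# Known limitations

Site rates are point estimates; no uncertainty is propagated into the
profiles (profile differences smaller than estimation noise should not
be over-read, especially for short partitions). The JC estimator
compresses absolute rates under strong compositional bias (see above).
Informativeness here is the quartet-based per-site form; it does not
model internode-specific resolution probabilities, amino-acid data, or
signal-vs-noise extensions. Calibration priors are summarized, not
sampled within any dating MCMC — placement of a fossil on stem vs crown
is an upstream modeling decision the package deliberately does not
make.
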