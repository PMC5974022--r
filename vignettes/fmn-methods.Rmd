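---
title: "Functional metagenomic networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional metagenomic networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmnet)
```

`fmnet` implements an integrated 16S-amplicon + ¹H-NMR metabolomics
analysis for case-control cohort studies of the gut-liver axis: taxon
abundance preprocessing and diversity, NMR bucket preprocessing,
construction of a *functional metagenomic network* (FMN) over merged
taxon and metabolite features, cross-correlation of features with
clinical parameters under false-discovery-rate control, and a consensus
ranking of features associated with hepatic encephalopathy (HE). This
vignette documents the statistical models, the tunable parameters and
their defaults, what the synthetic cohort generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The abundance side

Counts are depth-normalized by **rarefaction**: each sample is
subsampled without replacement to a common depth (default: the minimum
sample total; the motivating cohort used 3101 reads, the least rich
library). Subsampling rather than scaling preserves integer counts, so
observed richness remains meaningful. The draw is seed-controlled and a
single realization is used; the expected post-rarefaction composition
equals the original composition (hypergeometric mean), which the test
suite verifies by simulation.

After conversion to relative abundances, taxa are filtered by **mean
relative abundance ≥ 0.5%** (inclusive at the threshold, ties kept).
This is the screen that separates the analyzable community from the
long tail of rare OTUs; it is applied before any correlation work so
that network nodes are taxa whose abundances are estimated with
tolerable counting noise at depth ~3000.

Alpha diversity is observed richness and the Shannon index
\(H = -\sum_i p_i \ln p_i\) (natural log by default, matching the
upstream 16S tooling; the base is configurable). Beta diversity offers
the Yue & Clayton measure
\(\theta(a,b) = 1 - \frac{\sum a_i b_i}{\sum a_i^2 + \sum b_i^2 - \sum a_i b_i}\)
and Bray-Curtis \(\frac{\sum |a_i - b_i|}{\sum (a_i + b_i)}\)
(delegated to `vegan::vegdist`). Ordination is classical PCoA
(double-centring of \(-\tfrac12 D^2\), eigendecomposition, top-\(k\)
positive-eigenvalue axes); the sign of each axis is fixed so that the
largest-magnitude coordinate is positive, which makes ordinations
reproducible across BLAS implementations.

## The NMR side

Spectra pass through a fixed, enforced stage order:

1. **Rolling-ball baseline removal**: grey-scale erosion then dilation
   with a flat window of `2 * radius + 1` grid points, followed by a
   moving-average smoothing of the same width; the pre-smoothing
   baseline never exceeds the signal. The default radius of 50 grid
   points is a conventional choice (no value is fixed by the method
   itself): at a typical digital resolution of ~0.001-0.005 ppm/point
   the window is far wider than a metabolite peak but much narrower
   than baseline drift, and the tests confirm narrow-peak areas survive
   within 1%.
2. **Alignment**: each spectrum is rigidly shifted along the shared ppm
   grid by the integer offset (bounded by `max_shift_ppm`, default
   0.02 ppm — one bucket) that maximizes its normalized
   cross-correlation with the pointwise-median spectrum. Normalization
   makes the shift estimate invariant to global intensity scaling.
3. **Bucketing**: trapezoidal integration over half-open 0.02-ppm
   windows. Buckets overlapping an exclusion interval are dropped
   entirely. The default exclusions are the conventional water
   (4.50-5.20 ppm) and TSP reference (below 0.50 ppm) regions plus the
   spectrum extremes beyond 9.00 ppm. Published bucket counts depend on
   each study's exclusion bounds, which are rarely stated; the bucket
   count is therefore treated as configuration-dependent and never
   asserted.
4. **Total-integral normalization** to 1000 per spectrum.
5. **Probabilistic quotient normalization (PQN)**: the reference is the
   per-bucket median over all samples (a group-median option exists);
   each sample's quotient is the median of sample/reference ratios over
   buckets with positive reference, and the row is divided by it.

One subtlety deserves a note. PQN conventionally *follows*
total-integral normalization, and `pqn_normalize()` enforces that order
by default. But total normalization rescales every row to the same sum,
so it removes a pure dilution factor exactly — after it, PQN corrects
only the distortion that large individual signals impose on the total.
When the goal is to *estimate* per-sample dilution factors themselves
(as in the generator-recovery checks), PQN must run on the raw bucket
matrix (`enforce_total = FALSE`); the quotients then track planted
dilutions with correlation > 0.999 in the synthetic cohort.

Downstream feature selection keeps **informative buckets** only: those
with across-sample coefficient of variation ≥ 0.1 after normalization
(`select_informative_buckets()`). Most buckets of a normalized spectrum
are chemically uninteresting filler; carrying them into the network
would add hundreds of isolated nodes and dilute every descriptor
statistic.

## The functional metagenomic network

Filtered taxa and informative buckets are column-merged over shared
samples, tagged by kind. Pairwise Pearson correlations (with two-sided
t-distribution P values on \(n-2\) df) are computed **per cohort arm,
never pooled**: a correlation structure mixed across cases and controls
would reflect group mean differences, not co-occurrence. An edge joins
every pair with \(r > 0.7\) (*synergistic*) or \(r < -0.7\)
(*competitive*) — strict inequalities; a pair at exactly ±0.7 is not an
edge. Undefined correlations (constant features) never create edges,
and isolated nodes are retained. An optional P-value filter exists
(`p_max`) but is off by default: the published method states only the
correlation threshold for networks, so the default edge set is
r-thresholded only.

**Node metrics.** Degree is the incident-edge count. Betweenness is the
unnormalized Brandes value on the *unweighted* thresholded graph — the
sum over unordered node pairs of the fraction of shortest paths through
the node. Published keystone betweenness magnitudes (hundreds) are
consistent with unnormalized pair counts, and no edge weighting is
stated in the method; a weighted variant (lengths \(1/|r|\)) is
available behind a flag. The implementation delegates to `igraph`; the
test suite checks it against an independent exhaustive shortest-path
enumeration oracle on 30 random graphs.

**Communities (FMCs).** Louvain modularity maximization at resolution
\(\gamma = 1\) with edge weights \(w_{ij} = |r_{ij}|\):
\[
Q = \frac{1}{2m} \sum_{ij} \Bigl(w_{ij} - \gamma \frac{k_i k_j}{2m}\Bigr)
    \delta(c_i, c_j).
\]
Using \(|r|\) lets competitive edges contribute to connectivity instead
of requiring a signed-modularity extension (standard \(Q\) is undefined
for negative weights, and a signed variant is out of scope). The node
visit order is randomized per restart from the seed (20 restarts by
default) and the best-of-restarts partition is returned with its
modularity; the result is byte-reproducible for a fixed seed. Partition
quality can be checked with `validate_partition()`: silhouette on the
correlation distance \(1 - r\), and a Calinski-Harabasz score on a
classical-MDS embedding of the same distance (CH needs a Euclidean
representation; the embedding dimension is capped at 10).

**Descriptors and keystones.** `network_summary()` reports node/edge
counts, synergistic/competitive counts with percentages (1 decimal),
their ratio (2 decimals), density \(2E/(N(N-1))\) (3 decimals),
modularity and community count, plus the top-\(k\) keystones by
betweenness (ties broken by higher mean relative abundance, then
lexical id). \(k = 5\) by default. Because it is ambiguous whether
keystone species and keystone metabolites should be ranked in one pool
or separately, both reports are emitted (`keystones` and
`keystones_by_kind`).

## Clinical cross-correlation

`crosscorrelate()` computes Pearson \(r\) between every feature and
every numeric clinical parameter over shared samples, with
pairwise-complete handling of missing clinical values, and applies
Benjamini-Hochberg correction **pooled over the full matrix of tests**
— the most conservative reading when the correction family is not
stated. A pair is starred when \(q \le \alpha\) (inclusive by default;
published figure captions alternate between strict and inclusive
phrasing, so this is configurable). The step-up rule is implemented
directly (`bh_fdr()`) because it is part of the method's contract;
`p.adjust(.., "BH")` serves as an independent cross-check in the tests.
Group comparisons use the Mann-Whitney U test (two groups) or
Kruskal-Wallis (two or more); for Mann-Whitney the exact null
distribution applies when both groups have fewer than 50 observations
and no ties, otherwise the normal approximation with continuity
correction (the `stats::wilcox.test` switch).

## The HE consensus ranking

Features are mean-centred and scaled to unit *population* variance
(`sd \cdot \sqrt{(n-1)/n}`), then four models are fit against the
binary HE outcome:

- **Logistic regression**, per feature by default. A per-feature fit is
  the only reading under which a mixed-habitat table of
  \((\beta, \mathrm{OR})\) rows is coherent; a joint fit over all
  features exists behind `mode = "joint"`.
- **Odds ratios** use the base-2 transform \(\mathrm{OR} = 2^\beta\)
  exactly as reported (base e is conventional and available via
  `base =`, but never the default). The implied percentage change in
  risk is \((\mathrm{OR} - 1) \cdot 100\).
- **Randomized lasso** (stability selection): `B = 200` subsamples of
  fraction 0.5; per subsample an L1-penalized logistic fit in which
  each coefficient's penalty is randomly rescaled by the weakness
  \(w = 0.5\) (factor drawn uniformly from \(\{w, 1\}\)); the score is
  the selection frequency. The L1 strength is chosen once by
  cross-validation on the full data; the 1-SE rule (`lambda.1se`) is
  used because stability selection requires a sparsity level at which
  null features are rarely selected — with the looser `lambda.min`
  choice the mean null-feature score drifts toward 0.3, which defeats
  the purpose of a selection frequency. Cross-validation folds are
  stratified by class so small HE counts never produce single-class
  folds.
- **Elastic net**: penalized logistic regression, mixing 0.5, strength
  by cross-validation (`lambda.min`).
- **SGD classifier**: logistic loss with L2 penalty
  (\(\alpha = 10^{-4}\)), inverse-scaling learning-rate schedule
  \(\eta_t = \eta_0 / (1 + \alpha \eta_0 t)\) with \(\eta_0 = 0.01\),
  1000 epochs of seed-controlled shuffling. The update loop is compiled
  (Rcpp); the visit order is drawn under R's RNG so results are
  reproducible from the master seed.

The **consensus sign** is the sign shared by the three signed
coefficients (logistic, elastic net, SGD); the randomized-lasso score
is a frequency in \([0,1]\) and carries no sign, so it participates in
selection (`select_he_features()`, default threshold 0.25 — the usual
stability-selection convention) but not in the sign consensus. Any zero
coefficient or sign disagreement yields consensus 0, and such features
are excluded from the default report.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage can be tested
against known ground truth without any sequencing deposit. Its defaults
are the study conditions: 35 cirrhotic cases and 14 controls, library
sizes bounded below by the 3101-read rarefaction depth, an HE logistic
intercept of \(\mathrm{logit}(8/46)\) (the cohort's HE prevalence), and
generating coefficients with the magnitudes of the published logistic
betas.

The latent model is deliberately the simplest thing with controllable
planted correlation: per-block standard-normal factors \(z_b\) per
sample; each planted feature's latent is
\(\sqrt{\rho}\, z_{b(f)} + \sqrt{1-\rho}\,\varepsilon_f\) with
\(\rho\) = `block_corr`. Taxon latents map to relative abundances by a
softmax over log-weights and counts are drawn multinomially at the
sample's library size; metabolite buckets are noisy linear images of
their latents (intensity \(\propto 1 + 0.2x\)), scaled by per-sample
dilution factors drawn log-uniformly. HE labels are Bernoulli with
\(\mathrm{logit}\, p = \beta_0 + \sum_f \beta_f x_f\). One RNG stream
per output block (latents, counts, NMR, clinical, labels) is derived
from the master seed, so adding an output never perturbs the others and
every table is byte-identical under a fixed seed.

Two structural choices matter and were made once, for statistical
reasons:

- **Background mass.** Compositional closure is the dominant nuisance
  in both data types: if the planted features carried most of the
  community (or of the spectral integral), normalization would induce
  strong spurious negative correlations across blocks — with two
  planted blocks, up to \(r \approx -0.9\). The generator therefore
  gives planted taxa ~18% of the community, with 300 sub-threshold
  background taxa (each below the 0.5% filter, like the long tail of
  rare OTUs) carrying the rest; likewise 150 low-variance background
  buckets carry most of the total NMR integral, as in a real bucket
  table where informative peaks are a small share of the spectrum. The
  0.5% filter and the CV-based bucket filter then recover exactly the
  planted feature set, which is what those screens are for.
- **Bridge keystones.** A keystone loading \(1/\sqrt2\) on each of two
  *orthogonal* block factors has population correlation at most
  \(\sqrt{\rho/2} \approx 0.69\) (at \(\rho = 0.95\)) with any block
  member — strictly below the 0.7 edge threshold, so its bridging edges
  would exist only by sampling luck. Real communities linked by a
  bridging species are not orthogonal, and the generator encodes this:
  each bridged block pair shares a weak common factor
  (`bridge_corr = 0.45`), raising the keystone-member population
  correlation to \(\sqrt{\rho}\sqrt{(1+c)/2} \approx 0.83\) while
  across-block member correlation stays at \(\rho c \approx 0.43\), far
  below threshold. Keystones are pure bridges (no idiosyncratic term)
  and are drawn among metabolites by default, whose intensities carry
  no multinomial counting noise. A fraction (`frac_negative = 0.1`) of
  planted features loads negatively on its block, which produces the
  competitive edges seen in real FMNs.

What the generator does **not** emulate: raw sequencing reads, chimeras
and OTU picking; taxonomic identity and phylogeny; zero inflation
beyond what the multinomial induces; free-induction decays, phasing, or
peak-shape variation in the NMR dimension; longitudinal structure; and
any real biological covariance between taxa and clinical chemistry
beyond the planted linear associations. Passing the recovery suite
therefore shows that the pipeline's inference is correct *when its
assumptions hold*, not that it would recover structure from an
arbitrary real cohort.

Recovery checks confirmed by the test suite and the acceptance script
(at two planted blocks, `block_corr = 0.95`, `noise_sd = 0.05`,
analyzing the 35-sample case arm): the detected FMC partition matches
planted blocks with adjusted Rand index ≥ 0.9 in ≥ 90% of 50 seeds
(keystones excluded from the comparison — a bridge has no single true
block); both planted keystones rank in the top-5 betweenness in ≥ 90%
of seeds; PQN quotients on the raw matrix correlate ≥ 0.99 with planted
dilutions; a feature with generating \(\beta = +2\) among nine
independent nulls (200 samples) tops the randomized-lasso ranking in
≥ 90% of 50 replicates while null features keep mean scores ≤ 0.3.

## Numerical choices and degenerate inputs

- Strict thresholds throughout where the method prints strict
  inequalities (network edges); inclusive where it prints ≥ (the
  abundance filter, the FDR stars).
- `bh_fdr()` caps at 1 and clamps `q ≥ p` explicitly: the raw step-up
  product `p * m / rank` can round one ulp below `p` in floating point.
- Keystone ties break by mean relative abundance, then lexical id, so
  rankings are total and platform-stable.
- Rarefaction refuses samples shallower than the target depth, naming
  them; `to_relative()` and normalizations refuse all-zero rows ditto.
- Constant features are flagged and excluded from correlation work with
  a warning; they never silently produce edges or stars.
- The Louvain result is the best of 20 seeded restarts; modularity of
  the returned partition is always ≥ the all-singletons and
  one-community baselines (asserted in the tests).
- PCoA discards non-positive eigenvalues and errors when none are
  positive (a degenerate distance matrix).

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at
the cohort scale of the study design (tens of samples, tens of planted
features plus background): 50-seed loops for the network recovery
checks, 50 replicates for the randomized-lasso recovery, 200 for its
null calibration, 100 for the false-star simulation, and 30 random
graphs for the betweenness oracle. These sizes give binomial standard
errors of a few percent on each estimated rate while keeping a full run
in the single-digit minutes on one CPU.

## Known limitations

- The pipeline accepts OTU/KOrth/metabolite tables as given; OTU
  picking, taxonomy assignment, predicted-metagenome generation and
  their error modes are upstream of this package.
- Standard modularity with \(|r|\) weights treats a strong negative
  correlation as connectivity; a signed-modularity community criterion
  is deliberately not implemented.
- The per-feature logistic fits ignore correlation among features by
  design (that is what the published per-row table implies); the joint
  mode exists but is not the default and its coefficients are not
  comparable to the per-feature ones.
- Good's coverage is not implemented: the upstream definition used for
  the printed coverage value is not stated in the method, and guessing
  it would produce unverifiable numbers.
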