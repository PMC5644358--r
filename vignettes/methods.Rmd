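---
title: "Methods: models, simulators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microassembly)
```

This vignette is the package's own account of the science it implements:
the statistical models and their assumptions, the tunable parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical decisions taken where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The analysis chain

The package implements the community-assembly workflow typical of
habitat-comparison rDNA surveys: rarefy an OTU table to even depth; compute
alpha diversity; classify OTUs into abundance categories and check the
rarity cutoff with MultiCoLA; quantify beta diversity (Bray–Curtis, NMDS,
ANOSIM); relate community similarity to geographic and environmental
distance (Mantel, partial Mantel, distance decay); partition community
variance into environmental and spatial components (PCNM + RDA + varpart);
and fit the Sloan neutral community model. Each stage is exposed as an
ordinary R function; `run_pipeline()` composes them.

## 2. Alpha diversity

Per sample, with counts $c_j$, total $N$, proportions $p_j$, singleton and
doubleton counts $F_1, F_2$:

* richness $S_{obs} = \#\{c_j > 0\}$;
* Chao1 in the **bias-corrected** form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$,
  chosen because it stays defined at $F_2 = 0$ (the classical form does
  not);
* ACE with the community-standard rare-abundance cutoff of 10 reads; when
  every rare read is a singleton the coverage estimate is 0 and ACE is
  reported as `NA` rather than an arbitrary fallback;
* Shannon–Wiener $H' = -\sum p_j \ln p_j$ in **nats**; the log base is a
  convention and Pielou's $J' = H'/\ln S_{obs}$ is base-invariant; $J'$ is
  `NA` for single-OTU samples;
* Simpson's index of diversity $1 - \sum p_j^2$; Good's coverage
  $1 - F_1/N$.

Both Chao1 and ACE are verified against `vegan::estimateR` in the test
suite. Samples shallower than a requested rarefaction depth are an error,
never silently dropped: discarding data is an explicit caller decision.

## 3. Abundance categories and MultiCoLA

OTUs are classified by their per-sample relative-abundance profile with a
rarity threshold (default $10^{-4}$, i.e. 0.01 %) and an abundance
threshold (default $10^{-2}$, i.e. 1 %): abundant (AT) when at or above the
abundance threshold everywhere, rare (RT) when below the rarity threshold
everywhere, moderate (MT) when always between the two, and the conditional
categories (CAT, CRT, CRAT) when the profile crosses thresholds. Boundary
conventions are "$\ge$" at the abundance threshold and "$<$" at the rarity
threshold, and **absence counts as rare**: an OTU absent in one sample and
abundant in another is CRAT, not CAT. The six predicates are exhaustive and
mutually exclusive, which the tests check by brute-force re-evaluation on
random tables. "Dominant taxa" is the pooled set AT ∪ CAT ∪ CRAT.

MultiCoLA ranks OTU *types* by total abundance (ties broken by OTU id, so
truncation series are deterministic and nested) and removes the rarest
$\lceil f \cdot S \rceil$ types at each truncation fraction $f$; the
Bray–Curtis matrices of truncated and original tables are compared by
Spearman correlation of their off-diagonal entries (Procrustes $m^2$
between NMDS ordinations is available as a second comparator). Truncation
by types rather than by sequences is the default because robustness claims
are usually phrased in "% of rare types". A `remove_dominant` direction
profiles the inverse series. A truncation that empties a sample is flagged
`undefined` for that fraction rather than silently skipped.

## 4. Beta diversity

Bray–Curtis is computed on raw rarefied counts by default — at equal
depths, raw and relative versions coincide — with `sqrt` and `relative`
transforms available. NMDS wraps `vegan::monoMDS` (Kruskal stress-1,
monotone regression) with a metric-scaling start plus 50 random restarts
(tolerance $10^{-6}$, 500 iterations), keeping the lowest-stress solution;
an all-equal distance matrix is returned as a flagged zero-stress
degenerate solution instead of an error. ANOSIM uses the rank-based global
$R$ with a one-sided upper-tail permutation test.

Permutation tests in ANOSIM, Mantel and partial Mantel switch to **exact
enumeration** of all $n!$ relabelings whenever $n!$ fits within the
requested permutation count; the exact p-value is then the proportion of
the full permutation distribution at or above the observed statistic
(identity included). Otherwise the standard $(b+1)/(B+1)$ Monte-Carlo
estimate is used.

## 5. Spatial statistics

Geographic distances are haversine on a sphere of radius 6371.0088 km;
at coastal between-site spacings (1–20 km) ellipsoidal corrections are
far below any ecological signal. Environmental distances square-root
transform every variable except pH (concentrations are right-skewed; pH is
already logarithmic) and, by default, z-score each variable afterwards
because units are incommensurable — this standardization step is the
package's choice and can be disabled.

Mantel tests default to Spearman correlation. The partial Mantel
permutes the second matrix's rows and columns simultaneously (the classic
Smouse–Long–Sokal simple-permutation scheme, not residual permutation).
Perfect correlation between the conditioning matrix and either argument is
a hard error: the partial-correlation formula is 0/0 there.

Distance decay is reported as a Mantel test of similarity
(1 − dissimilarity) against distance with a **lower-tail** test, so decay
appears as $r < 0$; the orientation is recorded in the result because
similarity- and distance-oriented conventions are easy to mix up.

PCNM builds the truncation threshold $t$ as the longest edge of the
minimum spanning tree of the distance matrix, replaces all larger
distances by $4t$, double-centers $-\tfrac12 D^2$, and keeps eigenvectors
with eigenvalues above $10^{-9}$ of the largest, in descending order. The
eigenvectors are returned orthonormal. On a 10-site equidistant transect
the implementation is numerically identical to the reference
implementation (`vegan::pcnm`); note that with nearest-neighbour
truncation the *leading* eigenvector there is the full-period sine over
site order (|r| ≈ 0.99), not the half-period gradient (|r| ≈ 0.93) —
a property of classic PCNM worth knowing when interpreting "broad-scale"
axes at small n.

## 6. RDA, forward selection, variation partitioning

RDA is multivariate least squares of the column-centered community matrix
(typically Hellinger-transformed) on column-centered predictors:
$R^2 = \|\hat Y\|^2 / \|Y_c\|^2$, adjusted by the Ezekiel closed form
$1-(1-R^2)(n-1)/(n-p-1)$. Permutation p-values permute rows of $Y$ freely
(999 by default); no restricted schemes are implemented.

Forward selection applies both Blanchet stopping rules: a global pre-test
at $\alpha$, then per-step addition of the adjusted-$R^2$-maximizing
candidate only if its partial contribution is significant and the
cumulative adjusted $R^2$ stays at or below the global model's. A
consequence users should expect: with a single informative predictor among
pure noise, the single-variable adjusted $R^2$ fluctuates around the
global adjusted $R^2$, so the scope rule legitimately returns an empty
selection in roughly half of such cases (`vegan::ordiR2step` behaves
identically). The stopping reason is always recorded.

`varpart2` computes the four fractions from the three marginal adjusted
$R^2$ values ($a = R^2_{adj}(E{+}S) - R^2_{adj}(S)$, etc.; they sum to 1
algebraically). The combined model tolerates overlap between the two
predictor sets — its $R^2$ is that of the joint column space, adjusted at
the space's rank — so identical sets correctly give zero unique fractions.
Negative fractions are reported as-is, never clamped. The testable pure
fractions get p-values from partial RDA with the response residualized on
the other set. In the pipeline, selection is run **separately per
component** (environment, space), matching common practice; if selection
returns empty for a component, the single best predictor is used as a
flagged fallback so the partition is always computable.

## 7. The Sloan neutral community model

For a taxon with metacommunity relative abundance $p$, local relative
abundance at stationarity is $x \sim \mathrm{Beta}(Nm\,p,\ Nm(1-p))$, and
the predicted occurrence frequency at detection limit $d$ is
$1 - I_d(Nm\,p,\ Nm(1-p))$. Choices:

* the free parameter is **Nm directly**, minimized by a 60-point
  log-grid scan over $[1, 10^8]$ followed by bounded Brent optimization in
  the bracketing interval (tolerance $10^{-10}$); $m$ is derived as
  $Nm/N$ with $N$ the common rarefaction depth — the only equal-depth
  candidate for "local community size" in a rarefied table;
* detection limit $d = 1/N$ (one read), the Sloan convention;
* goodness of fit is the non-linear $R^2$ about the mean of observed
  frequencies, which **can be negative** — the signature of no fit, e.g.
  when habitats with disjoint species pools are pooled;
* 95 % bands are **Wilson** binomial intervals of the predicted frequency
  at $n$ samples — stable near frequencies 0 and 1 at small $n$ (12
  samples), where the normal approximation collapses;
* saturated points ($f = 1$, large $p$) are retained, not trimmed;
* hitting the optimization bound is recorded in the fit metadata.

The fit is deterministic; an invariant test checks the returned SSE
against a 200-point log-grid scan.

## 8. Synthetic data: what it emulates, what it does not

The generators provide ground truth for every stage:

* `simulate_metacommunity`: lognormal (default meanlog 0, sdlog 1.5 — a
  realistic rank-abundance slope for rDNA surveys with a long rare tail)
  or log-series abundance distributions, normalized to 1.
* `simulate_neutral_communities`: site compositions drawn from
  $\mathrm{Dirichlet}(Nm\,p)$ — the exact stationary law of the fitted
  model, whose margins are the model's betas — then multinomial reads.
  This makes generative/analytic consistency *testable*: empirical
  occurrence frequencies match the exact detection probability
  $E[1-(1-x)^N]$ at nominal 3-sigma coverage. Note `ncm_predict` is
  Sloan's continuous approximation $P(x > d)$, which deviates from the
  exact detection law by up to ~0.06 for intermediate-abundance taxa; the
  acceptance test checks both, at the appropriate strictness. Explicit
  birth–death dynamics are out of scope.
* `simulate_niche_communities`: sampling weights
  $p_j \cdot \exp(-(e - o_j)^2 / 2\beta_j^2)^w$ renormalized per site;
  $w$ interpolates between mass-effects sampling of the metacommunity
  ($w=0$) and pure Gaussian niche assembly ($w=1$).
* `simulate_env_gradient`: Gaussian-kernel smoothing of site-level white
  noise against the geographic distance matrix; the `range` parameter (km)
  sets the autocorrelation scale. The exact covariance family is an
  internal detail; the contract is "near sites similar, far sites
  independent", which is what the tests check.
* `simulate_study_layout`: 24 sites on a ~10 km ring, 12 water and 12
  sediment, in 4 stations of 3 replicates per habitat; environmental
  contrasts drawn within habitat-typical ranges (temperature 28.1–30.2 vs
  31.5–33.9 °C; salinity means 26.4 vs 25.0 psu; pH 9.35 vs 7.97; TN 0.57
  vs 3.07 mg/L; TP 0.018 vs 0.112 mg/L) with ~2–8 % relative jitter, a
  magnitude chosen to mimic replicate-scale field variability where only
  habitat means/ranges are known.

What the generators do **not** emulate: sequencing error, chimeras,
clustering artifacts, taxonomy misassignment, temporal dynamics, or biotic
interactions. A green test therefore establishes that the *statistical
machinery* behaves as specified on data whose generating process is known —
not that any particular field dataset satisfies the models' assumptions.

Two stated-world choices used by the acceptance suite deserve a note:

* *Distance decay* (power/null): isolation-by-distance is emulated as
  pure niche assembly ($w=1$, 300 species, 2000 reads, 12 ring sites)
  along a spatially autocorrelated gradient (range 4 km on a 10 km ring) —
  dispersal limitation and spatially structured selection are
  observationally equivalent for a Mantel test, and the gradient route
  gives a controlled effect size. The null uses the same geometry with
  $w=0$.
* *Two-regime no-fit*: two habitats with disjoint 1000-species
  metacommunities, each strongly coupled internally ($m=0.7$, N=5000, 12
  sites). Separately each habitat fits the neutral model well; pooled, every
  taxon's occurrence saturates at 0.5 while its pooled abundance spans the
  full range, so the merged R² collapses (negative in most seeds) — the
  qualitative analogue of fitting one neutral curve across two habitats.

## 9. Numerical conventions

* All randomized operations take an explicit integer seed, run in a local
  RNG scope, and restore the caller's RNG state.
* Distance matrices are `stats::dist` objects with labels; symmetry is
  enforced at $10^{-12}$, PCNM orthogonality at $10^{-8}$, varpart
  additivity at $10^{-10}$.
* Exact permutation enumeration activates when $n! \le$ the permutation
  budget; random permutation p-values use the $(b+1)/(B+1)$ estimator.
* MultiCoLA reports exactly 1 at zero truncation by identity, avoiding
  floating-point noise in `cor` on identical inputs.
* Ties in abundance ranking are broken by OTU id, making truncation series
  reproducible across platforms.

## 10. Known limitations

* Partial Mantel uses simple (not residual) permutation; its p-values are
  known to be anticonservative under strong spatial autocorrelation.
* NMDS inherits `monoMDS`'s local-optimum behaviour; 50 restarts is a
  pragmatic default, not a guarantee.
* The niche simulator draws reads multinomially, so it cannot produce
  overdispersion beyond the metacommunity distribution at a fixed site.
* Three- and four-component variation partitioning, PERMANOVA, UniFrac and
  BIOM import are deliberate non-goals.
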