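---
title: "Ising-model methylation analysis with methylIsing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ising-model methylation analysis with methylIsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylIsing)
```

## The model

Whole-genome bisulfite sequencing (WGBS) reads report the binary
methylation state of the CpG sites they cover. Most analysis tools treat
CpG sites marginally, one at a time, discarding the correlation between
neighboring sites that is plainly visible within reads. methylIsing
instead models the joint distribution of the methylation state
$X = (X_1, \dots, X_R)$ of all CpG sites of a genomic region by an
inhomogeneous one-dimensional Ising distribution

$$P(x) = \frac{1}{Z}\exp\Big\{\sum_{n=1}^R a_n(2x_n-1)
  + \sum_{n=2}^R c_n (2x_n-1)(2x_{n-1}-1)\Big\},$$

where $a_n$ is a per-site external field (intrinsic propensity towards
methylation), $c_n$ a nearest-neighbor coupling (cooperativity of the
maintenance machinery across neighboring sites), and $Z$ the partition
function. With $c \equiv 0$ the sites are independent; with $a = 0$ and
$c > 0$ mass concentrates on the fully unmethylated and fully methylated
states — methylation bistability.

Fitting $2R-1$ free parameters per region is hopeless at WGBS coverage,
so the genome is tiled into 3-kb estimation regions within which five
parameters $\theta = (\alpha', \alpha, \alpha'', \beta, \gamma)$
generate all potentials:

$$a_n = \alpha + \beta\rho_n \quad (1 < n < R), \qquad
  a_1 = \alpha' + \beta\rho_1, \qquad
  a_R = \alpha'' + \beta\rho_R, \qquad
  c_n = \gamma / d_n,$$

with $\rho_n$ the local CpG density (CpG sites within $\pm 500$ bp of
site $n$, divided by 1000, the site itself included so that $\rho_n > 0$
always holds) and $d_n$ the bp distance to the previous CpG site
(cooperativity decays with distance). The two boundary intrinsics
$\alpha'$, $\alpha''$ replace $\alpha$ at the region's first and last
site; they absorb coupling across the region boundary so that regions
can be modeled independently. This boundary convention is one of the
genuinely open design points: we place the boundary fields on exactly
the terminal CpG of each region, which realizes a five-parameter
region-level model with independent regions and keeps the parameter
count fixed.

All chain computations — partition function, per-site marginals,
marginal likelihoods of partially observed reads, level PMFs, exact
sampling — use transfer-matrix (forward–backward) recursions with
per-step rescaling, implemented in C++. Rescaling replaces the
arbitrary-precision arithmetic that a naive implementation of the
partition function requires; the numerical contract, enforced by the
test suite, is agreement with brute-force enumeration over all $2^R$
states to a relative $10^{-10}$ for $R \le 12$.

## Estimation from incomplete reads

A read observes only the CpG sites it covers. The five parameters are
fitted by maximizing the average marginalized log-likelihood

$$\mathcal{L}(\theta) = \frac{1}{M}\sum_{m=1}^M
  \ln P\big(\{x^{(m)}_r,\ r \in \mathcal{R}(m)\}\mid\theta\big),$$

where each term marginalizes the joint Ising distribution over all
unobserved sites. For a contiguous set of observed sites the marginal is
exact (flanks are summed out by message passing); a read with internal
gaps is split into maximal contiguous runs whose exact marginals are
multiplied — an approximation that is exact under independence and close
to exact otherwise, since the gaps that occur in practice are large.

Regions are only modeled when they have at least 10 CpG sites, at least
2/3 of the sites are observed by some read, and mean depth is at least
2.5 observations per site; everything else lands in a skip log.

The likelihood surface is non-convex, so the optimizer is a bounded,
derivative-free, multi-start search: Nelder–Mead runs from a fixed
center start plus seeded random starts on a logistic reparameterization
of the box (iterates therefore always satisfy the bounds), with a
function-evaluation budget (default 5000) split between starts. Default
bounds are $|\alpha^{(\cdot)}| \le 10$, $|\beta| \le 100$,
$|\gamma| \le 20$: fields of magnitude 10 already saturate the site
marginals, and $\gamma/d$ with $d \ge 2$ keeps couplings moderate.
The original methodology names multilevel coordinate search here; any
global bounded derivative-free method fulfils the same contract, and the
multi-start scheme keeps the fit deterministic under a seed.

Model adequacy can be checked per region by fitting the unconstrained
Ising model (all $a_n$, $c_n$ free, $2R-1$ parameters, initialized at
the constrained optimum so the likelihoods nest) and comparing by AIC:
$\mathrm{AIC}_i = -2 M \mathcal{L}_i + 2 p_i$, converted to the
probability $\pi = e^{-\Delta_1/2} / (e^{-\Delta_1/2} + e^{-\Delta_2/2})$
that the five-parameter model is the better of the pair.

## Genomic units and single-sample statistics

Statistics are reported at a resolution of 150-bp genomic units (GUs),
the approximate DNA content of one nucleosome; each 3-kb region holds
20 GUs. For a GU with $K$ CpG sites the methylation level is
$L = K^{-1}\sum_k X_k$; its full PMF over $\{0, 1/K, \dots, 1\}$ is
computed exactly by a dynamic program over (site, methylated count),
marginalizing the flanking sites of the region. GUs outside fitted
regions, or without CpG sites, emit nothing (track gaps).

* **MML** — mean methylation level $\mathrm{E}[L]$, equal to the average
  of the per-site marginals; the package computes it both ways and the
  tests pin their agreement.
* **NME** — normalized methylation entropy
  $h = -\log_2(N+1)^{-1} \sum_\ell P_L(\ell)\log_2 P_L(\ell) \in [0,1]$.
  Normalization makes GUs with different CpG counts comparable: a
  uniform level PMF has $h = 1$ for every $N$, a degenerate one $h = 0$.

Each GU is also classified by the *shape* of its level PMF into seven
classes (highly/partially unmethylated or methylated, mixed, highly
mixed, bistable) and by NME into five ordered classes (highly ordered …
highly disordered). The authoritative cut points of the original
software's classification live in supplementary material that is not
reproduced here; the rule set used — tail masses at levels 0.25/0.75
with cuts 0.9/0.75/0.4, and NME bins (0.28, 0.44, 0.56, 0.72] symmetric
about 0.5 — is exposed in `levelThresholds()`, `entropyThresholds()`
and friends, and every cut point is configurable.

## Differential analysis

For a test/reference pair the package computes, per GU: the PMF of
$D_L = L_t - L_r$ by cross-convolution (independence of the two samples
is assumed; supports are handled as exact rationals so equal differences
merge exactly), dMML $= \mathrm{E}[L_t] - \mathrm{E}[L_r]$, dNME
$= h_t - h_r$, and the Jensen–Shannon distance

$$d = \sqrt{\tfrac12\big(D(P^{(1)}, \bar P) + D(P^{(2)}, \bar P)\big)},
 \qquad \bar P = \tfrac12 (P^{(1)} + P^{(2)}),$$

with $D$ the Kullback–Leibler divergence in bits. The JSD is a
normalized metric on $[0,1]$: zero iff the PMFs coincide, one iff their
supports are disjoint. When the two GUs have different CpG counts the
PMFs are embedded on the union of their exact rational level grids,
which preserves the disjoint-support $\Rightarrow d = 1$ property. The
JSD captures distributional differences invisible to means: two PMFs
with equal means and equal entropies can still have $d = 1$.

Differential classifications mirror the single-sample ones: seven
level classes driven by the tail masses of $D_L$ (strong at $|D_L| \ge
0.5$ with mass 0.9, moderate at $0.25$ with mass 0.75, weak with mass
0.5) and seven entropy classes with bins at $\pm 0.05, \pm 0.25,
\pm 0.55$; again stand-ins for unavailable supplementary thresholds,
and configurable.

## DMR detection

Per-GU JSD is noisy, so it is smoothed along each chromosome by
Nadaraya–Watson kernel regression with a Gaussian kernel, evaluated at
the GU centers (`stats::ksmooth`; the kernel's quartiles sit at
$\pm 0.25\,\mathrm{bandwidth}$, so the genome-scale default bandwidth of
50 kb corresponds to $\sigma \approx 18.5$ kb). Smoothing never crosses
chromosome boundaries. The bandwidth is the scale knob of the DMR
finder: it should match the expected feature size (the synthetic study
below uses 1 kb for 3-kb features).

The null distribution of the smoothed statistic comes from one of two
sources:

* **Replicates available** — the empirical distribution of sJSD values
  over all pairs of replicate reference samples, pooled genome-wide.
  P-values are one-sided plus-one exceedance ranks,
  $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + \#\text{null})$,
  which guarantees $p > 0$. The granularity of these p-values is set by
  the size of the pooled null, which is why *all* replicate pairs are
  pooled rather than a single pair.
* **No replicates** — the sJSD values are logit-transformed (clipped to
  $[10^{-6}, 1-10^{-6}]$ first) and a two-component Gaussian mixture
  with unequal variances is fitted by EM (via mclust). The component
  with the smaller mean models ordinary biological/statistical/technical
  variability and its logit-normal back-transform is the null; the other
  component captures distinct epigenetic behavior.

The genome-wide family of per-GU p-values is adjusted by
Benjamini–Yekutieli (valid under dependence, which smoothed statistics
certainly exhibit) at FDR 0.01. Each significant GU gets a statistical
quality score $\mathrm{SQS} = -10\log_{10} q$ (capped at 300 when $q$
underflows). Significant GUs are merged into DMRs by a binary
morphological closing that fills gaps smaller than the smoothing
bandwidth, and each DMR is scored by the sum of its GUs' SQS values and
ranked by that score.

## Gene ranking

Promoters are 4-kb windows centered on each transcript's TSS
(strand-agnostic; windows running off the chromosome start are
truncated), carrying every modeled GU that intersects them by at least
one bp. Without replicates a promoter's score is the mean raw JSD of its
GUs (higher = more discordant). With replicates, per-GU plus-one
empirical p-values against the pooled replicate-pair *raw* JSD
distribution (unsmoothed — unlike the DMR path) are combined per
promoter by Fisher's method, $-2\sum\ln p_i \sim \chi^2_{2m}$; the
combination is exact only under independence and is used strictly as a
ranking score. Per gene only the best-ranked promoter is kept. Rankings
from several comparisons merge by rank products
$\mathrm{RP}(g) = (\prod_i r_i(g))^{1/k}$ (missing genes rank one past
the list end; ties break by mean rank, then gene id). Permutation
significance of rank products is out of scope — the ranking is the
deliverable.

## The synthetic study

The simulator reproduces the design used to validate the original
methodology: isolated 3-kb CpG islands of 200 uniformly spaced CpG
sites (spacing 15 bp) separated by 100-kb CpG-free gaps; 300-bp reads
placed uniformly at random at 15× mean coverage; no bisulfite-conversion
or sequencing errors, and no biological variability. Each read draws its
*own* latent full-island state from the island's Ising model — a read is
one cell's molecule — and reports the states of the sites it covers.
This is what makes within-read correlation carry signal. Both samples
use $a = 0$; the test sample has $c = 0$ and the reference $c = \delta$,
so every CpG site has marginal methylation probability exactly 0.5 in
*both* samples and all differences are invisible to marginal methods.

The full-scale design uses 5000 islands; the package default is a
desk-scale 50 islands (a ~5-Mb genome, a thousand modeled GUs), which
keeps a complete study at one $\delta$ around three minutes on one CPU
while preserving every qualitative feature of the design. The study
follows the matched structure of the original data: three test samples
and three matched references plus one held-out reference. The empirical
sJSD null pools the three pairwise comparisons among the matched
references; sensitivity is averaged over the three matched
test/reference comparisons and specificity over the three held-out
reference/reference comparisons. Pooling all replicate pairs matters
quantitatively: plus-one empirical p-values are bounded below by
$1/(1+\#\text{null})$, and the BY step-up at FDR 0.01 over ~1000 GUs
needs p-values well below $10^{-3}$, so a single replicate pair sits at
the edge of what the procedure can call at this scale.

```{r, eval = FALSE}
res <- runSimulationStudy(delta = 0.4, simulationConfig(nIslands = 50),
                          seed = 1, bandwidth = 1000)
res$sensitivity; res$specificity
```

What passing this study shows — and what it does not: the simulation has
no biological replicate variability, no conversion errors, uniform CpG
spacing and isolated islands, so it validates the statistical machinery
(estimation from partial reads, JSD separation of joint distributions
with identical marginals, FDR control), not robustness to the messiness
of real WGBS data.

## Numerical choices and degenerate inputs

* Chain recursions rescale per step and return log-domain quantities;
  enumeration agreement to $10^{-10}$ for $R \le 12$ is the contract.
* Empty observations have marginal likelihood 1; reads spanning a region
  boundary are split at it, consistent with region independence.
* An $R = 1$ region is a single Bernoulli with field
  $a_1 = \alpha' + \beta\rho_1$; such regions are filtered out anyway
  (fewer than 10 CpG sites).
* Level classification ties break in the documented rule order;
  `0 log 0 = 0` throughout; `LevelPMF` keeps the exact rational support
  with no binning.
* sJSD values of exactly 0 or 1 are clipped at $10^{-6}$ before the
  logit; a degenerate mixture fit (vanishing variance) fails loudly
  rather than silently producing a null.
* Smoothed values where no observation lies within kernel reach fall
  back to the raw value; in practice modeled GUs always have in-reach
  neighbors.
* BY q-values of 0 map to the SQS cap (default 300).

## Known limitations

* The boundary intrinsics $\alpha'$, $\alpha''$ are estimated from a
  single site each and are the noisiest part of the fit; GUs at region
  boundaries inherit that variance. Region tiling anchored at
  coordinate 1 can cut a CpG island into two regions, creating such
  boundaries mid-feature.
* The run-product approximation for gapped reads ignores correlation
  across the gap (exact only under independence).
* Classification cut points are package defaults, not the original
  software's (unavailable) supplementary values; treat class labels as
  configurable summaries rather than canonical annotations.
* One comparison at a time: no shared-subject modeling, no multi-sample
  designs beyond pooling and rank products.
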