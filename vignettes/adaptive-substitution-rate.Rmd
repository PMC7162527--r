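---
title: "Estimating the adaptive amino-acid substitution rate from polymorphism and divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the adaptive amino-acid substitution rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkadapt)
```

## The model

`mkadapt` estimates the per-mutation rate of adaptive amino-acid
substitution, $\omega_a$, by contrasting coding-sequence polymorphism with
divergence in the McDonald–Kreitman tradition, with an explicit model of the
distribution of fitness effects (DFE) of new non-synonymous mutations.

The quantities involved are:

* $\omega = dN/dS$, the observed ratio of non-synonymous to synonymous
  substitution rates (each normalized by its mutational-opportunity site
  count);
* $\omega_{na}$, the dN/dS expected under near-neutrality, i.e. produced by
  the fixation of neutral and (slightly) deleterious alleles alone;
* $\alpha = 1 - \omega_{na}/\omega$, the proportion of amino-acid
  substitutions attributable to positive selection;
* $\omega_a = \alpha\,\omega = \omega - \omega_{na}$.

$\omega_{na}$ is predicted from a DFE fitted to the folded synonymous and
non-synonymous site frequency spectra (SFS). Under the Wright–Fisher
diffusion, a semidominant mutation of scaled effect $S = 4N_e s$ contributes
to the SFS in proportion to its sojourn density

$$H(x; S) = \frac{1 - e^{-S(1-x)}}{x(1-x)\,(1 - e^{-S})},$$

with the neutral limit $1/x$, and fixes at rate $S/(1 - e^{-S})$ relative to
a neutral allele. The expected unfolded class count at frequency $j/n$ in a
sample of $n$ chromosomes is the binomial-sampled sojourn integral
$B(j; n, S) = \int_0^1 H(x;S)\binom{n}{j}x^j(1-x)^{n-j}\,dx$, averaged over
the DFE and folded by minor-allele count.

### DFE families

Three families are fitted and compared, following the established
model-averaging practice for this estimator:

* **GammaZero** — a reflected gamma on $S<0$ (mean $\bar S_d$, shape $b$);
  no beneficial mutations (2 free DFE parameters).
* **GammaExpo** — GammaZero plus, with probability $p_{pos}$, an
  exponential distribution of beneficial effects with mean $\bar S_b$
  (4 parameters).
* **ScaledBeta** — a Beta distribution rescaled to $S \in [-25, 25]$,
  covering weakly selected mutations of both signs (2 parameters). No
  additional strongly-deleterious mass is added; the family is deliberately
  restricted to the weak-selection window its support describes.

### Likelihood and nuisance parameters

Observed folded class counts are modelled as independent Poisson variables
(Poisson random field style): synonymous classes have mean
$L_s\,\theta\,r_i\,a_i$ with $a_i$ the neutral folded shape, non-synonymous
classes $L_n\,\theta\,r_i\,b_i$ with $b_i$ the DFE-weighted shape. The
$r_i$ ($r_1 \equiv 1$) are per-frequency-class nuisance multipliers shared
between the two spectra; they absorb recent demography, population
structure and orientation distortions without biasing the syn/non-synonymous
contrast. $\theta$ is a single per-site population mutation rate shared by
both spectra (site counts enter through $L_s$, $L_n$).

Because every class has its own multiplier, the products $\theta r_i$ have
closed-form Poisson maximum-likelihood solutions given the DFE parameters.
The numerical optimization therefore runs only over the 2–4 DFE parameters
(Nelder–Mead on log/logit scales, box-clamped, 10 seeded multistarts by
default, fully deterministic given the seed). Fractional observed counts —
which arise from hypergeometric projection and from pooling — enter the
Poisson kernel as $c\log\lambda - \lambda$.

AIC is $2k - 2\log L$ with $k$ counting DFE parameters, $\theta$, and the
free $r_i$. Estimates are averaged across families with Akaike weights
$w_m = e^{-\Delta AIC_m/2}/\sum_k e^{-\Delta AIC_k/2}$.

### Accounting for weakly beneficial fixations

$\omega_{na}$ integrates the fixation rate over the $S \le 0$ component of
the fitted DFE only; fixations driven by a fitted positive component
(GammaExpo, ScaledBeta) are counted as adaptive. The alternative
accounting — counting weak-positive fixations as non-adaptive — is exposed
as `include_weak_positive = TRUE` throughout, since the literature is not
unanimous on this point.

A practical caveat worth knowing: on folded spectra the positive DFE
component is weakly identified. GammaExpo occasionally finds a ridge
solution in which abundant weak beneficials mimic relaxed purifying
selection, collapsing $\omega_{na}$ and inflating $\alpha$; with AIC
weighting such solutions occasionally dominate a dataset. The median across
datasets (or the bootstrap) is robust to these excursions, and they are a
property of the estimator itself, not of this implementation.

### Group-level estimators

Two estimators combine species within a taxonomic group against the
group-tree divergence:

* $\omega_a[P]$ **(pooled)** — species SFS are pooled with equal weights:
  each species' spectrum is normalized by its total SNP count, normalized
  spectra are summed, and the sum rescaled so the pooled SNP total equals
  the across-species total. The DFE is fitted to the pooled spectrum.
* $\omega_a[A]$ **(averaged)** — the arithmetic mean of species-level
  $\omega_{na}$ is subtracted from the group $\omega$. This estimator is
  appropriate when population-size fluctuations are slow enough that each
  sampled species is near its own selection/drift equilibrium.

Spectra of unequal sample size are first projected to the smallest shared
even $n$ (the projection choice is a package decision; nothing in the
pooling recipe itself constrains it).

### Bootstrap

Confidence intervals resample SNPs: multinomial resampling of the folded
class counts with the SNP totals fixed, plus Poisson resampling of dN and
dS. The full fit-and-average pipeline is rerun per replicate, warm-started
at the point-estimate models with 2 optimizer starts (a deliberate
cost/robustness trade-off; the warm start removes almost all multistart
variability). Percentile 2.5/97.5% bounds are reported, deterministic given
the seed.

## Spectrum construction

`count_sites()` counts mutational opportunities per codon: each of the
three single-base changes at a position contributes 1/3 site to its class;
stop-involving changes are excluded from numerators and denominators alike
(including at the SNP level). GC-conservative spectra and site counts keep
only A↔T and C↔G changes; since exactly one GC-conservative change exists
per position, each position contributes one full GC-conservative site to
the class of that change. This per-site convention is one defensible
reading of GC-conservative opportunity counting; it is applied consistently
to SNPs, sites and divergence inputs, which is what the $\omega$ ratios
require.

Projection to a common sample size uses hypergeometric expectations
(fractional counts, deterministic) rather than random subsampling. Mass
landing in the monomorphic classes (0 or $m$ copies) is dropped — those
SNPs would be unobservable at sample size $m$ — and the remainder is folded
by minor-allele count, the symmetric class counted once. The default target
$m$ maximizes the fractional SNP mass surviving projection over even
$m \le 2\times$ individuals; SNPs called in fewer than $m$ chromosomes are
dropped with a warning rather than rescaled (the simplest defensible
missing-data policy; the alternative of rescaling is not implemented).

$\pi$ uses the $n/(n-1)$ unbiased correction; Tajima's D uses the standard
1989 constants; $F_{is} = 1 - \bar H_{obs}/\bar H_{exp}$ over polymorphic
sites with the $2n_c/(2n_c-1)$ small-sample correction on expected
heterozygosity.

## Numerical choices

* Frequency integrals $B(j;n,S)$: 64-point Gauss–Legendre on each side of a
  split point; for strongly deleterious $S$ the split adapts to the
  boundary layer at $x \approx 40/|S|$ where the sojourn density
  concentrates. Verified against dense-trapezoid quadrature to $10^{-6}$
  relative error (the test suite enforces this at $n = 4, 6$).
* DFE integrals over $S$: fixed log-spaced grids (256 bins over
  $|S| \in [10^{-7}, 3\times10^5]$ for the gamma component, 128 bins for
  the exponential positive part, 250 uniform bins for ScaledBeta), with
  exact bin masses from the parametric CDF and geometric-midpoint nodes.
  Fixed grids allow the sojourn kernel to be cached per sample size, which
  is what makes the fit fast enough for bootstrap and simulation use.
* $\omega_{na}$ integrals use adaptive quadrature (`stats::integrate`) with
  the upper bound tied to the gamma quantile function so that near-neutral
  spikes (gamma collapsing toward $S = 0$) are not missed.
* Degenerate inputs: classes with zero observed SNPs get a zero profiled
  multiplier (their Poisson term vanishes); zero expected count against
  positive observed count yields $-\infty$ log-likelihood (guarded);
  `dS = 0` is an error for $\omega$.

## Synthetic data: what it emulates and what it does not

`generate_sfs_dataset()` inverts the estimation model exactly: Poisson
class counts around the DFE-expected spectra, with a monotone ±20% nuisance
distortion by default (exercising the $r_i$ correction), and Poisson
divergence with the true $\omega_a$ injected on top of the model's own
$\omega_{na}$. Recovery tests on such data validate the estimation
machinery, not the model's adequacy for real genomes: linkage,
gene-to-gene rate variation, GC-biased gene conversion and misorientation
are absent by construction (linked-selection realism lives in the forward
simulator instead).

The default recovery conditions are chosen once as a realistic mid-size
study: the deleterious DFE is the primate-like gamma (mean $S = -740$,
shape 0.14) that also drives the simulation control; the beneficial
component is rare and weak ($p_{pos} = 0.005$, $\bar S_b = 4$, i.e. a mean
selective advantage of $10^{-4}$ at $N_e = 10^4$); $\theta = 0.005$ per
site; $10^6$ sites per class; $n = 20$ chromosomes; synonymous divergence
0.1 per site (within the divergence range over which time-constancy of the
drift/selection regime is a tenable assumption); true $\omega_a = 0.05$.

`generate_species_table()` builds multi-group species tables with
prescribed within-group slopes of $\omega_a$ on $\pi_s$ and log-linear
trait–diversity relationships, for exercising the comparative layer at the
published design shape (ten groups of 4–6 species).

## The forward-simulation control

A fluctuating population size violates the MK assumption of a constant
drift/selection regime and can manufacture spurious $\omega_a$ signal. The
package ships a forward Wright–Fisher simulator of coding sequences to test
whether the full estimation pipeline produces an artifactual
$\omega_a$–$\pi_s$ correlation under such demographies:

* codon-level sequences (default 999 bp genes), explicit standard genetic
  code, so synonymous/non-synonymous classification matches the SFS
  toolkit exactly; synonymous changes neutral, non-synonymous effects drawn
  from gamma (negative, in $S$ units) + exponential (positive, in $s$
  units) components, stop-gaining changes effectively lethal;
* diploid panmixia, discrete generations, fitness multiplicative per allele
  copy ($1 + s/2$ per copy — exact semidominance in the multiplicative
  sense), per-bp crossover recombination;
* stepwise cyclic demography schedules (e.g. 3- or 30-fold size ratios with
  high or low long-term size);
* burn-in of $10\,N_{max}$ generations; divergence counted from the
  end-of-burn-in reference; polymorphism and divergence sampled for 20
  individuals at requested time points.

Populations are run at reduced size with diffusion-invariant rescaling
(`rescale_parameters()` holds $4N\mu$, $4Nr$, $4Ns$ and durations in units
of $N$ fixed). Two desk-scale caveats are documented rather than hidden:
(1) strongly deleterious effects rescale past $s = -1$ and are truncated
there (an effectively-lethal class — the substitution process is
indistinguishable, but segregating load is compressed); (2) the per-genome
deleterious mutation input scales up as $N$ scales down, so background
selection and interference are exaggerated relative to the full-scale
experiment — realized $\pi_s$ falls well below $4N\mu$ and the realized
non-adaptive $\omega$ sits above its equilibrium prediction under the
default strongly deleterious DFE. Keeping the experiment's stated
recombination-to-mutation ratio ($r/\mu \approx 4.5$) matters here: with
heavily reduced recombination the interference-distorted spectra cause the
fitted $\omega_{na}$ to lag the realized non-adaptive rate and a small
spurious positive $\hat\omega_a$ appears even at constant size, whereas at
the stated ratio the estimator tracks the realized rate and the null
control is clean. The null-control configuration used by the test suite and
the acceptance script — 200 genes, $N = 100$, $4N\mu = 0.005$ per bp,
$r/\mu = 4.5$, five time points per replicate, ten replicates — was sized
so the whole control runs in minutes on one core; those sizes are package
choices, and larger runs only sharpen the same comparison.

## Comparative layer

The statistical layer mirrors standard comparative reporting: simple OLS
on (log10-transformed) traits with two-sided slope t-tests and unadjusted
$r^2$; Spearman rank correlations (exact permutation null for $n \le 9$
without ties, t-approximation otherwise); common-slope ANCOVA
(`response ~ covariate + group`) with F-tests for intercept differences
and for the slope-by-group interaction; and the within-group-slope versus
group-mean-$\pi_s$ Spearman meta-analysis, with groups of fewer than three
species flagged and excluded. Missing trait values are deleted listwise per
test, and no multiple-testing correction is applied — matching how such
comparative scans are conventionally reported; treat individual p-values
accordingly.

## Known limitations

* The positive-DFE component is weakly identified from folded spectra (see
  above); per-dataset GammaExpo estimates of $p_{pos}$, $\bar S_b$ should
  not be over-interpreted.
* The ScaledBeta parameterization covers only $|S| \le 25$; strongly
  deleterious mass outside that window is absorbed by the nuisance and
  $\theta$ parameters rather than modelled.
* Folded spectra only; no ancestral-state reconstruction or
  polarization-error model.
* The simulator does not aim at bit-compatibility with any external
  forward simulator, and records no tree sequences; selfing and structure
  are out of scope.
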