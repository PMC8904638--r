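---
title: "Models and methods behind mosaicpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mosaicpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mosaicpop` analyses fine-scale population structure and admixture history
from diploid SNP genotypes. This vignette documents the models it fits, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated against
known truth. It is first-class, tested code, not a fixture.

**Source populations.** Allele frequencies for each source population are
drawn under the Balding–Nichols model: at a SNP with ancestral frequency
$p$, a source at drift parameter $F \in [0, 1)$ has frequency
$\mathrm{Beta}\!\left(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$, with
mean $p$ and variance $F\,p(1-p)$. $F = 0$ returns $p$ unchanged. For two
sources simulated at the same $F$ the expected Weir–Cockerham FST between
them is close to $F$ (each source contributes $F\,p(1-p)$ of between-source
variance on a total of roughly $p(1-p)$); the exact expectation used in the
tests is computed by a Monte-Carlo oracle on the frequency model itself.
The model was chosen because it is the standard single-parameter drift
model; it makes no claim about the demographic history that produced the
divergence.

**Haplotype panels.** Haplotype alleles are independent Bernoulli draws at
the source frequency — sites are in linkage equilibrium *within* sources.
This is deliberate: it means any LD in an admixed genome is admixture LD,
which is exactly what the dating stage consumes. It also means the
generator does **not** emulate background LD, recombination hotspots,
genotyping error, allele-frequency ascertainment, or coalescent noise
shared between sources. Passing tests therefore demonstrate correctness of
the estimators under their own model assumptions, not robustness to those
real-data complications (background LD in particular is why the weighted-LD
fit starts at `d_min_cm = 0.5` on real data).

**Admixed genomes.** A single admixture pulse $g$ generations ago is
simulated by making each haplotype a mosaic of the source panels: ancestry
breakpoints form a Poisson process of rate $g$ per Morgan along each
chromosome, each segment's source is drawn independently from the mixing
proportions $\alpha$, and segment alleles are copied from a random
haplotype of that source's panel. Mean segment length is $1/g$ Morgans, and
the ancestry covariance between loci at distance $d$ Morgans is
$\alpha(1-\alpha)e^{-gd}$ — the decay that admixture dating fits.
Continuous migration and multiple pulses are out of scope; the single-pulse
assumption matches the single-date fits the dating module produces.

**Copying vectors.** Dirichlet draws around a known mixture of source
profiles (`concentration` controls tightness; `Inf` gives the exact
mixture), for testing the clustering, TVD and NNLS stages in isolation.

One master seed governs a simulation; stage-local seeds are derived by
fixed offsets (`derive_seed()`), and `with_seed()` restores the caller's
RNG state, so package randomness never perturbs a user's session.

**Genetic maps.** `uniform_map()` uses the conventional 1 cM/Mb scaling
(`bp = cm * 1e6`). Positions are stored internally in cM; the EIGENSTRAT
reader/writer converts from/to Morgans.

## Quality control and data handling

Filters run in a fixed order — SNP missingness, individual missingness,
minor-allele frequency, optional HWE (1-df chi-square) — with defaults
0.05 / 0.05 / 0.01 / disabled. These defaults are common practice for array
data; they are configurable and no claim is made that they reproduce any
particular study's counts, whose exact thresholds are typically in
supplementary protocols.

Relatedness removal estimates PI_HAT $= P(\mathrm{IBD}=2) +
\tfrac12 P(\mathrm{IBD}=1)$ by the method of moments from IBS counts,
conditioning the expected IBS-state probabilities on sample allele
frequencies (treated as known — the finite-sample correction factors are
omitted, which matters little beyond a few dozen individuals). The default
cutoff 0.25 removes second-degree and closer pairs; of each flagged pair
the member with more missing data is dropped, ties broken by id order.

LD pruning uses genotype (dosage) correlation, not haplotype $r^2$ — the
usual choice on unphased data — with the window/step/threshold convention
(200 SNPs, step 25, $r^2 > 0.4$) exposed as arguments. Within a window,
offending pairs are visited in position order and the later SNP is removed;
removal is permanent across windows, which makes the procedure idempotent.

Merging harmonises allele pairs by direct match, swap, strand complement,
or both; A/T and C/G SNPs are ambiguous under strand flips and are dropped
rather than guessed from frequency.

## Allele-frequency statistics

**FST.** Weir–Cockerham (1984) variance components $a$ (among populations),
$b$ (among individuals within), $c$ (within individuals) with $r = 2$,
combined as a ratio of sums $\sum a / \sum(a+b+c)$ — the lower-bias
convention — excluding monomorphic sites and sites with a zero denominator.
Negative estimates are reported as computed; clipping is a display option.

**RoH.** The PLINK-style scan: a window of 100 SNPs is a hit if it has at
most 1 heterozygous and 5 missing calls; a SNP is in the homozygous state
if at least 5% of the windows covering it are hits; maximal runs of at
least 100 SNPs spanning at least 1000 kb are emitted. The window, length,
het and missing parameters are the commonly used ones; the per-SNP hit
fraction (0.05) and minimum segment SNP count (100) are the scanning tool's
defaults, exposed as arguments because studies rarely state them.

**PCA.** Genotype PCA centres each SNP by mean dosage, scales by
$\sqrt{p(1-p)}$, zeroes missing values after centring, and
eigendecomposes the individual covariance matrix. Coancestry PCA is a
plain centred, unscaled principal-components call on the raw matrix (rows
as observations), matching how painted chunk-count matrices are usually
ordinated. Component signs are fixed by a largest-score-positive
convention purely so results (and tests) are deterministic.

**f-statistics.** $f_3(A,B;C) = \mathrm{E}[(c-a)(c-b)]$ with the unbiased
correction $-\hat c(1-\hat c)/(n_C-1)$ subtracted per SNP; the correction
is switched off automatically in population-frequency mode
(`freq_table(..., n_chrom = Inf)`). Normalisation by target
heterozygosity is available as a flag but off by default: whether published
tables are normalised is often unstated, so both modes are provided and
neither claims numeric parity with any real-data table. $f_4$ needs no
correction. The f4-ratio $\alpha = f_4(A,O;X,C)/f_4(A,O;B,C)$ jackknifes
the ratio per block and *flags* (rather than silently divides by) a
denominator whose |Z| < 3. Standard errors come from the weighted
block-jackknife (Busing et al. 1999) over contiguous blocks, 5 cM by
default (the ADMIXTOOLS convention), with SNP-count blocks available for
maps without genetic positions; listwise SNP exclusion per statistic.

## Haplotype painting

The painter is a simplified Li–Stephens copying model run all-vs-all: for
each recipient haplotype the hidden state is the donor haplotype (among all
haplotypes of *other* individuals) being copied; between adjacent SNPs at
distance $\Delta$ Morgans the chain switches with probability
$1-e^{-\rho\Delta}$ to a uniformly drawn donor, and emissions are
$1-\mu$ on allele match, $\mu$ on mismatch.

Two deliberate simplifications relative to the full painting methodology:

* **Viterbi decoding instead of expected chunk counts.** The established
  tool accumulates expected counts under the forward–backward recursion;
  the single best path is used here because it is deterministic and exactly
  checkable — the test suite verifies the Viterbi path probability against
  exhaustive enumeration over all $D^L$ donor paths on small instances.
  Chunk counts are therefore slightly "harder" than posterior expectations.
* **No EM re-estimation of $\rho$ and $\mu$.** Defaults $\rho = 50$ per
  Morgan and $\mu = 0.001$ are fixed, exposed as arguments. They are not
  claimed to match any particular study's fitted values (usually in
  supplements).

Ties in the Viterbi recursion are broken toward the lowest donor index
(stated and tested). Chunk lengths are measured in cM between midpoints of
the inter-SNP intervals at chunk boundaries, with terminal chunks extended
to the map ends — this makes each recipient's chunk lengths sum exactly to
twice the map span, a conservation law the tests assert.

## Clustering, refinement, and TVD

MCMC-based coancestry clustering is out of scope; `build_tree()` is a
deterministic stand-in (average-linkage agglomeration on pairwise TVD of
copying vectors), and externally produced assignments can be supplied as a
two-column TSV instead (`read_assignment()`), so a full MCMC clustering can
be plugged in.

**Size refinement** collapses every *maximal* dendrogram node whose
descendant leaves number fewer than 5 clusters with at least one cluster of
fewer than 5 individuals, then rebuilds the cluster tree and repeats to a
fixpoint. Two open points were resolved as follows: (1) the rule is
applied literally at every node including the root — on trees with fewer
than five clusters total this collapses everything, which is the rule's
honest reading and only matters far below the scale the rule was designed
for; (2) the refinement takes the assignment plus vectors and rebuilds the
cluster dendrogram internally on cluster mean vectors each pass, because
after a collapse the original tree no longer describes the clusters, and
rebuilding is what makes the fixpoint (and idempotence) well defined.

**TVD pooling** merges clusters whose mean copying vectors (chunk-count
basis by default; median available) are within a TVD threshold
(default 0.035), greedily from the most extreme eligible pair with
re-evaluation after each merge, pools capped at 3 original clusters
("pairs or triplets"). The published description of this step reads as
pooling clusters *above* the threshold, which is the opposite of standard
merge-similar practice; the direction is therefore a mandatory explicit
flag (`direction = "below"`/`"above"`, default `"below"`) and the ambiguity
is documented rather than silently resolved. Pool sizes ride along as an
attribute of the returned assignment so that re-applying the refinement is
the identity.

**TVD levels.** Heterogeneity is reported at three levels per cluster: all
member pairs; pairs involving at least one focal-group member; pairs of
focal members only — on either chunk-count or chunk-length copying vectors.
Clusters with no eligible pair at a level are reported with zero pairs, not
dropped. Self-cluster donation is removed from copying vectors by default
before TVD (a flag retains it).

## NNLS ancestry profiles

`nnls_profile()` minimises $\lVert y - S^{\mathsf T}\beta\rVert^2$ subject
to $\beta \ge 0$ with the sum-to-one constraint imposed by appending a
penalty row of weight $\lambda$ (so the solver sees
$\lambda\sum\beta \approx \lambda$) followed by exact renormalisation — the
classic "slight modification" of a plain NNLS solver. The default
$\lambda$ is 100× the largest design entry; if the pre-renormalisation sum
leaves $[0.99, 1.01]$ a warning says the penalty is too weak. The
Lawson–Hanson active-set solver is `pracma::lsqnonneg`; the wrapper
(penalty, renormalisation, self-cluster removal) is package code.

Donor-cluster columns belonging to the recipient's own cluster are removed
from $y$ and from every source profile, both renormalised, before solving —
otherwise the trivial self-copy solution dominates. A flag disables this
for vectors already externalised. Per-cluster profiles default to the
profile of the cluster's mean vector; the mean of per-individual profiles
is available via a flag, since either reading of "a cluster's profile" is
defensible.

## Weighted-LD admixture dating

For SNP pairs $(i,j)$ on one chromosome at genetic distance $d$, the
statistic is the target-population dosage covariance weighted by the
reference allele-frequency contrast, $\hat z_{ij} w_i w_j$ with
$w = p^{\mathrm{ref1}} - p^{\mathrm{ref2}}$, averaged in distance bins
(default 0.5 cM). In a single-pulse admixed population the curve follows
$a(d) = A e^{-gd} + c_0$ with $d$ in Morgans, and $g$ is the admixture time
in generations. Bins below `d_min_cm = 0.5` are excluded from fitting to
dodge background LD (on the synthetic data there is none; the default is
kept because it is the convention for real data and costs little power).

Numerically, the fit profiles out $A$ and $c_0$ (linear given $g$), scans
$g$ on a multiplicative grid 1–200 (factor 1.5), and refines continuously
(`optimize`, tolerance 1e-10) in the bracketing interval; the noiseless
recovery test demands agreement to 1e-6. Convergence is honest: if the
exponential term fails an F-test against a flat curve at $\alpha = 0.05$,
`converged = FALSE` and $g$ is `NA`. The pair accumulation is exact — a
banded block cross-product (BLAS) identical to the $O(n^2)$ double loop,
verified to 1e-12 in tests — so no FFT approximation or jackknife machinery
is carried; SNP counts beyond ~20k per chromosome should be thinned first.

Group-level date distributions are compared by two-sided Wilcoxon rank-sum
tests with Bonferroni adjustment (multiplier = number of pairs, capped at
1); ties fall back on the normal approximation with continuity correction.
Year conversions use 29 years/generation, configurable, since published
year figures rarely state the constant.

## Problem sizes and what the tests show

Module tests run at deliberately small scales (hundreds to a few thousand
SNPs, tens of individuals) with brute-force oracles: exhaustive Viterbi
enumeration at ≤6 SNPs, $O(n^2)$ weighted-LD loops at ≤8 SNPs, direct
transcriptions of the FST component formulas, window-by-window RoH
re-scans, and hand-enumerated refinement fixtures. The end-to-end
acceptance checks run the dating pipeline at 20,000 SNPs / 3 Morgans / 200
diploids with 10 replicates per scenario and the calibration checks at 500
small replicates; the broader date-recovery sweep (truths of 5 and 19
generations, 15% tolerance on the median) runs at 6,000 SNPs / 120
diploids. These sizes were chosen as the smallest at which the statistical
claims are comfortably testable; all scale parameters are plain arguments.

Because the generator omits background LD, ascertainment and genotyping
error, green tests certify the estimators under the stated models — they do
not certify robustness on real array data, where reference-panel choice,
phasing quality and background LD all matter.

## Known limitations

* Painting is Viterbi-based with fixed $\rho, \mu$; no per-chunk
  posteriors, no donor-panel (non-all-vs-all) mode.
* Dating fits a single exponential; multiple admixture waves produce a
  mixture of decays that the model will average into one date, flagged only
  by fit quality. No bootstrap confidence intervals on $g$.
* The clustering stand-in is hierarchical, not posterior-based; cluster
  counts depend on the cut, and only the refinement rules are claimed to
  match the published procedure.
* Binary PLINK, imputation, phasing, and strand inference from frequency
  are out of scope; the VCF reader consumes the GT field only.
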