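---
title: "Haplotype-informed genotype calling and selection scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-informed genotype calling and selection scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowpass)
```

# Scope

`lowpass` implements the computational core of a low-coverage
whole-genome analysis: per-site genotype likelihoods from read pileups,
genotype priors derived from a phased reference haplotype panel through
a haplotype-copying model, Bayesian combination of the two into
posterior genotype calls, depth-titration evaluation of calling
accuracy, a sliding-window Tajima's D selection scan with gene-level
and paralog-age stratification, and LD-based prioritization of novel
variants near disease-associated markers. Everything is exercisable on
synthetic data with known truth; the simulator is itself first-class,
tested code.

# Genotype likelihoods and conditionals

At a site with read bases $b_1,\dots,b_d$ and Phred qualities
$Q_1,\dots,Q_d$, the per-read error probability is
$e_r = \min(0.75,\ 10^{-Q_r/10})$. For an unordered diploid genotype
$g = \{a_1, a_2\}$,

$$P(b_r \mid g) = \tfrac12 P(b_r \mid a_1) + \tfrac12 P(b_r \mid a_2),
\qquad
P(b \mid a) = \begin{cases} 1 - e_r & b = a \\ e_r/3 & b \neq a,\end{cases}$$

and the site likelihood is the product over reads, computed in log
space. We work with the 10 unordered genotypes over $\{A,C,G,T\}$; the
ordered 16-genotype formulation is identical up to labeling. Likelihood
*ratios* scale the vector so the most likely genotype has value 1;
*conditionals* renormalize the ratios to sum to 1 across the genotype
space. An empty pileup carries no information and yields all-equal
ratios.

## Sequence-only calling

Diploid calls are maximum-a-posteriori genotypes under a prior
heterozygosity $\theta = 0.001$ arranged around the reference base:
mass $\theta$ split over the three reference-bearing heterozygotes,
$\theta/2$ over the three non-reference homozygotes, and the remainder
on the reference homozygote. This convention says nothing about
heterozygotes that do not contain the reference; we give them $\theta^2$
each — a double-mutation scale that keeps the distribution proper
without affecting biallelic calls. Sites with read depth outside
$[4, 100]$ are excluded (the haploid rule uses $[2, 100]$ and calls a
variant only when a non-reference allele's normalized likelihood
exceeds 0.5). Exact posterior ties are broken uniformly at random under
a dedicated seeded stream (`tie_break_seed`), so calling never perturbs
the session RNG.

The "consensus quality" knob is implemented as a cap on the reported
Phred-scaled call quality ($-10\log_{10}(1-\text{posterior})$, capped
at 100 by default). Consensus-quality cutoffs are applied in different
directions by different pipelines, so the default removes no call; the
cap only bounds the reported score.

# The haplotype-copying prior

The two haplotypes of the target individual are modelled as hidden
mosaics of the $N$ panel haplotypes. Each chain's copied haplotype
switches between adjacent sites with probability
$\rho(d) = 1 - e^{-\lambda d}$, where $d$ is the inter-site distance in
base pairs and $\lambda$ is `switch_rate` (default $10^{-6}$ per bp; a
switch lands uniformly on any of the $N$ haplotypes). The $1-e^{-\lambda d}$
form is the standard bounded version of a linear-in-distance switch
intensity. The copied allele is mis-read with probability
`mutation_rate` (default $10^{-3}$), which also regularizes sites where
the panel is monomorphic.

The two chains are independent *a priori* but coupled through the
evidence: read information at a neighboring site arrives as a genotype
(dosage) distribution, which constrains the *sum* of the two copied
alleles. The engine therefore runs forward–backward over the joint
state $(k, l) \in N \times N$. Because the per-chain transition is
"stay or jump to uniform", the joint transition decomposes into
row-mean, column-mean and grand-mean terms and costs $O(N^2)$ per step
rather than $O(N^4)$. The emission at site $j$ with evidence
$c = (c_0, c_1, c_2)$ is

$$E_j(k,l) = c_0\,\bar p_k \bar p_l + c_1\,(p_k \bar p_l + \bar p_k p_l)
  + c_2\, p_k p_l,$$

where $p_k = H_{kj}(1-\mu) + (1-H_{kj})\mu$ and $\bar p = 1 - p$. The
prior at a target site combines the forward and backward predictive
messages *without* the target's own evidence, so read evidence is never
used twice at the site being called. A `neighborhood` parameter
(default 10) limits the pass to the nearest informative sites on each
side of the target; this keeps the cost per target site at
$O(K N^2)$ and, at typical switch rates, loses essentially nothing
because more distant sites are decorrelated by the transition kernel.

Two limiting behaviours anchor the implementation and are enforced by
tests: with uniform neighbor evidence the prior collapses to the
panel's Hardy–Weinberg distribution at the target site, and with
truth-certain neighbor evidence on a target built from two panel rows
the prior concentrates (mass > 0.99) on the true genotype — including
heterozygous targets, which is precisely what a factored single-chain
approximation cannot do. On panels small enough to enumerate, the
forward–backward posterior matches exhaustive summation over all
copy-path pairs to $10^{-8}$.

## Prior modes and Bayesian combination

`call_with_prior()` supports three modes. `sequence_only` is the
likelihood caller above. `freq_prior` uses the Hardy–Weinberg prior
$\{(1-p)^2,\ 2p(1-p),\ p^2\}$ from the panel's alternate-allele
frequency — the "genotype frequency information only" baseline.
`haplotype_prior` feeds the copying model with the read conditionals of
surrounding sites; only sites covered by at least one read contribute
evidence. In the prior modes the read conditional is computed over the
site's two panel alleles and the posterior is the renormalized
element-wise product (the standard Bayes step). Depth filters apply in
every mode.

Neighbor evidence uses conditionals (uniform-prior normalization), not
posteriors, to avoid circular reuse of the panel at the target site.
When depths are titrated downward, priors are recomputed at each depth
from the thinned reads.

## Array-based imputation

`impute_untyped_sites()` runs the same engine with hard genotype
evidence at a typed subset of sites and emits untyped sites whose
posterior strictly exceeds `report_threshold` (default 0.9, strict
inequality). Typed sites pass through flagged.

# Depth titration and evaluation

`downsample_pileups()` emulates random read removal: each read is kept
independently with probability target/current mean depth. Thinning is
composable (two-step thinning is distributionally equivalent to direct
thinning). `genotype_concordance()` compares unfiltered calls to a
reference set at shared sites and reports concordance, positive
predictive value (fraction of called variant sites that are truly
variant), heterozygote undercall rate (true heterozygotes called
homozygous — the dominant low-coverage error mode) and the no-call
rate; filtered sites are excluded from the denominator.
`accuracy_vs_depth_curve()` populates the mode × depth × replicate
grid.

When comparing modes, each pipeline is scored over the sites it
considers callable: prior modes over sites covered by at least one read
(imputation carries zero-read neighbors), sequence-only under its
native depth-4 lower bound. The paired mode comparison in the tests
holds the configuration fixed across modes within each replicate.

# Selection scan

Tajima's D compares the mean pairwise diversity $\pi$ with the
normalized segregating-site count $S/a_1$:

$$D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}},$$

with the 1989 constants $a_1 = \sum_{i<n} 1/i$, $a_2 = \sum_{i<n}
1/i^2$, $b_1 = (n+1)/3(n-1)$, $b_2 = 2(n^2+n+3)/9n(n-1)$,
$c_1 = b_1 - 1/a_1$, $c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2$,
$e_1 = c_1/a_1$, $e_2 = c_2/(a_1^2+a_2)$. Both $\pi$ and $S$ depend
only on per-site allele counts, so the scan consumes a tibble of
per-site alternate-allele counts; default sample size is $n = 21$
chromosomes. Windows with $S = 0$ have undefined D and are excluded
from outlier handling rather than set to 0.

Windows are 1-based inclusive, length 10 kb, step 5 kb, starting at
coordinate 1 — window $[113505001, 113515000]$ spans exactly 10,000 bp
— and only full windows within the region are emitted. Outlier windows
($D < -2$ for putative positive selection, $D > +2$ for balancing
selection; strict inequalities) that overlap or abut are concatenated
into maximal regions. Genes receive the unweighted mean D of the
windows they overlap ("averaging" without length weighting; the
anchor for paralog-pair proximity is the interval start, and pairs
closer than 250 kb are excluded so a shared sweep is not mistaken for a
duplication effect). The age stratification reports per-class
mean/median D, a Kruskal–Wallis omnibus test across classes plus the
background of unpaired genes, and a secondary Welch t-test of each
retained pair's greater-D member against the background
(`greater_member_classes` restricts that test to, e.g., the youngest
class, mirroring the question of whether even the less-selected copy of
a recent duplicate sits below background).

# LD prioritization

$r^2$ between two panel sites is the squared correlation of allele
indicators over phased haplotypes,
$(p_{ab} - p_a p_b)^2 / p_a(1-p_a)p_b(1-p_b)$, undefined at
monomorphic sites. A novel variant and a disease marker have flanking
LD evidence when at least one panel marker pair spans both positions
(one member at or left of the leftmost, one at or right of the
rightmost) with $r^2$ at or above the threshold (default 0.8, the
conventional "high LD" cutoff; the search examines the nearest 25
polymorphic markers on each side). Candidate variants must be novel (absent from the known-variant
catalog), strictly within 250 kb of a disease marker that is
heterozygous in the individual, and carry the flanking evidence; output
is sorted by consequence severity (stop_gained > essential_splice >
splice > non_synonymous > other). Enlarging the distance limit or
lowering the $r^2$ threshold can only add candidates.

`enrichment_test()` wraps the 2×2 machinery: Fisher's exact test
(the one-sided variant is the hypergeometric upper tail) and the
Pearson chi-square without continuity correction, with a cross-product
odds ratio (Haldane 0.5 correction, flagged, when a cell is zero). The
reference group may include the subset being tested — the natural
construction when a genome-wide total already contains the subset —
or be supplied as disjoint counts for an exclusive background.

# The synthetic-data generator

`simulate_panel()` builds a phased panel from `n_founders` (default 8)
independent founder haplotypes whose per-site alternate-allele
probabilities follow a neutral-like $1/p$ spectrum with random
polarity, extended by sequential mosaic copying: each new haplotype
copies a random existing one with a Poisson number of switch points and
per-site copy error (`mutation_rate`, default 0.02). Copying creates
LD that decays with distance; founders supply intermediate-frequency
standing variation. The founder component is the generator's
neutrality calibration: pure sequential copying produces a
random-recursive-tree genealogy with a large singleton excess (window
mean D near $-1.9$ at $n = 21$), while the combined process keeps the
neutral window mean D inside $(-0.5, 0.5)$ with almost no $|D| > 2$
windows. Monomorphic sites are repolarised by flipping one random
haplotype, so every site is segregating.

`sample_diploid()` draws two mosaic haplotypes from the panel (switch
counts recorded as ground truth), `simulate_pileups()` adds
Poisson-depth reads with uniform base errors and a constant Phred
quality, `simulate_array_truth()` types a random site subset with a
small symmetric genotype error, and `simulate_annotations()` lays out
non-overlapping genes, age-tagged paralog pairs with a 250-kb
proximity flag, disease markers at panel sites, and a known-variant
catalog. Every generator is a pure function of its seed, implemented
against a temporary RNG state so library calls never disturb the
caller's stream.

What the simulator does *not* emulate: coalescent genealogies,
recombination-rate variation, indel alleles, base-quality miscalibration,
mapping artifacts, array cluster artifacts, population structure
between panel and target. Passing tests therefore demonstrate internal
correctness and the direction/magnitude of method differences under an
idealized panel-target match, not performance on real cohorts — in
particular, the advantage of haplotype priors shrinks when the target
is poorly represented by the panel.

# Numerical and design notes

* Likelihood products are accumulated in log space and shifted by their
  maximum before exponentiation; the two-chain forward pass
  renormalizes after every site and falls back to the uniform state
  distribution if evidence annihilates the message entirely.
* Strictness conventions: depth bounds are inclusive
  ($4 \le d \le 100$ passes), the imputation reporting threshold and
  the D outlier cutoffs are strict, indel spacing conflicts arise below
  20 bp and are resolved left-to-right by keeping the highest-quality
  candidate of each run, and indel depth bounds are exclusive
  ($4 < d < 100$, lower bound 2 for haploid).
* Degenerate inputs: an all-zero likelihood vector, a prior/conditional
  pair with disjoint support, LD at a monomorphic site, an empty typed
  set, and gene packings that cannot fit are all rejected with errors
  rather than silently patched.
* Coordinates are 1-based inclusive internally; BED output converts to
  0-based half-open on write and back on read, bit-exactly.

## Problem sizes used by the test-suite benchmarks

The depth-accuracy benchmark uses a 100-haplotype panel over 2,000
sites in 2 Mb, 1% base error, ten seeds, scoring roughly 20,000
genotypes per configuration; the paired mode-ordering check uses
60-haplotype, 400-site panels over twenty replicates; the neutral
calibration scans about 600 windows per replicate at $n = 21$; the
Kruskal–Wallis null calibration uses 200 replicates of 60 genes. These
sizes were chosen so each property is measured with comfortable margin
while the whole suite stays quick to run.

# Known limitations

* The copying model assumes a single panel population and a uniform
  switch intensity; no recombination map is supported.
* Prior modes are restricted to biallelic panel sites; multi-allelic
  sites and indel likelihood models are out of scope (only the indel
  candidate filters are implemented).
* The windowed neighborhood is an approximation to full-sequence
  forward–backward; with very high switch rates and sparse evidence the
  truncation is more visible.
* `impute_untyped_sites()` reports only the genotype posterior, not
  per-site imputation quality scores beyond it.
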