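# lowpass

Haplotype-informed genotype calling and population-genetic scans for
low-coverage sequencing, with a self-contained synthetic-data simulator.

## The problem

Low-coverage whole-genome sequencing (2–4X) is cheap but calls
genotypes badly: at a true heterozygote covered by *d* reads, both
alleles are observed with probability only $1 - 2^{1-d}$, so
heterozygote undercalling dominates the error budget. Because SNPs are
co-inherited in haplotypes, a phased reference panel carries strong
information about a genotype from the *surrounding* sites: calls made
confidently in well-covered stretches, combined with known haplotype
structure, can rescue poorly covered neighbors. `lowpass` is for
statistical geneticists and methods developers who want a transparent,
fully testable implementation of that idea, together with the
downstream analyses it feeds: depth-vs-accuracy evaluation, a Tajima's
D selection scan, and LD-based prioritization of novel variants near
disease markers.

## The model

Per-site read likelihoods for the 10 unordered diploid genotypes use
the Phred error model $P(b\,|\,a) = 1-e$ (match) or $e/3$ (mismatch),
with heterozygotes emitting each allele with probability ½. The
haplotype prior comes from a two-chain haplotype-copying HMM: each
target haplotype is a hidden mosaic of the $N$ panel haplotypes, with
switch probability $\rho(d) = 1 - e^{-\lambda d}$ per $d$ bp and copy
error $\mu$; the chains are coupled through genotype (dosage) evidence
at flanking sites, so the engine runs forward–backward over the joint
state $(k,l)$ at $O(N^2)$ per site. The posterior call at a site is
the renormalized product

$$P(g \mid \text{reads, panel}) \propto
  P_{\text{copying}}(g \mid \text{neighbors, panel}) \times
  P(\text{reads at the site} \mid g),$$

with the site's own reads never entering its prior. The selection scan
computes Tajima's
$D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ in 10-kb windows
stepping 5 kb, merges outlier windows ($|D| > 2$) into regions,
averages D per gene and stratifies genes by paralog duplication age.
See `vignettes/lowpass-methods.Rmd` for the full treatment.

## Worked example

Simulate an LD-structured panel, a diploid target that is a mosaic of
panel haplotypes, and 2.4X reads with 1% base error; then call
genotypes with and without the haplotype prior:

```r
library(lowpass)

panel  <- simulate_panel(n_haplotypes = 100, n_sites = 2000,
                         region_length = 2e6,
                         recombination_intensity = 1, seed = 42)
target <- sample_diploid(panel, recombination_intensity = 1, seed = 43)
reads  <- simulate_pileups(target, mean_depth = 2.4,
                           base_error = 0.01, seed = 44)

cfg <- caller_config(min_depth = 1)   # score sites with >= 1 read
hap <- call_with_prior(reads, panel, mode = "haplotype_prior", config = cfg)
seq <- call_with_prior(reads, panel, mode = "sequence_only",  config = cfg)

genotype_concordance(hap, target$genotypes)
#> # A tibble: 1 × 6
#>   n_compared n_match concordance   ppv het_undercall_rate no_call_rate
#> 1       1814    1768       0.975 0.993             0.0820        0.093
genotype_concordance(seq, target$genotypes)
#> # A tibble: 1 × 6
#>   n_compared n_match concordance   ppv het_undercall_rate no_call_rate
#> 1       1814    1358       0.749     1              0.776        0.093
```

At 2.4X the haplotype prior lifts concordance from 74.9% to 97.5% on
the same 1,814 scored sites, almost entirely by repairing heterozygote
undercalls (77.6% → 8.2%). `accuracy_vs_depth_curve()` sweeps the full
mode × depth grid and `autoplot()` draws the comparison.

A windowed selection scan over a 21-chromosome neutral simulation:

```r
scan_panel <- simulate_panel(21, 6000, region_length = 3e6,
                             recombination_intensity = 5, seed = 7)
windows <- sliding_window_scan(panel_to_variants(scan_panel),
                               window_length = 10000, step = 5000,
                               n_chromosomes = 21)
windows[1:3, ]
#>   chromosome start   end n_sites     S    pi       D
#> 1 chr1           1 10000      34    34  9.55  0.0422
#> 2 chr1        5001 15000      29    29  8.09  0.0120
#> 3 chr1       10001 20000      21    21  5.21 -0.406
mean(windows$D, na.rm = TRUE)   # -0.175 over 598 windows: near-neutral
merge_outlier_regions(windows, cutoff = -2)   # no sweep-like regions
```

And the 2×2 enrichment machinery used for deleterious-variant counts
(deleterious/benign in an LD-linked subset versus genome-wide):

```r
tab <- matrix(c(6, 744, 19, 7249), nrow = 2)
enrichment_test(tab, "fisher_one_sided")
#>   method           statistic p_value odds_ratio haldane
#> 1 fisher_one_sided        NA  0.0248       3.08 FALSE
```

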