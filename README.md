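# phylopi

Phylogenetic informativeness profiling and marker-utility evaluation on a
fixed time-calibrated tree.

## The problem

When a multi-gene dataset is assembled for phylogenetics — say a
concatenation of mitochondrial and nuclear protein-coding fragments plus
ribosomal genes — different markers, and different codon positions within
them, resolve different epochs. Fast-evolving mitochondrial third codon
positions accumulate signal quickly but saturate (multiple substitutions
overwrite earlier ones), so they inform recent radiations and mislead at
depth; slow first/second positions carry little signal per site but keep
accumulating it over tens of millions of years. `phylopi` quantifies this
trade-off for each partition of an alignment, given an ultrametric
reference tree with branch lengths in Ma.

## The method

For every alignment column, a substitution rate λ (substitutions/site/Ma)
is estimated by maximum likelihood on the fixed tree, using Felsenstein's
pruning algorithm under JC69 with uniform root frequencies (Brent
optimization of the per-site likelihood on [0, λ_max]). Per-site rates
are then turned into **phylogenetic informativeness** (PI) profiles over
time depth *t*:

- *original* (normalized): ρ(t; λ) = 16 λ² t e^(−4λt), unit area over
  (0, ∞);
- *modified*: ρ(t; λ) = λ t e^(−4λt), the 16λ normalizing factor
  excluded, so fast and slow sites are compared on an absolute scale;
- *average-modified*: the modified partition sum divided by partition
  length — informativeness per aligned base, the fairest cross-marker
  comparison.

Both per-site forms peak at t\* = 1/(4λ); two modified curves of rates
λ_slow < λ_fast cross exactly once, at
t_x = ln(λ_fast/λ_slow) / (4(λ_fast − λ_slow)), beyond which the slower
site is the more informative. Saturation is diagnosed independently by
plotting pairwise uncorrected p-distances per partition against
patristic distances on the tree. Alignment columns are also classified
as conserved / variable / parsimony-informative per partition, and
fossil age constraints are expressed as offset lognormal or offset
exponential priors with closed-form quantiles.

A partitioned simulator (Yule trees rescaled to a fixed root age, HKY +
gamma site rates, fragment-level missing data) generates alignments with
known per-site rates, so the whole pipeline is validated against ground
truth.

## Worked example

```r
library(phylopi)

# simulated stand-in for an eight-fragment beetle dataset:
# 40 taxa, 110 Ma root, 6095 bp, 20 gene-by-codon partitions
fx <- marker_fixture(seed = 1)
ncol(fx$matrix)
#> [1] 6095

# per-site rates on the fixed ultrametric tree (seconds for 6095 sites)
rates <- estimate_all_rates(fx$matrix, fx$tree, fx$scheme)

# estimated mean rate per rate class tracks the simulation truth
round(tapply(rates$lambda, fx$true_rates$rate_class, mean)[
  c("mito_pos3", "nuc_pos3", "nuc_pos2")], 5)
#> mito_pos3  nuc_pos3  nuc_pos2
#>   0.02112   0.00781   0.00011

# informativeness per aligned base at 15, 35 and 50 Ma
prof <- pi_profile(rates, fx$scheme, grid = c(15, 35, 50),
                   variants = "average_modified")
print(subset(prof, partition %in% c("CAD_pos3", "COI_3p_pos3")), digits = 3)
#>    t_ma   partition          variant     pi
#> 7    15    CAD_pos3 average_modified 0.0582
#> 8    35    CAD_pos3 average_modified 0.0703
#> 9    50    CAD_pos3 average_modified 0.0673
#> 16   15 COI_3p_pos3 average_modified 0.0733
#> 17   35 COI_3p_pos3 average_modified 0.0597
#> 18   50 COI_3p_pos3 average_modified 0.0456
```

The nuclear third-position partition (CAD_pos3) keeps gaining
informativeness towards its ~35 Ma peak and stays high at 50 Ma, while
the saturating mitochondrial third positions (COI_3p_pos3) have already
peaked shallow and decay with depth — the classic rationale for
preferring nuclear markers for Paleogene-and-older divergences.

```r
# fossil calibration: hard minimum 34 Ma, lognormal exceedance
pr <- calibration_prior("offset_lognormal", offset = 34, mean = 7, sd = 5)
summary(pr)
#> offset_lognormal prior: offset 34.00 Ma
#>   median  39.70 Ma
#>   95% CI  [35.62, 54.05] Ma
```

The whole workflow also runs as one call (`run_pipeline()`, see
`?run_pipeline`) or from a shell via the thin wrapper
`inst/scripts/phylopi-cli.R` (subcommands `run`, `simulate`, `priors`).

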