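# stoichioprot

Stoichioproteomics asks whether the elemental composition of proteins —
here, the oxygen carried on amino-acid side chains — tracks how strongly
those proteins are expressed. Resource (nutrient) limitation theory predicts
that in an oxygen-poor environment, such as the hypoxic microenvironment of
a glioma, highly expressed proteins should economise on oxygen-rich
residues. `stoichioprot` implements the full analysis needed to test that
prediction on immunohistochemistry-based proteome data (Human Protein Atlas
style: 12 glioma samples vs 4 normal cerebral-cortex cell types), and ships
a synthetic-data generator so the whole pipeline can be validated end to end
without any external download.

It is written for computational biologists: every user-facing function takes
a data frame and returns a tibble, so stages chain with the pipe; results
have `tidy()`, `glance()` and `autoplot()` methods.

## The statistics at the core

* **Side-chain element frequency.** For a protein of length *L* with residue
  counts *p\_i* and side-chain atom counts *w\_i* (R-group only, backbone
  excluded; derived from free amino-acid formulas minus free glycine),

  frequency = Σ *w\_i* · *p\_i* / *L*.

  The **C:O ratio** is the total side-chain carbon over total side-chain
  oxygen of the protein (undefined when a protein carries no side-chain
  oxygen).

* **Ordinal expression scores.** Staining intensity × stained-cell fraction
  maps to the 4-level scale *not detected / low / medium / high*, scored
  0 / 3 / 6 / 12; zeros are replaced by 0.1 so log ratios stay defined, and
  only proteins scored in ≥3 glioma and ≥3 normal samples are analysed.

* **Differential expression.** Per protein, log2 ratio of mean adjusted
  scores (glioma / normal), an exact Wilcoxon rank-sum p-value (exhaustive
  permutation null with mid-ranks — appropriate for heavily tied ordinal
  data), and Benjamini–Hochberg q-values. *Up*: log2 ratio ≥ 1, p < 0.05,
  q < 0.01; *down*: log2 ratio ≤ −1 under the same gates.

* **Group comparisons.** Highly vs lowly expressed sets (top/bottom 1/3/5%
  or score-threshold selection), directed percent differences of mean
  element content, two-sample Kolmogorov–Smirnov tests, Tukey HSD across
  proteomes, and per-chromosome counts of differentially expressed genes
  from a GFF3/GTF annotation.

## Worked example

```r
library(stoichioprot)
library(dplyr)

study <- simulate_study(synthetic_config(n_proteins = 1000, seed = 7))

profiles <- element_profile(study$proteins)
head(profiles, 3)
#> # A tibble: 3 × 5
#>   protein_id length o_freq c_freq co_ratio
#>   <chr>       <int>  <dbl>  <dbl>    <dbl>
#> 1 P00001        936  0.493   2.93     5.95
#> 2 P00002        232  0.478   2.76     5.77
#> 3 P00003        284  0.405   3.00     7.4
proteome_mean_frequency(profiles, "O")
#> [1] 0.4861717

dep <- study$scores |> filter_min_samples() |> dep_analysis()
glance(dep)
#> # A tibble: 1 × 6
#>   n_proteins  n_up n_down   lfc alpha   fdr
#>        <int> <int>  <int> <dbl> <dbl> <dbl>
#> 1       1000    18    102     1  0.05  0.01

o_of <- setNames(profiles$o_freq, profiles$protein_id)
dep_tbl <- tidy(dep)
compare_groups(o_of[dep_tbl$protein_id[dep_tbl$class == "up"]],
               o_of[dep_tbl$protein_id[dep_tbl$class == "down"]],
               labels = c("up", "down"))
#> Group comparison: up vs down (reference: down)
#>   n = 18 vs 102; means 0.5177 vs 0.4846 (+6.84% vs reference)
#>   KS D = 0.3431, p = 0.0545
```

Reading the output: per-protein side-chain oxygen frequencies sit near 0.49
atoms per residue and C:O ratios near 6, as expected for vertebrate-like
compositions. Of 1000 synthetic proteins, 18 are classified up-regulated and
102 down-regulated at the default gates (the generator plants 12% of
proteins as differentially expressed at a ~1:5.7 up:down ratio). The
up-regulated set's mean oxygen content is 6.8% above the down-regulated
set's — the planted oxygen-usage bias, recovered by the pipeline.

The generator and its planted effects are documented in
`vignettes/stoichioproteomics.Rmd`, along with every modelling assumption
and numerical choice.

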