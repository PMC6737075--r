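# bbmpattern

Expression-pattern analysis of the intestinal brush-border membrane (BBM)
proteome under a 2×2 factorial design.

## The problem

The microvilli of small-intestinal enterocytes are built from a small set of
structural proteins (villin, IRTKS-1, harmonin, β-actin, myosin-1a, …), and
their uniform length responds to the hormone GLP-2 through the intestinal
epithelial IGF-1 receptor (IE-IGF-1R). A label-free proteomics experiment on
isolated BBMs from four pooled groups of mice — control and IE-IGF-1R
knockout, each given vehicle or a long-acting GLP-2 agonist — asks, for each
protein, which of two regulation patterns it follows:

* **category 1** — changed only in GLP-2-treated control animals
  (a treatment effect that requires the intact receptor);
* **category 2** — changed in both knockout groups regardless of treatment
  (an effect of receptor loss alone).

`bbmpattern` implements this analysis as a tested, reusable pipeline for
anyone working with pooled spectral-count tables under a genotype × treatment
design, together with the study-style downstream statistics and a
synthetic-data generator with planted ground truth.

## The method

For a protein with spectral counts \(c = (c_1, c_2, c_3, c_4)\) over the
fixed group order (control-vehicle, control-GLP2, KO-vehicle, KO-GLP2):

1. **Normalization.** \(x_i = \max(c_i / \max_j c_j,\ 0.01)\), giving a
   profile in \([0.01, 1]\) with the largest group at exactly 1.
2. **Template correlation.** The profile is scored by Pearson correlation
   *r* against idealized template models built from a baseline of 0.5 and a
   deviation of 0.3: category 1 up = (0.5, 0.8, 0.5, 0.5), category 2 up =
   (0.5, 0.5, 0.8, 0.8), plus mirrored down-variants. With four values the
   correlation has df = 2 and \(p = 2\,P\!\left[T_2 \ge |r|\sqrt{2/(1-r^2)}\right]\);
   significance at α = 0.05 requires \(|r| \gtrsim 0.950\).
3. **Threshold gating.** The best-fitting template's category is called only
   if additionally every "changed" group deviates from the mean of the
   unchanged groups by ≥ 0.3 and the unchanged groups pairwise differ by
   ≤ 0.1. Profiles with all pairwise differences ≤ 0.1 are called null;
   everything else is unclassified.
4. **Protein selection** uses one-sided hypergeometric term enrichment
   (`P[X ≥ k]`) with Benjamini–Hochberg control over a flat
   term-to-gene annotation, the universe being the identified proteome.
5. **Supporting statistics**: plain group fold changes, 2×2 ANOVA (type-II
   SS) with Sidak post-hoc comparisons `1 − (1 − p)^m`, the 2^−ΔΔCT method
   for qPCR, and vehicle-control-relative densitometry normalization.

## Worked example

The package ships a small **synthetic** stand-in count table
(`inst/extdata/synthetic_bbm_counts.tsv`; constructed, not measured — see the
file header) whose group ratios for the named microvillar proteins encode
published fold changes:

```r
library(bbmpattern)
f   <- system.file("extdata", "synthetic_bbm_counts.tsv", package = "bbmpattern")
tab <- read_count_table(f)
#> read 20 proteins from .../synthetic_bbm_counts.tsv
res <- classify_counts(tab)
subset(res, category != "null",
       select = c(gene_symbol, category, r_squared, p_value,
                  fold_glp2_control, fold_ko_vehicle))
#>   gene_symbol     category r_squared   p_value fold_glp2_control fold_ko_vehicle
#> 1        Vil1      cat1_up     1.000 2.23e-308              1.43            1.00
#> 2    Baiap2l1 unclassified     0.606  2.22e-01              1.00            2.39
#> 3       Ush1c unclassified     0.573  2.43e-01              1.00            3.85
#> 4        Actb unclassified     0.497  2.95e-01              1.00            2.06
```

Villin rises 1.43-fold only in GLP-2-treated controls and is called
category 1 (R² = 1 against the category-1-up template; the p-value sits at
the numeric floor because the match is exact). IRTKS-1 and harmonin are
elevated in the knockout groups, but their treated-knockout elevation
(1.38- and 1.69-fold ≈ normalized deviations of 0.16–0.18) falls below the
0.3 change threshold, so with these ratios alone they remain unclassified
rather than being guessed into category 2. The remaining 16 proteins are
flat and called null.

A full synthetic run with planted truth:

```r
cfg <- pipeline_config(simulation = sim_config(n_proteins = 1000,
                                               effect_size = 3,
                                               dispersion = 0.001),
                       seed = 1)
out <- run_pipeline(cfg, "pipeline_out")   # enrichment, classification,
                                           # truth and manifest TSV/YAML
```

A thin command-line wrapper is installed at
`inst/scripts/bbm_pipeline.R` (`run`, `simulate`, `enrich`, `classify`,
`anova`, `ddct` subcommands).

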