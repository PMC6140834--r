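# gutliveR

Stage-wise gut–liver immune resilience analysis for fish feeding trials.

## The problem

Replacing fish meal with plant protein (soybean meal) in aquafeeds causes
foodborne enteritis in many fish; herbivorous species such as grass carp
can *recover* from it under moderate substitution. Demonstrating that
resilience takes an integrative time-course analysis: gut and liver
transcriptomes (n = 3 per time point) and a gut miRNAome (n = 2) sampled
at 0 days, 3, 5 and 7 weeks, classified against a curated immune gene
library, plus growth performance and histology morphometry. `gutliveR`
implements that analysis as a tested, reusable R package for anyone
running (or simulating) a multi-time-point dietary-stress trial:

* **Stage-wise differential expression** over the three consecutive
  contrasts (early = 3w vs 0d, middle = 5w vs 3w, late = 7w vs 5w):
  negative-binomial Wald tests with median-of-ratios size factors,
  moderated method-of-moments dispersions
  (Var = μ + αμ², α shrunk toward the cross-feature median), log2 fold
  changes with pseudocount 0.5, and Benjamini–Hochberg FDR calling at
  adjusted p < 0.05.
* **Immune classification**: a two-level immune gene library — nine fixed
  immune processes over free-text immune categories — with
  multi-membership classification and signed per-process tallies
  (down-regulated counts negative).
* **Enrichment**: upper-tail hypergeometric over-representation,
  rich factor k/K, BH q-values, significant at q < 0.05.
* **Immune checkpoints**: category-level t-tests across time points and
  the homeostasis rules — gut: significant in 7w vs 5w or 7w vs 3w but
  *not* 7w vs 0d (perturbed, then restored); liver: significant versus
  the 0d baseline at any time point.
* **miRNA–mRNA networks**: Pearson correlation of per-time-point mean
  profiles over predicted target pairs, edges where both members are DE
  in a stage, signed by correlation, filtered to immune targets, exported
  as SIF/GraphML/attribute TSVs.
* **Phenotype**: the eight growth/organ formulas (WG%, SGR, FE, ADFI,
  survival, HI, ILI, ISI), percent stained area, background-corrected
  IHC mean density, and Welch group comparisons (α = 0.05 growth,
  0.01 morphometry).
* **Synthetic studies**: a seeded generator that produces every input the
  pipeline consumes with planted DE genes, checkpoint categories and
  signed miRNA–target couplings recorded as ground truth.

## Worked example

```r
library(gutliveR)

cfg <- sim_config(seed = 1)          # the synthetic feeding trial
sim <- simulate_study(cfg)

de <- stage_de(sim$gut_mrna, alpha = 0.05)
for (s in names(de))
  cat(sprintf("%-6s %3d up / %3d down\n", s,
              length(de[[s]]$up_set), length(de[[s]]$down_set)))
#> early   70 up /  63 down
#> middle  51 up /  47 down
#> late    53 up /  62 down

cls <- classify_genes(de$early$up_set, sim$library)
cat("early up immune genes:", cls$n_distinct_immune,
    "| non-immune:", length(cls$non_immune), "\n")
#> early up immune genes: 70 | non-immune: 0

prof  <- category_profile(sim$gut_mrna, sim$library)
tests <- category_tests(prof, checkpoint_comparisons("gut"))
chk   <- select_checkpoints(tests, "gut")
head(chk[chk$selected, c("process", "category")], 5)
#>                               process category
#>                 acute phase reactions     IC01
#>                   pattern recognition     IC02
#>     antigen processing and regulators     IC03
#>                     complement system     IC04
#>  inflammatory cytokines and receptors     IC05

growth_metrics(list(fish_n_start = 40, fish_n_end = 38, days = 49))["survival"]
#> survival
#>       95
```

The stage tallies say enteritis-like expression turnover is largest early
and declines by the late stage; the five selected gut categories are
exactly the generator's planted checkpoints (perturbed at 3–5 weeks,
restored at 7); and the survival formula reproduces the textbook worked
value (38 live of 40 stocked → 95.00%).

## The analysis workflow

The numbered drivers under `analysis/` run the whole study over the
package functions and write their tables beneath `results/run/`:

```sh
Rscript analysis/01_simulate.R 1      # inputs + planted truth (seed 1)
Rscript analysis/02_diffexpr.R        # stage-wise DE, three assays
Rscript analysis/03_classify_enrich.R # immune tallies + enrichment
Rscript analysis/04_checkpoints.R     # checkpoint selection per tissue
Rscript analysis/05_network.R         # stage networks + exports
Rscript analysis/06_phenotype.R       # growth metrics + morphometry
Rscript analysis/07_report.R          # stage-wise summary tables
```

`run_config()`/`run_all()` execute the same sequence in one call.

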