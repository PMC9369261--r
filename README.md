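# refstab

Reference-gene stability ranking and relative quantification for RT-qPCR
Cq data stratified by tissue region and genotype.

Relative RT-qPCR quantification stands or falls with its reference
("housekeeping") genes. In heterogeneous tissue such as the mouse brain —
and doubly so when comparing a wild-type against a mutant genotype such as
the Prader-Willi critical-region deletion (PWScr) — classically used
references (β-actin, B2m, Sdha) can drift regionally or between genotypes.
`refstab` is for qPCR practitioners who need to pick a defensible reference
panel from candidate genes measured across a region × genotype design, and
then profile target genes against it.

## What it computes

Four stability estimators, each from its original formulation (lower =
more stable):

- **Comparative ΔCt** — mean over partner genes of SD<sub>samples</sub>(Cq difference), in cycles;
- **geNorm** — M = mean pairwise variation SD(log₂ Q ratio), with iterative
  exclusion of the worst gene and the V<sub>n/n+1</sub> series;
- **BestKeeper** — Cq dispersion SD[±Cq] and CV%, plus Pearson r against the
  per-sample geometric-mean index;
- **NormFinder** — model-based decomposition into intragroup variance and
  shrunken intergroup deviation after within-sample centering.

Per condition, the four ranks are combined by their **geometric mean**
(comprehensive ranking, ranks 1 = most stable … n = least stable). The
ranking is swept along both design axes — across regions within each
genotype, and across genotypes within each region — and the two axis scores
are combined 50%/50% into the final panel (top k = 3 by default).

Targets are then quantified per biological replicate as
**2<sup>−ΔCq</sup>** with ΔCq = Cq<sub>target</sub> − mean(Cq<sub>panel</sub>),
and genotype differences per region are tested with Student's *t*-test
(Welch optional) after a Shapiro–Wilk normality check, labelled
`* p ≤ 0.05, ** p ≤ 0.01, *** p ≤ 0.001`.

A seeded synthetic-data generator (`simulate_cq()`, `study_config()`)
reproduces the study's factorial layout — 9 brain regions × {WT, PWScr} ×
3 biological replicates (6 for the WT hypothalamus) × 3 technical
replicates — with known ground truth, so every stage is testable without
instrument data.

## Worked example

The four scripts under `analysis/` run the whole workflow on a simulated
study (each is a thin driver over the package functions and writes its
tables under `results/`):

```sh
Rscript analysis/01_simulate.R 1   # simulate the study design (seed 1)
Rscript analysis/02_screen.R       # screen 11 candidates -> keep 8
Rscript analysis/03_panel.R        # two-axis ranking + 50/50 panel
Rscript analysis/04_quantify.R     # targets vs the panel, per-region t-tests
```

Step 2 prints the comprehensive ranking of the 11 candidates on the
wild-type animals across all nine regions; the three designed-unstable
classics land at the bottom and are removed by the screen:

```
   gene geomean_rank  kept
   Alg5     1.456475  TRUE
   Gusb     1.565085  TRUE
   Hmbs     2.710806  TRUE
   Mogs     4.000000  TRUE
 Man2b2     5.233176  TRUE
   Cyc1     5.732657  TRUE
 Snhg12     7.000000  TRUE
   Tfrc     8.000000  TRUE
    B2m     9.000000 FALSE
   Sdha    10.000000 FALSE
   Actb    11.000000 FALSE
removed: Sdha, B2m, Actb
```

Step 3 combines the inter-regional axis (50%) with the intra-regional,
between-genotype axis (50%); lower combined rank = more stable, and the top
three genes form the panel:

```
combined ranking (50% regions / 50% genotypes):
  Alg5   Hmbs   Gusb   Mogs Man2b2 Snhg12   Cyc1   Tfrc
 2.193  2.230  2.279  4.434  5.246  5.905  6.097  6.359
reference-gene panel: Alg5-Hmbs-Gusb
```

Step 4 quantifies each target assay relative to that panel and reports the
per-region genotype comparisons; fold change is PWScr/WT, so the simulated
~2-fold Pcsk1 loss in hypothalamus shows up as 0.447:

```
       gene       region fold_change p_value label
     Igfbp7  hippocampus       1.389 0.00607    **
      Nhlh2     midbrain       2.149 0.02150     *
 Nlgn3_iso1   cerebellum       1.353 0.00090   ***
      Pcsk1 hypothalamus       0.447 0.00301    **
      Pcsk2    isocortex       1.557 0.00116    **
 ...
```

The same steps are available as package functions
(`stability_suite()`, `comprehensive_rank()`, `condition_sweep()`,
`compile_panel()`, `screen_candidates()`, `relative_expression()`,
`compare_by_region()`); see the vignette
`vignettes/reference-gene-stability.Rmd` for the methods and their
assumptions, and `inst/extdata/example_cq.csv` for a small simulated
long-format input.

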