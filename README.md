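# scpoolr

Iterated pseudocell pooling and variance partitioning for single-cell
RNA-seq.

## The problem

Single-cell UMI counts are too sparse and too pseudo-replicated for naive
differential expression: treating cells as biological replicates inflates
significance, and per-cell counts are mostly zeros. In stimulation
experiments — here, PBMCs from case and control donors cultured with or
without a cytokine stimulus and processed in batches — the quantities of
interest are *variance components*: how much of each gene's expression
variance is attributable to stimulus, disease status, processing batch,
individual donor, and the stimulus-by-status interaction.

`scpoolr` implements the **scPool** strategy for this design, aimed at
analysts working with 10x-style count matrices and pre-computed cell-type
labels:

1. **Pooling.** Within each stratum (one donor under one stimulus, one
   cell type), cells are randomly partitioned into pseudocells of a fixed
   size *k* ∈ {5, 10, 15, 20}. A stratum of *n* cells yields ⌊*n*/*k*⌋
   pseudocells (63 cells support 12, 6, 4 and 3 pseudocells at the four
   sizes); leftovers are dropped. Pseudocell counts are the sums of member
   cell counts, normalized to counts per 100,000 (CP100K). The random
   assignment is repeated (3 iterations by default) to yield
   pseudo-replicates.

2. **Variance partitioning.** For every gene with mean CP100K ≥ 1 in a
   cell type, the crossed random-intercepts model

   *y* = μ + *u*<sub>Stimulus</sub> + *u*<sub>Status</sub> +
   *u*<sub>Batch</sub> + *u*<sub>Donor</sub> +
   *u*<sub>Stimulus:Status</sub> + ε

   is fitted by REML to log2(CP100K + 1), and each component is reported
   as a fraction of the total variance, summarized per cell type as the
   mean fraction and the share of genes where a component explains > 5%.
   A closed-form method-of-moments (MINQUE(0)) estimator backs up the
   optimizer and doubles as a verification oracle on balanced designs.

3. **Concordance (AUCC).** Ranked top-*K* gene lists (e.g. top-100 donor
   components in two cell types, or in two pooling iterations) are
   compared with the area under the concordance curve:
   C<sub>i</sub> = |top<sub>i</sub>(a) ∩ top<sub>i</sub>(b)| for
   i = 1..K, AUCC = Σ C<sub>i</sub> / (K²/2) (the conventional
   denominator; an exact K(K+1)/2 variant that caps at 1 is also
   provided).

4. **Cell-type proportions.** Per-sample cell-type fractions are modelled
   with fixed Stimulus, Status and Interaction effects and random Donor
   and Batch intercepts (Satterthwaite F tests), reporting the donor and
   batch variance fractions.

5. **QC filters.** Cells with > 15% mitochondrial reads, a detected-gene
   count more than 3 SD above the mean, or a cluster label reproduced in
   fewer than 2 of 4 batch-wise clustering runs are flagged before
   pooling.

A first-class synthetic-data generator (`simulate_dataset()`,
`simulate_proportions()`, `simulate_pseudocell_expression()`) emulates the
8-donor (6 cases / 2 controls), 2-stimulus, 4-batch, ~2,900-cells-per-
sample design with known ground-truth effect fractions, so every step of
the pipeline is testable against its generative truth.

## Worked example

```r
library(scpoolr)

blocks <- tibble::tibble(
  n_genes = 300, frac_donor = 0.3, frac_stimulus = 0.1, frac_status = 0.01,
  frac_batch = 0.02, frac_interaction = 0.01, total_var = 1,
  base_log2_mean = 4, base_log2_sd = 1, dispersion = 5
)
cfg <- simulation_config(n_cell_types = 3, cells_per_sample = 300,
                         gene_blocks = blocks, reference_pool_size = 20)
sim <- simulate_dataset(cfg, seed = 1)
sim$matrix
#> <gene_expression_matrix> 4834 cells x 300 genes, 1228357 nonzero counts

pools <- run_scpool(sim$matrix, sim$annotation, sizes = c(5, 20),
                    iterations = 3, seed = 2)
pm <- pools$pm[[which(pools$pool_size == 20 & pools$iteration == 1)]]
vp <- partition_cell_type(pm, "type01")
glance(vp)
#> # A tibble: 6 × 4
#>   effect          mean_fraction frac_genes_gt5 n_genes
#>   <chr>                   <dbl>          <dbl>   <int>
#> 1 Batch                  0.0579         0.317      300
#> 2 Donor                  0.252          0.927      300
#> 3 Residual               0.537          1          300
#> 4 Status                 0.0560         0.267      300
#> 5 Stimulus               0.0847         0.483      300
#> 6 Stimulus:Status        0.0126         0.0867     300
```

The donor component dominates the non-residual variance, as configured
(`frac_donor = 0.3` of the sample-level signal; with donors nested in
batches and only two status levels, part of the donor signal is absorbed
by the Batch and Status components — see the methods vignette). Replicate
pooling iterations rank donor genes almost identically:

```r
lists <- lapply(pools$pm[pools$pool_size == 20], function(p)
  rank_genes(partition_cell_type(p, "type01"), "Donor", top_k = 100))
round(aucc_matrix(setNames(lists, paste0("iteration", 1:3))), 3)
#>            iteration1 iteration2 iteration3
#> iteration1      1.010      0.898      0.912
#> iteration2      0.898      1.010      0.884
#> iteration3      0.912      0.884      1.010
```

(identical lists score 1.01 = 5050/5000 under the conventional K²/2
denominator). Cell-type proportions at the study's sequencing depth show
the donor variance fraction dominating the mixed-model decomposition:

```r
sim_p <- simulate_proportions(simulation_config(n_cell_types = 5), seed = 3)
fits <- fit_proportion_models(sim_p$proportions)
summarize_donor_variance(fits)[
  , c("cell_type", "F_stimulus", "p_stimulus",
      "var_donor_fraction", "donor_dominant")]
#> # A tibble: 5 × 5
#>   cell_type F_stimulus p_stimulus var_donor_fraction donor_dominant
#>   <chr>          <dbl>      <dbl>              <dbl> <lgl>
#> 1 type01       0.498        0.507              0.910 TRUE
#> 2 type02       0.0688       0.802              0.798 TRUE
#> 3 type03       0.00679      0.937              0.940 TRUE
#> 4 type04       0.908        0.377              0.214 FALSE
#> 5 type05       0.146        0.715              0.726 TRUE
```

`autoplot()` on a variance-partition result, `plot_aucc_matrix()` and
`plot_proportions()` provide the matching diagnostic figures, and every
fitted object has broom-style `tidy()` / `glance()` methods.

## Command line

A thin CLI over the same functions ships in `inst/scripts/scpool`:

```sh
Rscript inst/scripts/scpool simulate --config cfg.json --seed 1 --out-dir sim/
Rscript inst/scripts/scpool pool --matrix-dir sim/counts --annotation sim/annotation.tsv \
    --sizes 5,10,15,20 --iterations 3 --seed 1 --out-dir pools/
Rscript inst/scripts/scpool aucc --lists a.txt,b.txt --k 100 --out-dir out/
```

Each subcommand writes its full parameterization to
`<out-dir>/<cmd>_params.json`.

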