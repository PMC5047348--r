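# panelforge

Rational design and evaluation of cost-effective cancer gene sequencing
panels.

## The problem

Targeted sequencing panels trade breadth for depth: every kilobase of
target DNA costs sequencing capacity, so a well-designed panel should
cover the largest possible fraction of tumors with the smallest possible
target region. Off-the-shelf pan-cancer panels often sequence hundreds of
genes — and a megabase or more of DNA — much of which contributes nothing
to detecting the cohort at hand.

`panelforge` designs panels from the observed mutation patterns of a
tumor cohort, for researchers assembling a targeted assay for one or more
cancer types. Its core ideas:

- **Mutational hotspots.** For each candidate gene, an iterative
  algorithm extracts genomic windows of at most *L* bp (default 100)
  with the highest count of protein-affecting mutations (PAMs), removing
  each window's mutations before the next iteration and stopping when no
  site carries ≥ 2 mutations. If the hotspots jointly capture at least a
  minimum fraction of the gene's PAMs (default 80%), the gene enters the
  panel as its hotspots; otherwise its whole coding exome is used.
- **Cumulative mutational frequency (CMF).** Panel items (hotspots or
  whole genes) are ranked greedily: item *n* is the one covering the most
  samples not yet covered, and

  CMF(n) = CMF(n−1) + |{samples with PAMs in item n, none in items 1..n−1}| / |cohort|

- **Tiers.** With *s* the expected per-rank CMF gain (the slope of the
  CMF trend over contributing items), Tier 1 items gain ≥ *s* (≥ 2*s*
  under the stringent option), Tier 2 items gain less but more than zero,
  and Tier 3 items add nothing.
- **Cost-effectiveness.** Any panel — designed here or an external BED —
  is evaluated on any cohort as coverage (fraction of samples with ≥ 1,
  ≥ 2 or ≥ 3 mutated panel items) versus targeted DNA in Kbps.

A seeded simulator generates synthetic cohorts with implanted hotspots
and known ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(panelforge)

models <- simulate_gene_models(30, seed = 2)
cfg    <- simulation_config(n_samples = 200, n_genes = 30, seed = 1)
sim    <- simulate_cohort(cfg, models)
sim$cohort
#> Cohort 'simulated_cohort': 200 samples, 344 mutations (303 PAMs) in 30 genes

d <- design_panel(sim$cohort, gene_list(sim$truth$driver_genes, "driver"),
                  models)
d
#> PanelDesign on 'simulated_cohort' (200 samples)
#>   8 items (5 hotspot, 3 whole-gene); tiers: T1=3 T2=5 T3=0
#>   coverage (k=1/2/3): 0.725 / 0.355 / 0.110; total 4.13 Kbps

head(d$items[c("rank", "item_id", "kind", "tier",
               "marginal_new_samples", "cmf", "length_bp")], 4)
#>   rank        item_id       kind tier marginal_new_samples   cmf length_bp
#> 1    1           G006 whole_gene    1                   40 0.200       998
#> 2    2 G004:hotspot_1    hotspot    1                   25 0.325        45
#> 3    3 G002:hotspot_1    hotspot    1                   23 0.440       100
#> 4    4           G008 whole_gene    2                   16 0.520      1569
```

Reading the table: the top-ranked gene `G006` alone covers 20% of the
cohort with under 1 Kbp of target; the 45-bp hotspot of `G004` adds
another 12.5% of samples. After eight items the panel detects 72.5% of
tumors sequencing only 4.13 Kbps. Exporting and re-evaluating the panel
reproduces the design's numbers exactly:

```r
bed <- tempfile(fileext = ".bed")
write_bed(d, bed)
evaluate_panel(read_panel_bed(bed), sim$cohort,
               driver_catalog = sim$truth$driver_genes, name = "designed")
#> PanelEvaluation 'designed': coverage 0.725 (k2 0.355, k3 0.110),
#>   4.13 Kbps, driver fraction 1.00
```

## Command line

```sh
exec/panelforge simulate --out simdir --seed 11
exec/panelforge design --cohort simdir/cohort.tsv \
    --samples simdir/cohort.tsv.samples \
    --genes simdir/genes_driver.txt:driver \
    --models simdir/exons.bed --out design_out
exec/panelforge evaluate --cohort simdir/cohort.tsv \
    --panel-bed design_out/panel.bed --out eval_out
```

Every run writes its outputs atomically plus a `manifest.json` (command,
flags, input MD5 checksums, version). Exit codes: 0 success, 1 usage
error, 2 data/format error.

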