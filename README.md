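# panreplicon

Replicon-resolved pangenome architecture of multipartite bacterial genomes.

Many bacteria split their genome across a chromosome and a *chromid* — a
large secondary replicon that carries some essential genes but uses
plasmid-type replication machinery. For people studying such genomes
(comparative genomicists working on *Vibrionaceae*-like or
*Pseudoalteromonas*-like families, and anyone asking how replication shapes
gene content), this package turns a set of per-genome tables into three
answers:

1. **Which orthologous clusters are core / softcore / shell / cloud?**
   A cluster present in $k$ of $N$ genomes is core when $k = N$, softcore
   when $\lceil 0.92N\rceil \le k < N$ (≥23 of 25), cloud when $k \le 2$,
   shell otherwise.
2. **Where do those categories sit relative to the replication origin?**
   Each replicon is cut into $S$ equal sectors clockwise from *oriC*
   (sector 1 starts at the origin); per category $c$ and sector $x$ the
   enrichment is the log-ratio of observed to uniform sector probability,

   $$r_{cx} = \log_{10}\frac{\bar n_{cx}/\bar N_c}{1/S},$$

   averaged over the genomes of a replicon class, with Kruskal–Wallis +
   Dunn's post hoc tests (Bonferroni-corrected) flagging significantly
   over-/under-represented sectors. Sector ranks translate into replication
   timing for both unidirectionally and bidirectionally replicated
   replicons.
3. **Is gene dosage visible in expression, and which genes mark the
   chromid?** Per-CDS read counts become RPKM, median-centred
   $\log_2$ maps with a 100-CDS sliding-window trend, per-category
   quartile tables contrasting replicon halves by rank-sum tests, and a
   census of chromid hallmark genes — core clusters located on the chromid
   in every genome — with their distance to the replication terminus.

A seeded synthetic-data generator produces complete multipartite
collections (prevalence spectra, placement bias toward origin or terminus,
dosage gradients with lognormal noise), so the entire pipeline is testable
and calibrated without any downloads.

## Worked example

Simulate a 25-genome collection (1 Mb chromosome with ~600 genes, 1 Mb
unidirectional chromid with ~400 genes) and run the full analysis:

```r
library(panreplicon)
cfg <- sim_config(seed = 42, n_genomes = 25,
                  chromosome_length = 1e6, chromid_length = 1e6,
                  genes_per_chromosome = 600, genes_per_chromid = 400)
res <- run_pipeline(config = cfg)

res$pangenome_summary
#>   category n_clusters
#> 1     core        310
#> 2 softcore        139
#> 3    shell        580
#> 4    cloud       4500
#> 5    total       5529

subset(res$sector_enrichment,
       replicon_class == "chromid_unidirectional" & category == "core")
#>          replicon_class category S sector mean_count summary_log10_ratio timing_rank  flag
#>  chromid_unidirectional     core 6      1      17.12               0.367           0  over
#>  chromid_unidirectional     core 6      2       2.04              -0.556           1 under
#>  chromid_unidirectional     core 6      3       2.20              -0.524           2 under
#>  chromid_unidirectional     core 6      4       2.24              -0.516           3 under
#>  chromid_unidirectional     core 6      5       2.32              -0.501           4 under
#>  chromid_unidirectional     core 6      6      18.16               0.393           5  over
```

Core genes pile up in the late-replicating sector 6 of the chromid (and,
because the terminus of a unidirectionally replicated circle coincides with
its origin, in the adjacent sector 1): the summary log10 ratio is ~0.39
(about 2.5× the uniform expectation) and Dunn's tests flag those sectors as
overrepresented at adjusted p ≤ 0.05, mirroring the planted placement bias.

```r
nrow(res$hallmark_summary)                       # core ∩ always-chromidal
#> [1] 37
sum(res$hallmark_summary$within_window)          # within 10% of the terminus
#> [1] 34

res$replicon_contrast
#>   genome_id replicon_id   n median_rpkm   p_raw   p_adj
#> 1       G01         chd 374         396 0.00839 0.00839
#> 2       G01         chr 632         484 0.00839 0.00839
```

Chromosomal genes are expressed significantly higher than chromidal genes
(median RPKM 484 vs 396, rank-sum adjusted p < 0.01), and
`res$expression_map` / `res$quartile_table` hold the per-CDS map with its
sliding-window trend and the per-category half-replicon quartile contrasts.

With `out_dir =`, every table is written as TSV next to a `manifest.json`
recording inputs, parameters, seed and package version; reruns with the
same seed are byte-identical. Real data enters through the same door:
`run_pipeline(replicon_table =, gene_table =, cluster_table =,
count_table =)` with plain TSVs (GFF3 accepted for gene coordinates via
`read_gene_table()`).

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "panreplicon.R", package = "panreplicon"))')" \
  run-all --seed 42 --out-dir results_run
```

with subcommands `simulate`, `classify`, `sectors`, `expression`,
`hallmark`, `run-all`.

## Package layout

- `R/` — readers/writers (`io_tables`), classification (`pangenome`),
  sector enrichment (`sectors`), rank statistics (`stats`), expression
  dosage (`expression`), hallmark census (`hallmark`), generator
  (`simulate`), orchestration (`pipeline`).
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  built in code).
- `vignettes/replicon-architecture.Rmd` — the models, their assumptions,
  parameter choices and limitations.
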