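# dielshift

Cross-species diel expression rescheduling analysis.

## What it is for

Plants with crassulacean acid metabolism (CAM) invert the day/night rhythm
of stomatal movement relative to C3 plants. One route to candidate genes
behind that inversion is comparative: find ortholog groups whose member in
a CAM species is expressed in the opposite half of the 24-h cycle from its
orthologs in C3 species. `dielshift` implements that screen for anyone with
diel time-course expression matrices (genes × sampling hours, FPKM) for one
CAM species and two C3 species, plus an ortholog-group table linking their
genes.

## The method

Each species' cycle is summarized by two 3-hour windows: *dusk* (hours
flanking lights-off; 10/12/14 h after lights-on for a 12-h light regime,
8/10/12 for a 10-h regime) and *dawn* (22/24≡0/2). Per gene *g*:

1. the profile is reduced to integer pseudo-counts summing to C = 1000
   (largest-remainder rounding of the within-gene relative expression);
2. with `S_W(g)` the count sum over window W and `T_W` the column total
   over all genes, the dusk enrichment p-value is the right tail of the
   Fisher exact test on
   `[[S_dusk(g), S_dawn(g)], [T_dusk − S_dusk(g), T_dawn − S_dawn(g)]]`,
   and symmetrically for dawn;
3. Benjamini–Hochberg FDR is controlled per species × window at α = 0.05;
   the gene's phase is the rejected window, else `neither`.

An ortholog group is **rescheduled** when some (CAM, C3-A, C3-B) gene trio
satisfies both:

- **criterion 1** — the CAM gene is dawn- or dusk-enriched and both C3
  orthologs are enriched in the opposite window;
- **criterion 2** — Spearman ρ(CAM, C3) < −0.6 for both C3 orthologs and
  ρ(C3-A, C3-B) > 0.6 (strict inequalities, mid-rank ties).

Species sampled every 4 h are first resampled per gene onto the common 2-h
grid with a not-a-knot cubic spline. A synthetic-study generator with
planted anti-phase ground truth makes every stage testable without any
external download, and a keyword/E-value filter post-processes
literature-homology hit records into per-species summaries and the
"underexplored gene" partition (literature-linked genes lacking both GO
annotation and known-key status).

## Worked example

Simulate a 50-group study (5 planted anti-phase), run the pipeline, and
look at the verdicts:

```r
library(dielshift)

study <- generate_study(synthetic_spec(n_ogs = 50, n_rescheduled = 5,
                                       seed = 42))
paths <- write_study(study, "demo")
w12 <- list(dusk = c(10, 12, 14), dawn = c(22, 24, 2))
cfg <- run_config(
  species = list(
    list(id = "cam", role = "cam", expression = paths$expression_cam,
         windows = w12),
    list(id = "c3a", role = "c3", expression = paths$expression_c3a,
         windows = w12),
    list(id = "c3b", role = "c3", expression = paths$expression_c3b,
         windows = w12)),
  ortholog_groups = paths$ortholog_groups, outdir = "demo/out")
man <- run_all(cfg)
#> [cam] 50 genes in, 0 negative removed, 0 low-expression removed, 50 tested
#> [c3a] 50 genes in, 0 negative removed, 0 low-expression removed, 50 tested
#> [c3b] resampled 6 -> 12 time points (6 values clamped to 0)
#> [c3b] 50 genes in, 0 negative removed, 0 low-expression removed, 50 tested
#> 50 ortholog groups: 50 evaluated (50 combinations), 0 skipped, 4 rescheduled

res <- read_results("demo/out/rescheduling.tsv", "rescheduling")
head(subset(as.data.frame(res), rescheduled,
            select = c(og_id, cam_gene, cam_phase, c3_phaseA,
                       rho_cam_A, rho_AB)))
#>    og_id   cam_gene cam_phase c3_phaseA rho_cam_A   rho_AB
#> 1 OG0001 OG0001_cam      dusk      dawn -0.888112 0.944056
#> 2 OG0002 OG0002_cam      dusk      dawn -0.874126 0.916084
#> 3 OG0003 OG0003_cam      dusk      dawn -0.741259 0.804196
#> 5 OG0005 OG0005_cam      dusk      dawn -0.930070 0.881119
```

Four of the five planted groups are recovered at these noise settings
(σ = 0.2 on the log scale): their CAM gene is dusk-enriched, both C3
orthologs dawn-enriched, the CAM–C3 correlations are below −0.6 and the
C3–C3 correlation above 0.6. The missed group's evidence is still in
`rescheduling.tsv`, with its criterion flags showing which threshold
failed. `demo/out/` also holds the per-species enrichment tables, the
group-level verdicts, and `manifest.json` with the per-stage gene counts.

Every tuning knob (windows per species, α, ρ thresholds, filter
thresholds, pseudo-count scale) lives in the config; `read_run_config()`
loads the same structure from YAML.

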