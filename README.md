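# miriscshift

Does nuclear relocalization of AGO2 release its cytoplasmic mRNA targets
from miRNA repression? `miriscshift` is an R package for transcriptomics
researchers asking exactly that: it implements, as one tested pipeline, the
inference chain from AGO2-eCLIP binding evidence to de-repressed candidate
targets —

1. **Seed-family scanning** — group miRNAs into families by their nt 2–8
   seed, rank families by TMM-normalized CPM abundance, and scan cytoplasmic
   AGO2-eCLIP peaks inside 3′UTRs for canonical strong sites
   (8mer / 7mer-m8 / 7mer-A1, Watson–Crick only);
2. **Differential expression** — TMM normalization and a negative-binomial
   exact test (conditional distribution of one group's sum given the total;
   binomial in the Poisson limit) between low- and high-density growth;
3. **Exon–intron split analysis (EISA)** — per-gene NB log-linear model
   `count ~ condition * count_type` with a likelihood-ratio test on the
   interaction, separating transcriptional (Δintron) from
   post-transcriptional (Δdiff = Δexon − Δintron) regulation at FDR < 0.001;
4. **mRNA half-lives** — 2^(−ΔΔCt) quantification of actinomycin-D decay
   courses against reference genes, with t½ = ln 2 / k from a log-linear
   fit;
5. **Absolute quantitation** — AGO2 copies per cell per compartment from
   densitometry standard curves (copies = (intensity − b)/slope × 10⁻⁹ /
   M × N_A / cells loaded), giving the nuclear:cytoplasmic ratio.

A first-class synthetic-data generator (`simulate_dataset()`) plants known
candidates, seed sites, effect sizes, half-lives and copy numbers, so the
entire pipeline is testable end-to-end with no downloads. Everything is
tibble-in / tibble-out and pipe-friendly; fitted objects have `tidy()` /
`glance()` methods and result tables have `autoplot()` methods.

## Worked example

```r
library(miriscshift)

cfg <- pipeline_config(sim = sim_config(rng_seed = 42), rng_seed = 42)
res <- run_all(cfg, "demo_run")
cat(res$report, sep = "\n")
```

```
miRISC candidate refinement summary
genes tested (DE): 500
top families used: 20
candidate targets: 50
  upregulated (log2FC > 0, FDR < 0.05): 50
  post-transcriptional by EISA (FDR < 0.001): 24
half-life fits: 8 (8 estimable)
nuclear:cytoplasmic copy ratios: high=12.00, low=2.00
```

The 500-gene simulation plants 50 miRISC candidates; all 50 pass the
peak/site/compartment refinement and are upregulated at high density, and
24 additionally clear the stringent EISA post-transcriptional call. The
ranked candidate table carries the evidence per gene:

```r
head(dplyr::select(res$candidates, gene_id, n_utr_peaks, n_utr_sites,
                   log2fc, fdr, upregulated, eisa_class), 5)
#>   gene_id n_utr_peaks n_utr_sites log2fc      fdr upregulated eisa_class
#> 1 G0354             3           6   2.29 3.55e-17 TRUE        post_transcriptional
#> 2 G0428             3           6   1.81 5.85e-18 TRUE        unclassified
#> 3 G0054             3           6   1.77 1.33e- 7 TRUE        unclassified
#> 4 G0069             3           6   1.75 2.93e-14 TRUE        unclassified
#> 5 G0475             3           6   1.39 1.07e- 8 TRUE        unclassified
```

Cytoplasmic transcripts of the planted targets roughly double their
half-life at high density (planted 6 h → 12 h):

```r
dplyr::filter(res$halflives, fraction == "cytoplasm")
#>   gene    fraction  condition      k t_half_h    se_k r_squared n_points flag
#> 1 TARGET1 cytoplasm high      0.0607    11.4  0.00140     0.985       30 ok
#> 2 TARGET1 cytoplasm low       0.119      5.81 0.00271     0.987       27 ok
#> 3 TARGET2 cytoplasm high      0.0566    12.2  0.00150     0.981       30 ok
#> 4 TARGET2 cytoplasm low       0.117      5.93 0.00255     0.988       27 ok
```

and the absolute quantitation stage recovers the planted compartment shift:
a nuclear:cytoplasmic ratio of 2.0 at low density rising to 12.0 at high
density (`res$quant$ratios`), from whole-cell pools of 70,000 and 88,000
copies per cell.

Individual stages compose with the pipe, e.g.:

```r
sim <- simulate_dataset(sim_config(rng_seed = 1))
fam <- group_families(sim$mirnome$mirnas, sim$smallrna, design = sim$design)
de  <- nb_exact_test(sim$exonic, sim$design)
annotate_peaks(sim$peaks, sim$annotation, fam) |>
  refine_candidates(fam, de, pipeline_config())
```

`autoplot()` on a `de_result` draws the volcano plot, on an `eisa_result`
(after `classify_regulation()`) the Δintron–Δexon plane with the best-fit
line, and `plot_decay()` the decay courses.

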