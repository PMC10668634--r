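# oncostates

Transcriptomic characterization of oncogene-induced *dual-identity*
lung epithelial cells, as an R package. When oncogenic Kras is
activated in alveolar type II (AT2) cells, a population emerges that
co-expresses AT2 markers (Sftpc) and type I (AT1) markers (Rage,
Podoplanin). `oncostates` implements the downstream computational
chain used to characterize such dual-positive cells from sorted-
population bulk RNA-seq — and a synthetic-data module with planted
ground truth so every stage is testable without any download.

The stages, each an exported function over validated S4 containers:

- **NMF sample clustering** (`fitNmf`, `assignClusters`): Lee–Seung
  multiplicative updates minimizing ‖V − WH‖_F, best of seeded
  restarts; samples cluster by their dominant factor (F0, F1, F2, ...).
- **Signature derivation** (`deriveSignature`, `deriveAll`): one-vs-rest
  differential expression on reference panels; the top-100 genes by
  variance-floored signal-to-noise ratio (μ_A − μ_B)/(s_A + s_B) form
  each cell-type gene set.
- **ssGSEA** (`rankNormalize`, `enrichmentScore`, `scoreCollection`):
  per-sample scores from the running-sum difference between the
  weighted in-set ECDF and the out-of-set ECDF of rank-normalized
  expression, ES = Σ_i [P_in^w(i) − P_out(i)], weight w = 0.75.
- **Information-coefficient association** (`informationCoefficient`,
  `permutationTest`, `associateCollection`):
  IC = sign(ρ)·√(1 − e^(−2·MI)) with MI from a bivariate Gaussian KDE;
  for Gaussian data IC = |ρ| with ρ's sign. Significance by seeded
  label permutations with add-one correction, BH FDR across sets.
- **Onco-GPS state maps** (`buildMap`, `projectSamples`): NMF of an
  oncogene-responsive gene module over a cell-line panel; factors
  become nodes on the unit circle, reference samples get k-means
  states, and new samples are placed at the power-normalized pull
  xy = Σ_j c_j·w_j^p / Σ_j w_j^p (p = 2) with the state of their
  nearest reference neighbour in weight space.
- **Differential expression** (`differentialExpression`,
  `benjaminiHochberg`): per-gene two-sample t-tests (pooled Student by
  default, Welch optional) with BH FDR and SNR.
- **Bench quantifications** (`foldChange`, `gateCells`,
  `compareFractions`): delta-delta-CT fold change FC = 2^(−ΔΔCT),
  marker-threshold gating into population percentages, and
  Haldane-corrected odds ratios with Fisher exact p.
- **Synthetic data** (`simulateStudy`, `simulateReferencePanels`,
  `simulateKrasPanel`, `simulateCells`, `simulateCtTable`): planted
  gene programs, latent cell-line states, marker-intensity mixtures
  and CT tables, all pure functions of (parameters, seed).
- **Pipeline** (`runPipeline`): the full synthetic end-to-end run from
  one (YAML-able) config, writing TSV/GMT/JSON artifacts plus a
  hash-stamped manifest; reruns are byte-identical.

File formats: TSV and GCT 1.2 for expression, GMT for gene sets, TSV
for annotations and CT tables, JSON for maps and manifests.

## Worked example

```r
library(oncostates)

design <- defaultStudyDesign(seed = 7)   # 2000 genes, 3 x 3 samples
study  <- simulateStudy(design)
study$matrix
#> ExpressionMatrix: 2000 genes x 9 samples [log2 scale]
#>   samples: typeI_1, typeI_2, typeI_3, typeII_1, typeII_2 ...

model <- fitNmf(study$matrix, k = 3, seed = 7)
table(assignClusters(model), study$annotation$group)
#>      dualpos typeI typeII
#>   F0       0     3      0
#>   F1       0     0      3
#>   F2       3     0      0
```

The nine samples cluster perfectly by cell type at rank 3. Scoring the
signatures derived from the synthetic developmental reference panels
and associating them with the dual-positive indicator:

```r
panels <- simulateReferencePanels(seed = 1)
sigs   <- deriveAll(panels, nTop = 100)
scores <- scoreCollection(study$matrix, sigs, w = 0.75)
pheno  <- setNames(as.numeric(study$annotation$group == "dualpos"),
                   study$annotation$sample_id)
associateCollection(scores, pheno, nPermutations = 1000, seed = 7)
#>               set_name    ic  p_perm fdr_bh
#> 1     E11_5_progenitor 0.849 0.00899  0.030
#> 2     E17_5_progenitor 0.848 0.00999  0.030
#> 3            adult_AT1 0.256 0.49351  0.494
#> 4 E17_5_differentiated 0.255 0.48052  0.494
#> 5 E11_5_differentiated 0.237 0.44156  0.494
#> 6            adult_AT2 0.236 0.43556  0.494
```

Both progenitor signatures — the sets carrying the planted embryonic
program — top the ranking with IC ≈ 0.85 at the permutation floor,
while every differentiated-epithelium signature sits far below: the
synthetic dual-positive samples are "transcriptionally closer to
progenitors", exactly as planted. Finally, gating 100,000 simulated
epithelial cells whose dual-positive fraction is the literature-reported
2.6%:

```r
gateCells(simulateCells(epithelialPopulationSpec(seed = 7)),
          epithelialGate())
#>   population count percent
#> 1      typeI 32402  32.402
#> 2     typeII 64985  64.985
#> 3    dualpos  2612   2.612
#> 4   negative     1   0.001
```

The gate recovers 2.612% against the 2.6% ground truth, within
binomial sampling error.

The full chain, including the Onco-GPS map build and projection,
differential expression and qPCR fold changes, runs from one config:

```r
runPipeline(defaultPipelineConfig(seed = 7), outDir = "out")
```

## Package layout

- `R/` — S4 classes (`ExpressionMatrix`, `GeneSet(Collection)`,
  `EnrichmentMatrix`, `NMFModel`, `OncoGPSMap`) and one file per
  analysis stage.
- `vignettes/oncostates-methods.Rmd` — the methods vignette: models,
  assumptions, parameter defaults, numerical choices, and what the
  synthetic generators do and do not emulate.
- `inst/extdata/default_config.yaml` — the committed default pipeline
  configuration.
- `tests/testthat/` — unit, property and acceptance suites.
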