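# coumarinQSAR

2D-QSAR modelling of the anti-proliferative activity of seventeen
coumarin-6-sulfonamide derivatives against HepG2, MCF-7 and Caco-2
cancer cell lines.

## What it does, and for whom

For medicinal/computational chemists working with small assay panels,
the package implements the complete descriptor-to-model pipeline behind
this compound series:

* **Structures** — SMILES/SDF input, a plain molecule data model, seeded
  deterministic 3D conformer generation; the 17 synthesized compounds
  (4a–b, 6, 8a–d, 9, 11a–d, 13a–b, 15a–c) ship as validated fixtures
  with their IC50 tables.
* **Descriptors** — Kier–Hall connectivity indices (`CHI_0` … `CHI_3_C`),
  atomic-composition information content (`IAC_Mean`, `IAC_Total`),
  Gasteiger (PEOE) partial charges, dipole components in the
  principal-inertia frame, Shrake–Rupley solvent-accessible surface
  area, the Stanton–Jurs CPSA family (`Jurs_PPSA_*`, `Jurs_PNSA_*`, …)
  and shadow projection descriptors (`Shadow_YZ`, `Shadow_Ylength`, …).
* **Model building** — genetic function approximation (GFA) over
  descriptor subsets scored by Friedman's lack-of-fit,
  LOF = (SSE/m) / (1 − (c + d·p)/m)², and multiple linear regression
  with r², adjusted r², PRESS and leave-one-out q² = 1 − PRESS/SST.
* **Published models** — the two fixed regression equations ship as
  model files and drive prediction, residual and external-validation
  tables:

  ```
  HepG2:  pIC50 = −0.7926 − 1.598·CHI_3_C + 0.2775·Dipole_Y
                  − 0.03102·Jurs_PNSA_3 + 0.04829·Shadow_YZ
  Caco-2: pIC50 = −6.6095 − 3.7896·IAC_Mean + 0.11713·Dipole_X
                  − 0.1615·Shadow_Ylength
  ```

  with pIC50 = −log10(IC50 in µM).

## Worked example

```r
library(coumarinQSAR)

fx <- load_fixtures()          # the 17 compounds with activities
fx[["13a"]]$ic50
#>    cell_line ic50_um   se censored
#> 37     HepG2    3.48 0.28    FALSE
#> 38      MCF7   83.23 6.85    FALSE
#> 39    Caco-2   83.43 7.04    FALSE

pic50(3.48)                    # micromolar IC50 -> pIC50
#> [1] -0.5415792

published_models()$HepG2
#> <qsar_model> HepG2: pIC50 = -0.7926 -1.598*CHI_3_C +0.2775*Dipole_Y
#>                              -0.03102*Jurs_PNSA_3 +0.04829*Shadow_YZ

# printed training table: residual bookkeeping and model statistics
t4 <- training_table()
hep <- t4[t4$cell_line == "HepG2", ]
rt <- residual_table(setNames(hep$experimental, hep$compound),
                     setNames(hep$predicted, hep$compound))
round(attr(rt, "lse"), 4)                         # mean squared residual
#> [1] 0.0168
round(cor(hep$experimental, hep$predicted)^2, 3)  # r2
#> [1] 0.94

# descriptors from structures (seeded, reproducible)
dt <- descriptor_table(lapply(fx[c("4a", "13a")], `[[`, "molecule"),
                       seed = 1)
round(dt[, c("CHI_3_C", "IAC_Mean", "Dipole_Y", "Jurs_PNSA_3",
             "Shadow_YZ")], 3)
#>     CHI_3_C IAC_Mean Dipole_Y Jurs_PNSA_3 Shadow_YZ
#> 4a    3.531    1.936    1.131     -56.304     57.60
#> 13a   2.961    1.760   -0.201     -41.356     79.57

# every desk-scale printed quantity, recomputed and checked
tail(format_report(reproduce_report()), 1)
#> [1] "0 of 73 checks failed"
```

The mean squared residual (0.0168) and r² (0.940) recomputed from the
printed experimental/predicted columns are the published values; the
report covers all 73 such checks (31 pIC50 cells, 27 residuals, the
r²/adjusted-r² identities, selectivity indices, marker fold changes and
the annexin-positive fold).

A thin command-line wrapper over the same functions is installed at
`inst/cli/coumarin-qsar` with subcommands `descriptors`, `fit`, `gfa`,
`predict`, `validate`, `simulate` and `reproduce`.

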