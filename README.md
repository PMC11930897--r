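# lungrads

Risk stratification of pure ground-glass pulmonary nodules (pGGNs) with
Lung-RADS rule sets, and the diagnostic-accuracy machinery to compare them.

Low-dose CT screening detects large numbers of pGGNs — hazy nodules without
a solid component — whose management hinges on whether the underlying lesion
is invasive (minimally invasive or invasive adenocarcinoma, a surgical
candidate) or noninvasive (benign, inflammatory, or an adenomatous precursor
lesion, suitable for follow-up). Diameter-only Lung-RADS rules stratify
pGGNs poorly: almost all screening-detected pGGNs fall below the 20 mm /
30 mm cutoffs and land in the low-risk categories regardless of pathology.
The complementary cLung-RADS v2022 system additionally grades the
nodule–vessel relationship (GVR): type I (vessels pass beside the nodule),
II (vessels pass through unchanged), III (vessels pass through with
localised thickening), IV (increased, thickened, twisted, convoluted
vessels).

This package is for biostatisticians and screening-programme methodologists
who want to reproduce, stress-test, or extend that kind of rule-based
stratifier on nodule-level tabular data.

## The rule sets

| Category | Lung-RADS 1.0 | Lung-RADS v2022 | cLung-RADS v2022 |
|---|---|---|---|
| 2 | d < 20 mm | d < 30 mm | GVR I and d < 30 mm |
| 3 | d ≥ 20 mm | d ≥ 30 mm | GVR I and d ≥ 30 mm; GVR II |
| 4a | — | — | GVR III (any size) |
| 4b | — | — | GVR IV (any size) |
| 4x | category 3 with other suspicious malignant imaging features | same | categories 3/4a/4b with such features |

`d` is the mean diameter, the average of the maximum axis and its
perpendicular minor axis. A nodule is called *invasive* when its category
is 4a–4x under cLung-RADS v2022, and 4x under the baselines (the only
reachable category ≥ 4 for pGGNs there).

Performance against pathology is summarised by recall, precision, accuracy,
F1, the weighted F-beta

F_β = (1 + β²)·P·R / (β²·P + R),  β = 0.5 by default,

the Matthews correlation coefficient

MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

and the tie-corrected ordinal ROC AUC over category ranks, with DeLong
variances and paired DeLong tests for correlated AUCs, plus ICC(2,1) for
inter-rater agreement.

## Worked example

```r
library(lungrads)

# rebuild the benchmark training cohort (n = 169) from its published
# confusion cells and evaluate the complementary system on it
co <- fixture_exact_cohort(
  calibration_target("CLUNGRADS2022", tp = 131, fp = 14, fn = 7, tn = 17),
  label = "training")
evaluate_system(co, "CLUNGRADS2022")
```

```
CLUNGRADS2022 on cohort 'training' (n = 169 nodules)
Confusion cells: TP=131 FP=14 FN=7 TN=17 (n=169)
  Recall:     94.9%
  Precision:  90.3%
  MCC:        55.2%
  F1:         92.6%
  F_beta (beta=0.5): 91.2%
  Accuracy:   87.6%
AUC 0.749 (95% CI 0.658-0.840; 138 invasive / 31 noninvasive)
```

Recall 94.9% says the 4a–4x cutoff catches 131 of the 138 invasive lesions;
precision 90.3% says 131 of the 145 positive calls are confirmed invasive;
MCC 55.2% is the chance-corrected correlation computed exactly from the
cells. A synthetic screening cohort with the same composition (GVR mix,
lognormal diameters, invasiveness conditionals) comes from the seeded
generator:

```r
cohort <- generate_cohort(generator_config("pooled"), seed = 7)
print(cohort)
compare_models(cohort, "CLUNGRADS2022", "LUNGRADS10")
```

There is also a command-line pipeline over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/lungrads.R", package = "lungrads"))')
Rscript "$CLI" simulate --set pooled --seed 7 --out cohort.csv
Rscript "$CLI" evaluate --in cohort.csv --out report.md --format md
Rscript "$CLI" agreement --in ratings.csv
```

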