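# homeovert

Homeotic transformations of the human vertebral column — rule-based
pattern classification, ordinal severity scoring, malformation coding,
and severity-association statistics, with a seeded synthetic cohort
generator that stands in for the original autopsy archive.

## The scientific problem

Changes of regional vertebral identity (homeotic transformations) are
remarkably common in deceased human fetuses and infants: cervical ribs on
the seventh vertebra, rudimentary or absent first or twelfth ribs, lumbar
ribs, and shifts of the lumbo-sacral boundary. These variations mark a
disturbance of early anterior–posterior patterning of the paraxial
mesoderm and travel together with congenital malformations across many
organ systems. Quantifying that coupling requires three ingredients this
package provides for epidemiologists and developmental biologists working
with perinatal radiographic/autopsy material:

1. **A deterministic rule engine** that reads per-vertebra, per-side rib
   observations and decides which of the three investigated boundaries
   (cervico-thoracic, thoraco-lumbar, lumbo-sacral) are shifted. The
   eight resulting pattern classes are scored on an ordinal severity
   scale reflecting anteriority and extent of the disturbance:

   | pattern | R | LS | TL | TL_LS | CT | CT_LS | CT_TL | CT_TL_LS |
   |---------|---|----|----|-------|----|-------|-------|----------|
   | severity| 0 | 1  | 3  | 4     | 6  | 7     | 8     | 9        |

   Values 2 and 5 are never assigned; any cervico-thoracic change scores
   at least 6. Transitional vertebrae (e.g. a cervical rib no longer than
   half the adjacent thoracic rib) count half in each neighbouring
   region, so regional counts come in half units and always sum to the
   presacral count.

2. **Malformation coding** of autopsy findings into primary organ-system
   flags (ten systems: BP, CV, CF, DS, LD, MS, NS, SK, UG, VBW) under
   primary/secondary causal rules — a tracheo-esophageal fistula counts
   for the digestive system only, holoprosencephaly for the nervous
   system, lung hypoplasia is not counted when caused by a diaphragmatic
   hernia, and so on — plus germ-layer (endoderm/mesoderm/ectoderm) and
   morphogenetic-process (midline, neural crest, left–right,
   segmentation) derivations from an editable coding map.

3. **Association statistics**: simple correspondence analysis of
   malformation-by-pattern contingency tables (SVD of the standardized
   residuals `S = D_r^{-1/2}(P - rc')D_c^{-1/2}`; principal inertias are
   squared singular values and total inertia is the Pearson chi-square
   over the grand total), and binomial GLMs with logit link fitted by
   iteratively reweighted least squares, `logit P(outcome) = a + b *
   severity`, with Wald tests, overdispersion checks, pairwise slope
   comparisons, interaction likelihood-ratio tests and frequency-trend
   correlations.

Because the underlying autopsy data are archival and not deposited, the
package ships a **synthetic cohort generator** (`generate_cohort()`)
whose defaults reproduce the published cohort structure — the
eight-class pattern multinomial, per-system malformation risks
logit-linear in severity with published slopes and case counts, and
independent per-system missingness — so every stage of the pipeline is
testable end to end.

## Worked example

```r
library(homeovert)

# classify the four example columns shipped with the package
path <- system.file("extdata", "example_patterns_synthetic.csv",
                    package = "homeovert")
cls <- classify_cohort(read_morphology(path))
cls[, c("subject_id", "pattern", "severity", "presacral",
        "cervical", "thoracic", "lumbar")]
#>   subject_id      pattern  severity presacral cervical thoracic lumbar
#> 1 ex_regular      R               0        24      7       12      5
#> 2 ex_cervical_rib CT              6        24      6.5     12.5    5
#> 3 ex_ct_tl        CT_TL           8        24      6.5     12      5.5
#> 4 ex_ct_tl_ls     CT_TL_LS        9        23      6.5     12      4.5
```

The regular column scores 0; a lone cervical rib makes the seventh
vertebra transitional (half cervical, half thoracic) and scores 6;
adding rudimentary twelfth ribs scores 8; adding a lumbo-sacral shift
(only 23 presacral vertebrae) scores 9.

A full synthetic analysis (1062 subjects, seed 101 — the numbered
scripts under `analysis/` run exactly this) classifies every subject,
codes the findings, and fits the association models:

```
four_level grouping: dimension 1 explains 92.3 % of the inertia
  first axis, malformation rows (left to right):
    No-Mal < NS < CV < VBW < UG < BP < LD < DS < MS < CF < SK
Severity x germ-layer interaction: chi2 = 3.817, df = 2, p = 0.15
Trend of regular-pattern frequency across bands: R = -0.96 (p = 0.00883)
```

The no-malformation group clusters with the regular pattern at one end
of the first correspondence axis and the craniofacial/skeletal groups
with the most abnormal patterns at the other; the regular-pattern
frequency falls steeply with the number of affected organ systems; the
germ layer of origin shows no significant interaction with severity.

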