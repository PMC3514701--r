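---
title: "Methods: vertebral pattern classification, severity scoring and association models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertebral pattern classification, severity scoring and association models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeovert)
```

This vignette is the package's own account of its models and the design
choices behind them: what the rule engine decides and why, what the
synthetic cohort generator emulates (and what it deliberately does not),
how the correspondence analysis and the IRLS logistic fits are computed,
and where the genuinely open choices were settled.

## The rule engine

A vertebral column enters as long-format rows (one per
subject–vertebra–side) holding the rib state (`absent`, `tp_enlarged`,
`present`), the rib length as a fraction of the adjacent thoracic rib,
a flag for an enlarged transverse process exceeding that of the first
thoracic vertebra, a sacral-attachment flag, and an observer flag for a
transitional lumbo-sacral vertebra. Only the presacral portion — all
vertebrae anterior to the first sacral-attached one — is analysed, and
ordinals count caudally from the atlas so that the presacral count is
simply the list length.

Three boundaries can shift:

* **Cervico-thoracic (C-T).** Any rib on the seventh vertebra marks a
  posteriorized seventh vertebra: a rib of at most half the adjacent
  thoracic rib's length makes it transitional; a longer rib (rare)
  gives it full thoracic identity. An enlarged transverse process
  qualifies as a rudimentary cervical rib only when it exceeds the
  transverse process of the first thoracic vertebra. All of these are
  anterior C-T shifts; a rudimentary (< 0.5 of the adjacent rib) or
  absent first thoracic rib is a posterior shift.
* **Thoraco-lumbar (T-L).** A rudimentary or absent rib at the twelfth
  thoracic position is an anterior shift; any rib on the vertebra
  caudal to the twelve thoracic positions (a lumbar rib) is a posterior
  shift.
* **Lumbo-sacral (L-S).** Shifted when the presacral count differs from
  24 or the observer flagged a transitional lumbo-sacral vertebra. The
  flag is an input, not an inference: the L-S transition is read from
  vertebral shape and position on the radiograph, a judgement the data
  model should record rather than reconstruct.

The three shift flags map bijectively onto eight pattern classes, and
the classes onto the ordinal severity scale 0/1/3/4/6/7/8/9. The scale
encodes two assumptions: anterior changes are graver than posterior
ones (any C-T change scores at least 6), and each additional shifted
boundary reflects a longer developmental disturbance (within the C-T
and non-C-T halves, severity rises with the number of boundaries).
Laterality never changes the class: a unilateral cervical rib and
bilateral ones are the same pattern.

Numerical edge rules, fixed once:

* A ratio of exactly 0.5 is *not* rudimentary (the rule is strictly
  "less than half") and, at the seventh vertebra, *not* thoracic
  identity (strictly "longer than half"). Exactly-half ribs are
  therefore full at thoracic boundary positions and transitional at the
  seventh vertebra.
* A full-length seventh-vertebra rib still sets the C-T flag: every
  seventh-vertebra rib is a C-T boundary change; the rare full-identity
  case gets no separate severity.
* Conflicting sides (one side thoracic identity, the other normal) are
  classified by the more severe side, with a warning.
* When anterior and posterior evidence co-occur at one boundary the flag
  is set once, direction anterior.
* Columns with fewer than 22 or more than 26 presacral vertebrae are
  classified and counted but flagged `extreme`; such columns reflect
  absence of formation (caudal regression, acephalus) rather than
  patterning, and downstream users can filter on the flag.
* A non-contiguous rib-bearing block triggers a `segmentation-suspect`
  warning; regional counts are still returned.

Regional counts assign each vertebra a unit split across regions:
transitional vertebrae contribute 0.5 to each neighbour, full identity
shifts a whole unit, so cervical + thoracic + lumbar equals the
presacral count exactly, by construction — the property tests assert
this for every generated column.

## Malformation coding

Findings are controlled-vocabulary terms mapped to exactly one primary
organ system. The primary/secondary causal rules are hard-coded because
they are substantive, not configurational: tracheo-esophageal fistulas
count for the digestive system (the trachea and esophagus both derive
from the primary gut); skeletal dysplasias for the skeleton;
holoprosencephaly for the nervous system; limb reduction and polydactyly
for the limbs; lung hypoplasia is secondary when caused by skeletal
dysplasia, diaphragmatic hernia or oligohydramnios; anything attributed
to hypoxic stress is secondary. Secondary findings are never counted, so
removing one cannot change the affected-system count.

Germ-layer and process involvement derive from the primary findings
only, through a coding map that ships as an editable YAML default. The
map is a considered assignment (e.g. holoprosencephaly involves midline
patterning and neural crest development, with the malformed structures
ectodermal; hemivertebrae and rib fusions are segmentation defects), but
no published assignment table exists to validate it against beyond
marginal frequencies — all layer- and process-level analyses are
therefore *map-relative*, and the map travels with the config so users
can substitute their own.

Systems scored non-available (maceration, autopsy not approved) get no
flag and enter no denominator; missingness is handled per outcome, not
listwise. A subject whose only findings are secondary lands in the
no-malformation group — the alternative (a separate "secondary-only"
stratum) is not distinguishable in the data model and is flagged here as
a known coding choice.

## The synthetic cohort generator

The generator's defaults are the study conditions, fixed once:

* **Cohort size** 1062 — the number of analysable columns.
* **Pattern multinomial**: 20.6 % regular, 3.4 % isolated L-S, 8.6 %
  T-L with or without L-S, 67.4 % C-T-involving, of which 33.4 % also
  T-L and 10.6 % all three boundaries. Composite frequencies (TL with
  TL_LS, CT with CT_LS) are split 50:50 by default — the only free
  choice the published marginals leave open — and the split is a config
  parameter.
* **Morphology synthesis** is class-exact: the emitted ribs, ratios and
  lumbar counts always classify back to the latent class (tested
  exhaustively). Within a class the generator randomizes what the
  marginals do not pin down: anterior vs posterior realisation of the
  C-T shift (85.5 % anterior, from the 9.8 %-of-67.4 % share of
  first-rib cases), anterior vs posterior T-L realisation (80 %
  anterior: rudimentary/absent twelfth ribs are described as the usual
  finding), laterality (50 % bilateral), rudimentary vs absent boundary
  ribs (60:40), the enlarged-transverse-process presentation (10 % of
  anterior C-T shifts), the rare long cervical rib (2 %), and the L-S
  realisation (23 or 25 presacral vertebrae or a flagged transitional
  vertebra at 24, 45/35/20). These shares are realism choices, set once
  and documented here, not fitted quantities.
* **Malformation events** are Bernoulli per system, logit-linear in the
  numeric severity score with the published per-system slopes; the
  intercepts are root-found so the expected affected count among
  available subjects matches the published case count at the reference
  size of 1062. Severity enters generation exactly as it enters the
  fitted model — as its numeric scale value — so the generating slope
  and the estimand coincide.
* **Missingness** is independent per system at 12 % (roughly the
  published available-case denominators); the simplest mechanism
  consistent with per-system "non-available" scoring.
* **Sex and gestational age** (589:460:13 male:female:unknown; truncated
  normal, mean 26.6, SD 10.4, range 13–92 weeks) have no effect on
  pattern class, matching the reported null checks; the chi-square
  property test verifies the independence.

One root seed drives per-stage substreams (pattern draw, morphology,
events, missingness), so regenerating any stage is reproducible in
isolation and two runs with one seed produce byte-identical CSVs.

What the generator does **not** emulate: radiographic noise and observer
disagreement (all generated columns are evaluable), ossification-age
effects, correlated missingness across systems, secondary findings and
cause contexts (all generated findings are primary), and any dependence
between malformation events beyond their shared severity. Passing tests
therefore demonstrate the correctness and calibration of the pipeline's
logic under the study's marginal structure — not robustness to
real-world measurement error. One consequence worth naming: because the
generator produces per-system events independently given severity, the
implied slope of the *no-malformation* indicator is steeper than the
published −0.11 (the complement of ten independent events concentrates
faster); the no-malformation slope is therefore recovered in a direct
single-outcome simulation, not from the full generator.

## Correspondence analysis

`correspondence_analysis()` is a from-scratch simple CA: with
correspondence matrix \(P\), row and column masses \(r, c\), it takes
the SVD of \(S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}\); principal inertias
are squared singular values, principal coordinates are mass-rescaled
singular vectors scaled by singular values, and the total inertia equals
the Pearson chi-square over the grand total (asserted to 1e-10 against
an independent chi-square computation, with the eigen-decomposition of
\(S^\top S\) and an established CA implementation as cross-checks).
Zero-margin rows or columns are dropped with a warning rather than
failing the run — small simulated cohorts can lack a malformation class.
The SVD sign is arbitrary, so the first axis is anchored with the
no-malformation row on the negative side; an independence table (total
inertia below 1e-12) is flagged degenerate instead of interpreted.

Both published contingency groupings are supported: eight pattern
classes, or four groups merging each class with its `_LS` counterpart
(ignoring the harder-to-read lumbo-sacral boundary). Rows are the ten
organ systems plus the no-malformation group; a subject counts once in
every system row it is affected in, without down-weighting
multi-system subjects — the tables are count tables of affected
subjects, not a partition.

## Association models

`glm_logit_irls()` fits the Bernoulli logit model by iteratively
reweighted least squares: working response
\(z = \eta + (y - \mu)/w\) with weights \(w = \mu(1-\mu)\), iterated to
a relative deviance change below 1e-8 (maximum 100 iterations), with
Wald standard errors from the inverse Fisher information. The unit tests
pin the fit against both the reference ML implementation and a
brute-force likelihood maximization. Coefficients exceeding 15 in
magnitude, or non-convergence, set a separation flag with a warning.
Severity enters as a single numeric covariate over
\(\{0,1,3,4,6,7,8,9\}\): the published per-outcome summaries are single
slopes, so "eight levels" is read as eight scale values, and a
factor-coded severity can be obtained through the covariate interface
when wanted.

Slope comparisons between two outcome groups stack the observations and
read the difference off the group-by-severity interaction in a joint
model (the published pairwise t statistics do not specify their
mechanics; a Wald interaction contrast is the standard construction).
The severity-by-factor interaction test is a likelihood-ratio test with
levels − 1 degrees of freedom. Overdispersion is the Pearson chi-square
over residual degrees of freedom, with a configurable 1.5 verdict
threshold; because extra-binomial variation is invisible in ungrouped
0/1 data, the check accepts an optional grouping vector and then pools
observed and expected events per group. Frequency trends across
affected-system bands (0, 1, 2, 3, 4+) are plain Pearson correlations
with two-sided p values. Gestational age enters the models and
chi-square checks as a banded factor (default split at 28 weeks —
roughly the cohort median and the viability threshold); the published
analyses imply a categorization without stating it, so the banding is
exposed as configuration rather than guessed more finely. No
multiple-testing correction is applied by default, mirroring the
original analysis plan; `p.adjust` can be applied to the slope table by
the user.

Per-outcome denominators exclude only the subjects non-available for
that outcome (no listwise deletion), and subjects with every system
non-available are excluded from all malformation denominators.

## Problem sizes and tolerances used by the checks

The shipped checks run at sizes chosen to make binomial noise bands
informative: exhaustive round-trip tests over all eight classes,
frequency reproduction on a 10,000-subject cohort (3 binomial SEs),
and parameter recovery over 200 replicates at n = 1062 (2 Monte-Carlo
standard errors of the mean). The analysis scripts use the study-scale
1062.

## Known limitations

* Layer- and process-level conclusions are only as good as the coding
  map; the shipped default is plausible but unvalidated beyond marginal
  frequencies.
* The maximum-likelihood logistic slope carries a small positive
  finite-sample bias for rare outcomes (of order 2/cases; noticeable at
  ~64 events in a cohort of 1062). The recovery simulations sit close
  to, and the mean estimate slightly above, the generating slope for
  the rare outcomes; a bias-reduced (Firth-type) fit is deliberately
  not the default because the estimand is the ordinary ML slope.
* The generator's independence assumptions (events given severity,
  missingness across systems) are simplifications; real autopsy data
  correlate both.
* The rule engine presumes radiograph reading has already happened:
  it validates and classifies observations, it does not model observer
  error or ossification-dependent detectability.
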