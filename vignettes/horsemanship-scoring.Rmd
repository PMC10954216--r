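---
title: "Scoring horsemanship syndrome in skeletal assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring horsemanship syndrome in skeletal assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridescore)
```

## The diagnostic problem

Habitual horseback riding loads the human skeleton in a characteristic
way: the adductor and gluteal muscles grip the mount continuously, the
hip is held flexed and abducted, the spine absorbs repeated vertical
impact, and falls are the most common riding accident. Each of the
resulting skeletal changes is individually non-specific — heavy load
carrying, barrel making or simply high body mass can mimic single
traits — so diagnosis rests on the *co-occurrence* of several traits in
one skeleton. The package encodes that logic as a weighted scoring rule
over six trait categories and handles the central nuisance of
archaeological material: preservation. A trait can be present, absent,
or *unobservable* because the relevant skeletal region did not survive.

## The model

Let $s_i \in \{\text{present}, \text{absent}, \text{unobservable}\}$ be
the state of trait $i = 1,\dots,6$ with weights
$w = (3, 3, 2, 2, 1, 1)$ (femoral/pelvic entheses, acetabular
ovalization, femoroacetabular lesion, platymeric femur, vertebral
degeneration, trauma), $\sum_i w_i = 12$. Define

* trait count $T = \#\{i : s_i = \text{present}\}$,
* base score $S = \sum_i w_i \, 1[s_i = \text{present}]$,
* score bounds $[S,\; S + \sum_{i:\, s_i = \text{unobs.}} w_i]$,
* maximum attainable score $12 - \sum_{i:\, s_i = \text{unobs.}} w_i$.

An individual is positive iff $T \ge t$ **and** score $\ge p$, with
defaults $t = 4$, $p = 7$ — both "more than half" rules. Unobservable
traits contribute zero rather than being imputed: the published
assemblage scores a four-trait individual (116) at 7 points with two
traits unpreserved, which fixes the missing-equals-no-points
convention, and the bounds quantify how much preservation may have cost
an individual. The `preservation_capped` flag marks negatives whose
*best-case* completion (every unobservable trait present) would meet
both thresholds; it is advisory only and never upgrades a
classification, mirroring the cautious treatment of such cases in the
source material ("would possibly score higher"). Fourteen of the
fifteen negatives in the packaged assemblage carry the flag, almost all
because the acetabulum (weight 3) is rarely preserved — a useful
reminder of how asymmetric taphonomic censoring is.

### Score sources

The published per-individual scores embed a severity-of-expression
adjustment whose exact rules were never published; they are therefore
stored as transcription (`reported_score`) and never recomputed
silently. `classify()` exposes four score sources: `base` (recomputed
weighted sum), `reported`, `adjusted` (base minus explicit per-trait
deductions validated against trait state and weight), and the default
`auto` (reported where available, else base, recorded per row). Whether
the point threshold was originally applied to the adjusted or the raw
sum cannot be decided from the printed data — on the 24 published
records both give the same nine positives, which the test suite
asserts — so the package exposes both and documents the equivalence
rather than guessing. The deduction gap `base − reported` lies in
[0, 3] on every published record; `apply_adjustment()` accepts
deduction tables as explicit input only, since reverse-engineering the
rules (e.g. individual 118's 11 → 10) would attribute invented
precision to the method.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_traits` | 4 of 6 | trait-count threshold (>50% rule) |
| `min_points` | 7 of 12 | weighted point threshold (>50% rule) |
| `subadult_cutoff` | 18 y | subadult iff upper age bound is below it |
| state symbols | `+` `-` `?` | `−` (Unicode minus) also parses as absent |

The subadult cutoff is configurable because the source cohort summary
does not define "subadult"; 18 years is the conventional osteological
adult boundary and reproduces the published 28.1% (61 of 217) when
applied to counts. The masculinity index rounds half away from zero:
$1000 \times 132 / 65 = 2030.77$ prints as 2031, matching the published
value (nearest-integer rounding is the only convention that does).
Platymeric categories use the standard osteometric cuts (index < 85
platymeric, 85–100 eurymeric, ≥ 100 stenomeric) with boundary values
assigned upward, since the source uses the term without defining
cut-offs.

## The synthetic generator

`generate_assemblage()` draws individuals with (a) latent rider status
~ Bernoulli(`rider_fraction`); (b) traits conditionally independent
given status, trait $i$ present with probability
`p_trait_rider[i]` or `p_trait_nonrider[i]`; (c) preservation masking
applied *after* trait realisation and independent of status — taphonomy
does not know who rode — either per-trait global observability
probabilities or a completeness-linked model (completeness ~
U(20, 95) by default, observability = completeness/100 for every trait
of that skeleton); (d) sex and age-class metadata. Defaults emulate the
structure of the published cohort: 217 individuals, mean completeness
57.5 (the cohort reports 57), 61% male, 28.1% subadult. The rider
fraction and prevalence vectors are *illustrative*: no nonrider base
rate has been published for any trait, so every
sensitivity/specificity figure is conditional on the configured rates
and reports must say so.

What the generator deliberately does **not** model: correlated trait
etiology (one syndrome presumably couples the traits, but no
correlation structure is published — conditional independence is the
simplest defensible null, and the config leaves room for a latent-factor
extension), age/sex-dependent trait expression (explicitly "not fully
understood"), and the selection bias of the published 24 (only
individuals with ≥3 traits were printed, which is why prevalences are
never fitted to the fixture). Passing simulation tests therefore
validate the *rule's arithmetic and the estimator's calibration*, not
the realism of any particular prevalence configuration.

Randomness uses one seeded stream per individual, derived
deterministically from the config seed and the individual's index, so
growing `n_individuals` never reshuffles earlier individuals and every
draw is bit-for-bit reproducible from the seed.

## Numerical and design choices

* **Enumeration oracle.** `exact_positive_probability()` computes the
  positive probability exactly by enumerating all $3^6 = 729$ observation
  outcomes with per-trait probabilities $(pq, (1-p)q, 1-q)$. It covers
  the global preservation model only; under the completeness-linked
  model the six traits are dependent through the shared completeness
  draw, and Monte-Carlo is the supported estimator there.
* **Monte-Carlo calibration.** `estimate_performance()` aggregates
  confusion totals over replicates; standard errors are binomial on the
  totals. Tests require agreement with the enumeration oracle within 4
  standard errors at 200 replicates of 500 individuals — a few seconds
  of compute — and exact nesting of positive sets across thresholds
  under common random numbers (`threshold_sweep()` reuses one set of
  draws for the whole grid, so monotonicity is exact, not statistical).
* **Degenerate inputs.** Empty assemblages classify to empty results
  and summarise to zeros; `rider_fraction = 0` flags sensitivity as
  undefined rather than dividing by zero; a zero female count makes the
  masculinity index an error, not infinity; zero preservation yields
  all-unobservable records scoring 0.
* **Ties and boundaries.** Thresholds are inclusive ($\ge$);
  platymeric boundaries go to the upper category; score bounds are
  attained (they equal brute-force extremes over completions, verified
  exhaustively over all 729 vectors).
* **Transcription safety.** Readers reject unknown state symbols,
  duplicate identifiers and missing columns with the offending
  row/column named; writers emit ASCII symbols only, and the write/read
  round trip is the identity on content (property-tested on random
  assemblages).

## Problem sizes used by the test suite

Exhaustive checks run over all 729 observation vectors; Monte-Carlo
checks use 200 replicates of 500 individuals (oracle agreement), 10,000
individuals (prevalence recovery at 3 binomial standard errors), and
smaller grids for sweeps. These sizes make the full suite run in well
under a minute while leaving the statistical tolerances (3–4 standard
errors) meaningful.

## Known limitations

Scores say nothing about individuals never examined; the packaged 24
are the ≥3-trait tail of a 217-individual cohort, so fixture-derived
prevalences would be badly biased and are never used as generator
defaults. The severity adjustment behind the published scores is not
reproducible and is supported only as explicit input. Specificity
claims inherit all uncertainty in nonrider trait base rates, which are
unknown; the generator quantifies the rule's behaviour under stated
assumptions, it does not validate those assumptions.
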