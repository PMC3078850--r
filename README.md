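# survbiasim

Monte-Carlo simulation of **survival bias** and **treatment
effect-modification** in cross-sectional genetic case-control studies.

## Why

A common risk allele can carry a reproducible prospective risk ratio (say
RR = 1.5 for coronary events in carriers) and still look null in
case-control comparisons. Two mechanisms suffice, and this package
quantifies both:

* **Fatal-case exclusion.** Cross-sectional studies can only recruit
  surviving cases. If carrier cases die more often than noncarrier cases
  (case-fatality rates `f_c > f_n`), each age/sex stratum's odds ratio is
  scaled by exactly `(1 - f_c) / (1 - f_n)` and the estimated OR shrinks
  toward 1 — or below it, even when the allele has no risk effect at all.
* **Genotype-specific drug benefit.** If statin treatment eliminates a
  fraction `e` of the carrier *excess* risk and a fraction `s` of the
  population is treated, the marginal carrier multiplier falls from `RR` to
  `1 + (RR - 1)(1 - s·e)`, and the OR falls with it. Adding statin use as a
  regression covariate does **not** undo this: the drug acts as an
  interaction with genotype, not as an additive log-odds term.

Cohorts are synthesized from a banded age-by-sex population pyramid and a
cumulative cardiovascular-incidence surface `p0(age, sex)`; a carrier
indicator (frequency `q = 0.59`) multiplies individual risk by
`m = 1 + (RR - 1)(1 - e·statin)`; events and fatalities are Bernoulli
draws; the analysis is the standard logistic regression
`event ~ age + sex + carrier` on the non-fatal individuals, pooled over
replicates. A closed-form **expected-count oracle** predicts every
condition deterministically and anchors the one-scalar calibration of the
incidence surface (zero-bias OR = 1.55 at RR = 1.5); everything else the
package reports is an out-of-sample consequence.

## Worked example

Attenuation of a true RR = 1.25 effect when 41.5% of incident cases are
fatal and carrier cases die 20% (of the overall rate) more often than
noncarrier cases:

```r
library(survbiasim)

demog <- load_demography("canada2006")
baseline <- default_baseline()        # calibrated so zero-bias OR(RR=1.5) = 1.55

cfg <- scenario_config(n = 1e6, replicates = 10, base_seed = 1,
                       RR = 1.25, F = 0.415, d = 0.20)
res <- run_condition(cfg, demog, baseline)
res$pooled
#> Pooled carrier OR = 1.105 +/- 0.0122 (95% MC half-width, 10 replicates)

expected_or(demog, baseline, cfg, F = cfg$F, d = cfg$d)
#> Expected carrier OR = 1.1033  (closed-form approximation 1.1038)
```

The simulated pooled OR (1.105 ± 0.012) agrees with the deterministic
oracle (1.1033): a true 25% risk increase is read as a ~10% one. With no
fatality differential (`d = 0`) the same machinery returns ≈ 1.27–1.29
regardless of `F`; the published attenuation sequence 1.18 / 1.11 / 1.08
at `d` = 10/20/25% falls out of the same calibrated model.

Grid runners reproduce the three canonical experiments end to end and
write per-replicate, pooled and oracle CSVs:

```r
run_figure1_grid(out_dir = "out")   # OR vs fatality differential, F in {33, 41.5, 50}%
run_figure2_grid(out_dir = "out")   # OR vs statin use, e = 1, with/without statin covariate
run_figure3_grid(out_dir = "out")   # OR vs statin use for e in {0.2, ..., 1}
```

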