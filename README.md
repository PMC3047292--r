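# ctalert

Recruiting general-practice patients for research is notoriously hard:
practice staff have little spare time, enrolment rates are low, and — because
nobody knows who *could* have been enrolled — the selection bias of the final
sample is usually unquantifiable. A clinical trial alert (CTA) tool changes
that: it runs in the background of the practice software, recognises every
patient who meets the demographic inclusion rule the moment their electronic
patient record (EPR) is opened, fires an on-screen reminder, and streams a
pseudonymised record of every identification, exclusion, refusal and
enrolment to the study centre in real time. Because the *whole* population at
risk is registered, not just the enrolees, selection bias becomes a
measurable quantity instead of a caveat.

`ctalert` implements that recruitment engine as a testable R package, for
methodologists and trial teams who want to study (or simulate) EPR-driven
recruitment:

* **Eligibility and identification** — the net-sample rule (women ≥ 60,
  men ≥ 70, completed age evaluated at every EPR opening) and the five
  sex/age strata `F60-69, F70-79, F80+, M70-79, M80+`.
* **Pseudonymisation** — HMAC-SHA256 study IDs under a per-practice secret;
  re-identification is possible only with the practice-local key map.
* **A recruitment state machine** — `OPEN → {EXCLUDED, REFUSED, ENROLLED,
  DECEASED}` with `SURVEY_IN_PROGRESS` for interrupted surveys; ignored
  reminders stay open and the alert re-fires at the next EPR opening.
  Event logs (JSON Lines) replay deterministically through the machine.
* **Funnel accounting** — CONSORT-style stage totals with the conservation
  identities `identified = open + excluded + contacted` and
  `contacted = refused + enrolled`, per-practice enrolment and
  target-achievement tables, and small/large practice stratification.
* **Selection-bias monitoring** — stage-by-stratum demography, Pearson
  chi-square tests of enrolees against net-sample non-enrolees on the 2×k
  stratum table, representation ratios (enrolled share ÷ net share), and a
  registry-consistency audit against full panel queries.
* **Adaptive suppression** — a policy that withholds the reminder for strata
  whose enrolled share exceeds their net share by more than a tolerance,
  until the selection levels reflect the net sample again.
* **A practice simulator** — synthetic panels, Poisson visit streams,
  software downtime windows, and probabilistic staff behaviour (with a
  per-stratum bias injector), so every pipeline stage can be exercised and
  calibrated without real EPR data.

Reference tables from a 12-month osteoporosis-survey recruitment study in 25
German general practices (16,067 identified, 1,526 enrolled, target 200 per
practice) are bundled as `cta_reference_*()` fixtures for worked examples and
regression checks.

## Worked example

```r
library(ctalert)

log <- cta_reference_log()      # event log reconstructed from the reference tables
f   <- funnel_counts(log)
cat(consort_text(f))
#> Identified (net sample): 16067
#>   Open / no response:    10906 (68%) incl. 43 surveys in progress
#>   Excluded:              3248 (20%) incl. 22 deceased
#>   Contacted:             1913 (12%)
#>     Refused:             387
#>     Enrolled:            1526
#> Reviewed for eligibility: 5161 (32%)
```

Only 12% of the identified patients were ever contacted — but of those, 80%
enrolled: the funnel's bottleneck is staff response, not patient willingness.

```r
practice_table(log, target = 200) |> size_strata_summary(threshold = 600)
#> # A tibble: 2 × 6
#>   size_class n_practices net_sample enrolled pooled_pct poor_recruiters
#>   <chr>            <int>      <int>    <int>      <dbl>           <int>
#> 1 small               13       5061      753         15               1
#> 2 large               12      11006      773          7               7
```

Small practices (net sample < 600) enrolled 15% of their population at risk,
large ones only 7%, and 7 of the 12 large practices were poor recruiters
(< 5%) — more identified patients did not mean more enrolment.

```r
strata <- stage_demography(log)
w <- tidyr::pivot_wider(strata, id_cols = stratum, names_from = stage, values_from = n)
chi_square_bias_test(setNames(w$net_sample, w$stratum), setNames(w$enrolled, w$stratum))
#> Chi-square selection-bias test (enrolled_vs_rest)
#> X-squared = 297.2207, df = 4, p = < 2.22e-16

round(representation_ratio(strata), 3)
#> F60-69 F70-79   F80+ M70-79   M80+
#>  1.453  1.458  0.603  0.839  0.452
```

Enrolment was demographically selective: women under 80 are over-represented
by ~45%, while the 80+ strata of both sexes (ratios 0.60 and 0.45) and men
generally (0.670 overall) are under-represented. `update_suppression()` turns
exactly this diagnosis into an adaptive reminder-suppression policy, and the
simulator (`practice_config()`, `staff_behaviour()`, `simulate_study()`)
shows that it pulls the enrolled demography back toward the net sample.

A command-line interface wraps the same functions
(`inst/cli/cta simulate | replay | funnel | bias | report`); see
`?run_cli` and the example configuration in `inst/extdata/example_run.yaml`.

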