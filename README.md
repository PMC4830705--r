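# casechar

Terminology-aware case-series characterization for drug-safety signal
verification.

When a suspected adverse-drug-event signal (say, pancreatitis under an
ACE inhibitor) needs verification against real electronic health
records, the analyst contrasts a **foreground population** — patients
with the drug *and* the reaction within a time window — against the
**background population** of all patients on the drug. Doing this
across heterogeneous EHR sources raises four problems that `casechar`
solves as one pipeline:

1. **Semantic mediation** — sources ship data as XML patient summaries
   or relational tables in local models; declarative conversion rules
   map both, one-to-one and losslessly, into a common patient model.
2. **Terminology reasoning** — sources code conditions in ICD-style
   schemes while the analyst thinks in a MedDRA-style hierarchy.
   Curated cross-scheme mapping sets are materialized into a
   transitively closed `close_match` relation and level-targeted
   grouping links, so queries can be *localized* (analyst code →
   source codes + descendants) and results *enriched* (source code →
   analyst-level group). Hierarchy is never folded into equivalence —
   the over-inference that makes naive transitive/symmetric match
   vocabularies clinically wrong.
3. **Temporal eligibility** — criteria combine coded leaves with
   AND/OR and windowed temporal constraints ("reaction within 120 days
   after prescription", inclusive bounds).
4. **De-identification** — keyed pseudonyms, birth dates generalized
   to years, coherent per-patient date shifting (intervals, and hence
   interval-based eligibility, are preserved exactly), and rare-code
   removal.

The headline statistic is the foreground share of the background,

    share = 100 * |foreground| / |background|   (percent, half-up to 2 dp)

reported alongside comparative statistics boxes (age bands, gender,
country, common conditions/medications overall and before/after the
index date, risk-factor prevalences), all patient-level counts.

Real MedDRA/SNOMED CT/ICD releases are licensed and not required: the
`generator_spec()` / `generate_terminologies()` / `generate_cohort()`
family produces structurally analogous schemes, mapping sets and
cohorts with known ground truth, so every stage is testable.

## Worked example

```r
library(casechar)

spec    <- generator_spec(seed = 42, n_patients = 1000)
terms   <- generate_terminologies(spec)
closure <- materialize_close_match(unname(terms$schemes), terms$mappings)
gen     <- generate_cohort(spec, terms)

study <- read_study(system.file("extdata", "demo_study.yaml", package = "casechar"))
res   <- run_study(study, list(list(source_id = "S1", cohort = gen$cohort)),
                   unname(terms$schemes), closure)
res$report
#> <comparative_report> demo-signal
#>   foreground: 19 patients; background: 303 patients (6.27% of background)
#>   boxes: age, gender, country, common_conditions, common_medications, ...
```

19 of the 1,000 simulated patients took the study drug *and* had the
reaction within 120 days of the prescription; 303 took the drug at
all, so the case series covers 6.27% of the exposed population.
`glance()`, `tidy()` and `autoplot()` give the broom/ggplot views:

```r
glance(res$report)
#> # A tibble: 1 × 5
#>   study_id    fg_size bg_size fg_share_pct n_boxes
#> 1 demo-signal      19     303         6.27       8

res$report$boxes$gender
#> <stat_box> gender (fg n=19, bg n=303)
#>   item_code item_label fg_count fg_rate bg_count bg_rate
#> 1 female    female           10    52.6      133    43.9
#> 2 male      male              9    47.4      170    56.1
```

Each box row is an item with its patient count and occurrence rate in
both populations — here the foreground skews female relative to the
background, the kind of contrast an analyst inspects for confounding.
The same study can be driven from the shell:

```sh
Rscript inst/cli/casechar.R gen --seed 1 --n 500 --out fixtures
Rscript inst/cli/casechar.R materialize --terminology fixtures/terminology --out fixtures/terminology
Rscript inst/cli/casechar.R run-study --study inst/extdata/demo_study.yaml \
    --sources S1=fixtures/records.ndjson --terminology fixtures/terminology --out out
```

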