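---
title: "Characterizing case series across heterogeneous EHR sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing case series across heterogeneous EHR sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casechar)
```

## The problem and the model

A drug-safety signal is a hypothesized causal association between a
drug and an adverse event. One way to verify it against observational
data is case-series characterization: select the **foreground**
population (drug + event within a window) and the **background**
population (drug, regardless of event), and contrast their
demographics, comorbidities, co-medications and risk-factor
prevalences. The headline number is the foreground share of the
background,

$$\text{share} = 100 \cdot \frac{|FG|}{|BG|}\ \%,$$

rounded half-up to two decimals wherever it is printed. `proportion()`
implements exactly this; `proportion(108, 34773)` is `0.31` and
`proportion(423, 34773)` is `1.22`, which pins the rounding rule.

Everything else in the package exists to make those two sets, and the
statistics over them, computable when the data live in several EHR
systems that disagree about both structure and coding.

### Eligibility criteria

Criteria form an AST: coded leaves (statement kind + a set of
(scheme, code) pairs), AND/OR nodes, and temporal nodes relating two
leaf criteria by a window. Window semantics were genuinely open — the
phrase "within $N$ days after" does not fix its bounds — so they are
declared and boundary-tested: the window is inclusive at both ends
(`[anchor, anchor + N]` for `after`; day 0 counts; `before` mirrors
it; `either` is the union). Matching is existential: any qualifying
(anchor, related) statement pair makes the patient eligible. The
anchor date is the statement's start date; end dates are ignored for
temporal matching because prescriptions in administrative sources are
point events. Undated statements never satisfy a temporal node.
Temporal anchor/related criteria are restricted to leaves, since
statement-level matching is not well defined for a boolean subtree.

### Terminology model and reasoning

A `concept_scheme` declares an ordered list of named levels (broadest
first) and concepts carrying an explicit level tag — levels are
declared, not inferred from depth, because real terminologies have
uneven depth. `broader` edges may give a concept several parents
(multiaxial hierarchies, as in MedDRA) but must stay acyclic.

Cross-scheme knowledge enters only through curated mapping-assertion
sets, tagged by their origin (`omop_like`, `protect_like`,
`crossmap_like`, `identical_code`). `materialize_close_match()`
computes the least fixed point of (i) each assertion in its configured
direction(s), (ii) symmetry per bidirectional assertion, and (iii)
transitivity. Two choices matter:

* **Hierarchy never leaks into equivalence.** Generic match
  vocabularies whose relations are transitively and bidirectionally
  closed over everything produce clinically wrong equivalences; here
  `broader` edges are never folded into `close_match`, and the
  regression test asserts that rich hierarchies with zero assertions
  yield an empty closure.
* **Direction is explicit.** The curated sets are stored as directed
  links but used for mutual matching, so the default derivation
  treats every close-strength assertion as bidirectional; a
  per-relation switch can restrict a set to its asserted direction.
  Under the default the closure is symmetric and transitive, which the
  property tests assert directly. Context-conditional mappings (rules
  attached to individual map entries) are out of scope; the relation
  tag is the unit of configuration.

Grouping links (`materialize_group_links()`) connect every concept to
each ancestor-or-self at exactly the target level of each of its
close matches in the target scheme (zero hops when the concept is
already there). A code grouping under several target-level codes is
counted in every group — dropping axes silently would bias the
characterization. Codes with no route to the target scheme go to a
reserved `UNMAPPED` group rather than being dropped: silent loss is
unacceptable in a safety analysis.

Query localization (`expand_query_codes()`) is the reverse direction:
an analyst-scheme code expands to its close matches in the source
scheme plus all their narrower descendants (sources code at finer
granularity than the criterion). A code already in the source scheme
expands to itself plus descendants — the zero-hop case is included by
analogy with grouping, since a criterion already expressed in the
source's own scheme must stay satisfiable. Unmapped codes produce an
empty expansion and an unsatisfiable leaf, reported but never an
error. Materialized links are cached as sorted TSV keyed by a content
hash of their inputs, so reruns are bit-stable and stale caches
rebuild transparently.

### Mediation

Source data is first formalized one-to-one: every XML element becomes
a node, every attribute a literal, nothing is interpreted. The
round-trip (graph → XML → graph) is exact up to attribute order and
whitespace, which the tests assert. Conversion to the common model is
then purely declarative: YAML rules bind path expressions (document
dialect) or table columns (relational dialect) to common-model
fields. Unmatched content is reported as residue (paths + counts),
never converted or silently lost; dangling foreign keys in the
relational dialect are findings with the row skipped; unparseable
dates keep the statement with an absent date plus a finding. Because
both dialects converge to canonically sorted records, rule-order
independence and cross-dialect equivalence are testable as exact
equalities.

The common model itself is deliberately a subset: demographics plus
five statement kinds (condition, medication, lab result, procedure,
allergy), with day-granularity dates (all criteria in this domain are
day-scale; times are discarded on ingest). Code-system identifiers in
XML (OID-like strings) are normalized to scheme ids via a lookup
table that travels with the emitted data.

### De-identification

Before records leave the data owner's zone: identifiers become keyed
pseudonyms (stable within a run, unlinkable across seeds, collision
checked); birth dates are generalized to years; one uniform offset in
`[-shift_range_days, +shift_range_days]` per patient shifts all of
that patient's dates, so every intra-patient interval — and therefore
any interval-based eligibility result — is unchanged, which is tested
end-to-end. Zero offset is allowed: excluding it would itself leak
one bit. Codes carried by fewer than `rare_threshold` distinct
patients are removed at statement level (not patient level — the
least destructive reading of "eliminated", and it is logged). The
defaults (30-day half-range, threshold 5) are declared package
choices, not claims about any production deployment.

## The synthetic-data generator

The generator emulates the statistical structure a characterization
study assumes, with ground truth recorded for every draw:

* **Terminologies**: a four-level research scheme (SOC > HLGT > HLT >
  PT analogue), a flat bridge scheme standing in for a pivot
  vocabulary, two three-level care schemes and a two-level drug
  scheme. Mapping sets chain care-1 → bridge → research PT and bridge
  → care-2 in three relation tags, so closure correctness is exercised
  on genuine two-hop chains rather than direct links.
* **Cohort**: exposure to the study drug with probability 0.3 and one
  dated prescription per exposed patient; a reaction within the
  120-day window with probability $p_w = 0.05$ for exposed patients; a
  baseline reaction with probability $p_{bg} = 0.005$ for everyone;
  confounder conditions at prevalence 0.25 in reactors vs 0.10 in
  non-reactors; background noise conditions/medications; lab results;
  demographics (52/48 gender split, birth years 1920–1990, two
  countries). Dates sit on a 10-year observation span. One RNG stream
  per concern is derived from the master seed, so changing one spec
  field does not perturb unrelated draws, and output is
  byte-deterministic under a fixed seed.

The exposure probability is a toy-scale choice: at the realistic
population share of a single drug (a few percent), a 2,000-patient
cohort would leave a background too small to characterize; 0.3 keeps
the background around 600 patients while leaving the reaction model at
its stated rates. One prescription per exposed patient keeps the
foreground share analytically tractable:

$$E\left[\frac{|FG|}{|BG|}\right] = p_w + (1-p_w)\, p_{bg}\, q,
\qquad q = \frac{(W+1)D - W(W+1)/2}{D^2},$$

with window $W$ and span $D$ in days — $q$ is the chance that an
independently, uniformly dated baseline reaction lands inside the
post-prescription window. `expected_fg_share()` computes this, and the
recovery test asserts the measured share stays within three binomial
standard errors across seeds.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: coding error and mapping noise beyond
missingness (`mapping_consistency` removes mappings, it never corrupts
them), visit structure and informative observation gaps, repeat
prescriptions and dose, correlated comorbidity structure, free-text
content, and record volumes at population scale. Tests at these sizes
demonstrate correctness of the machinery, not epidemiological realism.

## Numerical and reporting choices

* All printed percentages round half-up to two decimals (validated
  against the worked-example shares above).
* Box rows sort by foreground rate descending, ties broken by code —
  no ordering is inherent in the statistic, and determinism requires
  one; reports are byte-identical for identical inputs.
* Counts are patient counts. "Number of occurrences" is ambiguous
  between events and patients; patient-level is chosen because rates
  must be population-comparable, and an event-level tally is emitted
  alongside in the JSON for transparency.
* Before/after-index boxes use strict inequality against the index
  date (the earliest statement matching the index anchor); index-day
  events appear only in the overall box, avoiding double counting.
  Patients without an index date are excluded from those denominators,
  which the box records.
* Background denominators count distinct patients; whether a
  production warehouse would deduplicate across years is an assumption
  this engine makes explicit.
* Derived-condition rules (age bound + medication set + lab threshold
  → inferred condition) date the inferred statement at the earliest
  supporting evidence, flag it `derived`, skip patients already
  carrying the condition, and are idempotent.

## Problem sizes

The shipped test-suite and acceptance runs use cohorts of 120–2,000
patients, terminologies of a few hundred concepts, and 200 random
closure graphs of up to 300 concepts; these sizes were chosen so the
whole suite exercises every oracle comfortably on a laptop-class
machine while keeping every check exact.

## Known limitations

* The common model covers five statement kinds and core demographics;
  encounters, family history and richer data types are out of scope,
  though the record format tolerates extension without disturbing
  existing fields.
* Negated leaves are supported in the engine but not surfaced in the
  CLI study format, matching the affirmative style of the target
  criteria.
* The rule language is deliberately small (paths, predicates, column
  bindings); anything needing computation does not belong in a
  conversion rule.
* No disproportionality statistics or credibility intervals — the
  report characterizes, the analyst judges.
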