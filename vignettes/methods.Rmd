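---
title: "Chained PICOS screening: model, synthetic data, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chained PICOS screening: model, synthetic data, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picoscreen)
```

## The screening model

`picoscreen` treats study eligibility as a conjunction of four
per-dimension criteria derived from a PICOS decomposition of the review
question. The dimensions are evaluated in a fixed chain order —
interventions/comparators, then populations, outcomes, and study
designs — and the chain short-circuits: the first dimension whose task
answers "no" excludes the record and supplies its exclusion reason; a
record that passes every task is included. The "Comparison" criterion is
folded into the intervention/comparator task rather than getting a fifth
link, because intervention and comparator are assessed as one domain in
practice.

Two consequences of chaining are worth making explicit:

* **Reason attribution is order-dependent.** A record failing several
  dimensions is always attributed to the chain-earliest failure. When a
  gold standard attributes the same record to a later dimension, the
  reason-concordance rate is *conservatively* underestimated even though
  the decision is right. This is inherent to any first-failure protocol
  and is covered by a property test (earliest failing dimension always
  wins).
* **Short-circuiting halves backend traffic** relative to
  evaluate-all-four, at the price of an incomplete trace for excluded
  records. The trace records exactly the tasks that ran.

Each chain task is rendered as a prompt with fixed block order: role and
task definition, medical definitions, step-by-step thinking
(chain-of-thought), few-shot examples, an output-format instruction
naming every JSON schema key, a machine-readable `DIMENSION:` marker,
and finally the document. Prompt assembly is a pure function — identical
inputs render byte-identical prompts — which, combined with a
temperature-0 backend contract, makes screening runs reproducible.
Responses must be JSON; the parser strips code fences and surrounding
prose, extracts the first balanced object, and validates keys and types.
A malformed response earns exactly one retry with a "respond with JSON
only" reminder; a second failure surfaces as a classed error carrying
the raw text.

The refinement loop the package supports is deliberately manual:
`add_error_examples()` appends misclassified documents (with their gold
answers) to a task's few-shot store with `provenance = "misclassified"`,
deduplicating on the document snippet. There is no automated prompt
search.

## Stages

*Title–abstract*: the chain input is the title plus the cleaned
abstract; records without an abstract run on the title alone (a
documented degenerate case, not an error). *Full text*: the input is the
concatenation of a structured article's sections in canonical reading
order (title, abstract, introduction, methods, results, discussion,
conclusion, other, references), so evidence buried in a results section
is visible to every task. The full-text chain re-evaluates all four
dimensions rather than only those untestable from the abstract — a
simpler contract that matches an in-depth second pass. The two stages
use distinct task suites by default (shared criteria, stage-specific
role text); nothing prevents a user from passing one suite to both.

The outcome task's default reasoning steps include a safeguard learned
from screening practice: a randomized controlled trial is *not* failed
at the title–abstract stage merely because its abstract omits safety
outcomes, since those are normally reported in the full text. This is
prompt text, not a hard-coded rule, and is overridable per scenario.

## Document structuring

Full texts arrive as plain-text page streams (a PDF-reader or OCR
adapter is a contract, not a dependency: tests inject a mock OCR
function; image-only pages with no OCR contract raise an error naming
the page). Headings are detected by normalize-then-match: strip leading
enumeration ("2.", "III.", "(b)"), strip trailing punctuation,
lowercase, and require at most 8 tokens before comparing against an
editable vocabulary covering IMRaD plus common variants ("Background",
"Materials and Methods", "Patients and Methods", "Conclusions",
"References", "Acknowledgments", ...). Only textual features are used —
the module consumes plain text, so font or size cues are unavailable by
construction.

Segmentation assigns every non-empty line to exactly one section
(heading lines belong to their own section; spans with the same label
are merged), with two carve-outs: text before the first heading is front
matter (first non-empty line = title, remainder = abstract — a heuristic
for abstracts without an explicit heading), and lines matching caption
patterns (`Table N`, `Fig(ure) N`) divert to a non-prose element list.
The partition property — concatenating all section texts plus captions
recovers every input prose line exactly once — is enforced by property
tests on random generated documents. Table *content* parsing, reference
parsing and multi-column layout reconstruction are out of scope.

## Deduplication

Two records are duplicates when their normalized titles (Unicode NFKC,
lowercase, non-alphanumerics stripped, space runs collapsed) are equal
and their years are compatible (equal, or either missing). First-seen
wins; output order is preserved; the report satisfies
`input = unique + removed` and idempotence (re-deduplicating removes
nothing). Year compatibility is checked against the cluster head, which
keeps clustering deterministic even though "compatible" is not
transitive (2019 ~ NA ~ 2021). A token-Jaccard fuzzy mode exists behind
a flag but is off by default: the exact rule is the documented contract,
and no similarity threshold can be justified from first principles here.

## The synthetic world

`generate_corpus()` emulates a screening corpus, not a literature. Its
defaults are the stated world of the validation setting: a 1:9
included-to-excluded prevalence, exclusion reasons spread over the four
chain dimensions (uniformly by default — no published breakdown exists
to calibrate against), years 2008–2024, unique titles. Each record
embeds a guillemet sentinel (`«INC»` or `«EXC:dimension»`) consistent
with its gold label; the mock backend answers tasks by sentinel lookup,
so no NLP stands between a green test and the pipeline logic under
test. That is precisely the point and precisely the limitation: a green
end-to-end test establishes that ingestion, cleaning, deduplication,
segmentation, chaining, short-circuiting, reason attribution, PRISMA
accounting and evaluation are correct — it establishes nothing about any
real model's language understanding, and the generator makes no attempt
to imitate real abstract prose.

`stratified_sample()` reproduces training-set construction: exact class
counts at an `a:b` ratio (the two reference splits are 400 at 1:9 = 40 +
360 and 80 at 3:1 = 60 + 20), sampling without replacement, erroring on
non-integral splits rather than rounding — both reference splits divide
evenly, so silent rounding would only ever mask a user mistake.
`inject_duplicates()` appends mutated copies (case, punctuation,
whitespace — all invisible to the dedup key) together with the exact
report `deduplicate()` must reproduce. `generate_fulltext_pages()`
renders a record as IMRaD pages with the sentinel placed where that
dimension's evidence naturally lives (outcome evidence in Results;
intervention, population and design evidence in Methods), or as a
heading-free single page to exercise the degenerate front-matter path.

### Mock noise

The mock's noise contract flips "the answer on a deterministic
pseudo-random subset". We apply the flip **per document**, not per task:
a document is noisy when `hash(document, seed) / 2^31 < noise`, and a
noisy document is answered as if its gold label were flipped (gold
excludes pass every task; gold includes fail at the first link). A
per-task flip would compound along the chain — a gold include would be
misclassified with probability `1 − (1 − ε)^4` — breaking the intended
calibration `accuracy ≈ 1 − ε` that the noise-recovery acceptance test
checks (within 3 binomial standard errors at n = 1000). The hash is a
31-bit polynomial rolling hash with a Lehmer mixing step: stable across
sessions and platforms (R's RNG is not used, so the flip set is a pure
function of document text and seed, independent of call order).

## Evaluation

Confusion counts, the three metrics, reason concordance and the Pearson
2×k chi-square are implemented directly in the package (the chi-square
per its textbook formula, df = k − 1, no continuity correction) and
oracle-tested against brute-force recounts and
`stats::chisq.test(correct = FALSE)` at tolerance 1e-9. Choices the
definitions leave open:

* **Concordance denominator** — records excluded by *both* tool and
  gold: reasons are only comparable where both sides excluded. Reason
  labels match after whitespace/case normalization; no semantic
  matching. Zero co-excluded records yield an undefined-flagged rate,
  not an exception or a silent 0.
* **Undefined metrics** — `TP + FP = 0` (precision) or `TP + FN = 0`
  (recall) are flagged, never reported as 0.
* **Rounding** — percentages are rendered half-up at two decimals
  (base R rounds half to even, which would print 99.375 as 99.37).
* **Multiple testing** — none across the two chi-square comparisons,
  matching common practice in screening-tool reports.
* **Degenerate comparisons** — a single decision set, or a table with a
  zero column marginal, yields no between-model test (`NULL`) rather
  than an error; identical perfect columns report statistic 0, p = 1.

## Backends

All backends satisfy one contract: `complete(backend, prompt, params)`
returns raw text, retrying transport failures up to `max_retries` with
exponential backoff and raising a classed `backend_unavailable` error
when exhausted; semantically wrong but well-formed answers are the
parser's concern. An optional JSON file cache keyed on (backend, model,
prompt hash) makes reruns cheap and exactly reproducible. One
OpenAI-compatible HTTP adapter (credentials from an environment
variable, never config) covers the vendor dialects that share the
chat-completions shape; it requires network and is exercised by no test
— the suite runs entirely against the mock, which also demonstrates
backend interchangeability behind the contract.

## Known limitations

* The heading detector uses lexical features only; unusual layouts
  (e.g. two-column conference abstracts) are out of scope.
* Reason concordance is conservative under multi-ground exclusions (see
  above) and assumes gold reasons use the same label vocabulary.
* The synthetic generator's "realism" is intentionally shallow; nothing
  here measures real-model screening quality.
* Non-integral stratified splits error by design; callers wanting
  approximate ratios must round explicitly.
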