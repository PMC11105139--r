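---
title: "Detecting comorbid conditions in clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting comorbid conditions in clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidr)
```

`comorbidr` detects 18 medical conditions — the 16 comorbidities of the
Charlson comorbidity index (CCI) plus tobacco and alcohol consumption — in
French clinical notes, aggregates them to the hospital-stay level, computes
the CCI, and compares note-based detection against ICD-10 claim codes. This
vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, the synthetic data used to
validate it, and the design choices made where the design was genuinely
open.

## The detection model

The pipeline is hybrid: deterministic, auditable rules for named entity
recognition, and either rules or a small trainable classifier for deciding
whether a detected mention is actually asserted for the patient.

### Preprocessing with exact offset accounting

Clinical text is normalized by lowercasing, stripping diacritics and
standardizing typographic quotes. Normalization uses an **explicit
per-character table** rather than a generic Unicode decomposition: every
normalized character records the raw character that produced it (ligatures
such as `œ → oe` expand, and both output characters map to the source).
This makes the normalized→raw offset map total, deterministic and
auditable, which matters because gold-standard annotations are character
spans on the raw text and must survive arbitrary round trips. The
assumption is that no character *disappears* during normalization — the
table only rewrites or expands — which holds by construction.

Tokenization splits on whitespace, severs punctuation into single-character
tokens, and applies the French elision rule (`l'asthme` → `l'`, `asthme`).
Sections are opened by titled lines (`antécédents familiaux :`), matched
from a configurable lexicon at line starts only, with longest-match-wins at
a position; each section runs to the next title. Text before the first
title is one implicit relevant section.

### Rule-based NER with severity and exclusions

Each of the 18 conditions has a dictionary of regex synonyms (matched on
normalized text), exclusion patterns for identified false-positive
mechanisms (a condition inside a care-site name, acronym clashes,
look-alike diagnoses such as *diabète insipide*), and — for the five
*statused* conditions (diabetes, liver disease, solid tumor, tobacco,
alcohol) — context severity rules. Overlapping matches of the same
condition merge to the longest (then leftmost) span; different conditions
may overlap freely. A severity rule fires when its context regex matches
within `window_tokens` tokens of the mention; several firing rules resolve
to the **most severe** status (statuses are declared least→most severe),
and no firing rule yields the least severe, "present-unspecified" status.

Severity context windows are **truncated at sentence terminators**
(`. ; ! ?`). The motivation is containment: without truncation, a severity
cue like *actif* in an adjacent sentence about tobacco could contaminate a
nearby alcohol mention. The cost is that severity phrasing split across
sentences is missed; stay-level aggregation recovers most of these because
any one severity-bearing mention suffices.

The bundled dictionaries are **original starter content**: structurally
complete (≥5 inclusion patterns, ≥1 exclusion, ≥2 severity rules per
statused condition, ICD-10 prefix lists, CCI weights), authored from the
condition names and common French clinical synonyms and acronyms. A
production deployment would refine them iteratively with clinicians; the
package deliberately keeps every pattern in the YAML config so that no code
change is needed to do so.

### Qualification

A mention is discarded when it is negated (*pas de diabète*), hypothetical
(*suspicion de…*), related to someone other than the patient (*diabète chez
le père*, or any mention inside a family-history section), or a generic
false positive (exclusion hit, irrelevant section). Two interchangeable
modules implement the decision:

* **Rule-based**: three NegEx-style detectors. A cue phrase governs an
  entity when it lies within a scope window of the entity (in tokens) on
  the appropriate side with no scope terminator between. Defaults: negation
  5 tokens, hypothesis 6, family 8; terminators are sentence punctuation
  plus adversative conjunctions (*mais*). These windows follow the NegEx
  tradition of short scopes; all are configurable, and the detectors are
  verified against a brute-force oracle that enumerates every (cue, entity)
  pair and applies the scope definition literally.

* **Learned**: the architecture contract is (1) embed each token of the
  mention's snippet, (2) mean-pool the embeddings of the entity's tokens,
  (3) classify the pooled vector with a fully-connected layer. The
  embedding backend here is a hashed bag of lexical features — token
  identity, a position-relative-to-entity bucket, and the two neighbor
  tokens on each side, hashed into `d = 2^16` buckets — so context enters
  the pooled vector through the neighbor features. The dense layer is
  logistic, trained by full-batch gradient descent with a halving line
  search (loss provably nonincreasing). Weights start at zero, which makes
  training deterministic and exactly symmetric under label flips; the seed
  is recorded for provenance. The featurizer is a pluggable boundary: a
  contextual transformer encoder could replace the hashed features without
  touching the pooling or the classifier. The decision threshold on the
  keep-probability defaults to 0.5.

This lexical stand-in is *not* a contextual language model: it cannot
disambiguate by long-range context and shares no knowledge across surface
forms. On cue-determined synthetic snippets it separates nearly perfectly,
which validates the training and pooling machinery — not clinical-grade
qualification.

### Aggregation and the Charlson index

A condition is present for a stay iff at least one of the stay's mentions
survives qualification; statused conditions take the most severe surviving
status (unset counts least severe). Mentions are pooled across all notes of
the stay. These rules make aggregation idempotent, order-independent, and
monotone: extra kept mentions can only add conditions or raise statuses.

The CCI is `Σ_c w_c(status_c)` over present index conditions. The weight
table ships in config with the canonical 1/2/3/6 assignment (e.g. diabetes
1/2 by complication status, liver disease 1/3, solid tumor 2/6, AIDS 6);
tobacco and alcohol consumption are tracked but never weighted. A statused
condition reported as bare "present" takes its least-severe weight — a
conservative default, configurable. No age adjustment is applied.

### The claim comparator

Claim records are ICD-10 codes per inpatient stay, normalized to dot-free
uppercase. A condition is claim-present when any code starts with any
configured prefix; per-status prefix lists give statused conditions their
most severe matching status. Diagnosis position (principal vs associated)
is ignored. The starter prefix lists are config content like the
dictionaries.

### Evaluation protocol

* **Entity level**: a predicted mention is correct iff it shares at least
  one raw character with a gold mention of the same condition (and status,
  for per-status rows). Predictions are judged independently — k
  predictions over one gold mention are k true positives — and each
  unmatched gold mention is one false negative. There is no entity-level
  true-negative universe, so specificity is undefined and rendered as `NA`,
  never 0.
* **Stay level**: per-stay presence/status agreement, with true negatives.
* Statused conditions are reported as one binary task per status plus an
  "any" (presence) task; micro, macro and support-weighted averages pool
  all non-PPV-only tasks (support = gold positives).
* **PPV-only protocol**: conditions too rare for unbiased validation
  (hemiplegia, AIDS in the default config) report only PPV and are
  excluded from every average.
* **Bootstrap**: percentile intervals over resamples of *stays* — the
  independent sampling unit of the validation design — drawn with
  replacement, deterministic given the seed; degenerate resamples are
  skipped and counted. Displayed percentages round half-up to one decimal;
  raw values are retained in the JSON output.
* No multiple-testing correction is applied anywhere.

## The synthetic corpus

Real clinical corpora are protected, so validation runs on generated
French-style notes with known truth. Each positive (stay, condition) emits
at least one mention sentence assembled from templates: optional cue +
dictionary phrase + optional severity phrase; the cue class is recorded as
the gold qualifier label, family mentions may instead land in a generated
*antécédents familiaux* section, and care-site templates produce labeled
generic false positives. Claim codes retain each truly present condition
with probability `1 − u` (undercoding), for inpatient stays only.

Defaults are chosen to emulate the shape of an annotated validation corpus
of discharge summaries and consultation reports: per-condition prevalences
follow the relative note-level condition frequencies typical of such
cohorts (1–40%); about a quarter of gold mentions carry a discard
qualifier, negation being the most common; the mention count per positive
stay-condition averages 2 (capped at 5); 40% of statused occurrences take
the severe status; the claim undercoding rate defaults to 0.3 and
overcoding to 0 — undercoding, not overcoding, is the documented failure
mode of claim data. The out-of-vocabulary rate (default 0.1) governs
realization misses: a discard-cued mention draws a cue outside the default
lexicon (the rule-based qualifier will wrongly keep it), while a clean
mention draws a surface form outside the dictionaries (the NER will miss
it, and stay-level aggregation may recover it through sibling mentions).
Interpreting the single rate over both realizations is a package design
choice: it keeps "how often does language escape the dictionaries" one
dial while exercising both failure paths that dial is meant to create.

Dictionary phrases are embedded verbatim (sometimes re-accented, to
exercise the offset map), so NER misses are attributable solely to the oov
rate. What the generator does **not** emulate: discourse structure and
coreference, abbreviation ambiguity, spelling noise, co-occurring mentions
inside one sentence, inter-annotator disagreement, and realistic code
distributions. Passing on this corpus therefore demonstrates the
correctness of the machinery — span bookkeeping, scope logic, aggregation
laws, metric computation — not clinical-grade accuracy on real notes.

Identical configurations produce byte-identical corpora: all randomness
flows from the mandatory seed through R's RNG, restored afterwards.

## Numerical and degenerate-input choices

* Offsets are 0-based, half-open, in characters, on raw text — everywhere.
* Metrics with zero denominators propagate as `NA` and are dropped from
  macro/weighted averages (weights renormalized over defined rows).
* Same-condition span ties resolve longest-then-leftmost; severity ties
  resolve most-severe; claim status ties likewise.
* `aggregate_stays` on zero kept mentions yields `absent`; prevalence over
  an empty stay set is an error (division by zero is signaled, not
  returned).
* Training uses a line search with at most 30 halvings per epoch from an
  initial rate of 4; an epoch that cannot decrease the loss leaves the
  parameters unchanged, so the loss sequence is nonincreasing by
  construction. Model serialization keeps full double precision.
* The hashing dimension default `2^16` keeps collisions rare at the
  vocabulary sizes the generator produces; halving it mostly costs
  calibration, not separability.

## Problem sizes used in validation

The shipped tests and the acceptance script exercise: exact recovery on a
200-stay noise-free corpus (entity and stay level); 1000 randomized
snippets against the cue-scope oracle; the claim trade-off on a 1000-stay
corpus with 50% undercoding; bootstrap coverage over 100 trials of 300
stays × 1000 resamples against a known claim sensitivity; the learned
qualifier on 2000 cue-determined snippets (70/30 split); and offset round
trips over 500 generated notes. These sizes were chosen so each check has
enough resolution to fail informatively while the whole battery stays
comfortably runnable on a laptop.

## Known limitations

* The dictionaries are starter content; recall on real notes depends
  entirely on their curation, which is the intended clinician-in-the-loop
  workflow.
* The learned qualifier's hashed features are a desk-scale stand-in for a
  contextual encoder; the interface is designed for that substitution.
* Scope-based qualification mishandles long-range or discourse-level
  negation ("no evidence of the following: …").
* Claim mapping ignores diagnosis position and code versions other than
  ICD-10.
* The rule-based severity logic assigns a status per mention; conditions
  whose severity is only derivable from laboratory values or medication
  context are out of reach by design.
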