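---
title: "Rule-based verification of PSI chart documentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based verification of PSI chart documentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psichart)
```

## The verification model

A prostate seed implant (PSI) chart consists of five core documents — the
prescription, the volume study report, the quality checklist, the
radiation survey report and the end-of-treatment note — whose default
schemas carry 20, 16, 34, 27 and 36 checkable items respectively, 133 data
points in total. Each item is a `field_spec`: the labels under which it
appears in the source text, its value type (number with unit, integer,
text, date, enumeration, checkbox), and at most one of three expectations
(an exact expected value, an inclusive numeric range, or a discrete set of
permitted values — the three are mutually exclusive by construction).

Verification is layered, and each layer is total: a check never raises on
document *content*; every anomaly becomes a result with a severity.

1. **Completeness.** One result per required, auto-checkable field.
   `missing` and `unparsable` are errors; an expected-value mismatch is an
   error; a picture-backed field is `manual_required`. The count of
   completeness results for a document is therefore a schema constant,
   which the tests assert.
2. **Consistency.** A rule names two or more `(document, field)` pairs and
   a comparator — exact equality after unit/whitespace/case
   normalization, or a numeric tolerance (default 0; the prostate-volume
   comparison tolerates nothing, so a 33 vs. 30 cm³ pair warns). On a
   mismatch the rule's severity fires **and** a completeness pass over
   every involved document is appended with `triggered_by` set, so the
   report carries the explanation next to the discrepancy. When a
   comparison is impossible (document absent, value missing or
   picture-backed) the result is `manual_required`, never a silent pass:
   the monthly audit treats non-digital material the same way.
3. **Range.** Inclusive bounds on both ends, because institutional limits
   are stated as acceptable values; a value exactly at a bound passes.
   Discrete allowed sets (a prescribed dose of 110 or 145 Gy) use the same
   layer. Missing values are not judged twice — completeness already
   reported them — so the range result defers with a pass-level note.

Severities are fixed at `pass < manual_required < warning < error` for
reporting purposes; consistency mismatches default to warnings, but the
implanted-seed-count rule across quality checklist, survey report and
end-of-treatment note defaults to an error because a disagreement there
points at a real counting problem for post-implant planning.

## The seed nomogram and its tolerance

The bundled nomogram tabulates the average number of I-125 seeds
(0.36 mCi per seed) for prostate volumes 10–80 cm³ in 5 cm³ steps at the
two dose levels in use (110 Gy boost, 145 Gy definitive).

```{r}
seeds_required(30, 145)
seeds_required(32.5, 145)   # linear interpolation between 71 and 78
```

Three numerical choices deserve a note:

* **Interpolation is linear** between rows. Real prostates fall between
  the 5 cm³ rows, and the table is explicitly an *average* requirement, so
  a piecewise-linear reading is the conservative choice. The interpolated
  value is *not* rounded before the difference test — rounding first and
  differencing second would double-round and shift verdicts at the
  tolerance boundary.
* **The tolerance is strict at the boundary**: with `d = manual − nomogram`
  and tolerance 5, `d = +5` and `d = −5` pass; only `|d| > 5` triggers.
  Over-orders warn (physicist verification), under-orders error
  (immediate attention) — under-ordering is the clinically dangerous
  direction, and for the same reason `round_order_quantity()` always
  rounds *up* to the 5-seed ordering increment.
* **No extrapolation.** Volumes outside 10–80 cm³ raise a condition
  carrying a manual-review flag; the nomogram encodes institutional scope
  and guessing beyond it would be invented clinical guidance. How a clinic
  compares manual numbers at non-tabulated volumes (nearest row vs.
  interpolation) is genuinely open; interpolation was chosen here and is
  config-replaceable along with the table itself.

```{r}
classify_order(77, 30, 145)$severity   # d = +6
classify_order(65, 30, 145)$severity   # d = -6
classify_order(76, 30, 145)$severity   # d = +5, boundary passes
```

## Document extraction

Both readers produce the same block model — ordered text blocks with an
image flag — from which label matching proceeds identically, so a DOCX and
a text-layer PDF of the same document yield identical field values and
statuses (asserted as a property test). Matching tries the exact label
first and then a punctuation/case-insensitive alias; there is deliberately
no fuzzy edit-distance matching, because a silent mismatch is worse than a
missing-field flag. Every `label: value` split of a block is tried, so
labels that themselves contain colons ("Time-out: consent signed") still
match.

PDF reading uses the embedded text layer only. Content painted as an image
— and a fully rasterized (scanned) document, which has images but no text
layer — surfaces as `image_skipped` fields and `manual_required` results.
This mirrors the tool's deliberate no-OCR scope: automation reports what
it cannot read instead of guessing.

Units are normalized over a small synonym table (cc/cm3/cm³; mR/hr;
etc.). A number followed by anything that is not the field's expected unit
is `unparsable` — this is precisely how a stray letter in a numeric field
(a classic transcription typo) surfaces. Dates are accepted in ISO and US
forms because clinical templates are inconsistent about them.

## The monthly audit

The audit item list is configuration, not code: six categories whose slots
are either mapped to concrete checks over the digital documents
(signatures present *and* dated, documents complete, confirmation boxes
ticked) or declared non-digital with a reason. The defaults give 19
auto-checkable slots of 27, with 8 manual to-dos (PNG-embedded plan
approvals, the vendor-confirmation screenshot, binder paperwork, the
hot-lab shipment/assay logbook). Declaring the unreachable items in config
— rather than silently skipping them — is deliberate: the audit report
must account for every slot, and the partition (auto + manual = total) is
asserted in tests. Signature detection is presence-and-dated only; no
image-based signature verification is attempted.

## What the synthetic generator emulates — and what it does not

There is no shareable clinical dataset for chart documents, so the
generator is a first-class module. From one parameter block (volume, dose
level, seed and needle counts, survey readings) it derives an internally
consistent five-document chart — the seed order is the nomogram value
rounded up to the ordering increment — and renders it to DOCX and PDF from
one intermediate representation, byte-deterministically (fixed archive
timestamps), so fixtures never need to be stored.

Defaults are chosen to be clinically plausible: volumes uniform on
15–75 cm³ (inside the nomogram domain with margin), an even split between
110 and 145 Gy, survey readings drawn below their limits (surface
1–6 mR/h against a 10 mR/h limit, 0.05–0.4 mR/h at 1 m against 1 mR/h,
post-procedure care unit 0.2–1.2 mR/h against 2 mR/h), one needle per
roughly four seeds. The paper-trail values (names, meter model, lot
numbers) are constants.

The validation protocol seeds controlled defects — field deletion, a
letter injected into a numeric value, a cross-document inconsistency, a
limit violation, a picture substituted for text — and logs, per mutation,
the check ids that must flag it. The acceptance suite (20 clean + 20
defective charts at a fixed seed, alternating DOCX and PDF) requires zero
warnings/errors on clean charts and 100% recall of detectable defects. Two
generator details protect the ground truth itself: two value mutations are
never aimed at the same consistency rule (equal offsets on both sides of a
rule would cancel), and a typo in a free-text field — which remains a
valid string — is logged as undetectable, which is a true statement about
rule-based checking, not a weakness of the fixture.

What passing these suites does **not** show: the fixtures use one document
dialect (label–value paragraphs plus a header table) with clean spelling
of labels; real Aria templates vary in layout, and adapting to them is
schema configuration (labels and aliases), not new code. The generator
also makes no attempt at statistically realistic clinical distributions —
the checks are rules, not models, and need structural coverage, not
epidemiology.

## Scale of the bundled suites

The shipped tests run the full validation protocol at 20 + 20 charts and
the property suites (nomogram truth table over differences −20…+20, dense
monotonicity grids, format-equivalence over every field of all five
documents); the whole suite completes in well under a minute on a single
CPU. Larger suites are a `build_validation_suite()` call away and scale
linearly.

## Known limitations

* No OCR, by design: anything rasterized is routed to manual inspection.
* Label matching is exact-or-normalized only; a template that renames a
  field needs a schema alias, and the tool will report the field missing
  until it gets one.
* The engine verifies the physician's seed order; it never computes one
  for them. Replacing clinical judgment is out of scope — the tool's job
  is to route human attention, and exception handling stays with the
  physicist.
* Live EMR connectivity is abstracted to a filesystem contract (a
  patient-list file plus per-patient chart directories); a database
  connector is a deployment seam, and the email dispatch is an outbox stub
  with no transport.
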