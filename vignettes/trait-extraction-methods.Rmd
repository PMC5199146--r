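---
title: "Methods: rule-based trait extraction and harmonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based trait extraction and harmonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwctraits)
```

## The problem and the approach

Specimen labels carry body measurements written by generations of
collectors in idiosyncratic but conventional ways. Once digitized into
Darwin Core, that content lands in three generic free-text fields
(`dynamicProperties`, `occurrenceRemarks`, `fieldNotes`) with no shared
syntax: explicit "key: value" pairs, concatenated database column names
(`totalLengthInMM=182`), two-letter abbreviations (`TL`, `SVL`), Imperial
units, unitless numbers, multi-specimen summaries, and the mammalogy
shorthand `total-tail-hindfoot-ear = mass`.

`dwctraits` extracts four targets — body length (five subtype
conventions), body mass, sex and life stage — with ordered regular-
expression matching rather than statistical NLP. The ordering is the
model: more explicit evidence always outranks more abbreviated evidence,

1. explicit key with units (`total length: 230 mm`),
2. explicit key without units (`total length 230`),
3. abbreviation with an adjacent numeric (`TL 230`; the value must start
   within 3 characters of the key),
4. positional shorthand (`235-97-31-25 = 71.9`),

and within the same tier the longer (more specific) match wins any
overlap, so `standard length: 20` can never also fire the generic bare
`length` synonym. Each retained extraction is a provenance quadruplet:
source field, standardized trait type, value, and units (or `"inferred"`),
plus the verbatim matched substring and its character span.

The design consistently prefers false negatives over false positives,
because a wrong measurement silently poisons downstream aggregation while
a missed one merely stays undiscovered:

* mass is only read behind a key (or the shorthand) — a bare `71.9 g`
  in running text is not a body mass;
* single letters `m`/`f` count as sex only when keyed; a field mentioning
  both sexes (a multi-individual lot) yields nothing;
* bare life-stage words (`adult` with no key) are skipped by default; an
  opt-in aggressive mode extracts and flags them;
* keyed measurement *ranges* for mass are dropped (lots), and length
  ranges are kept presence-only (below);
* dash triples that look like dates (`12-05-2003`, or all components
  ≤ 31) never trigger the shorthand.

## Field priority and tie-breaks

For every trait type the first field yielding a match wins, in the order
`dynamicProperties` → `occurrenceRemarks` → `fieldNotes`:
`dynamicProperties` is the field *intended* for attribute–value content
and empirically carries most of it. When several length subtypes survive
for one record, harmonization keeps the one from the highest-priority
field, then the lowest precedence tier, then the leftmost span, then a
fixed subtype order (total, head–body, snout–vent, standard, fork). All
matching is case-insensitive and separator-tolerant (`snout-vent length`,
`snout vent length`, `snoutventlength`).

Numeric tokens accept a decimal comma (`71,9` → 71.9, common with
international publishers) and thousands grouping (`1,250 g` → 1250); the
two are disambiguated by digit-group shape.

## Standardization

All lengths are converted to millimetres and masses to grams with exact
factors (cm ×10, m ×1000, in ×25.4, ft ×304.8; kg ×1000, lb ×453.59237,
oz ×28.349523125; `X lb Y oz` sums its components). Units absent from the
text but certain by community custom — the shorthand — and units simply
absent are both assumed mm/g and flagged `wereLengthUnitsInferred` /
`wereMassUnitsInferred`; inference is always to mm/g, never to kg even
for large values, because the collector customs the flag encodes are
mm/g customs. Values are **truncated** (not rounded) to two decimal
places; lower-precision inputs keep their reported precision. Non-positive
values and unknown unit tokens are rejected, which simply leaves the trait
unset for that record. No plausibility bounds are applied — an 8 m "total
length" passes; outlier screening is a downstream analysis concern, not an
extraction concern.

Length ranges (`standard length: 20–35 mm`) mostly describe
multi-specimen lots, so no midpoint is invented: the record gets
`hasLength = TRUE` and `lengthType = "<subtype> range"` but no
`lengthInMM`.

`derivedSex` is the `dwc:sex` field when non-empty, else the extracted
sex, else empty; `derivedLifeStage` is analogous. `hasSex`/`hasLifeStage`
reflect the *derived* values (true when the Darwin Core field alone is
populated), matching the filter semantics a search portal needs.

## Validation model

Gold standards are per-record labels (`record_id, trait, present, value,
units, keyless_implied`). A record is TP when gold has the trait and the
prediction matches — presence and, for measurements, exact equality of
the harmonized value after truncation (hand-checked gold is verbatim
correct, so no tolerance is warranted); FP when predicted but absent or
different in gold; FN when in gold but not predicted; TN otherwise.
Values a human can infer without any key (`keyless_implied`) are tallied
separately and excluded from the error calculation, since the default
extractor is *designed* not to fire on them. Validation predictions come
from extractions only, never from the `dwc:sex`/`dwc:lifeStage` fallback.

TPR, TNR and MCC are reported to three decimals. When any factor of the
MCC denominator is zero the statistic is undefined; 0 is returned as the
documented convention. The test suite checks MCC against an independent
brute-force oracle (Pearson correlation of the reconstructed binary
vectors), plus its bounds, its symmetry under swapping TP↔TN with FP↔FN,
and the perfect-classifier identity.

Validation samples are drawn exactly the way hand-validation sets are
customarily made from spreadsheets — attach a random-number column, sort
on it, take the first *n* rows — with an explicit seed parameter.

## The synthetic corpus

`generate_corpus()` renders known true values into eight styles:
`explicit_keyed`, `abbreviated`, `shorthand`, `range`, `imperial_units`,
`unitless`, `verbose_multi_individual`, and `empty`. True values are
drawn log-uniformly — body sizes span orders of magnitude — over lengths
5–2000 mm and masses 0.5–25 000 g, with sex in {male, female} and stage
in {adult, juvenile, subadult}; shorthand middle values are drawn so tail
< total length, as the mammal convention implies. Taxa come from a small
per-clade species pool so clade/species aggregation is exercised; about
5% of records have an empty `dwc:class` and rely on collection-context
fallback. Everything is deterministic under a fixed seed.

The first five styles are "clean": their rendering is unambiguous, and
the pipeline is expected to recover the generated truth *exactly* on
them — the test suite asserts zero false positives and zero false
negatives over a 10 000-record clean corpus (that size keeps the full
suite comfortably fast on one CPU while being large enough to hit every
style/unit combination many hundreds of times). The verbose style is the
false-positive guard: sex must never be extracted from it.

What passing these tests does **not** show: the generator writes
grammatical, correctly spelled, single-convention text. Real corpora add
OCR noise, typos, mixed conventions inside one field, JSON-styled
`dynamicProperties`, and vocabulary outside the shipped lexicon. Recovery
rates on the synthetic corpus are therefore an upper bound on real-world
performance, not an estimate of it; real-data quality is what the
gold-standard validation machinery is for.

## Configuration surface

* **Lexicon** (`load_lexicon()`): YAML, per trait class, canonical term →
  explicit/abbreviation synonym lists; absent sections fall back to the
  built-in defaults; a synonym claimed by two canonicals within a class is
  a validation error. The shipped synonym list reconstructs the common
  conventions; it is deliberately config-extensible because no printed
  inventory of the long tail exists.
* **Descriptor taxonomy** (`categorize_descriptors()`): maps verbatim
  descriptors to body regions (head, neck, appendage, tail, trunk,
  wholeOrg, orgPartsComplex, nonOrg) × measurement/qualitative. The
  shipped table (~60 descriptors) is a representative seed, not a census;
  where a descriptor sits (e.g. "gonad" under trunk) is a configuration
  choice, not a fixed fact.
* **Clade buckets**: nine fish classes fold into Fish; the non-vertebrate
  detection list is illustrative and extensible; collection-context
  fallback maps ornithology→Aves, mammalogy→Mammalia, ichthyology→Fish.
  Herpetology is deliberately not mapped — it cannot separate Reptilia
  from Amphibia — so such records stay Unknown.
* **Modes**: `aggressive_lifestage` (flagged keyless stage words); input
  dialect (`csv`, `tsv`, `dwca-core`; Darwin Core Archives are read-only,
  occurrence core only, extensions ignored with a warning).

## Known limitations

* `dynamicProperties` is treated as an opaque string even when it holds
  JSON-styled content; no structured decoding is attempted before
  matching.
* Life-stage values are captured up to the next delimiter, so unpunctuated
  run-on text can carry trailing words into the value.
* Imperial length compounds ("5 ft 3 in") are not parsed (the mass
  compound "2 lb 3 oz" is).
* Species names are not taxonomically resolved; a name split across
  clades by a data error is counted in each clade independently.
* Writing Darwin Core Archives and MeasurementOrFact emission are out of
  scope.
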