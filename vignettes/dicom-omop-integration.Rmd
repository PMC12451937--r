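---
title: "Integrating DICOM terminology into the OMOP CDM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating DICOM terminology into the OMOP CDM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicomop)
```

## The problem

Imaging metadata lives in DICOM headers inside a PACS; structured clinical
data lives in the EHR, increasingly harmonized to the OMOP Common Data Model.
An observational researcher who wants "patients with a T1-weighted volumetric
brain MRI" cannot express that phenotype in OMOP because the acquisition
parameters that define it (repetition, echo and inversion times; modality;
body part) have no OMOP concepts. `dicomop` closes that gap in four stages:

1. **standard model** -- load a normalized representation of the DICOM
   Standard's content: the Part-6 attribute dictionary, Part-16 context
   groups (coded value sets) and the Part-3 Enumerated Values / Defined
   Terms with their per-attribute constraints.
2. **vocabulary build** -- deduplicate the coded values, mint custom OMOP
   concepts for attributes and values, and connect them with
   `"Maps to value"` (attribute to permitted value) and `"Maps to"` (DICOM
   value to standard SNOMED concept) relationships.
3. **harvest and load** -- index a DICOM file tree, extract one header per
   series, filter elements by value representation, and load the result into
   the medical-imaging extension tables (`Procedure_occurrence`,
   `Image_occurrence`, `Image_feature`, `Measurement`).
4. **cohorts** -- evaluate conjunctive attribute criteria over the loaded
   tables, in memory or via SQL against an SQLite store.

## The vocabulary model

Every dictionary attribute with a non-empty name becomes a concept of class
`Attribute` whose `concept_code` is its 8-hex-digit tag. Coded values become
class `Value` concepts from two sources:

* **Context-group members** managed by DICOM (coding scheme `DCM`). A code
  may belong to several context groups; occurrences are collapsed by
  `(scheme, code)` with the CID memberships unioned, and the concept code is
  `DCM:<code>`. Members drawn from foreign terminologies (SNOMED `SCT`,
  LOINC `LN`) never receive custom concepts -- they are reachable only
  through an *external concept resolver* that maps `(scheme, code)` to
  pre-existing standard concept ids.
* **Part-3 terms**, the per-attribute string constraints. A term whose value
  string exactly equals an existing `DCM` code value is a duplicate: it does
  not become a second concept. Matching is case-sensitive by design --
  DICOM code strings are upper-case by convention, and case-folding could
  merge genuinely distinct codes. Surviving terms get concept code
  `<tag>:<value>`.

Custom ids are consecutive integers from a configurable base, by default
2&nbsp;128&nbsp;000&nbsp;000, inside the 2-billion range OMOP reserves for
site-defined concepts. Because the id sequence is meaningful only if it is
reproducible, payloads are ordered deterministically before assignment:
attributes by tag, then `DCM` values by `(scheme, code)`, then term values by
`(attribute, value)`. Rebuilding from the same input yields byte-identical
tables; permuting input rows changes nothing downstream.

Relationships follow the constraints:

* a **CID constraint** (attribute A restricted to context group G) yields one
  `"Maps to value"` row per `DCM` member of G;
* a **TermList constraint** yields one `"Maps to value"` row per term of the
  attribute. A term that was dropped as a duplicate still produces a row --
  pointing at the `DCM` twin concept that absorbed it. This is the design
  choice that keeps deduplication lossless: the attribute-to-value mapping
  survives even when the value concept is shared. Without it, collapsing a
  duplicate would silently delete the constraint it documented;
* each **body-part cross-map** row whose value string has a value concept and
  whose SNOMED code the resolver knows yields one `"Maps to"` row.
  Unresolvable rows are logged and skipped, never fatal, because cross-map
  coverage is inherently partial.

The build summary counts concepts by category and -- following the reporting
convention of vocabulary work in this space -- counts relationship rows
toward the total vocabulary content, while the emitted CSVs keep
relationships strictly in `CONCEPT_RELATIONSHIP.csv`.

## Harvesting and the VR filter

The harvester reads one instance per series: the file with the lowest
Instance Number, ties broken by lexicographic path. The standard only says
*one image per series*; fixing the representative makes re-indexing
deterministic. Only top-level data elements are used. Sequences (`SQ`) are
skipped, not descended -- nested anatomic codes are therefore unavailable,
consistent with a filter that excludes `SQ` anyway -- and private tags (odd
group numbers) are never emitted, since their meaning is
manufacturer-specific.

Filtering is a pure predicate applied in two steps: elements whose value is
empty after trimming whitespace and padding are dropped first; the remainder
are kept iff their VR is one of

```
AT CS DA DT DS FL FD IS SL SS SV TM UL US UV
```

(numeric, coded, date and time representations) *or* the element is
Manufacturer `(0008,0070)` -- the single free-text exception, kept because
manufacturer is a practical cohort criterion. Counts of both drop reasons are
attached to the result, since the split between empty-value and VR drops is a
useful data-quality signal in its own right.

## Loading conventions

* One `Procedure_occurrence` row per study, one `Image_occurrence` row per
  series, and exactly one `Image_feature` + `Measurement` pair per kept
  element -- the conservation chain asserted throughout the tests.
* `measurement_date` and the image-occurrence date are the Series Date,
  converted from DICOM `DA` (`YYYYMMDD`) to ISO.
* `value_as_number` is parsed only for the numeric VRs
  (`DS IS FL FD SL SS SV UL US UV`); `value_as_concept_id` is set when a
  coded value resolves through a `"Maps to value"` path; never both. Date
  and time values (`DA`, `DT`, `TM`) stay in `value_source_value` only --
  no numeric encoding of dates is defined here, and inventing one would be
  easy to misuse in range criteria.
* Modality or body-part strings that do not resolve map to concept 0 rather
  than failing: real-world archives populate these fields inconsistently,
  and a loader that aborts on the first nonconformant value is useless for
  exactly the data that most needs auditing. Units are not populated;
  DICOM's implicit units (TR/TE/TI in ms) travel with the attribute concept.

## Cohort semantics

A definition is a conjunction of criteria (`present`, `eq`, `in_range`) plus
an optional modality. All criteria must hold **within the same series**: a
patient with the right TR in one series and the right TE only in another
does not match. This is the stricter of the two possible readings and the
protocol-faithful one -- acquisition parameters characterize a series, not a
patient. Numeric criteria compare `value_as_number` inclusively at both
bounds; criteria on date/time attributes are not supported in this version.
In-memory evaluation and the generated SQL (one `EXISTS` subquery per
criterion, scoped to the `image_occurrence` row) are required by the test
suite to agree exactly.

The built-in `t1_volumetric_definition()` (TI present, TR 2100--2500 ms,
TE 2--4 ms, TI 800--1100 ms) is calibrated to the package's own synthetic
MPRAGE protocol. They are configuration defaults to adapt to a real
archive's protocols, not reference thresholds.

## What the synthetic data emulates

**Standard-content profiles.** The `"table2"` profile generates normalized
standard content whose category counts reproduce a full vocabulary build:
5190 dictionary attributes of which 7 are nameless; 5223 context-group
member occurrences over 3281 distinct `DCM` codes, of which 1063 appear in
more than one CID; Part-3 term lists of 79 (Modality, 74 duplicating CID
codes), 318 (Body Part Examined), 16 (Patient Position) and 8 (Lossy Image
Compression Method); a 398-row body-part cross-map with 307 resolvable
SNOMED targets. Totals 5223 and 3281 with 1063 repeats do not determine the
per-code multiplicities, so the profile fixes one admissible plan -- 879
codes in three CIDs, 184 in two, 2218 in one -- and sizes the CID
constraints (two attributes sharing one group of 999 singletons, two sharing
one triple-occurrence group, and so on) so that the build yields 7101
CID-derived `"Maps to value"` rows. The term side adds a fifth constrained
attribute, a synthetic anatomic-region code attribute whose 318 terms all
duplicate CID codes: with the duplicate-to-twin rule above, term-derived
rows total 79 + 318 + 318 + 16 + 8 = 739 while value concepts stay at
3281 + 318 + 5 + 16 + 8 = 3628. The seed only shuffles row order -- content
is fixed by the counts -- which is precisely what the order-insensitivity
property needs to be a meaningful test.

**DICOM trees.** `make_dicom_fixture()` writes genuine Part-10 files
(explicit VR little endian, written and read by the package's own I/O layer,
conformance-checked against an independent DICOM reader in the tests) laid
out patient/study/series/instance, with MPRAGE, T2 and FLAIR acquisition
parameters; MPRAGE and FLAIR carry an inversion time, T2 does not, so TI
presence plus TR/TE ranges separates the protocols. Each series also
carries a private tag, a sequence, a placeholder pixel-data element, an
always-empty element and excluded-VR elements, so the filter's every branch
is exercised; a manifest CSV records per-series ground truth, including the
expected kept-element count, and serves as the oracle for the conservation
chain. UIDs use a test OID root and patients are `SYN-xxxx`, so nothing can
be mistaken for real data.

What the fixtures deliberately do **not** emulate: pixel content (frames are
placeholders), implicit-VR or big-endian transfer syntaxes, multi-frame and
encapsulated objects, vendor-specific private blocks, or the free-text chaos
of real Series Description fields. Passing tests therefore demonstrate the
correctness of the vocabulary construction, filtering, loading and cohort
logic -- not robustness against every archive in the wild.

**EHR tables.** `make_ehr_fixture()` produces person/condition/measurement
CSVs with a cognitively-normal : MCI : AD mix defaulting to 133 : 151 : 87
(an ADNI-3-like cohort composition) allocated by largest remainder, plus the
patient-to-person map the loader needs.

## Numerical and edge-case choices

* Tags are canonicalized to 8 upper-case hex digits; `(gggg,eeee)` is
  presentation only.
* Unknown VR codes in the dictionary are errors, not warnings: silent schema
  drift in the ingestion contract is worse than a hard stop. Retired
  attributes load like active ones.
* Value decoding falls back to byte-wise replacement on malformed text, so
  one bad file cannot abort a harvest; unreadable files are skipped and
  listed, and an empty tree yields an empty index with a warning.
* Empty-value testing strips whitespace and the trailing space/NUL padding
  DICOM uses to even out lengths.
* `dedup(dedup(x)) == dedup(x)` and permutation invariance are asserted
  against a brute-force distinct-set oracle on random multisets.

## Problem sizes in the test suite

The suite builds the `"table2"` profile (5190 attributes, 5223 occurrences)
in well under a second, uses DICOM trees of 8--30 files with 1--5 instances
per series, and EHR fixtures up to 371 persons -- sizes chosen so the whole
suite, including the double-run determinism check of the full pipeline,
completes in seconds while still covering every code path at full fidelity.

## Known limitations

* Only explicit VR little endian Part-10 files are read or written; an
  adapter for other transfer syntaxes would slot in at `read_dicom()`.
* The official DocBook XML of the DICOM Standard is not parsed; the
  normalized interchange schema (documented in
  `inst/extdata/interchange-schema.json`) is the ingestion contract, and a
  DocBook adapter targeting it is future work.
* Which edition of the Standard a given interchange bundle reflects is the
  producer's responsibility; category counts are edition-dependent.
* Hierarchical (`Is a`) relationships, concept synonyms, and
  vocabulary-driven mapping of free-text fields beyond Manufacturer are out
  of scope.
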