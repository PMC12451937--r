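# dicomop

Integrate DICOM Standard terminology into the OMOP Common Data Model.

## The problem

DICOM headers carry the acquisition parameters that actually define an
imaging protocol — repetition time (TR), echo time (TE), inversion time
(TI), modality, body part — but those parameters have no concepts in the
OMOP CDM, so EHR-based observational research cannot phenotype on them. An
order for "Brain MRI" in the EHR cannot distinguish a T1-weighted
volumetric MPRAGE from a T2 or FLAIR series; the DICOM metadata can.

`dicomop` is for imaging informaticists and OHDSI-style observational
researchers who want imaging phenotypes to be first-class OMOP citizens. It:

* builds a **custom OMOP vocabulary** from normalized DICOM Standard
  content: Part-6 attributes become concepts of class `Attribute`
  (`concept_code` = 8-hex tag), Part-16 context-group codes and Part-3
  Enumerated Values / Defined Terms become class `Value` concepts
  (`DCM:<code>` / `<tag>:<value>`), with consecutive custom ids from
  2 128 000 000 in OMOP's reserved 2-billion range;
* connects them with `"Maps to value"` rows (attribute → permitted value,
  one per context-group member or term) and `"Maps to"` rows (DICOM
  body-part value → standard SNOMED concept via an external resolver);
* **harvests** DICOM Part-10 file trees (one header per series, lowest
  Instance Number), filters elements to the value-representation whitelist
  `AT CS DA DT DS FL FD IS SL SS SV TM UL US UV` plus the Manufacturer
  `(0008,0070)` free-text exception, after dropping empty values;
* **loads** the OMOP medical-imaging extension tables — one
  `Procedure_occurrence` per study, one `Image_occurrence` per series, one
  `Image_feature` + `Measurement` pair per kept element;
* **evaluates cohort definitions** (conjunctions of `present` / `eq` /
  `in_range` criteria, series-scoped) in memory or as SQL against an SQLite
  store, e.g. T1-volumetric MRI as {TI present, TR ∈ [2100, 2500] ms,
  TE ∈ [2, 4] ms, TI ∈ [800, 1100] ms};
* ships deterministic **synthetic-data generators**: normalized standard
  bundles (including a profile reproducing a full build's category counts),
  genuine Part-10 MR file trees (MPRAGE/T2/FLAIR), and simulated EHR
  tables.

## Worked example

```r
library(dicomop)

# 1. generate normalized standard content and build the vocabulary
std <- file.path(tempdir(), "std")
make_standard_fixture(standard_fixture_profile("table2"), std)
vocab <- build_dicom_vocabulary(load_standard_bundle(std))
vocab$summary
#> OMOP concepts for DICOM terminology
#>   Attributes (Part 6)                   5183
#>   Coded values: context groups (DCM)    3281
#>                 Body Part Examined       318
#>                 Modality                   5
#>                 Patient Position          16
#>                 Lossy Compression          8
#>   Total coded values                    3628
#>   'Maps to value' relationships         7840
#>   'Maps to' relationships                307
#>   Total relationships                   8147
#>   Total vocabulary content             16958
vdir <- file.path(tempdir(), "vocab"); emit_vocabulary(vocab, vdir)

# 2. synthesize an MR archive, harvest it, and load the extension tables
dcm <- file.path(tempdir(), "dcm")
make_dicom_fixture(dicom_fixture_spec(n_patients = 15, series_per_study = 1,
  protocol_mix = c(MPRAGE = 2/3, T2 = 1/3, FLAIR = 0), seed = 23), dcm)
h <- harvest_dataset(dcm)
ehr <- make_ehr_fixture(15, seed = 4, out_dir = file.path(tempdir(), "ehr"))
rows <- build_cdm_rows(h$series, h$elements, vdir, ehr$patient_map)
sapply(rows, nrow)
#> procedure_occurrence     image_occurrence        image_feature
#>                   15                   15                  235
#>          measurement
#>                  235

# 3. find the patients with a T1-weighted volumetric series
res <- evaluate_cohort(t1_volumetric_definition(), rows)
res
#> <cohort_result> 10 persons, 10 series
head(res$series_uids, 3)
#> [1] "1.2.826.0.1.3680043.9999.1.10.1.1" "1.2.826.0.1.3680043.9999.1.12.1.1"
#> [3] "1.2.826.0.1.3680043.9999.1.14.1.1"
```

Reading the output: the build minted 5183 attribute concepts (5190
dictionary entries minus 7 without names) and 3628 coded-value concepts
(3281 deduplicated context-group codes plus the surviving Body Part
Examined, Modality, Patient Position and compression terms); 7840
attribute→value and 307 value→SNOMED relationship rows connect them. The 15
synthetic patients yielded 235 kept metadata elements — exactly one
`Image_feature` and one `Measurement` row each — and the ten patients whose
single series is an MPRAGE (TI present, TR/TE/TI in range) form the
T1-volumetric cohort.

A thin command-line front-end wraps the same functions
(`inst/cli/dicomop.R`: `build-vocab`, `harvest`, `load-cdm`, `cohort`,
`fixtures`); the methods vignette
(`vignettes/dicom-omop-integration.Rmd`) documents the model, the design
choices and the limits of the synthetic data.

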