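# dedicated archive for cohort tests: 15 patients, one series each,
# two-thirds MPRAGE (TI present) and one-third T2 (no TI)
cohort_dataset <- function() {
  if (is.null(.fixture_cache$cohort)) {
    dir <- file.path(tempdir(), "dicomop-cohort-fixture")
    spec <- dicom_fixture_spec(n_patients = 15, series_per_study = 1,
                               instances_per_series = 1,
                               protocol_mix = c(MPRAGE = 10 / 15, T2 = 5 / 15,
                                                FLAIR = 0),
                               seed = 23)
    manifest <- make_dicom_fixture(spec, dir)
    harvest <- harvest_dataset(dir)
    ehr <- make_ehr_fixture(15, seed = 4, out_dir = tempfile())
    rows <- build_cdm_rows(harvest$series, harvest$elements,
                           table2_build()$vocab_dir, ehr$patient_map)
    db <- file.path(tempdir(), "dicomop-cohort.sqlite")
    load_cdm_sqlite(rows, db)
    .fixture_cache$cohort <- list(manifest = manifest, rows = rows, db = db,
                                  ehr = ehr)
  }
  .fixture_cache$cohort
}

test_that("a vacuous criterion matches every imaged person", {
  fx <- cohort_dataset()
  defn <- cohort_definition(cohort_criterion("00180080", "present"))
  res <- evaluate_cohort(defn, fx$rows)
  expect_setequal(res$person_ids, unique(fx$rows$image_occurrence$person_id))
  expect_setequal(res$series_uids, fx$manifest$series_uid)
})

test_that("the T1-volumetric definition selects exactly the MPRAGE patients", {
  fx <- cohort_dataset()
  res <- evaluate_cohort(t1_volumetric_definition(), fx$rows)
  mprage <- fx$manifest[fx$manifest$protocol == "MPRAGE", ]
  expect_equal(nrow(mprage), 10)
  expect_setequal(res$series_uids, mprage$series_uid)
  expected_persons <- fx$ehr$patient_map$person_id[
    fx$ehr$patient_map$patient_id %in% mprage$patient_id]
  expect_setequal(res$person_ids, expected_persons)
  expect_length(res$person_ids, 10)
  # every matched series belongs to a matched person
  expect_true(all(res$matches$person_id %in% res$person_ids))
})

test_that("criteria on attributes absent from all series give empty results", {
  fx <- cohort_dataset()
  res <- evaluate_cohort(
    cohort_definition(cohort_criterion("00181060", "present")), fx$rows)
  expect_length(res$series_uids, 0)
  expect_length(res$person_ids, 0)
  # malformed criteria are definition errors
  expect_error(cohort_criterion("zz", "present"), "malformed")
  expect_error(cohort_criterion("00180080", "eq"), "value")
  expect_error(cohort_criterion("00180080", "in_range", low = 5, high = 1), "low")
  expect_error(cohort_definition(), "at least one")
})

test_that("adding a criterion never enlarges the cohort", {
  fx <- cohort_dataset()
  pool <- list(
    cohort_criterion("00180082", "present"),
    cohort_criterion("00180080", "in_range", low = 2100, high = 2500),
    cohort_criterion("00180081", "in_range", low = 2, high = 4),
    cohort_criterion("00185100", "eq", value = "HFS"),
    cohort_criterion("00080070", "eq", value = "SYN Imaging Works"),
    cohort_criterion("00180087", "in_range", low = 3, high = 3)
  )
  set.seed(17)
  for (rep in 1:5) {
    seq_idx <- sample(seq_along(pool))
    acc <- list()
    prev <- NULL
    for (i in seq_idx) {
      acc <- c(acc, list(pool[[i]]))
      res <- evaluate_cohort(cohort_definition(acc), fx$rows)
      if (!is.null(prev)) {
        expect_true(all(res$series_uids %in% prev))
      }
      prev <- res$series_uids
    }
  }
})

test_that("CSV-backed and SQL-backed evaluation agree exactly", {
  fx <- cohort_dataset()
  defns <- list(
    t1_volumetric_definition(),
    cohort_definition(cohort_criterion("00180080", "present"), modality = "MR"),
    cohort_definition(cohort_criterion("00080070", "eq",
                                       value = "SYN Imaging Works")),
    cohort_definition(cohort_criterion("00181060", "present")),
    cohort_definition(modality = "CT")
  )
  for (defn in defns) {
    in_memory <- evaluate_cohort(defn, fx$rows)
    via_sql <- evaluate_cohort(defn, fx$db)
    expect_equal(via_sql$series_uids, in_memory$series_uids)
    expect_equal(via_sql$person_ids, in_memory$person_ids)
  }
})

test_that("results export as UID list, person counts and reproducing SQL", {
  fx <- cohort_dataset()
  defn <- t1_volumetric_definition()
  res <- evaluate_cohort(defn, fx$rows)
  out <- tempfile()
  paths <- export_cohort_result(res, out, defn)
  expect_equal(readLines(file.path(out, "series_uids.txt")), res$series_uids)
  persons <- readr::read_csv(file.path(out, "persons.csv"),
                             col_types = readr::cols())
  expect_setequal(persons$person_id, res$person_ids)
  expect_equal(sum(persons$n_matching_series), nrow(res$matches))
  sql <- paste(readLines(file.path(out, "cohort.sql")), collapse = "\n")
  expect_match(sql, "EXISTS", fixed = TRUE)

  empty <- evaluate_cohort(
    cohort_definition(cohort_criterion("00181060", "present")), fx$rows)
  out2 <- tempfile()
  export_cohort_result(empty, out2)
  expect_equal(length(readLines(file.path(out2, "series_uids.txt"))), 0)
})

test_that("cohort definitions load from YAML config files", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("modality: MR",
               "criteria:",
               "  - {attribute: '00180082', op: present}",
               "  - {attribute: '00180080', op: in_range, low: 2100, high: 2500}"),
             path)
  defn <- read_cohort_definition(path)
  expect_s3_class(defn, "cohort_definition")
  expect_equal(defn$modality, "MR")
  expect_length(defn$criteria, 2)
  fx <- cohort_dataset()
  expect_equal(evaluate_cohort(defn, fx$rows)$series_uids,
               evaluate_cohort(defn, fx$db)$series_uids)
})
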