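# Shared fixtures, built once per test run and cached in the session.

.fixture_cache <- new.env(parent = emptyenv())

# table2-profile standard bundle and its vocabulary build
table2_build <- function() {
  if (is.null(.fixture_cache$table2)) {
    dir <- file.path(tempdir(), "dicomop-table2-fixture")
    make_standard_fixture(standard_fixture_profile("table2", seed = 1), dir)
    bundle <- load_standard_bundle(dir)
    vocab <- build_dicom_vocabulary(bundle)
    vocab_dir <- file.path(tempdir(), "dicomop-table2-vocab")
    emit_vocabulary(vocab, vocab_dir)
    .fixture_cache$table2 <- list(dir = dir, bundle = bundle, vocab = vocab,
                                  vocab_dir = vocab_dir)
  }
  .fixture_cache$table2
}

tiny_build <- function() {
  if (is.null(.fixture_cache$tiny)) {
    dir <- file.path(tempdir(), "dicomop-tiny-fixture")
    make_standard_fixture(standard_fixture_profile("tiny", seed = 1), dir)
    bundle <- load_standard_bundle(dir)
    .fixture_cache$tiny <- list(dir = dir, bundle = bundle,
                                vocab = build_dicom_vocabulary(bundle))
  }
  .fixture_cache$tiny
}

# small MR archive: 3 patients x 2 series x 5 instances, harvested and loaded
mr_dataset <- function() {
  if (is.null(.fixture_cache$mr)) {
    dir <- file.path(tempdir(), "dicomop-mr-fixture")
    spec <- dicom_fixture_spec(n_patients = 3, series_per_study = 2,
                               instances_per_series = 5,
                               missing_bodypart_rate = 0.2,
                               empty_value_rate = 0.2, seed = 11)
    manifest <- make_dicom_fixture(spec, dir)
    harvest <- harvest_dataset(dir)
    ehr_dir <- file.path(tempdir(), "dicomop-ehr-fixture")
    ehr <- make_ehr_fixture(5, seed = 3, out_dir = ehr_dir)
    rows <- build_cdm_rows(harvest$series, harvest$elements,
                           table2_build()$vocab_dir, ehr$patient_map)
    .fixture_cache$mr <- list(dir = dir, spec = spec, manifest = manifest,
                              harvest = harvest, ehr = ehr, rows = rows)
  }
  .fixture_cache$mr
}

# write a one-off DICOM file from (tag, vr, value) triples
write_test_dicom <- function(..., path = tempfile(fileext = ".dcm")) {
  triples <- list(...)
  df <- tibble::tibble(tag = vapply(triples, function(x) x[[1]], ""),
                       vr = vapply(triples, function(x) x[[2]], ""),
                       value = lapply(triples, function(x) x[[3]]))
  write_dicom(df, path)
  path
}

# brute-force distinct-set oracle over occurrence rows (independent of dplyr
# grouping): distinct (scheme, code) pairs and per-pair cid sets via base R
oracle_distinct_codes <- function(occurrences) {
  occ <- occurrences[occurrences$is_dcm, , drop = FALSE]
  key <- paste(occ$scheme, occ$code, sep = "\r")
  split_cids <- split(occ$cid, key)
  list(n = length(split_cids),
       cids = lapply(split_cids, function(x) sort(unique(x))))
}

random_occurrences <- function(n, n_codes = 12, n_cids = 5, p_foreign = 0.2) {
  scheme <- ifelse(stats::runif(n) < p_foreign, "SCT", "DCM")
  tibble::tibble(
    cid = sample.int(n_cids, n, replace = TRUE),
    scheme = scheme,
    code = sprintf("C%02d", sample.int(n_codes, n, replace = TRUE)),
    meaning = "m",
    is_dcm = scheme == "DCM"
  )
}
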