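test_that("attribute dictionary parses rows in order and canonicalizes tags", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("tag,name,keyword,vr,vm,retired",
               '"(0008,0060)",Modality,Modality,CS,1,FALSE',
               "00180080,Repetition Time,RepetitionTime,DS,1,FALSE",
               "300a0001,,,UN,1,TRUE"), path)
  dict <- load_attribute_dictionary(path)
  expect_equal(dict$tag, c("00080060", "00180080", "300A0001"))
  expect_equal(dict$name[1], "Modality")
  expect_equal(dict$vr, c("CS", "DS", "UN"))
  expect_equal(dict$retired, c(FALSE, FALSE, TRUE))
  expect_equal(dict$source_part, rep("6", 3))
  # nameless entries are retained at load time
  expect_equal(sum(!nzchar(dict$name)), 1)

  empty <- tempfile(fileext = ".csv")
  writeLines("tag,name,keyword,vr,vm,retired", empty)
  expect_equal(nrow(load_attribute_dictionary(empty)), 0)
})

test_that("malformed tags, unknown VRs, duplicates and missing cids are schema errors", {
  bad_tag <- tempfile(fileext = ".csv")
  writeLines(c("tag,name,keyword,vr,vm,retired", "00080060,Modality,Modality,CS,1,FALSE",
               "NOTATAG,Broken,Broken,CS,1,FALSE"), bad_tag)
  expect_error(load_attribute_dictionary(bad_tag), "row 2", class = "dicomop_schema_error")

  bad_vr <- tempfile(fileext = ".csv")
  writeLines(c("tag,name,keyword,vr,vm,retired", "00080060,Modality,Modality,XX,1,FALSE"),
             bad_vr)
  expect_error(load_attribute_dictionary(bad_vr), "unknown VR",
               class = "dicomop_schema_error")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("tag,name,keyword,vr,vm,retired",
               "00080060,Modality,Modality,CS,1,FALSE",
               "00080060,Modality Again,Modality2,CS,1,FALSE"), dup)
  expect_error(load_attribute_dictionary(dup), "duplicate tag",
               class = "dicomop_schema_error")

  no_cid <- tempfile(fileext = ".csv")
  writeLines(c("cid,scheme,code,meaning", ",DCM,MR,Magnetic Resonance"), no_cid)
  expect_error(load_context_groups(no_cid), "cid", class = "dicomop_schema_error")
})

test_that("context-group occurrences pass through un-deduplicated and flag non-DCM schemes", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("cid,scheme,code,meaning",
               "29,DCM,MR,Magnetic Resonance",
               "30,DCM,MR,Magnetic Resonance",
               "4030,SCT,113091000,Magnetic resonance imaging"), path)
  p16 <- load_context_groups(path)
  expect_equal(nrow(p16$occurrences), 3)
  expect_equal(sum(p16$occurrences$code == "MR"), 2)  # not yet collapsed
  expect_equal(p16$occurrences$is_dcm, c(TRUE, TRUE, FALSE))
})

test_that("part-3 terms collapse duplicate rows and reject dangling attribute tags", {
  dict_path <- tempfile(fileext = ".csv")
  writeLines(c("tag,name,keyword,vr,vm,retired",
               "00080060,Modality,Modality,CS,1,FALSE"), dict_path)
  dict <- load_attribute_dictionary(dict_path)

  set.seed(42)
  pool <- sprintf("V%02d", 1:8)
  draws <- sample(pool, 30, replace = TRUE)
  terms_path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(attribute_tag = "00080060", value_string = draws,
                                  meaning = paste("meaning", draws),
                                  term_kind = "Defined", snomed_code = ""),
                   terms_path)
  p3 <- load_part3_terms(terms_path, NULL, dict)
  # independent distinct oracle: scan of the raw draws
  expect_equal(nrow(p3$terms), length(unique(draws)))
  expect_setequal(p3$terms$value_string, unique(draws))

  dangling <- tempfile(fileext = ".csv")
  writeLines(c("attribute_tag,value_string,meaning,term_kind,snomed_code",
               "00185100,HFS,Head First Supine,Enumerated,"), dangling)
  expect_error(load_part3_terms(dangling, NULL, dict),
               class = "dicomop_referential_error")
})

test_that("the table2 bundle reproduces the standard's category counts", {
  fx <- table2_build()
  b <- fx$bundle
  expect_equal(nrow(b$attributes), 5190)
  expect_equal(sum(!nzchar(trimws(b$attributes$name))), 7)
  expect_equal(nrow(b$occurrences), 5223)
  expect_true(all(b$occurrences$is_dcm))
  expect_equal(nrow(b$bodypart_map), 398)
  counts <- table(b$terms$attribute_tag)
  expect_equal(unname(counts[["00080060"]]), 79)   # Modality
  expect_equal(unname(counts[["00180015"]]), 318)  # Body Part Examined
  expect_equal(unname(counts[["00185100"]]), 16)   # Patient Position
  expect_equal(unname(counts[["00282114"]]), 8)    # Lossy Image Compression Method
})

test_that("bundles round-trip through the interchange format", {
  fx <- table2_build()
  out <- tempfile()
  write_standard_bundle(fx$bundle, out)
  again <- load_standard_bundle(out)
  expect_equal(again$attributes, fx$bundle$attributes)
  expect_equal(again$occurrences, fx$bundle$occurrences)
  expect_equal(again$terms, fx$bundle$terms)
  expect_equal(again$constraints, fx$bundle$constraints)
  expect_equal(again$bodypart_map, fx$bundle$bodypart_map)
})

test_that("permuting interchange rows changes no downstream concept set", {
  fx <- table2_build()
  perm_dir <- tempfile()
  dir.create(perm_dir)
  file.copy(list.files(fx$dir, full.names = TRUE), perm_dir)
  set.seed(99)
  for (f in c("attributes.csv", "cid_members.csv", "part3_terms.csv")) {
    df <- readr::read_csv(file.path(perm_dir, f),
                          col_types = readr::cols(.default = readr::col_character()),
                          na = character())
    readr::write_csv(df[sample.int(nrow(df)), ], file.path(perm_dir, f))
  }
  vocab_perm <- build_dicom_vocabulary(load_standard_bundle(perm_dir))
  expect_equal(vocab_perm$concepts$concept_id, fx$vocab$concepts$concept_id)
  expect_equal(vocab_perm$concepts$concept_code, fx$vocab$concepts$concept_code)
  rel_key <- function(v) sort(paste(v$relationships$concept_id_1,
                                    v$relationships$concept_id_2,
                                    v$relationships$relationship_id))
  expect_equal(rel_key(vocab_perm), rel_key(fx$vocab))
})
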