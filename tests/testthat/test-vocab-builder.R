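make_dict <- function(...) {
  rows <- list(...)
  tibble::tibble(tag = vapply(rows, `[`, "", 1), name = vapply(rows, `[`, "", 2),
                 keyword = gsub(" ", "", vapply(rows, `[`, "", 2)),
                 vr = vapply(rows, `[`, "", 3), vm = "1", retired = FALSE,
                 source_part = "6")
}

test_that("nameless dictionary entries are excluded from attribute concepts", {
  dict <- make_dict(c("00080060", "Modality", "CS"), c("00180080", "", "DS"),
                    c("00180081", "Echo Time", "DS"))
  payload <- build_attribute_concepts(dict)
  expect_equal(nrow(payload), 2)
  expect_setequal(payload$concept_code, c("00080060", "00180081"))

  none <- build_attribute_concepts(make_dict(c("00080060", "", "CS")))
  expect_equal(nrow(none), 0)
  all_named <- build_attribute_concepts(make_dict(c("00080060", "Modality", "CS")))
  expect_equal(nrow(all_named), 1)
})

test_that("deduplication matches a brute-force oracle, is idempotent and permutation-invariant", {
  set.seed(7)
  for (rep in 1:20) {
    occ <- random_occurrences(n = sample(5:60, 1))
    deduped <- dedup_coded_values(occ)
    oracle <- oracle_distinct_codes(occ)
    expect_equal(nrow(deduped$values), oracle$n)
    got_cids <- setNames(deduped$values$cids,
                         paste(deduped$values$scheme, deduped$values$code, sep = "\r"))
    expect_equal(got_cids[names(oracle$cids)], oracle$cids, ignore_attr = TRUE)

    # permutation invariance
    perm <- occ[sample.int(nrow(occ)), ]
    expect_equal(dedup_coded_values(perm)$values, deduped$values)

    # idempotence: re-collapsing the collapsed set changes nothing
    flat <- tidyr::unnest(deduped$values, "cids") |>
      dplyr::transmute(cid = cids, scheme, code, meaning, is_dcm = TRUE)
    expect_equal(dedup_coded_values(flat)$values, deduped$values)
  }
})

test_that("part-3 terms matching DCM code values are flagged as duplicates", {
  occ <- tibble::tibble(cid = c(29, 30, 29), scheme = "DCM",
                        code = c("MR", "MR", "CT"), meaning = "m", is_dcm = TRUE)
  terms <- tibble::tibble(attribute_tag = "00080060",
                          value_string = c("MR", "CS", "mr"),
                          meaning = "", term_kind = "Defined", snomed_code = "")
  deduped <- dedup_coded_values(occ, terms)
  expect_equal(nrow(deduped$values), 2)
  expect_equal(deduped$values$cids[deduped$values$code == "MR"][[1]], c(29, 30))
  # exact, case-sensitive matching: "mr" survives, "MR" is a duplicate
  expect_equal(deduped$terms$duplicate_of_dcm, c(TRUE, FALSE, FALSE))
})

test_that("concept ids start at the base, are consecutive, and rebuild byte-identically", {
  fx <- tiny_build()
  ids <- sort(fx$vocab$concepts$concept_id)
  expect_equal(ids[1], 2128000000)
  expect_equal(ids, 2128000000 + seq_along(ids) - 1)

  d1 <- tempfile(); d2 <- tempfile()
  emit_vocabulary(fx$vocab, d1)
  emit_vocabulary(build_dicom_vocabulary(load_standard_bundle(fx$dir)), d2)
  for (f in c("CONCEPT.csv", "CONCEPT_RELATIONSHIP.csv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))))
  }

  custom_base <- builder_config(id_base = 2200000000)
  shifted <- build_dicom_vocabulary(load_standard_bundle(fx$dir), custom_base)
  expect_equal(min(shifted$concepts$concept_id), 2200000000)
  expect_error(builder_config(id_base = 100), "2000000000")
})

test_that("relationship construction follows constraints, twins and the resolver", {
  dict <- make_dict(c("00080060", "Modality", "CS"),
                    c("0040A001", "Coded Attribute", "CS"),
                    c("00180015", "Body Part Examined", "CS"))
  occ <- tibble::tibble(cid = 1, scheme = "DCM", code = c("A", "B", "C"),
                        meaning = paste("code", c("A", "B", "C")), is_dcm = TRUE)
  terms <- tibble::tibble(
    attribute_tag = c("00080060", "00080060", "00180015", "00180015"),
    value_string = c("A", "NEW", "BRAIN", "SKULL"),
    meaning = "", term_kind = "Defined", snomed_code = "")
  bundle <- structure(list(
    attributes = dict, occurrences = occ,
    bodypart_map = tibble::tibble(value_string = c("BRAIN", "SKULL"),
                                  snomed_code = c("12738006", "")),
    terms = terms,
    constraints = tibble::tibble(
      attribute_tag = c("0040A001", "00080060", "00180015"),
      constraint_kind = c("CID", "TermList", "TermList"),
      cid = c(1L, NA, NA)),
    log = NULL), class = "standard_bundle")
  resolver <- concept_resolver(tibble::tibble(scheme = "SCT", code = "12738006",
                                              concept_id = 4049999))
  vocab <- build_dicom_vocabulary(bundle, resolver = resolver)
  rel <- vocab$relationships

  # CID constraint: one row per member
  expect_equal(sum(rel$source == "cid"), 3)
  # term rows: all four terms, with the duplicate "A" mapped to its DCM twin
  expect_equal(sum(rel$source == "term"), 4)
  a_concept <- vocab$concepts$concept_id[vocab$concepts$concept_code == "DCM:A"]
  modality_id <- vocab$concepts$concept_id[vocab$concepts$concept_code == "00080060"]
  expect_true(any(rel$concept_id_1 == modality_id & rel$concept_id_2 == a_concept))
  # resolver: BRAIN resolves, SKULL (no SNOMED code) is skipped softly
  expect_equal(sum(rel$relationship_id == "Maps to"), 1)
  expect_equal(rel$concept_id_2[rel$relationship_id == "Maps to"], 4049999)
  expect_true(any(vocab$log$event == "maps_to_skipped"))
  # endpoints all resolve
  known <- c(vocab$concepts$concept_id, resolver$table$concept_id)
  expect_true(all(rel$concept_id_1 %in% known))
  expect_true(all(rel$concept_id_2 %in% known))

  # id collisions with resolver-supplied ids are fatal
  clash <- concept_resolver(tibble::tibble(scheme = "SCT", code = "12738006",
                                           concept_id = 2128000001))
  expect_error(build_dicom_vocabulary(bundle, resolver = clash), "collides")
})

test_that("summary identities hold and agree with a recount of emitted files", {
  fx <- table2_build()
  s <- fx$vocab$summary
  expect_equal(s$n_total_values,
               s$n_cid_values + s$n_bodypart_values + s$n_modality_terms +
                 s$n_patientposition_terms + s$n_compression_terms + s$n_other_terms)
  expect_equal(s$n_total_relationships, s$n_maps_to_value + s$n_maps_to)
  expect_equal(s$n_total_concepts,
               s$n_attributes + s$n_total_values + s$n_total_relationships)

  emitted <- read_vocabulary(fx$vocab_dir)
  expect_equal(nrow(emitted$concepts), s$n_attributes + s$n_total_values)
  expect_equal(nrow(emitted$relationships), s$n_total_relationships)
  expect_equal(sum(emitted$concepts$concept_class_id == "Attribute"), s$n_attributes)
  expect_equal(sum(emitted$concepts$concept_class_id == "Value"), s$n_total_values)

  empty <- summarize_vocabulary(
    fx$vocab$concepts[0, ], fx$vocab$relationships[0, ])
  expect_true(all(unlist(empty) == 0))

  g <- glance(fx$vocab)
  expect_equal(g$n_total_concepts, s$n_total_concepts)
  td <- tidy(fx$vocab)
  expect_equal(sum(td$n), s$n_total_concepts)
})

test_that("emitted vocabulary tables round-trip", {
  fx <- tiny_build()
  out <- tempfile()
  emit_vocabulary(fx$vocab, out)
  again <- read_vocabulary(out)
  expect_equal(again$concepts$concept_id, fx$vocab$concepts$concept_id)
  expect_equal(again$concepts$concept_code, fx$vocab$concepts$concept_code)
  expect_equal(nrow(again$relationships), nrow(fx$vocab$relationships))
})
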