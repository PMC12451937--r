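test_that("indexing finds one record per series with a deterministic representative", {
  fx <- mr_dataset()
  idx <- fx$harvest$series
  expect_equal(nrow(idx), 6)  # 3 patients x 2 series
  expect_setequal(idx$series_uid, fx$manifest$series_uid)
  expect_equal(idx$n_instances, rep(5L, 6))
  expect_false(anyDuplicated(idx$series_uid) > 0)
  # lowest Instance Number wins: fixture instances are numbered from 1
  expect_match(idx$representative_file, "IM0001", fixed = TRUE)
  # re-indexing is deterministic
  again <- index_dicom_dataset(fx$dir)
  expect_equal(again, idx, ignore_attr = TRUE)
})

test_that("the representative is the lowest instance number, path as tie-break", {
  dir <- tempfile(); dir.create(dir)
  uid <- "1.2.826.0.1.3680043.9999.42.1"
  mk <- function(name, inst) {
    df <- tibble::tibble(
      tag = c("00100020", "0020000D", "0020000E", "00080018", "00200013",
              "00080060"),
      vr = c("LO", "UI", "UI", "UI", "IS", "CS"),
      value = list("SYN-0001", paste0(uid, ".s"), uid,
                   paste0(uid, ".", inst), as.character(inst), "MR"))
    write_dicom(df, file.path(dir, name))
  }
  mk("a_second.dcm", 2)
  mk("z_first.dcm", 1)
  idx <- index_dicom_dataset(dir)
  expect_equal(nrow(idx), 1)
  expect_match(idx$representative_file, "z_first")

  # tie on instance number: lexicographically first path
  mk("a_tie.dcm", 1)
  idx2 <- index_dicom_dataset(dir)
  expect_match(idx2$representative_file, "a_tie")

  # files without a series UID are skipped, not fatal
  write_dicom(tibble::tibble(tag = "00080060", vr = "CS", value = list("MR")),
              file.path(dir, "no_series.dcm"))
  idx3 <- index_dicom_dataset(dir)
  expect_equal(nrow(idx3), 1)
  expect_true(any(grepl("no_series", attr(idx3, "skipped"))))

  expect_error(index_dicom_dataset(file.path(dir, "missing")),
               class = "dicomop_io_error")
  empty_dir <- tempfile(); dir.create(empty_dir)
  expect_warning(empty <- index_dicom_dataset(empty_dir), "no DICOM")
  expect_equal(nrow(empty), 0)
})

test_that("harvest excludes private tags and sequences and expands multi-values", {
  path <- write_test_dicom(
    list("00080060", "CS", "MR"),
    list("00080008", "CS", c("ORIGINAL", "PRIMARY", "M")),
    list("00090010", "LO", "PRIVATE PAYLOAD"),
    list("00091001", "DS", "42"),
    list("00081140", "SQ", list(tibble::tibble(tag = "00081155", vr = "UI",
                                               value = list("1.2.3")))),
    list("00180080", "DS", "2300")
  )
  elements <- harvest_header(path)
  expect_false(any(c("00090010", "00091001") %in% elements$tag))
  expect_false("00081140" %in% elements$tag)
  it <- elements[elements$tag == "00080008", ]
  expect_equal(it$value, c("ORIGINAL", "PRIMARY", "M"))
  expect_equal(it$value_index, 0:2)
  # keyword resolution through a dictionary
  dict_path <- tempfile(fileext = ".csv")
  writeLines(c("tag,name,keyword,vr,vm,retired",
               "00080060,Modality,Modality,CS,1,FALSE"), dict_path)
  with_kw <- harvest_header(path, load_attribute_dictionary(dict_path))
  expect_equal(with_kw$keyword[with_kw$tag == "00080060"], "Modality")
})

test_that("the filter keeps exactly the VR whitelist plus the Manufacturer exception", {
  vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS", "LO",
           "LT", "PN", "SH", "SL", "SS", "ST", "SV", "TM", "UC", "UI", "UL",
           "UR", "US", "UT", "UV")
  elements <- tibble::tibble(
    tag = sprintf("0010%04X", seq_along(vrs)),
    keyword = NA_character_, vr = vrs, value = "X", value_index = 0L)
  manufacturer <- tibble::tibble(tag = "00080070", keyword = NA_character_,
                                 vr = "LO", value = "ACME", value_index = 0L)
  empties <- tibble::tibble(tag = c("00181030", "00180015"),
                            keyword = NA_character_, vr = c("DS", "CS"),
                            value = c("", "   "), value_index = 0L)
  input <- rbind(elements, manufacturer, empties)

  kept <- filter_elements(input)
  expect_setequal(kept$vr[kept$tag != "00080070"],
                  intersect(vrs, dicom_vr_whitelist()))
  expect_true("00080070" %in% kept$tag)      # Manufacturer survives despite LO
  expect_false(any(kept$value %in% c("", "   ")))  # empty values dropped first
  drops <- attr(kept, "dropped")
  expect_equal(unname(drops["empty_value"]), 2)

  # pure predicate: subset, order-preserving, idempotent
  set.seed(5)
  for (i in 1:10) {
    shuffled <- input[sample.int(nrow(input)), ]
    k <- filter_elements(shuffled)
    expect_true(all(paste(k$tag, k$vr) %in% paste(shuffled$tag, shuffled$vr)))
    expect_equal(match(paste(k$tag, k$vr), paste(shuffled$tag, shuffled$vr)),
                 sort(match(paste(k$tag, k$vr), paste(shuffled$tag, shuffled$vr))))
    expect_equal(filter_elements(k), k, ignore_attr = TRUE)
  }
})

test_that("harvest keeps exactly the manifest's expected element counts", {
  fx <- mr_dataset()
  per_series <- table(fx$harvest$elements$series_uid)
  expect_equal(unname(per_series[fx$manifest$series_uid]),
               fx$manifest$n_kept_expected, ignore_attr = TRUE)
  expect_equal(nrow(fx$harvest$elements), sum(fx$manifest$n_kept_expected))
  # no kept element is private, empty, or outside the whitelist + exception
  el <- fx$harvest$elements
  expect_false(any(strtoi(substr(el$tag, 1, 4), 16L) %% 2 == 1))
  expect_false(any(!nzchar(trimws(el$value))))
  expect_true(all(el$vr %in% dicom_vr_whitelist() | el$tag == "00080070"))
})
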