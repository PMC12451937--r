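# Indexing a DICOM file tree, harvesting one header per series, and the
# value-representation filter.

#' Index a DICOM file tree into series records
#'
#' Walks `root` recursively, reads every file's header, and returns one
#' record per distinct Series Instance UID. The representative instance of a
#' series is the file with the lowest Instance Number, ties broken by
#' lexicographic file path; files that are not readable DICOM or lack a
#' series UID are skipped and counted in the `skipped` attribute.
#'
#' @param root Directory containing DICOM Part-10 files (any layout).
#' @return Tibble with one row per series: `patient_id`, `study_uid`,
#'   `series_uid`, `series_date`, `modality`, `body_part`,
#'   `representative_file`, `n_instances`.
#' @export
index_dicom_dataset <- function(root) {
  if (!dir.exists(root)) {
    abort(sprintf("unreadable DICOM root: %s", root), class = "dicomop_io_error")
  }
  files <- sort(list.files(root, recursive = TRUE, full.names = TRUE))
  rows <- list()
  skipped <- character()
  for (f in files) {
    hdr <- tryCatch(read_dicom(f), error = function(e) NULL)
    if (is.null(hdr)) { skipped <- c(skipped, f); next }
    get1 <- function(tag) {
      v <- hdr$value[hdr$tag == tag]
      if (length(v) == 0 || is.na(v[1])) NA_character_ else v[1]
    }
    series_uid <- get1(TAG_SERIES_UID)
    if (is.na(series_uid) || !nzchar(dicom_trim(series_uid))) {
      skipped <- c(skipped, f)
      next
    }
    inst <- suppressWarnings(as.integer(get1(TAG_INSTANCE_NUMBER)))
    rows[[length(rows) + 1]] <- tibble(
      file = f,
      patient_id = get1(TAG_PATIENT_ID),
      study_uid = get1(TAG_STUDY_UID),
      series_uid = series_uid,
      series_date = get1(TAG_SERIES_DATE),
      modality = get1(TAG_MODALITY),
      body_part = get1(TAG_BODY_PART),
      instance_number = ifelse(is.na(inst), .Machine$integer.max, inst)
    )
  }
  if (length(rows) == 0) {
    warn(sprintf("no DICOM series found under %s", root))
    out <- tibble(patient_id = character(), study_uid = character(),
                  series_uid = character(), series_date = character(),
                  modality = character(), body_part = character(),
                  representative_file = character(), n_instances = integer())
    attr(out, "skipped") <- skipped
    return(out)
  }
  idx <- bind_rows(rows) |>
    arrange(.data$series_uid, .data$instance_number, .data$file) |>
    group_by(.data$series_uid) |>
    summarise(patient_id = first(.data$patient_id),
              study_uid = first(.data$study_uid),
              series_date = first(.data$series_date),
              modality = first(.data$modality),
              body_part = first(.data$body_part),
              representative_file = first(.data$file),
              n_instances = n(), .groups = "drop") |>
    select("patient_id", "study_uid", "series_uid", "series_date", "modality",
           "body_part", "representative_file", "n_instances")
  attr(idx, "skipped") <- skipped
  idx
}

#' Harvest top-level header elements from one DICOM file
#'
#' Extracts the top-level data elements of a Part-10 file as key-value rows:
#' sequence contents are not descended, pixel and other bulk data are
#' excluded, and private tags (odd group numbers) are never emitted.
#' Multi-valued attributes expand to one row per value with a 0-based
#' `value_index`.
#'
#' @param file Path to a DICOM Part-10 file.
#' @param dictionary Optional attribute dictionary (from
#'   [load_attribute_dictionary()]) used to fill the `keyword` column.
#' @return Tibble with columns `tag`, `keyword`, `vr`, `value`,
#'   `value_index`.
#' @export
harvest_header <- function(file, dictionary = NULL) {
  hdr <- read_dicom(file)
  hdr <- filter(hdr,
                !is_private_tag(.data$tag),
                .data$vr != "SQ",
                !.data$vr %in% c("OB", "OW", "OD", "OF", "OL", "OV", "UN"),
                .data$tag != TAG_PIXEL_DATA,
                !is.na(.data$value))
  if (nrow(hdr) == 0) {
    return(tibble(tag = character(), keyword = character(), vr = character(),
                  value = character(), value_index = integer()))
  }
  expanded <- hdr |>
    mutate(value = strsplit(.data$value, "\\", fixed = TRUE)) |>
    mutate(value = lapply(.data$value, function(v) if (length(v) == 0) "" else v)) |>
    tidyr::unnest_longer("value", indices_to = "value_index") |>
    mutate(value_index = .data$value_index - 1L)
  keyword <- rep(NA_character_, nrow(expanded))
  if (!is.null(dictionary)) {
    keyword <- dictionary$keyword[match(expanded$tag, dictionary$tag)]
  }
  tibble(tag = expanded$tag, keyword = keyword, vr = expanded$vr,
         value = expanded$value, value_index = as.integer(expanded$value_index))
}

#' Filter harvested metadata elements by value representation
#'
#' The pure keep/drop predicate applied to harvested elements before loading:
#' elements whose trimmed value is empty are dropped first; an element is
#' then kept iff its VR is in [dicom_vr_whitelist()] (numeric, coded, date
#' and time representations) or it is the Manufacturer attribute
#' `(0008,0070)` -- the single free-text exception, needed for cohort
#' definitions. The filter preserves order and is idempotent; counts of
#' drops by reason are attached as the `dropped` attribute.
#'
#' @param elements Tibble from [harvest_header()] (columns `tag`, `vr`,
#'   `value` required).
#' @return The kept subset, same columns and order.
#' @export
filter_elements <- function(elements) {
  empty <- is_empty_value(elements$value)
  after_empty <- elements[!empty, , drop = FALSE]
  keep <- after_empty$vr %in% VR_WHITELIST | after_empty$tag == TAG_MANUFACTURER
  out <- after_empty[keep, , drop = FALSE]
  attr(out, "dropped") <- c(empty_value = sum(empty), vr_excluded = sum(!keep))
  out
}

#' Harvest and filter a whole DICOM dataset
#'
#' Pipeline convenience: [index_dicom_dataset()], then [harvest_header()] on
#' each series' representative instance, then [filter_elements()]. Returns
#' the long per-element table the CDM loader consumes.
#'
#' @param root DICOM directory.
#' @param dictionary Optional attribute dictionary for keywords.
#' @return List with `series` (the index) and `elements` (tibble
#'   `patient_id`, `study_uid`, `series_uid`, `tag`, `keyword`, `vr`,
#'   `value`, `value_index`); drop counts summed over series in the
#'   `dropped` attribute of `elements`.
#' @export
harvest_dataset <- function(root, dictionary = NULL) {
  series <- index_dicom_dataset(root)
  dropped <- c(empty_value = 0L, vr_excluded = 0L)
  harvested <- vector("list", nrow(series))
  for (i in seq_len(nrow(series))) {
    kept <- filter_elements(harvest_header(series$representative_file[i], dictionary))
    dropped <- dropped + attr(kept, "dropped")
    if (nrow(kept) > 0) {
      harvested[[i]] <- mutate(kept,
                               patient_id = series$patient_id[i],
                               study_uid = series$study_uid[i],
                               series_uid = series$series_uid[i])
    }
  }
  elements <- bind_rows(harvested)
  if (nrow(elements) == 0) {
    elements <- tibble(patient_id = character(), study_uid = character(),
                       series_uid = character(), tag = character(),
                       keyword = character(), vr = character(),
                       value = character(), value_index = integer())
  } else {
    elements <- select(elements, "patient_id", "study_uid", "series_uid",
                       "tag", "keyword", "vr", "value", "value_index")
  }
  attr(elements, "dropped") <- dropped
  list(series = series, elements = elements)
}
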