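# Transforming filtered series metadata into OMOP medical-imaging extension
# rows: Procedure_occurrence (study), Image_occurrence (series),
# Image_feature + Measurement (element), using the built vocabulary.

#' Build a lookup index over an emitted vocabulary
#'
#' Indexes a `CONCEPT.csv` / `CONCEPT_RELATIONSHIP.csv` pair (or an in-memory
#' `dicom_vocabulary`) for fast attribute and value lookups. Attribute
#' concepts are keyed by tag; value lookups follow the `"Maps to value"`
#' relationships from the attribute concept and match on the code part of
#' the target's `concept_code` (`scheme:code` or `tag:value`).
#'
#' @param vocab A directory path (read via [read_vocabulary()]), a
#'   `dicom_vocabulary`, or a list with `concepts`/`relationships`.
#' @return A `vocab_index`.
#' @export
vocab_index <- function(vocab) {
  if (is.character(vocab)) vocab <- read_vocabulary(vocab)
  concepts <- as_tibble(vocab$concepts)
  relationships <- as_tibble(vocab$relationships)
  attrs <- filter(concepts, .data$concept_class_id == "Attribute")
  values <- filter(concepts, .data$concept_class_id == "Value") |>
    mutate(code_part = sub("^[^:]*:", "", .data$concept_code))
  mtv <- filter(relationships, .data$relationship_id == "Maps to value") |>
    left_join(select(values, "concept_id", "code_part"),
              by = c(concept_id_2 = "concept_id")) |>
    filter(!is.na(.data$code_part))
  structure(list(
    attr_by_tag = setNames(attrs$concept_id, attrs$concept_code),
    value_key = paste(mtv$concept_id_1, mtv$code_part, sep = "\r"),
    value_id = mtv$concept_id_2
  ), class = "vocab_index")
}

#' Resolve a DICOM attribute or (attribute, value) pair to a concept id
#'
#' An attribute query returns the Attribute concept for that tag; a
#' `(tag, value)` query returns the Value concept reachable from that
#' attribute through a `"Maps to value"` relationship. Misses return 0 (a
#' soft failure, so real-world nonconformant values never abort a load).
#'
#' @param index A [vocab_index()].
#' @param tag 8-hex attribute tag (vectorized).
#' @param value Optional code-string value (vectorized, recycled with `tag`).
#' @return Numeric concept id(s); 0 for misses.
#' @export
#' @examples
#' dir <- tempfile(); make_standard_fixture(standard_fixture_profile("tiny"), dir)
#' v <- build_dicom_vocabulary(load_standard_bundle(dir))
#' idx <- vocab_index(v)
#' resolve_concept(idx, "00080060")          # Modality attribute concept
#' resolve_concept(idx, "00080060", "NOPE")  # 0
resolve_concept <- function(index, tag, value = NULL) {
  tag <- canonical_tag(tag)
  attr_id <- unname(index$attr_by_tag[tag])
  if (is.null(value)) {
    out <- attr_id
  } else {
    key <- paste(attr_id, value, sep = "\r")
    out <- index$value_id[match(key, index$value_key)]
    out[is.na(attr_id)] <- NA_real_
  }
  out[is.na(out)] <- 0
  as.numeric(out)
}

da_to_iso <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{8}$", dicom_trim(x))
  out <- rep(NA_character_, length(x))
  v <- dicom_trim(x[ok])
  out[ok] <- paste(substr(v, 1, 4), substr(v, 5, 6), substr(v, 7, 8), sep = "-")
  out
}

#' Build the four OMOP row sets from harvested metadata
#'
#' Study-level rows go to Procedure_occurrence, series-level rows to
#' Image_occurrence (modality and anatomic-site concepts resolved, 0 when
#' absent), and every kept metadata element becomes one Image_feature +
#' Measurement pair. `value_as_number` is set only for numeric VRs whose
#' text parses; a `CS` value with a mapped value concept sets
#' `value_as_concept_id` instead (never both). Date/time VRs (`DA`, `DT`,
#' `TM`) stay in `value_source_value` only. The measurement date is the
#' series date, following the extension's convention of dating series-level
#' events by Series Date.
#'
#' @param series Series index from [index_dicom_dataset()] /
#'   [harvest_dataset()].
#' @param elements Kept elements from [harvest_dataset()].
#' @param vocab A [vocab_index()] (or anything `vocab_index()` accepts).
#' @param person_map Tibble mapping `patient_id` to `person_id`.
#' @param procedure_concept_id Concept id stamped on imaging procedures.
#' @param on_missing_person `"skip"` (drop that patient's rows, with a log
#'   note) or `"fail"`.
#' @return A `cdm_rows` list of tibbles: `procedure_occurrence`,
#'   `image_occurrence`, `image_feature`, `measurement`; skipped patients in
#'   the `log` attribute.
#' @export
build_cdm_rows <- function(series, elements, vocab, person_map,
                           procedure_concept_id = 4180938,
                           on_missing_person = c("skip", "fail")) {
  on_missing_person <- match.arg(on_missing_person)
  if (!inherits(vocab, "vocab_index")) vocab <- vocab_index(vocab)
  stopifnot(all(c("patient_id", "person_id") %in% names(person_map)))
  log <- empty_log()

  series <- mutate(series,
                   person_id = person_map$person_id[
                     match(.data$patient_id, person_map$patient_id)])
  unmapped <- filter(series, is.na(.data$person_id))
  if (nrow(unmapped) > 0) {
    if (on_missing_person == "fail") {
      abort(sprintf("no person mapping for patient %s", unmapped$patient_id[1]),
            class = "dicomop_person_error")
    }
    log <- log_note(log, "patients_skipped", "series with no person mapping",
                    nrow(unmapped))
    series <- filter(series, !is.na(.data$person_id))
  }

  procedure_occurrence <- series |>
    distinct(.data$study_uid, .keep_all = TRUE) |>
    arrange(.data$study_uid) |>
    mutate(procedure_occurrence_id = row_number(),
           procedure_concept_id = procedure_concept_id,
           procedure_date = da_to_iso(.data$series_date),
           procedure_source_value = .data$study_uid) |>
    select("procedure_occurrence_id", "person_id", "procedure_concept_id",
           "procedure_date", "procedure_source_value")

  image_occurrence <- series |>
    arrange(.data$series_uid) |>
    mutate(image_occurrence_id = row_number(),
           procedure_occurrence_id = procedure_occurrence$procedure_occurrence_id[
             match(.data$study_uid, procedure_occurrence$procedure_source_value)],
           image_occurrence_date = da_to_iso(.data$series_date),
           modality_concept_id = resolve_concept(vocab, TAG_MODALITY, .data$modality),
           anatomic_site_concept_id = resolve_concept(vocab, TAG_BODY_PART,
                                                      .data$body_part)) |>
    select("image_occurrence_id", "person_id", "procedure_occurrence_id",
           "image_occurrence_date",
           image_study_uid = "study_uid", image_series_uid = "series_uid",
           "modality_concept_id", "anatomic_site_concept_id",
           modality_source_value = "modality",
           anatomic_site_source_value = "body_part")

  kept <- semi_join(elements, series, by = "series_uid")
  if (nrow(kept) > 0) {
    kept <- kept |>
      left_join(select(image_occurrence, "image_occurrence_id",
                       "anatomic_site_concept_id", "person_id",
                       "image_occurrence_date",
                       series_uid = "image_series_uid"),
                by = "series_uid") |>
      mutate(measurement_id = row_number(),
             image_feature_id = row_number(),
             measurement_concept_id = resolve_concept(vocab, .data$tag),
             numeric_ok = .data$vr %in% NUMERIC_VRS,
             value_as_number = ifelse(.data$numeric_ok,
                                      suppressWarnings(as.numeric(.data$value)),
                                      NA_real_),
             mapped = resolve_concept(vocab, .data$tag, .data$value),
             value_as_concept_id = ifelse(!is.na(.data$value_as_number), NA_real_,
                                          ifelse(.data$mapped > 0, .data$mapped,
                                                 NA_real_)))
    measurement <- select(kept, "measurement_id", "person_id",
                          "measurement_concept_id",
                          measurement_date = "image_occurrence_date",
                          "value_as_number", "value_as_concept_id",
                          value_source_value = "value",
                          measurement_source_value = "tag")
    image_feature <- select(kept, "image_feature_id", "image_occurrence_id",
                            image_feature_concept_id = "measurement_concept_id",
                            "anatomic_site_concept_id", "measurement_id")
  } else {
    measurement <- tibble(measurement_id = integer(), person_id = numeric(),
                          measurement_concept_id = numeric(),
                          measurement_date = character(),
                          value_as_number = numeric(),
                          value_as_concept_id = numeric(),
                          value_source_value = character(),
                          measurement_source_value = character())
    image_feature <- tibble(image_feature_id = integer(),
                            image_occurrence_id = integer(),
                            image_feature_concept_id = numeric(),
                            anatomic_site_concept_id = numeric(),
                            measurement_id = integer())
  }

  rows <- structure(list(procedure_occurrence = procedure_occurrence,
                         image_occurrence = image_occurrence,
                         image_feature = image_feature,
                         measurement = measurement),
                    class = "cdm_rows")
  attr(rows, "log") <- log
  rows
}

CDM_FILES <- c(procedure_occurrence = "PROCEDURE_OCCURRENCE.csv",
               image_occurrence = "IMAGE_OCCURRENCE.csv",
               image_feature = "IMAGE_FEATURE.csv",
               measurement = "MEASUREMENT.csv")

#' Emit CDM row sets as CSV files
#'
#' Writes `PROCEDURE_OCCURRENCE.csv`, `IMAGE_OCCURRENCE.csv`,
#' `IMAGE_FEATURE.csv` and `MEASUREMENT.csv` to a directory.
#'
#' @param rows A `cdm_rows` list from [build_cdm_rows()].
#' @param out_dir Output directory (created if needed).
#' @return Named integer vector of row counts, invisibly.
#' @export
emit_cdm <- function(rows, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- integer(0)
  for (nm in names(CDM_FILES)) {
    readr::write_csv(rows[[nm]], file.path(out_dir, CDM_FILES[[nm]]),
                     progress = FALSE, na = "")
    counts[nm] <- nrow(rows[[nm]])
  }
  invisible(counts)
}

#' Read emitted CDM tables
#'
#' @param dir Directory written by [emit_cdm()].
#' @return A `cdm_rows` list of tibbles.
#' @export
read_cdm <- function(dir) {
  out <- lapply(names(CDM_FILES), function(nm) {
    readr::read_csv(file.path(dir, CDM_FILES[[nm]]), col_types = readr::cols(),
                    na = "", progress = FALSE)
  })
  structure(setNames(out, names(CDM_FILES)), class = "cdm_rows")
}

#' Load CDM row sets into a file-backed SQLite store
#'
#' Populates (overwriting) the four extension tables in an SQLite database so
#' cohort definitions can be evaluated in SQL as well as in memory.
#'
#' @param rows A `cdm_rows` list (or a directory readable by [read_cdm()]).
#' @param db_path Path to the SQLite file (created if needed).
#' @return `db_path`, invisibly.
#' @export
load_cdm_sqlite <- function(rows, db_path) {
  if (is.character(rows)) rows <- read_cdm(rows)
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  for (nm in names(CDM_FILES)) {
    DBI::dbWriteTable(con, nm, as.data.frame(rows[[nm]]), overwrite = TRUE)
  }
  invisible(db_path)
}

#' Check link integrity of CDM row sets
#'
#' Full-scan referential checks: every image_feature must reference an
#' existing image_occurrence and measurement, every image_occurrence an
#' existing procedure_occurrence, and the element-conservation chain
#' `|image_feature| == |measurement|` must hold.
#'
#' @param rows A `cdm_rows` list.
#' @return Tibble of violations (zero rows when clean).
#' @export
validate_cdm <- function(rows) {
  bad <- list()
  chk <- function(name, cond) {
    if (!cond) bad[[length(bad) + 1]] <<- tibble(check = name)
  }
  chk("feature_count_equals_measurement_count",
      nrow(rows$image_feature) == nrow(rows$measurement))
  chk("feature_links_occurrence",
      all(rows$image_feature$image_occurrence_id %in%
            rows$image_occurrence$image_occurrence_id))
  chk("feature_links_measurement",
      all(rows$image_feature$measurement_id %in% rows$measurement$measurement_id))
  chk("occurrence_links_procedure",
      all(rows$image_occurrence$procedure_occurrence_id %in%
            rows$procedure_occurrence$procedure_occurrence_id))
  chk("series_unique", !anyDuplicated(rows$image_occurrence$image_series_uid))
  chk("study_unique", !anyDuplicated(rows$procedure_occurrence$procedure_source_value))
  if (length(bad) == 0) tibble(check = character()) else bind_rows(bad)
}
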