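# Imaging-phenotype cohort definitions: attribute criteria evaluated with
# series-scoped conjunction semantics, in memory or against the SQLite store.

#' Define a single cohort criterion
#'
#' A criterion constrains one DICOM attribute within a series: `present`
#' (any kept element for that attribute), `eq` (code-string equality on the
#' raw value), or `in_range` (inclusive bounds on `value_as_number`).
#' Attributes are named by 8-hex tag or by attribute concept id. Criteria on
#' date/time attributes (`DA`/`DT`/`TM`) are not supported: those values are
#' never numerically encoded.
#'
#' @param attribute Tag string (e.g. `"00180080"`) or numeric concept id.
#' @param op One of `"present"`, `"eq"`, `"in_range"`.
#' @param value Code string, required for `op = "eq"`.
#' @param low,high Inclusive numeric bounds, required for `op = "in_range"`.
#' @return A `cohort_criterion`.
#' @export
#' @examples
#' cohort_criterion("00180080", "in_range", low = 2100, high = 2500)
cohort_criterion <- function(attribute, op = c("present", "eq", "in_range"),
                             value = NULL, low = NULL, high = NULL) {
  op <- match.arg(op)
  if (is.character(attribute)) {
    attribute <- canonical_tag(attribute)
    if (!is_valid_tag(attribute)) abort(sprintf("malformed attribute tag %s", attribute))
  }
  if (op == "eq" && (is.null(value) || !nzchar(value))) {
    abort("op = 'eq' requires a value")
  }
  if (op == "in_range") {
    if (is.null(low) || is.null(high)) abort("op = 'in_range' requires low and high")
    if (low > high) abort("in_range requires low <= high")
  }
  structure(list(attribute = attribute, op = op, value = value,
                 low = low, high = high),
            class = "cohort_criterion")
}

#' Define an imaging cohort
#'
#' A conjunction of [cohort_criterion()]s plus an optional modality code; a
#' series matches iff every criterion holds within that same series
#' (criteria are series-scoped, never satisfied across different series of
#' one person), and a person matches iff at least one of their series
#' matches.
#'
#' @param ... `cohort_criterion` objects (or one list of them).
#' @param modality Optional modality code string (e.g. `"MR"`) matched
#'   against the series' modality source value.
#' @return A `cohort_definition`.
#' @export
cohort_definition <- function(..., modality = NULL) {
  criteria <- list(...)
  if (length(criteria) == 1 && is.list(criteria[[1]]) &&
      !inherits(criteria[[1]], "cohort_criterion")) {
    criteria <- criteria[[1]]
  }
  if (length(criteria) == 0 && is.null(modality)) {
    abort("a cohort definition needs at least one criterion or a modality")
  }
  ok <- vapply(criteria, inherits, TRUE, what = "cohort_criterion")
  if (!all(ok)) abort("criteria must be cohort_criterion objects")
  structure(list(criteria = criteria, modality = modality),
            class = "cohort_definition")
}

#' Read a cohort definition from a YAML config file
#'
#' Config layout:
#' ```yaml
#' modality: MR
#' criteria:
#'   - {attribute: "00180082", op: present}
#'   - {attribute: "00180080", op: in_range, low: 2100, high: 2500}
#'   - {attribute: "00180081", op: in_range, low: 2, high: 4}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `cohort_definition`.
#' @export
read_cohort_definition <- function(path) {
  cfg <- yaml::read_yaml(path)
  criteria <- lapply(cfg$criteria, function(cr) {
    cohort_criterion(attribute = cr$attribute, op = cr$op,
                     value = cr$value, low = cr$low, high = cr$high)
  })
  cohort_definition(criteria, modality = cfg$modality)
}

#' Built-in T1-weighted volumetric MR template
#'
#' An MPRAGE-style definition: inversion time present, TR and TE within
#' MPRAGE-typical bounds. The default TR/TE/TI ranges (TR 2100-2500 ms,
#' TE 2-4 ms, TI 800-1100 ms) are the acquisition parameters of the
#' package's synthetic MPRAGE protocol -- configuration defaults to adjust
#' to the protocols of a real archive, not reference values.
#'
#' @param tr,te,ti Length-2 numeric ranges in milliseconds; `ti = NULL`
#'   keeps only the presence test on inversion time.
#' @return A `cohort_definition`.
#' @export
t1_volumetric_definition <- function(tr = c(2100, 2500), te = c(2, 4),
                                     ti = c(800, 1100)) {
  criteria <- list(
    cohort_criterion("00180082", "present"),
    cohort_criterion("00180080", "in_range", low = tr[1], high = tr[2]),
    cohort_criterion("00180081", "in_range", low = te[1], high = te[2])
  )
  if (!is.null(ti)) {
    criteria <- c(criteria,
                  list(cohort_criterion("00180082", "in_range",
                                        low = ti[1], high = ti[2])))
  }
  cohort_definition(criteria, modality = "MR")
}

criterion_attribute_key <- function(criterion) {
  if (is.character(criterion$attribute)) {
    list(col = "measurement_source_value", val = criterion$attribute)
  } else {
    list(col = "measurement_concept_id", val = as.numeric(criterion$attribute))
  }
}

#' Evaluate a cohort definition over loaded CDM tables
#'
#' Joins Measurement to Image_occurrence through Image_feature and computes,
#' per criterion, the set of matching series; the result is their
#' intersection (series-scoped conjunction), optionally restricted by
#' modality. Malformed attribute references are definition errors (caught
#' when the criterion is built); a well-formed attribute that no loaded
#' series carries simply yields an empty result.
#'
#' @param defn A `cohort_definition`.
#' @param cdm A `cdm_rows` list, a directory readable by [read_cdm()], or an
#'   SQLite file path created by [load_cdm_sqlite()] (evaluated in SQL).
#' @return A `cohort_result`: list with `person_ids`, `series_uids`, and
#'   `matches` (tibble `person_id`, `image_series_uid`).
#' @export
evaluate_cohort <- function(defn, cdm) {
  stopifnot(inherits(defn, "cohort_definition"))
  if (is.character(cdm) && length(cdm) == 1 && grepl("\\.(db|sqlite)$", cdm)) {
    return(evaluate_cohort_sql(defn, cdm))
  }
  if (is.character(cdm)) cdm <- read_cdm(cdm)

  io <- cdm$image_occurrence
  candidates <- io
  if (!is.null(defn$modality)) {
    candidates <- filter(candidates, .data$modality_source_value == defn$modality)
  }
  long <- cdm$measurement |>
    inner_join(select(cdm$image_feature, "measurement_id", "image_occurrence_id"),
               by = "measurement_id")
  for (criterion in defn$criteria) {
    key <- criterion_attribute_key(criterion)
    rows <- long[long[[key$col]] == key$val, , drop = FALSE]
    rows <- switch(criterion$op,
      present = rows,
      eq = filter(rows, .data$value_source_value == criterion$value),
      in_range = filter(rows, !is.na(.data$value_as_number),
                        .data$value_as_number >= criterion$low,
                        .data$value_as_number <= criterion$high)
    )
    candidates <- semi_join(candidates, rows, by = "image_occurrence_id")
  }
  matches <- candidates |>
    select("person_id", "image_series_uid") |>
    arrange(.data$person_id, .data$image_series_uid)
  structure(list(person_ids = sort(unique(matches$person_id)),
                 series_uids = sort(unique(matches$image_series_uid)),
                 matches = matches),
            class = "cohort_result")
}

sql_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

#' Render a cohort definition as SQL
#'
#' Builds a standalone `SELECT` reproducing [evaluate_cohort()] against the
#' SQLite store: one `EXISTS` subquery per criterion, all scoped to the same
#' `image_occurrence` row.
#'
#' @param defn A `cohort_definition`.
#' @return A single SQL string selecting `person_id, image_series_uid`.
#' @export
cohort_sql <- function(defn) {
  clauses <- character()
  if (!is.null(defn$modality)) {
    clauses <- c(clauses, sprintf("io.modality_source_value = %s",
                                  sql_quote(defn$modality)))
  }
  for (criterion in defn$criteria) {
    key <- criterion_attribute_key(criterion)
    keyval <- if (is.character(criterion$attribute)) sql_quote(key$val) else
      format(key$val, scientific = FALSE)
    test <- switch(criterion$op,
      present = "",
      eq = sprintf(" AND m.value_source_value = %s", sql_quote(criterion$value)),
      in_range = sprintf(" AND m.value_as_number BETWEEN %s AND %s",
                         format(criterion$low, scientific = FALSE),
                         format(criterion$high, scientific = FALSE))
    )
    clauses <- c(clauses, sprintf(paste0(
      "EXISTS (SELECT 1 FROM image_feature f ",
      "JOIN measurement m ON m.measurement_id = f.measurement_id ",
      "WHERE f.image_occurrence_id = io.image_occurrence_id ",
      "AND m.%s = %s%s)"), key$col, keyval, test))
  }
  where <- if (length(clauses) == 0) "" else
    paste0("\nWHERE ", paste(clauses, collapse = "\n  AND "))
  paste0("SELECT io.person_id, io.image_series_uid FROM image_occurrence io",
         where, "\nORDER BY io.person_id, io.image_series_uid")
}

evaluate_cohort_sql <- function(defn, db_path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  matches <- as_tibble(DBI::dbGetQuery(con, cohort_sql(defn)))
  structure(list(person_ids = sort(unique(matches$person_id)),
                 series_uids = sort(unique(matches$image_series_uid)),
                 matches = matches),
            class = "cohort_result")
}

#' Export a cohort result
#'
#' Writes the matching Series Instance UIDs (one per line), a person-id CSV
#' with per-person matched-series counts, and the SQL text reproducing the
#' evaluation when the definition is supplied.
#'
#' @param result A `cohort_result`.
#' @param out_dir Output directory.
#' @param defn Optional `cohort_definition`; when given, `cohort.sql` is
#'   written alongside.
#' @return Paths of the written files, invisibly.
#' @export
export_cohort_result <- function(result, out_dir, defn = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  uid_path <- file.path(out_dir, "series_uids.txt")
  writeLines(result$series_uids, uid_path)
  person_path <- file.path(out_dir, "persons.csv")
  persons <- result$matches |>
    count(.data$person_id, name = "n_matching_series") |>
    arrange(.data$person_id)
  readr::write_csv(persons, person_path, progress = FALSE)
  paths <- c(uid_path, person_path)
  if (!is.null(defn)) {
    sql_path <- file.path(out_dir, "cohort.sql")
    writeLines(cohort_sql(defn), sql_path)
    paths <- c(paths, sql_path)
  }
  invisible(paths)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d persons, %d series\n",
              length(x$person_ids), length(x$series_uids)))
  invisible(x)
}
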