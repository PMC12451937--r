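# Building the custom OMOP vocabulary: deduplication, concept-id assignment,
# "Maps to" / "Maps to value" relationships, summary and CSV emission.

OMOP_CUSTOM_ID_FLOOR <- 2000000000
DEFAULT_ID_BASE <- 2128000000

#' Configuration for the vocabulary build
#'
#' Custom concept identifiers are assigned consecutively from `id_base`,
#' which must sit in the reserved 2-billion range OMOP sets aside for
#' site-defined concepts; the default base is 2&nbsp;128&nbsp;000&nbsp;000.
#' All emitted concepts are non-standard (`standard_concept` empty).
#'
#' @param id_base First concept id to assign (integer-valued, >= 2e9).
#' @param vocabulary_id Label for the custom vocabulary.
#' @param domain_id OMOP domain assigned to every DICOM concept. A single
#'   configurable label is used because per-concept domains are not defined
#'   for DICOM content; `"Measurement"` fits the acquisition-parameter use.
#' @param valid_start_date,valid_end_date ISO dates stamped on every row.
#' @return A `builder_config` list.
#' @export
builder_config <- function(id_base = DEFAULT_ID_BASE,
                           vocabulary_id = "DICOM",
                           domain_id = "Measurement",
                           valid_start_date = "1970-01-01",
                           valid_end_date = "2099-12-31") {
  if (id_base < OMOP_CUSTOM_ID_FLOOR) {
    abort("id_base must be >= 2000000000 (the OMOP reserved custom range)")
  }
  structure(list(id_base = id_base, vocabulary_id = vocabulary_id,
                 domain_id = domain_id, valid_start_date = valid_start_date,
                 valid_end_date = valid_end_date),
            class = "builder_config")
}

#' External concept resolver for standard terminologies
#'
#' Maps `(coding_scheme, code)` pairs of standard terminologies (SNOMED,
#' LOINC) to pre-existing OMOP concept ids. Codes of those terminologies that
#' appear in DICOM context groups do not receive custom concepts; they are
#' reachable only through a resolver. Misses are soft: reported by the build
#' log, never fatal.
#'
#' @param table Tibble with columns `scheme`, `code`, `concept_id`.
#' @return A `concept_resolver`.
#' @seealso [resolver_from_bodypart_map()]
#' @export
concept_resolver <- function(table) {
  stopifnot(all(c("scheme", "code", "concept_id") %in% names(table)))
  table <- distinct(as_tibble(table), .data$scheme, .data$code, .keep_all = TRUE)
  structure(list(table = table), class = "concept_resolver")
}

resolver_lookup <- function(resolver, scheme, code) {
  if (is.null(resolver)) return(rep(NA_real_, length(code)))
  key <- paste(scheme, code, sep = "\r")
  idx <- match(key, paste(resolver$table$scheme, resolver$table$code, sep = "\r"))
  as.numeric(resolver$table$concept_id[idx])
}

#' Build a stub resolver from a body-part SNOMED cross-map
#'
#' Assigns deterministic synthetic standard-concept ids (from `base`,
#' ordered by code) to the distinct SNOMED codes of a body-part map. This
#' stands in for a real OMOP vocabulary download, which cannot be
#' redistributed; ids are synthetic and live far below the custom range.
#'
#' @param bodypart_map Tibble with columns `value_string`, `snomed_code`.
#' @param base First synthetic standard id.
#' @return A `concept_resolver` covering every non-empty SNOMED code.
#' @export
resolver_from_bodypart_map <- function(bodypart_map, base = 4000000) {
  codes <- sort(unique(bodypart_map$snomed_code[nzchar(dicom_trim(bodypart_map$snomed_code))]))
  concept_resolver(tibble(scheme = "SCT", code = codes,
                          concept_id = base + seq_along(codes) - 1))
}

#' Build Attribute concepts from a Part-6 dictionary
#'
#' One concept payload per dictionary entry with a non-empty attribute name;
#' nameless entries are excluded (and counted in the attached log). Ids are
#' not assigned here -- see [assign_concept_ids()].
#'
#' @param attributes Dictionary tibble from [load_attribute_dictionary()].
#' @param cfg A [builder_config()].
#' @return Tibble of concept payloads (`concept_name`, `concept_class_id`
#'   `"Attribute"`, `concept_code` = tag, source bookkeeping columns), with a
#'   `log` attribute.
#' @export
build_attribute_concepts <- function(attributes, cfg = builder_config()) {
  nameless <- !nzchar(dicom_trim(attributes$name))
  payload <- attributes |>
    filter(!nameless) |>
    mutate(concept_name = .data$name,
           concept_class_id = "Attribute",
           concept_code = .data$tag,
           source_kind = "attribute",
           attribute_tag = .data$tag,
           scheme = NA_character_,
           code = NA_character_) |>
    select("concept_name", "concept_class_id", "concept_code",
           "source_kind", "attribute_tag", "scheme", "code")
  log <- log_note(empty_log(), "attributes_excluded_nameless",
                  "dictionary entries without an attribute name", sum(nameless))
  attr(payload, "log") <- log
  payload
}

#' Deduplicate coded values across context groups and against Part-3 terms
#'
#' Two-stage deduplication mirroring the vocabulary construction:
#' \enumerate{
#' \item DCM-scheme member occurrences are collapsed by `(scheme, code)`,
#'   unioning the context groups each code belongs to. Non-DCM occurrences
#'   (SNOMED, LOINC) are set aside -- they receive no custom concepts.
#' \item Part-3 terms whose `value_string` exactly equals (case-sensitive) an
#'   existing DCM code value are flagged as duplicates and do not become
#'   concepts of their own; their attribute still maps to the existing DCM
#'   value concept when relationships are built. Surviving terms become
#'   `Value` concepts keyed `tag:value_string`.
#' }
#'
#' @param occurrences Member occurrences from [load_context_groups()].
#' @param terms Part-3 terms from [load_part3_terms()].
#' @return A list: `values` (tibble of distinct DCM codes with list-column
#'   `cids`), `terms` (input terms plus `duplicate_of_dcm` flag), `log`.
#' @export
dedup_coded_values <- function(occurrences, terms = NULL) {
  dcm <- filter(occurrences, .data$is_dcm)
  values <- dcm |>
    group_by(.data$scheme, .data$code) |>
    summarise(meaning = first(.data$meaning),
              cids = list(sort(unique(.data$cid))), .groups = "drop") |>
    arrange(.data$scheme, .data$code)
  n_repeated <- sum(vapply(values$cids, length, 1L) > 1)
  log <- empty_log()
  log <- log_note(log, "dcm_occurrences", "Part-16 DCM member occurrences", nrow(dcm))
  log <- log_note(log, "dcm_distinct", "distinct DCM codes after collapse", nrow(values))
  log <- log_note(log, "dcm_repeated", "codes present in more than one context group",
                  n_repeated)
  non_dcm <- sum(!occurrences$is_dcm)
  if (non_dcm > 0) {
    log <- log_note(log, "non_dcm_skipped",
                    "non-DCM members left to the external resolver", non_dcm)
  }
  if (is.null(terms)) {
    terms <- tibble(attribute_tag = character(), value_string = character(),
                    meaning = character(), term_kind = character(),
                    snomed_code = character())
  }
  terms <- mutate(terms, duplicate_of_dcm = .data$value_string %in% values$code)
  if (nrow(terms) > 0) {
    log <- log_note(log, "terms_duplicating_dcm",
                    "Part-3 terms matching an existing DCM code value",
                    sum(terms$duplicate_of_dcm))
  }
  list(values = values, terms = terms, log = log)
}

value_concept_payloads <- function(deduped) {
  dcm <- deduped$values |>
    mutate(concept_name = .data$meaning,
           concept_class_id = "Value",
           concept_code = paste0(.data$scheme, ":", .data$code),
           source_kind = "cid_value",
           attribute_tag = NA_character_) |>
    select("concept_name", "concept_class_id", "concept_code",
           "source_kind", "attribute_tag", "scheme", "code") |>
    arrange(.data$scheme, .data$code)
  term <- deduped$terms |>
    filter(!.data$duplicate_of_dcm) |>
    mutate(concept_name = dplyr::if_else(nzchar(dicom_trim(.data$meaning)),
                                         .data$meaning, .data$value_string),
           concept_class_id = "Value",
           concept_code = paste0(.data$attribute_tag, ":", .data$value_string),
           source_kind = "term_value",
           scheme = NA_character_,
           code = .data$value_string) |>
    select("concept_name", "concept_class_id", "concept_code",
           "source_kind", "attribute_tag", "scheme", "code") |>
    arrange(.data$attribute_tag, .data$code)
  bind_rows(dcm, term)
}

#' Assign consecutive custom concept ids
#'
#' Stamps ids `id_base, id_base + 1, ...` onto deterministically ordered
#' concept payloads, together with the OMOP vocabulary columns. Rerunning on
#' identical input reproduces identical ids; concept codes must be unique.
#'
#' @param payloads Ordered concept payloads (attributes sorted by tag, then
#'   DCM values by scheme/code, then term values by attribute/value -- the
#'   order produced by [build_dicom_vocabulary()]).
#' @param cfg A [builder_config()].
#' @param resolver Optional [concept_resolver()]; assigned ids colliding with
#'   resolver-supplied external ids are a fatal error.
#' @return Tibble of full concept rows (`concept_id` ... `invalid_reason`).
#' @export
assign_concept_ids <- function(payloads, cfg = builder_config(), resolver = NULL) {
  if (anyDuplicated(payloads$concept_code)) {
    dup <- payloads$concept_code[duplicated(payloads$concept_code)][1]
    abort(sprintf("duplicate concept_code %s", dQuote(dup)))
  }
  ids <- cfg$id_base + seq_len(nrow(payloads)) - 1
  if (!is.null(resolver) && any(ids %in% resolver$table$concept_id)) {
    abort("custom concept id collides with a resolver-supplied external id")
  }
  mutate(payloads,
         concept_id = ids,
         domain_id = cfg$domain_id,
         vocabulary_id = cfg$vocabulary_id,
         standard_concept = "",
         valid_start_date = cfg$valid_start_date,
         valid_end_date = cfg$valid_end_date,
         invalid_reason = "") |>
    select("concept_id", "concept_name", "domain_id", "vocabulary_id",
           "concept_class_id", "standard_concept", "concept_code",
           "valid_start_date", "valid_end_date", "invalid_reason",
           "source_kind", "attribute_tag", "scheme", "code")
}

#' Build "Maps to value" and "Maps to" relationships
#'
#' For every CID constraint, one `"Maps to value"` row per (attribute, DCM
#' member of that context group). For every TermList constraint, one row per
#' term of that attribute: surviving terms map to their own `Value` concept,
#' terms dropped as duplicates map to the DCM concept carrying the same code
#' value. For every body-part cross-map row whose value string has a `Value`
#' concept and whose SNOMED code resolves, one `"Maps to"` row from the DICOM
#' value concept to the resolved standard concept; unresolvable rows are
#' logged and skipped. Duplicate `(id1, id2, relationship)` rows collapse.
#'
#' @param bundle A `standard_bundle`.
#' @param concepts Concept table from [assign_concept_ids()].
#' @param deduped Output of [dedup_coded_values()].
#' @param resolver Optional [concept_resolver()] for SNOMED targets.
#' @param cfg A [builder_config()].
#' @return Tibble of relationship rows with a provenance column `source`
#'   (`"cid"`, `"term"`, `"bodypart"`) retained in memory and dropped on
#'   emission; `log` attribute records skips.
#' @export
build_relationships <- function(bundle, concepts, deduped,
                                resolver = NULL, cfg = builder_config()) {
  log <- empty_log()
  attr_ids <- setNames(concepts$concept_id[concepts$source_kind == "attribute"],
                       concepts$attribute_tag[concepts$source_kind == "attribute"])
  dcm_ids <- setNames(concepts$concept_id[concepts$source_kind == "cid_value"],
                      concepts$code[concepts$source_kind == "cid_value"])
  term_key <- paste(concepts$attribute_tag, concepts$code, sep = "\r")
  term_ids <- setNames(concepts$concept_id[concepts$source_kind == "term_value"],
                       term_key[concepts$source_kind == "term_value"])

  rel <- list()

  # CID constraints: attribute -> each DCM member of the context group.
  cid_constraints <- filter(bundle$constraints, .data$constraint_kind == "CID")
  if (nrow(cid_constraints) > 0) {
    members <- bundle$occurrences |>
      filter(.data$is_dcm) |>
      distinct(.data$cid, .data$code)
    cid_rel <- inner_join(cid_constraints, members, by = "cid",
                          relationship = "many-to-many")
    id1 <- unname(attr_ids[cid_rel$attribute_tag])
    id2 <- unname(dcm_ids[cid_rel$code])
    if (anyNA(id1)) {
      abort(sprintf("CID constraint on %s references an attribute with no concept",
                    format_tag(cid_rel$attribute_tag[which(is.na(id1))[1]])),
            class = "dicomop_referential_error")
    }
    if (anyNA(id2)) {
      abort("CID member code has no DCM value concept",
            class = "dicomop_referential_error")
    }
    rel$cid <- tibble(concept_id_1 = id1, concept_id_2 = id2,
                      relationship_id = "Maps to value", source = "cid")
  }

  # TermList constraints: attribute -> term concept, or the DCM twin for
  # terms dropped as duplicates.
  tl_constraints <- filter(bundle$constraints, .data$constraint_kind == "TermList")
  if (nrow(tl_constraints) > 0) {
    tl <- inner_join(tl_constraints, deduped$terms, by = "attribute_tag",
                     relationship = "many-to-many")
    id1 <- unname(attr_ids[tl$attribute_tag])
    if (anyNA(id1)) {
      abort(sprintf("TermList constraint on %s references an attribute with no concept",
                    format_tag(tl$attribute_tag[which(is.na(id1))[1]])),
            class = "dicomop_referential_error")
    }
    id2 <- ifelse(tl$duplicate_of_dcm,
                  unname(dcm_ids[tl$value_string]),
                  unname(term_ids[paste(tl$attribute_tag, tl$value_string, sep = "\r")]))
    if (anyNA(id2)) {
      abort("Part-3 term has neither a term concept nor a DCM twin",
            class = "dicomop_referential_error")
    }
    rel$term <- tibble(concept_id_1 = id1, concept_id_2 = id2,
                       relationship_id = "Maps to value", source = "term")
  }

  # Body-part cross-map: DICOM value concept -> resolved SNOMED concept.
  bp <- filter(bundle$bodypart_map, nzchar(dicom_trim(.data$value_string)))
  if (nrow(bp) > 0) {
    src <- unname(term_ids[paste(TAG_BODY_PART, bp$value_string, sep = "\r")])
    # values without a term concept may still exist as DCM codes
    src <- ifelse(is.na(src), unname(dcm_ids[bp$value_string]), src)
    dst <- resolver_lookup(resolver, "SCT", bp$snomed_code)
    dst[!nzchar(dicom_trim(bp$snomed_code))] <- NA_real_
    usable <- !is.na(src) & !is.na(dst)
    if (any(!usable)) {
      log <- log_note(log, "maps_to_skipped",
                      "body-part rows without a value concept or resolvable SNOMED target",
                      sum(!usable))
    }
    if (any(usable)) {
      rel$bodypart <- tibble(concept_id_1 = src[usable], concept_id_2 = dst[usable],
                             relationship_id = "Maps to", source = "bodypart")
    }
  }

  out <- bind_rows(rel)
  if (nrow(out) == 0) {
    out <- tibble(concept_id_1 = numeric(), concept_id_2 = numeric(),
                  relationship_id = character(), source = character())
  }
  out <- distinct(out, .data$concept_id_1, .data$concept_id_2,
                  .data$relationship_id, .keep_all = TRUE)
  out <- mutate(out, valid_start_date = cfg$valid_start_date,
                valid_end_date = cfg$valid_end_date, invalid_reason = "") |>
    select("concept_id_1", "concept_id_2", "relationship_id",
           "valid_start_date", "valid_end_date", "invalid_reason", "source")
  attr(out, "log") <- log
  out
}

#' Summarize a vocabulary build
#'
#' Category counts in the layout of the build report: attribute concepts,
#' coded-value concepts by provenance (context groups, Body Part Examined,
#' Modality, Patient Position, Lossy Image Compression Method, any other
#' term-constrained attribute), relationship counts by type, and the grand
#' total, which -- following the reporting convention of the build -- counts
#' relationship rows toward the total vocabulary content. Internal sums are
#' asserted on every call.
#'
#' @param concepts Concept table from [assign_concept_ids()].
#' @param relationships Relationship table from [build_relationships()].
#' @return A `vocabulary_summary` (named list of non-negative integers).
#' @export
summarize_vocabulary <- function(concepts, relationships) {
  term_counts <- function(tag) {
    sum(concepts$source_kind == "term_value" & concepts$attribute_tag == tag)
  }
  n_attributes <- sum(concepts$source_kind == "attribute")
  n_cid_values <- sum(concepts$source_kind == "cid_value")
  n_bodypart <- term_counts(TAG_BODY_PART)
  n_modality <- term_counts(TAG_MODALITY)
  n_position <- term_counts(TAG_PATIENT_POSITION)
  n_compression <- term_counts(TAG_LOSSY_COMPRESSION_METHOD)
  n_other_terms <- sum(concepts$source_kind == "term_value") -
    n_bodypart - n_modality - n_position - n_compression
  n_maps_to_value <- sum(relationships$relationship_id == "Maps to value")
  n_maps_to <- sum(relationships$relationship_id == "Maps to")
  s <- list(
    n_attributes = n_attributes,
    n_cid_values = n_cid_values,
    n_bodypart_values = n_bodypart,
    n_modality_terms = n_modality,
    n_patientposition_terms = n_position,
    n_compression_terms = n_compression,
    n_other_terms = n_other_terms,
    n_total_values = n_cid_values + n_bodypart + n_modality + n_position +
      n_compression + n_other_terms,
    n_maps_to_value = n_maps_to_value,
    n_maps_to = n_maps_to,
    n_total_relationships = n_maps_to_value + n_maps_to
  )
  s$n_total_concepts <- s$n_attributes + s$n_total_values + s$n_total_relationships
  stopifnot(
    s$n_total_values == sum(concepts$concept_class_id == "Value"),
    s$n_total_relationships == nrow(relationships),
    s$n_attributes + s$n_total_values == nrow(concepts)
  )
  structure(lapply(s, as.integer), class = "vocabulary_summary")
}

#' @export
print.vocabulary_summary <- function(x, ...) {
  cat("OMOP concepts for DICOM terminology\n")
  cat(sprintf("  Attributes (Part 6)                 %6d\n", x$n_attributes))
  cat(sprintf("  Coded values: context groups (DCM)  %6d\n", x$n_cid_values))
  cat(sprintf("                Body Part Examined    %6d\n", x$n_bodypart_values))
  cat(sprintf("                Modality              %6d\n", x$n_modality_terms))
  cat(sprintf("                Patient Position      %6d\n", x$n_patientposition_terms))
  cat(sprintf("                Lossy Compression     %6d\n", x$n_compression_terms))
  if (x$n_other_terms > 0)
    cat(sprintf("                other term values     %6d\n", x$n_other_terms))
  cat(sprintf("  Total coded values                  %6d\n", x$n_total_values))
  cat(sprintf("  'Maps to value' relationships       %6d\n", x$n_maps_to_value))
  cat(sprintf("  'Maps to' relationships             %6d\n", x$n_maps_to))
  cat(sprintf("  Total relationships                 %6d\n", x$n_total_relationships))
  cat(sprintf("  Total vocabulary content            %6d\n", x$n_total_concepts))
  invisible(x)
}

#' Run the full vocabulary build
#'
#' End-to-end construction: attribute concepts (nameless entries excluded),
#' coded-value deduplication, deterministic ordering (attributes by tag, DCM
#' values by scheme/code, term values by attribute/value), consecutive id
#' assignment from `cfg$id_base`, relationship construction and the summary.
#'
#' @param bundle A `standard_bundle` from [load_standard_bundle()].
#' @param cfg A [builder_config()].
#' @param resolver A [concept_resolver()]; when `NULL`, a stub resolver is
#'   derived from the bundle's body-part map via [resolver_from_bodypart_map()].
#' @return A `dicom_vocabulary` object: list with `concepts`,
#'   `relationships`, `summary`, `deduped`, `config`, `log`.
#' @export
#' @examples
#' dir <- tempfile(); make_standard_fixture(standard_fixture_profile("tiny"), dir)
#' vocab <- build_dicom_vocabulary(load_standard_bundle(dir))
#' vocab$summary
build_dicom_vocabulary <- function(bundle, cfg = builder_config(), resolver = NULL) {
  validate_standard_bundle(bundle)
  if (is.null(resolver)) resolver <- resolver_from_bodypart_map(bundle$bodypart_map)
  attrs <- build_attribute_concepts(bundle$attributes, cfg) |>
    arrange(.data$concept_code)
  deduped <- dedup_coded_values(bundle$occurrences, bundle$terms)
  payloads <- bind_rows(attrs, value_concept_payloads(deduped))
  concepts <- assign_concept_ids(payloads, cfg, resolver)
  relationships <- build_relationships(bundle, concepts, deduped, resolver, cfg)
  log <- bind_rows(attr(attrs, "log"), deduped$log, attr(relationships, "log"))
  structure(
    list(concepts = concepts, relationships = relationships,
         summary = summarize_vocabulary(concepts, relationships),
         deduped = deduped, config = cfg, log = log),
    class = "dicom_vocabulary"
  )
}

OMOP_CONCEPT_COLS <- c("concept_id", "concept_name", "domain_id", "vocabulary_id",
                       "concept_class_id", "standard_concept", "concept_code",
                       "valid_start_date", "valid_end_date", "invalid_reason")
OMOP_RELATIONSHIP_COLS <- c("concept_id_1", "concept_id_2", "relationship_id",
                            "valid_start_date", "valid_end_date", "invalid_reason")

#' Emit the vocabulary as OMOP CSV tables
#'
#' Writes `CONCEPT.csv` and `CONCEPT_RELATIONSHIP.csv` with the standard OMOP
#' column sets (internal provenance columns dropped). Dates are ISO-8601.
#'
#' @param vocab A `dicom_vocabulary` (or a list with `concepts` and
#'   `relationships` tables).
#' @param out_dir Output directory (created if needed).
#' @return Named integer vector of emitted row counts, invisibly.
#' @export
emit_vocabulary <- function(vocab, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  concepts <- select(vocab$concepts, all_of(OMOP_CONCEPT_COLS))
  relationships <- select(vocab$relationships, all_of(OMOP_RELATIONSHIP_COLS))
  readr::write_csv(concepts, file.path(out_dir, "CONCEPT.csv"), progress = FALSE)
  readr::write_csv(relationships, file.path(out_dir, "CONCEPT_RELATIONSHIP.csv"),
                   progress = FALSE)
  invisible(c(concepts = nrow(concepts), relationships = nrow(relationships)))
}

#' Read emitted vocabulary tables
#'
#' Re-loads `CONCEPT.csv` / `CONCEPT_RELATIONSHIP.csv` written by
#' [emit_vocabulary()].
#'
#' @param dir Directory containing the two files.
#' @return List with tibbles `concepts` and `relationships`.
#' @export
read_vocabulary <- function(dir) {
  concepts <- readr::read_csv(
    file.path(dir, "CONCEPT.csv"),
    col_types = readr::cols(concept_id = readr::col_double(),
                            .default = readr::col_character()),
    na = character(), progress = FALSE)
  relationships <- readr::read_csv(
    file.path(dir, "CONCEPT_RELATIONSHIP.csv"),
    col_types = readr::cols(concept_id_1 = readr::col_double(),
                            concept_id_2 = readr::col_double(),
                            .default = readr::col_character()),
    na = character(), progress = FALSE)
  list(concepts = concepts, relationships = relationships)
}

#' @export
print.dicom_vocabulary <- function(x, ...) {
  cat("<dicom_vocabulary> id base", format(x$config$id_base, scientific = FALSE), "\n")
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.dicom_vocabulary
#' @export
glance.dicom_vocabulary <- function(x, ...) {
  as_tibble(unclass(x$summary))
}

#' Tidy and glance methods for vocabulary builds
#'
#' `tidy()` returns one row per concept category with its count; `glance()`
#' returns the full summary as a one-row tibble.
#'
#' @param x A `dicom_vocabulary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dicom_vocabulary <- function(x, ...) {
  s <- x$summary
  tibble(
    category = c("attribute_concepts", "cid_value_concepts",
                 "bodypart_value_concepts", "modality_term_concepts",
                 "patient_position_term_concepts", "compression_term_concepts",
                 "other_term_concepts", "maps_to_value_relationships",
                 "maps_to_relationships"),
    n = c(s$n_attributes, s$n_cid_values, s$n_bodypart_values,
          s$n_modality_terms, s$n_patientposition_terms,
          s$n_compression_terms, s$n_other_terms,
          s$n_maps_to_value, s$n_maps_to)
  )
}

#' Plot the composition of a vocabulary build
#'
#' Horizontal bar chart of concept and relationship counts by category.
#'
#' @param object A `dicom_vocabulary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dicom_vocabulary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n,
                                   y = stats::reorder(.data$category, .data$n))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "rows", y = NULL,
                  title = "Custom DICOM vocabulary composition") +
    ggplot2::theme_minimal()
}
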