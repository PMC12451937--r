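# Loading the normalized DICOM Standard content (Parts 3, 6, 16).
#
# Ingestion contract: five UTF-8 comma-delimited headered files --
#   attributes.csv    tag,name,keyword,vr,vm,retired          (Part 6)
#   cid_members.csv   cid,scheme,code,meaning                 (Part 16)
#   part3_terms.csv   attribute_tag,value_string,meaning,term_kind,snomed_code
#   constraints.csv   attribute_tag,constraint_kind,cid
#   bodypart_map.csv  value_string,snomed_code                (Part 16 cross-map)
# A JSON schema describing the contract ships in inst/extdata/interchange-schema.json.

schema_violation <- function(file, row, msg) {
  abort(sprintf("schema violation in %s (row %s): %s", file, row, msg),
        class = "dicomop_schema_error")
}

read_interchange_csv <- function(path, required_cols) {
  if (!file.exists(path)) {
    abort(sprintf("interchange file not found: %s", path), class = "dicomop_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    schema_violation(basename(path), "header",
                     paste("missing columns:", paste(missing, collapse = ", ")))
  }
  df
}

#' Load a normalized Part-6 attribute dictionary
#'
#' Reads `attributes.csv` (columns `tag,name,keyword,vr,vm,retired`) into one
#' row per dictionary entry, preserving input order. Tags are stored as
#' 8-hex-digit uppercase strings without punctuation; `"(0008,0060)"` and
#' `"00080060"` are accepted on input. Entries with an empty attribute name are
#' retained here -- their exclusion from the vocabulary happens in
#' [build_attribute_concepts()].
#'
#' @param source Path to the normalized Part-6 file.
#' @return A tibble with columns `tag`, `name`, `keyword`, `vr`, `vm`,
#'   `retired` (logical) and `source_part` (`"6"`).
#' @export
#' @examples
#' dir <- tempfile(); make_standard_fixture(standard_fixture_profile("tiny"), dir)
#' load_attribute_dictionary(file.path(dir, "attributes.csv"))
load_attribute_dictionary <- function(source) {
  df <- read_interchange_csv(source, c("tag", "name", "keyword", "vr", "vm", "retired"))
  if (nrow(df) == 0) {
    return(tibble(tag = character(), name = character(), keyword = character(),
                  vr = character(), vm = character(), retired = logical(),
                  source_part = character()))
  }
  tag <- canonical_tag(df$tag)
  bad_tag <- which(!is_valid_tag(tag))
  if (length(bad_tag) > 0) {
    schema_violation(basename(source), bad_tag[1],
                     sprintf("malformed tag %s", dQuote(df$tag[bad_tag[1]])))
  }
  vr <- toupper(dicom_trim(df$vr))
  bad_vr <- which(!vr %in% DICOM_VRS)
  if (length(bad_vr) > 0) {
    schema_violation(basename(source), bad_vr[1],
                     sprintf("unknown VR %s for tag %s", dQuote(df$vr[bad_vr[1]]),
                             format_tag(tag[bad_vr[1]])))
  }
  if (anyDuplicated(tag)) {
    dup <- tag[duplicated(tag)][1]
    schema_violation(basename(source), which(tag == dup)[2],
                     sprintf("duplicate tag %s", format_tag(dup)))
  }
  tibble(
    tag = tag,
    name = df$name,
    keyword = df$keyword,
    vr = vr,
    vm = df$vm,
    retired = tolower(dicom_trim(df$retired)) %in% c("true", "t", "1", "yes"),
    source_part = "6"
  )
}

#' Load Part-16 context-group members and the body-part cross-map
#'
#' Reads `cid_members.csv` (one row per context-group member occurrence) and
#' `bodypart_map.csv` (the Body Part Examined to SNOMED cross-map). Member
#' occurrences are *not* deduplicated across CIDs here -- a code used by
#' several context groups appears once per (cid, scheme, code) row; collapsing
#' happens in [dedup_coded_values()]. Members whose coding scheme is not `DCM`
#' (for example `SCT`, `LN`) are loaded and flagged `is_dcm = FALSE`; they
#' never receive custom concepts.
#'
#' @param source Path to the normalized Part-16 member file.
#' @param bodypart_source Path to the body-part cross-map file; `NULL` for an
#'   empty map.
#' @return A list with elements `occurrences` (tibble `cid`, `scheme`, `code`,
#'   `meaning`, `is_dcm`) and `bodypart_map` (tibble `value_string`,
#'   `snomed_code`).
#' @export
load_context_groups <- function(source, bodypart_source = NULL) {
  df <- read_interchange_csv(source, c("cid", "scheme", "code", "meaning"))
  cid_num <- suppressWarnings(as.integer(df$cid))
  bad <- which(is.na(cid_num) | !nzchar(dicom_trim(df$cid)))
  if (nrow(df) > 0 && length(bad) > 0) {
    schema_violation(basename(source), bad[1], "missing or non-integer cid")
  }
  occurrences <- tibble(
    cid = if (nrow(df) > 0) cid_num else integer(),
    scheme = dicom_trim(df$scheme),
    code = df$code,
    meaning = df$meaning,
    is_dcm = dicom_trim(df$scheme) == "DCM"
  )
  bodypart_map <- tibble(value_string = character(), snomed_code = character())
  if (!is.null(bodypart_source)) {
    bp <- read_interchange_csv(bodypart_source, c("value_string", "snomed_code"))
    bodypart_map <- tibble(value_string = bp$value_string, snomed_code = bp$snomed_code)
  }
  list(occurrences = occurrences, bodypart_map = bodypart_map)
}

#' Load Part-3 Enumerated Values / Defined Terms and value constraints
#'
#' Reads `part3_terms.csv` and `constraints.csv`. Terms are the per-attribute
#' string value constraints of Part 3 (for example the Modality, Body Part
#' Examined, Patient Position and Lossy Image Compression Method code
#' strings); duplicate `(attribute_tag, value_string)` rows collapse to one
#' term. Constraints tie an attribute either to a context group (`CID`) or to
#' its own term list (`TermList`). Every referenced attribute tag must exist
#' in `attributes`.
#'
#' @param terms_source Path to the term file.
#' @param constraints_source Path to the constraint file; `NULL` for none.
#' @param attributes Attribute dictionary from [load_attribute_dictionary()].
#' @return A list with `terms` (tibble `attribute_tag`, `value_string`,
#'   `meaning`, `term_kind`, `snomed_code`), `constraints` (tibble
#'   `attribute_tag`, `constraint_kind`, `cid`) and `log` (per-attribute term
#'   counts and collapse notes).
#' @export
load_part3_terms <- function(terms_source, constraints_source, attributes) {
  df <- read_interchange_csv(terms_source,
    c("attribute_tag", "value_string", "meaning", "term_kind", "snomed_code"))
  log <- empty_log()
  terms <- tibble(
    attribute_tag = canonical_tag(df$attribute_tag),
    value_string = df$value_string,
    meaning = df$meaning,
    term_kind = df$term_kind,
    snomed_code = df$snomed_code
  )
  if (nrow(terms) > 0) {
    bad <- which(!is_valid_tag(terms$attribute_tag))
    if (length(bad) > 0) {
      schema_violation(basename(terms_source), bad[1], "malformed attribute_tag")
    }
    blank <- which(!nzchar(dicom_trim(terms$value_string)))
    if (length(blank) > 0) {
      schema_violation(basename(terms_source), blank[1], "empty value_string")
    }
    dangling <- setdiff(unique(terms$attribute_tag), attributes$tag)
    if (length(dangling) > 0) {
      abort(sprintf("term attribute tag %s not in the attribute dictionary",
                    format_tag(dangling[1])),
            class = "dicomop_referential_error")
    }
    bad_kind <- which(!terms$term_kind %in% c("Enumerated", "Defined"))
    if (length(bad_kind) > 0) {
      schema_violation(basename(terms_source), bad_kind[1],
                       sprintf("term_kind must be Enumerated or Defined, got %s",
                               dQuote(terms$term_kind[bad_kind[1]])))
    }
    n_raw <- nrow(terms)
    terms <- distinct(terms, .data$attribute_tag, .data$value_string, .keep_all = TRUE)
    if (nrow(terms) < n_raw) {
      log <- log_note(log, "terms_collapsed", "duplicate (attribute_tag, value_string) rows",
                      n_raw - nrow(terms))
    }
    counts <- count(terms, .data$attribute_tag)
    for (i in seq_len(nrow(counts))) {
      log <- log_note(log, "terms_per_attribute", format_tag(counts$attribute_tag[i]),
                      counts$n[i])
    }
  }
  constraints <- tibble(attribute_tag = character(), constraint_kind = character(),
                        cid = integer())
  if (!is.null(constraints_source)) {
    cf <- read_interchange_csv(constraints_source,
                               c("attribute_tag", "constraint_kind", "cid"))
    if (nrow(cf) > 0) {
      ctag <- canonical_tag(cf$attribute_tag)
      dangling <- setdiff(unique(ctag), attributes$tag)
      if (length(dangling) > 0) {
        abort(sprintf("constraint attribute tag %s not in the attribute dictionary",
                      format_tag(dangling[1])),
              class = "dicomop_referential_error")
      }
      kind <- dicom_trim(cf$constraint_kind)
      bad_kind <- which(!kind %in% c("CID", "TermList"))
      if (length(bad_kind) > 0) {
        schema_violation(basename(constraints_source), bad_kind[1],
                         "constraint_kind must be CID or TermList")
      }
      cid_num <- suppressWarnings(as.integer(cf$cid))
      need_cid <- which(kind == "CID" & is.na(cid_num))
      if (length(need_cid) > 0) {
        schema_violation(basename(constraints_source), need_cid[1],
                         "CID constraint requires an integer cid")
      }
      stray_cid <- which(kind == "TermList" & nzchar(dicom_trim(cf$cid)))
      if (length(stray_cid) > 0) {
        schema_violation(basename(constraints_source), stray_cid[1],
                         "TermList constraint must leave cid empty")
      }
      constraints <- tibble(attribute_tag = ctag, constraint_kind = kind, cid = cid_num)
    }
  }
  list(terms = terms, constraints = constraints, log = log)
}

#' Load a full standard bundle from an interchange directory
#'
#' Convenience wrapper reading the five interchange files from one directory
#' and returning a validated `standard_bundle` holding the Part-6 dictionary,
#' Part-16 member occurrences and body-part cross-map, and the Part-3 terms
#' and attribute value constraints.
#'
#' @param dir Directory containing `attributes.csv`, `cid_members.csv`,
#'   `part3_terms.csv`, `constraints.csv` and `bodypart_map.csv`.
#' @return An object of class `standard_bundle`: a list with `attributes`,
#'   `occurrences`, `bodypart_map`, `terms`, `constraints`, `log`.
#' @export
load_standard_bundle <- function(dir) {
  attributes <- load_attribute_dictionary(file.path(dir, "attributes.csv"))
  p16 <- load_context_groups(file.path(dir, "cid_members.csv"),
                             file.path(dir, "bodypart_map.csv"))
  p3 <- load_part3_terms(file.path(dir, "part3_terms.csv"),
                         file.path(dir, "constraints.csv"), attributes)
  bundle <- structure(
    list(attributes = attributes,
         occurrences = p16$occurrences,
         bodypart_map = p16$bodypart_map,
         terms = p3$terms,
         constraints = p3$constraints,
         log = p3$log),
    class = "standard_bundle"
  )
  validate_standard_bundle(bundle)
  bundle
}

#' Validate the cross-references of a standard bundle
#'
#' Full-scan referential checks: unique attribute tags, every term and
#' constraint tag resolving to a dictionary entry, and every CID constraint
#' pointing at a context group present in the member occurrences.
#'
#' @param bundle A `standard_bundle`.
#' @return The bundle, invisibly; errors on violation.
#' @export
validate_standard_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "standard_bundle"))
  if (anyDuplicated(bundle$attributes$tag)) {
    abort("duplicate attribute tags in bundle", class = "dicomop_referential_error")
  }
  dangling <- setdiff(unique(c(bundle$terms$attribute_tag,
                               bundle$constraints$attribute_tag)),
                      bundle$attributes$tag)
  if (length(dangling) > 0) {
    abort(sprintf("unresolved attribute tag %s", format_tag(dangling[1])),
          class = "dicomop_referential_error")
  }
  cid_constraints <- bundle$constraints$cid[bundle$constraints$constraint_kind == "CID"]
  missing_cid <- setdiff(cid_constraints, unique(bundle$occurrences$cid))
  if (length(missing_cid) > 0) {
    abort(sprintf("constraint references CID %d with no member occurrences",
                  missing_cid[1]),
          class = "dicomop_referential_error")
  }
  term_tags <- unique(bundle$terms$attribute_tag)
  termlist_tags <- bundle$constraints$attribute_tag[
    bundle$constraints$constraint_kind == "TermList"]
  missing_terms <- setdiff(termlist_tags, term_tags)
  if (length(missing_terms) > 0) {
    abort(sprintf("TermList constraint on %s has no terms", format_tag(missing_terms[1])),
          class = "dicomop_referential_error")
  }
  invisible(bundle)
}

#' Write a standard bundle back to the interchange format
#'
#' Inverse of [load_standard_bundle()]: writes the five interchange files so
#' that re-loading yields structurally identical content (round-trip).
#'
#' @param bundle A `standard_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_standard_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "standard_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(select(bundle$attributes, -"source_part"),
                   file.path(dir, "attributes.csv"), progress = FALSE, na = "")
  readr::write_csv(select(bundle$occurrences, -"is_dcm"),
                   file.path(dir, "cid_members.csv"), progress = FALSE, na = "")
  readr::write_csv(bundle$terms, file.path(dir, "part3_terms.csv"),
                   progress = FALSE, na = "")
  readr::write_csv(bundle$constraints, file.path(dir, "constraints.csv"),
                   progress = FALSE, na = "")
  readr::write_csv(bundle$bodypart_map, file.path(dir, "bodypart_map.csv"),
                   progress = FALSE, na = "")
  invisible(dir)
}

#' @export
print.standard_bundle <- function(x, ...) {
  cat("<standard_bundle>\n")
  cat(sprintf("  attributes:   %d (%d nameless)\n", nrow(x$attributes),
              sum(!nzchar(dicom_trim(x$attributes$name)))))
  cat(sprintf("  cid members:  %d occurrences in %d context groups (%d DCM)\n",
              nrow(x$occurrences), dplyr::n_distinct(x$occurrences$cid),
              sum(x$occurrences$is_dcm)))
  cat(sprintf("  part-3 terms: %d over %d attributes\n", nrow(x$terms),
              dplyr::n_distinct(x$terms$attribute_tag)))
  cat(sprintf("  constraints:  %d CID, %d TermList\n",
              sum(x$constraints$constraint_kind == "CID"),
              sum(x$constraints$constraint_kind == "TermList")))
  cat(sprintf("  body-part map: %d rows\n", nrow(x$bodypart_map)))
  invisible(x)
}
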