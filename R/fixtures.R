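# Synthetic inputs: normalized standard bundles, DICOM file trees emulating
# ADNI-like MR series, and simulated EHR tables. All generators are
# deterministic given their seed, and every generated identifier is clearly
# synthetic (test-OID UID root, "SYN-xxxx" patient ids).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

MODALITY_CID_CODES <- c(
  "MR", "CT", "US", "PT", "NM", "CR", "DX", "MG", "XA", "RF", "SC", "OT",
  "BI", "DG", "ES", "GM", "IO", "KER", "KO", "LEN", "OAM", "OCT", "OP",
  "OPM", "OPT", "OPV", "OSS", "PX", "REG", "RESP", "RG", "SEG", "SM", "SR",
  "TG", "VA", "XC", "ECG", "EPS", "HC", "HD", "AU", "BDUS", "BMD", "DOC",
  "FID", "IOL", "PLAN", "PR", "RWV", "STAIN", "ANN", "EEG", "EMG", "EOG",
  "POS", "IVUS", "IVOCT", "RTDOSE", "RTIMAGE", "RTPLAN", "RTRECORD",
  "RTSTRUCT", "SRF", "M3D", "DMS", "CFM", "TEXTUREMAP", "OPTBSV", "OPTENF",
  "MTOMO", "LS", "DD", "CD"
)

MODALITY_RETIRED_TERMS <- c("CF", "CP", "CS", "DF", "DM")

BODY_PART_BASE <- c(
  "BRAIN", "HEAD", "NECK", "CHEST", "ABDOMEN", "PELVIS", "SPINE", "CSPINE",
  "TSPINE", "LSPINE", "HIP", "KNEE", "ANKLE", "FOOT", "HAND", "WRIST",
  "ELBOW", "SHOULDER", "FEMUR", "TIBIA", "SKULL", "HEART", "LIVER",
  "KIDNEY", "BREAST", "PROSTATE", "BLADDER", "THYROID", "LUNG", "AORTA",
  "CAROTID", "ORBIT", "SINUS", "JAW", "CLAVICLE", "RIB", "STERNUM",
  "SCAPULA", "HUMERUS", "RADIUS", "ULNA"
)

PATIENT_POSITION_TERMS <- c("HFS", "HFP", "FFS", "FFP", "HFDR", "HFDL",
                            "FFDR", "FFDL", "LFP", "LFS", "RFP", "RFS",
                            "AFDR", "AFDL", "PFDR", "PFDL")

COMPRESSION_TERMS <- c("ISO_10918_1", "ISO_14495_1", "ISO_15444_1",
                       "ISO_13818_2", "ISO_14496_10", "ISO_15444_15",
                       "ISO_23008_2", "ISO_10918_4")

TAG_ANATOMIC_REGION_CODE <- "00182300"  # synthetic anatomic-region code attribute

pad_terms <- function(base, n, fmt) {
  if (n <= length(base)) head(base, n) else c(base, sprintf(fmt, seq_len(n - length(base))))
}

#' Profiles for the standard-content fixture generator
#'
#' Two built-in profiles drive [make_standard_fixture()]:
#' \describe{
#' \item{`"table2"`}{A bundle whose category counts match the vocabulary
#'   build report: 5190 dictionary attributes (7 nameless); a context-group
#'   multiplicity plan of 2218 codes in one CID, 879 in three and 184 in two
#'   (5223 member occurrences, 3281 distinct, 1063 repeated); Part-3 terms
#'   79 Modality (74 duplicating context-group codes), 318 Body Part
#'   Examined, 16 Patient Position, 8 Lossy Image Compression Method, plus
#'   318 anatomic-region terms that all duplicate context-group codes; a
#'   398-row body-part cross-map with 307 resolvable SNOMED targets; CID
#'   constraints referencing the context groups so the build yields 7101
#'   CID-derived and 739 term-derived "Maps to value" rows.}
#' \item{`"tiny"`}{5 attributes, one context group of 3 DCM codes, no terms:
#'   the minimal end-to-end bundle (3 "Maps to value" rows after build).}
#' }
#' The multiplicity split (879 codes x3 + 184 x2 = 1063 repeated codes) is
#' one fixed admissible solution of the under-determined totals, so builds
#' on the profile are exactly reproducible.
#'
#' @param name `"table2"` or `"tiny"`.
#' @param seed Seed used for (order-only) shuffling of emitted rows.
#' @return A `standard_fixture_profile` list; see fields in the source.
#' @export
standard_fixture_profile <- function(name = c("table2", "tiny"), seed = 1) {
  name <- match.arg(name)
  profile <- if (name == "table2") {
    list(
      name = "table2", seed = seed,
      n_attributes = 5190, n_nameless = 7,
      n_singles = 2218, n_triples = 879, n_doubles = 184,
      singles_split = c(999, 1219), singles_refs = c(2, 1),
      triple_refs = c(2, 1, 1), double_refs = c(1, 1),
      n_modality_terms = 79, n_modality_overlap = 74,
      n_bodypart_terms = 318, n_patientposition_terms = 16,
      n_compression_terms = 8, n_anatomic_dup_terms = 318,
      n_bodypart_p16 = 398, n_snomed_mapped = 307
    )
  } else {
    list(
      name = "tiny", seed = seed,
      n_attributes = 5, n_nameless = 0,
      n_singles = 3, n_triples = 0, n_doubles = 0,
      singles_split = 3, singles_refs = 1,
      triple_refs = integer(), double_refs = integer(),
      n_modality_terms = 0, n_modality_overlap = 0,
      n_bodypart_terms = 0, n_patientposition_terms = 0,
      n_compression_terms = 0, n_anatomic_dup_terms = 0,
      n_bodypart_p16 = 0, n_snomed_mapped = 0
    )
  }
  structure(profile, class = "standard_fixture_profile")
}

validate_profile <- function(p) {
  fail <- function(msg) abort(paste("inconsistent fixture profile:", msg),
                              class = "dicomop_fixture_error")
  counts <- unlist(p[startsWith(names(p), "n_")])
  if (any(counts < 0)) fail("negative count")
  if (sum(p$singles_split) != p$n_singles) fail("singles_split must sum to n_singles")
  if (length(p$singles_split) != length(p$singles_refs))
    fail("singles_split and singles_refs lengths differ")
  if (p$n_triples > 0 && length(p$triple_refs) != 3)
    fail("triple codes need exactly three context groups")
  if (p$n_doubles > 0 && length(p$double_refs) != 2)
    fail("double codes need exactly two context groups")
  if (p$n_modality_overlap > p$n_modality_terms)
    fail("modality overlap exceeds modality term count")
  if (p$n_snomed_mapped > p$n_bodypart_terms)
    fail("resolvable SNOMED rows exceed body-part term count")
  if (p$n_modality_overlap + p$n_anatomic_dup_terms > p$n_singles)
    fail("overlap codes exceed the singleton code pool")
  if (p$n_bodypart_p16 < p$n_bodypart_terms)
    fail("body-part map smaller than the body-part term list")
  invisible(p)
}

fixture_special_attributes <- function(p, n_cid_attrs) {
  rows <- list(
    c("00080060", "Modality", "Modality", "CS"),
    c("00180015", "Body Part Examined", "BodyPartExamined", "CS"),
    c("00080070", "Manufacturer", "Manufacturer", "LO"),
    c("00180080", "Repetition Time", "RepetitionTime", "DS")
  )
  if (p$n_patientposition_terms > 0) {
    rows <- c(rows, list(c("00185100", "Patient Position", "PatientPosition", "CS")))
  }
  if (p$n_compression_terms > 0) {
    rows <- c(rows, list(c("00282114", "Lossy Image Compression Method",
                           "LossyImageCompressionMethod", "CS")))
  }
  if (p$n_anatomic_dup_terms > 0) {
    rows <- c(rows, list(c(TAG_ANATOMIC_REGION_CODE, "Anatomic Region Code",
                           "AnatomicRegionCode", "CS")))
  }
  extra <- list(
    c("00080020", "Study Date", "StudyDate", "DA"),
    c("00080021", "Series Date", "SeriesDate", "DA"),
    c("00080018", "SOP Instance UID", "SOPInstanceUID", "UI"),
    c("0020000D", "Study Instance UID", "StudyInstanceUID", "UI"),
    c("0020000E", "Series Instance UID", "SeriesInstanceUID", "UI"),
    c("00200013", "Instance Number", "InstanceNumber", "IS"),
    c("00100020", "Patient ID", "PatientID", "LO"),
    c("00180081", "Echo Time", "EchoTime", "DS"),
    c("00180082", "Inversion Time", "InversionTime", "DS"),
    c("00181314", "Flip Angle", "FlipAngle", "DS"),
    c("00180050", "Slice Thickness", "SliceThickness", "DS"),
    c("00080008", "Image Type", "ImageType", "CS"),
    c("0008103E", "Series Description", "SeriesDescription", "LO")
  )
  cid_attrs <- lapply(seq_len(n_cid_attrs), function(i) {
    c(sprintf("0040A%03X", i), sprintf("Coded Attribute %d", i),
      sprintf("CodedAttribute%d", i), "CS")
  })
  all_rows <- c(rows, cid_attrs)
  # only grow with bookkeeping attributes while the dictionary has room
  budget <- p$n_attributes - p$n_nameless - length(all_rows)
  all_rows <- c(all_rows, head(extra, max(0, min(length(extra), budget))))
  tibble(
    tag = vapply(all_rows, `[`, "", 1),
    name = vapply(all_rows, `[`, "", 2),
    keyword = vapply(all_rows, `[`, "", 3),
    vr = vapply(all_rows, `[`, "", 4)
  )
}

#' Generate a normalized standard-content fixture
#'
#' Writes the five interchange files (`attributes.csv`, `cid_members.csv`,
#' `part3_terms.csv`, `constraints.csv`, `bodypart_map.csv`) for a
#' [standard_fixture_profile()]. Output is deterministic given the profile's
#' seed (the seed only shuffles row order; content is fixed by the counts).
#'
#' @param profile A `standard_fixture_profile`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
#' @examples
#' dir <- tempfile()
#' make_standard_fixture(standard_fixture_profile("tiny"), dir)
#' list.files(dir)
make_standard_fixture <- function(profile, out_dir) {
  validate_profile(profile)
  p <- profile
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # one constraint row per context-group reference; each gets its own attribute
  n_cid_constraints <- sum(p$singles_refs) +
    (if (p$n_triples > 0) sum(p$triple_refs) else 0) +
    (if (p$n_doubles > 0) sum(p$double_refs) else 0)

  special <- fixture_special_attributes(p, n_cid_constraints)
  n_fill <- p$n_attributes - nrow(special) - p$n_nameless
  if (n_fill < 0) {
    abort("inconsistent fixture profile: n_attributes too small for required attributes",
          class = "dicomop_fixture_error")
  }
  filler_vrs <- c("DS", "IS", "CS", "LO", "TM", "US", "FD", "UI", "SH", "DA")
  fillers <- tibble(
    tag = sprintf("3000%04X", seq_len(n_fill)),
    name = sprintf("Synthetic Attribute %04d", seq_len(n_fill)),
    keyword = sprintf("SyntheticAttribute%04d", seq_len(n_fill)),
    vr = rep_len(filler_vrs, n_fill)
  )
  nameless <- tibble(
    tag = sprintf("3002%04X", seq_len(p$n_nameless)),
    name = rep("", p$n_nameless),
    keyword = rep("", p$n_nameless),
    vr = rep("UN", p$n_nameless)
  )
  attributes <- bind_rows(special, fillers, nameless) |>
    mutate(vm = "1", retired = "FALSE")

  # --- context-group member occurrences ------------------------------------
  modality_overlap <- pad_terms(MODALITY_CID_CODES, p$n_modality_overlap, "MOD%02d")
  anatomic_dup <- sprintf("AR%04d", seq_len(p$n_anatomic_dup_terms))
  n_plain_singles <- p$n_singles - length(modality_overlap) - length(anatomic_dup)
  single_codes <- c(modality_overlap, anatomic_dup,
                    sprintf("D1%05d", seq_len(n_plain_singles)))
  triple_codes <- sprintf("DT%04d", seq_len(p$n_triples))
  double_codes <- sprintf("DD%04d", seq_len(p$n_doubles))

  cid_of <- list()
  occ <- list()
  next_cid <- 10L
  split_start <- cumsum(c(0, p$singles_split))
  for (i in seq_along(p$singles_split)) {
    codes <- single_codes[(split_start[i] + 1):split_start[i + 1]]
    cid_of[[length(cid_of) + 1]] <- list(cid = next_cid, codes = codes,
                                         refs = p$singles_refs[i])
    next_cid <- next_cid + 1L
  }
  if (p$n_triples > 0) {
    for (i in 1:3) {
      cid_of[[length(cid_of) + 1]] <- list(cid = next_cid, codes = triple_codes,
                                           refs = p$triple_refs[i])
      next_cid <- next_cid + 1L
    }
  }
  if (p$n_doubles > 0) {
    for (i in 1:2) {
      cid_of[[length(cid_of) + 1]] <- list(cid = next_cid, codes = double_codes,
                                           refs = p$double_refs[i])
      next_cid <- next_cid + 1L
    }
  }
  cid_members <- bind_rows(lapply(cid_of, function(g) {
    tibble(cid = g$cid, scheme = "DCM", code = g$codes,
           meaning = paste("Meaning of", g$codes))
  }))

  # --- Part-3 terms ---------------------------------------------------------
  term_rows <- list()
  if (p$n_modality_terms > 0) {
    modality_terms <- c(modality_overlap,
                        pad_terms(MODALITY_RETIRED_TERMS,
                                  p$n_modality_terms - p$n_modality_overlap, "ZM%02d"))
    term_rows$modality <- tibble(attribute_tag = TAG_MODALITY,
                                 value_string = modality_terms,
                                 meaning = paste("Modality", modality_terms),
                                 term_kind = "Defined")
  }
  bodypart_terms <- character()
  if (p$n_bodypart_terms > 0) {
    bodypart_terms <- pad_terms(BODY_PART_BASE, p$n_bodypart_terms, "BODYPART%03d")
    term_rows$bodypart <- tibble(attribute_tag = TAG_BODY_PART,
                                 value_string = bodypart_terms,
                                 meaning = paste("Body part", bodypart_terms),
                                 term_kind = "Defined")
  }
  if (p$n_anatomic_dup_terms > 0) {
    term_rows$anatomic <- tibble(attribute_tag = TAG_ANATOMIC_REGION_CODE,
                                 value_string = anatomic_dup,
                                 meaning = paste("Anatomic region", anatomic_dup),
                                 term_kind = "Defined")
  }
  if (p$n_patientposition_terms > 0) {
    pp <- pad_terms(PATIENT_POSITION_TERMS, p$n_patientposition_terms, "PP%02d")
    term_rows$position <- tibble(attribute_tag = TAG_PATIENT_POSITION,
                                 value_string = pp,
                                 meaning = paste("Patient position", pp),
                                 term_kind = "Enumerated")
  }
  if (p$n_compression_terms > 0) {
    lc <- pad_terms(COMPRESSION_TERMS, p$n_compression_terms, "ISO_SYN_%d")
    term_rows$compression <- tibble(attribute_tag = TAG_LOSSY_COMPRESSION_METHOD,
                                    value_string = lc,
                                    meaning = paste("Compression", lc),
                                    term_kind = "Defined")
  }
  part3_terms <- bind_rows(term_rows)
  if (nrow(part3_terms) == 0) {
    part3_terms <- tibble(attribute_tag = character(), value_string = character(),
                          meaning = character(), term_kind = character())
  }
  part3_terms <- mutate(part3_terms, snomed_code = "")

  # --- constraints ----------------------------------------------------------
  cid_attr_tags <- sprintf("0040A%03X", seq_len(n_cid_constraints))
  cid_targets <- unlist(lapply(cid_of, function(g) rep(g$cid, g$refs)))
  stopifnot(length(cid_targets) == n_cid_constraints)
  constraints <- tibble(attribute_tag = cid_attr_tags, constraint_kind = "CID",
                        cid = as.character(cid_targets))
  term_attr_tags <- unique(part3_terms$attribute_tag)
  if (length(term_attr_tags) > 0) {
    constraints <- bind_rows(constraints,
                             tibble(attribute_tag = term_attr_tags,
                                    constraint_kind = "TermList", cid = ""))
  }

  # --- body-part cross-map --------------------------------------------------
  if (p$n_bodypart_p16 > 0) {
    snomed <- sprintf("%d", 244000000 + seq_len(p$n_snomed_mapped))
    mapped <- tibble(
      value_string = bodypart_terms,
      snomed_code = c(snomed, rep("", p$n_bodypart_terms - p$n_snomed_mapped))
    )
    n_snomed_only <- p$n_bodypart_p16 - p$n_bodypart_terms
    snomed_only <- tibble(
      value_string = rep("", n_snomed_only),
      snomed_code = sprintf("%d", 245000000 + seq_len(n_snomed_only))
    )
    bodypart_map <- bind_rows(mapped, snomed_only)
  } else {
    bodypart_map <- tibble(value_string = character(), snomed_code = character())
  }

  with_seed(p$seed, {
    cid_members <- cid_members[sample.int(nrow(cid_members)), ]
    if (nrow(bodypart_map) > 0) bodypart_map <- bodypart_map[sample.int(nrow(bodypart_map)), ]
  })

  readr::write_csv(attributes, file.path(out_dir, "attributes.csv"), progress = FALSE)
  readr::write_csv(cid_members, file.path(out_dir, "cid_members.csv"), progress = FALSE)
  readr::write_csv(part3_terms, file.path(out_dir, "part3_terms.csv"), progress = FALSE)
  readr::write_csv(constraints, file.path(out_dir, "constraints.csv"), progress = FALSE)
  readr::write_csv(bodypart_map, file.path(out_dir, "bodypart_map.csv"), progress = FALSE)
  invisible(out_dir)
}

#' Specification for the synthetic DICOM file tree
#'
#' Describes an ADNI-like MR archive: patients, studies and series counts, a
#' protocol mix over MPRAGE / T2 / FLAIR (MPRAGE and FLAIR series carry an
#' inversion time, T2 does not), instances per series, and rates of missing
#' and deliberately empty Body Part Examined values used to exercise the
#' metadata filter.
#'
#' @param n_patients,studies_per_patient,series_per_study,instances_per_series
#'   Tree dimensions (all >= 1).
#' @param protocol_mix Named fractions over `MPRAGE`, `T2`, `FLAIR`; must sum
#'   to 1.
#' @param missing_bodypart_rate Fraction of series without a Body Part
#'   Examined element at all.
#' @param empty_value_rate Fraction of series whose Body Part Examined is
#'   present but empty (dropped by the empty-value rule).
#' @param seed RNG seed.
#' @return A `dicom_fixture_spec`.
#' @export
dicom_fixture_spec <- function(n_patients = 3, studies_per_patient = 1,
                               series_per_study = 2, instances_per_series = 5,
                               protocol_mix = c(MPRAGE = 0.5, T2 = 0.25, FLAIR = 0.25),
                               missing_bodypart_rate = 0,
                               empty_value_rate = 0, seed = 1) {
  if (n_patients < 1 || studies_per_patient < 1 || series_per_study < 1 ||
      instances_per_series < 1) {
    abort("tree dimensions must all be >= 1", class = "dicomop_fixture_error")
  }
  if (abs(sum(protocol_mix) - 1) > 1e-8) {
    abort("protocol_mix fractions must sum to 1", class = "dicomop_fixture_error")
  }
  if (!all(names(protocol_mix) %in% c("MPRAGE", "T2", "FLAIR"))) {
    abort("protocol_mix names must be MPRAGE, T2, FLAIR",
          class = "dicomop_fixture_error")
  }
  rates <- c(missing_bodypart_rate, empty_value_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "dicomop_fixture_error")
  }
  structure(list(n_patients = n_patients, studies_per_patient = studies_per_patient,
                 series_per_study = series_per_study,
                 instances_per_series = instances_per_series,
                 protocol_mix = protocol_mix,
                 missing_bodypart_rate = missing_bodypart_rate,
                 empty_value_rate = empty_value_rate, seed = seed),
            class = "dicom_fixture_spec")
}

# largest-remainder allocation of n slots over named fractions
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(fractions))
}

protocol_params <- function(protocol) {
  switch(protocol,
    MPRAGE = list(tr = c(2100, 2500), te = c(2, 4), ti = c(800, 1100),
                  desc = "Accelerated Sagittal MPRAGE"),
    T2 = list(tr = c(3000, 6000), te = c(80, 120), ti = NULL,
              desc = "Axial T2 TSE"),
    FLAIR = list(tr = c(8000, 11000), te = c(90, 130), ti = c(2200, 2800),
                 desc = "Sagittal 3D FLAIR")
  )
}

#' Generate a synthetic DICOM file tree
#'
#' Writes Part-10 files organized `patient/study/series/instance` with
#' MPRAGE / T2 / FLAIR acquisition parameters, together with deliberately
#' empty values, excluded-VR attributes, a private tag and a sequence to
#' exercise the harvest filter. A manifest CSV in `out_dir` records ground
#' truth per series, including the number of metadata elements the VR filter
#' is expected to keep.
#'
#' @param spec A [dicom_fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
make_dicom_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "dicom_fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_series_total <- spec$n_patients * spec$studies_per_patient * spec$series_per_study
  proto_counts <- allocate_counts(n_series_total, spec$protocol_mix)
  protocols <- rep(names(proto_counts), proto_counts)

  manifest <- list()
  with_seed(spec$seed, {
    protocols <- sample(protocols)
    series_i <- 0L
    for (pat in seq_len(spec$n_patients)) {
      patient_id <- sprintf("SYN-%04d", pat)
      for (stu in seq_len(spec$studies_per_patient)) {
        study_uid <- sprintf("%s.1.%d.%d", UID_ROOT_TEST, pat, stu)
        study_date <- format(as.Date("2017-01-01") + ((pat * 7 + stu) %% 365), "%Y%m%d")
        for (ser in seq_len(spec$series_per_study)) {
          series_i <- series_i + 1L
          protocol <- protocols[series_i]
          prm <- protocol_params(protocol)
          series_uid <- sprintf("%s.1.%d.%d.%d", UID_ROOT_TEST, pat, stu, ser)
          tr <- round(stats::runif(1, prm$tr[1], prm$tr[2]))
          te <- round(stats::runif(1, prm$te[1], prm$te[2]), 1)
          ti <- if (is.null(prm$ti)) NULL else round(stats::runif(1, prm$ti[1], prm$ti[2]))
          bp_missing <- stats::runif(1) < spec$missing_bodypart_rate
          bp_empty <- !bp_missing && stats::runif(1) < spec$empty_value_rate
          body_part <- if (bp_missing) NULL else if (bp_empty) "" else "BRAIN"

          base <- list(
            list(TAG_PATIENT_ID, "LO", patient_id),
            list(TAG_STUDY_DATE, "DA", study_date),
            list(TAG_SERIES_DATE, "DA", study_date),
            list(TAG_MODALITY, "CS", "MR"),
            list(TAG_MANUFACTURER, "LO", "SYN Imaging Works"),
            list("0008103E", "LO", prm$desc),
            list(TAG_STUDY_UID, "UI", study_uid),
            list(TAG_SERIES_UID, "UI", series_uid),
            list(TAG_SOP_CLASS_UID, "UI", MR_SOP_CLASS),
            list("00180080", "DS", format(tr, scientific = FALSE)),
            list("00180081", "DS", format(te, scientific = FALSE)),
            list("00180087", "DS", "3"),                 # field strength
            list("00181314", "DS", "9"),                 # flip angle
            list("00180050", "DS", "1.2"),               # slice thickness
            list("00180091", "IS", "1"),                 # echo train length
            list(TAG_PATIENT_POSITION, "CS", "HFS"),
            list("00080008", "CS", c("ORIGINAL", "PRIMARY")),
            list("00080022", "DA", ""),                  # deliberately empty
            list("00081010", "SH", "SYNSCAN1"),          # excluded VR (SH)
            list("00090010", "LO", "SYNTH PRIVATE"),     # private tag
            list("7FE00010", "OW", as.raw(rep(0, 16)))   # placeholder pixels
          )
          if (!is.null(ti)) {
            base <- c(base, list(list("00180082", "DS", format(ti, scientific = FALSE))))
          }
          if (!is.null(body_part)) {
            base <- c(base, list(list(TAG_BODY_PART, "CS", body_part)))
          }
          # referenced image sequence: harvest must skip it, not descend
          sq_item <- tibble(tag = c("00081150", "00081155"), vr = c("UI", "UI"),
                            value = list(MR_SOP_CLASS,
                                         paste0(UID_ROOT_TEST, ".ref.1")))
          base <- c(base, list(list("00081140", "SQ", list(sq_item))))

          kept_per_instance <- sum(vapply(base, function(el) {
            vr <- el[[2]]; val <- el[[3]]
            if (vr == "SQ" || is.raw(val)) return(0L)
            vals <- as.character(val)
            vals <- vals[!is_empty_value(vals)]
            if (vr %in% VR_WHITELIST || el[[1]] == TAG_MANUFACTURER)
              length(vals) else 0L
          }, 0L)) + 1L  # + InstanceNumber (IS)

          series_dir <- file.path(out_dir, patient_id,
                                  sprintf("study%02d", stu), sprintf("series%02d", ser))
          dir.create(series_dir, recursive = TRUE, showWarnings = FALSE)
          for (inst in seq_len(spec$instances_per_series)) {
            sop_uid <- sprintf("%s.%d", series_uid, inst)
            elements <- c(base, list(
              list(TAG_SOP_INSTANCE_UID, "UI", sop_uid),
              list(TAG_INSTANCE_NUMBER, "IS", as.character(inst))
            ))
            df <- tibble(tag = vapply(elements, function(e) e[[1]], ""),
                         vr = vapply(elements, function(e) e[[2]], ""),
                         value = lapply(elements, function(e) e[[3]]))
            write_dicom(df, file.path(series_dir, sprintf("IM%04d.dcm", inst)),
                        sop_instance_uid = sop_uid)
          }
          manifest[[length(manifest) + 1]] <- tibble(
            patient_id = patient_id, study_uid = study_uid,
            series_uid = series_uid, protocol = protocol,
            series_date = study_date,
            tr = tr, te = te, ti = ifelse(is.null(ti), NA_real_, ti),
            body_part = ifelse(is.null(body_part), NA_character_, body_part),
            n_instances = spec$instances_per_series,
            n_kept_expected = kept_per_instance
          )
        }
      }
    }
  })
  manifest <- bind_rows(manifest)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Generate simulated EHR tables
#'
#' Emits `person.csv`, `condition_occurrence.csv`, `measurement.csv` and the
#' `patient_map.csv` linking synthetic DICOM patient ids (`SYN-xxxx`) to
#' OMOP person ids. Diagnoses follow a cognitively-normal / MCI / AD mix
#' with the configurable proportions of an ADNI-3-like cohort (default
#' 133:151:87); measurements are questionnaire-style neuropsychiatric
#' inventory items.
#'
#' @param n_persons Number of persons (>= 1).
#' @param seed RNG seed.
#' @param out_dir Output directory (created if needed).
#' @param diagnosis_mix Named weights over `CN`, `MCI`, `AD`.
#' @param items Questionnaire items per person.
#' @return List of the four tibbles, invisibly.
#' @export
make_ehr_fixture <- function(n_persons, seed = 1, out_dir,
                             diagnosis_mix = c(CN = 133, MCI = 151, AD = 87),
                             items = 10) {
  if (n_persons < 1) abort("n_persons must be >= 1", class = "dicomop_fixture_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- allocate_counts(n_persons, diagnosis_mix / sum(diagnosis_mix))
  with_seed(seed, {
    diagnosis <- sample(rep(names(counts), counts))
    person <- tibble(
      person_id = seq_len(n_persons),
      gender_concept_id = sample(c(8507, 8532), n_persons, replace = TRUE),
      year_of_birth = sample(1930:1955, n_persons, replace = TRUE),
      person_source_value = sprintf("SYN-%04d", seq_len(n_persons))
    )
    condition <- tibble(
      condition_occurrence_id = seq_len(n_persons),
      person_id = person$person_id,
      condition_concept_id = c(CN = 4297400, MCI = 4148109, AD = 378419)[diagnosis],
      condition_source_value = diagnosis,
      condition_start_date = format(as.Date("2017-01-01") +
                                      sample(0:364, n_persons, replace = TRUE))
    )
    measurement <- tidyr::expand_grid(person_id = person$person_id,
                                      item = seq_len(items)) |>
      mutate(measurement_id = row_number(),
             measurement_source_value = sprintf("NPI-Q%02d", .data$item),
             value_as_number = sample(0:3, n(), replace = TRUE),
             measurement_date = "2017-06-01") |>
      select("measurement_id", "person_id", "measurement_source_value",
             "value_as_number", "measurement_date")
  })
  patient_map <- tibble(patient_id = person$person_source_value,
                        person_id = person$person_id)
  readr::write_csv(person, file.path(out_dir, "person.csv"), progress = FALSE)
  readr::write_csv(condition, file.path(out_dir, "condition_occurrence.csv"),
                   progress = FALSE)
  readr::write_csv(measurement, file.path(out_dir, "measurement.csv"), progress = FALSE)
  readr::write_csv(patient_map, file.path(out_dir, "patient_map.csv"), progress = FALSE)
  invisible(list(person = person, condition_occurrence = condition,
                 measurement = measurement, patient_map = patient_map))
}
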