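# Value-representation code sets and tag arithmetic shared across modules.

# Full two-letter VR code set of the current standard.
DICOM_VRS <- c(
  "AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS", "LO", "LT",
  "OB", "OD", "OF", "OL", "OV", "OW", "PN", "SH", "SL", "SQ", "SS", "ST",
  "SV", "TM", "UC", "UI", "UL", "UN", "UR", "US", "UT", "UV"
)

# VRs whose explicit-VR encoding uses the 12-byte header (2 reserved bytes +
# 32-bit length); all others use the 8-byte header with a 16-bit length.
LONG_FORM_VRS <- c("OB", "OD", "OF", "OL", "OV", "OW", "SQ", "UC", "UN",
                   "UR", "UT", "SV", "UV")

# VRs whose values are kept when filtering harvested metadata: numeric and
# coded/date/time representations. Free-text VRs (LO, LT, SH, ST, UC, UT, PN)
# are excluded apart from the Manufacturer exception handled by the filter.
VR_WHITELIST <- c("AT", "CS", "DA", "DT", "DS", "FL", "FD", "IS", "SL", "SS",
                  "SV", "TM", "UL", "US", "UV")

# VRs eligible for numeric value_as_number parsing in the Measurement table.
NUMERIC_VRS <- c("DS", "IS", "FL", "FD", "SL", "SS", "SV", "UL", "US", "UV")

TAG_MANUFACTURER <- "00080070"
TAG_MODALITY <- "00080060"
TAG_BODY_PART <- "00180015"
TAG_PATIENT_POSITION <- "00185100"
TAG_LOSSY_COMPRESSION_METHOD <- "00282114"
TAG_SERIES_DATE <- "00080021"
TAG_STUDY_DATE <- "00080020"
TAG_STUDY_UID <- "0020000D"
TAG_SERIES_UID <- "0020000E"
TAG_SOP_INSTANCE_UID <- "00080018"
TAG_SOP_CLASS_UID <- "00080016"
TAG_INSTANCE_NUMBER <- "00200013"
TAG_PATIENT_ID <- "00100020"
TAG_PIXEL_DATA <- "7FE00010"

#' Value-representation whitelist used by the metadata filter
#'
#' Returns the set of two-letter VR codes retained by [filter_elements()]:
#' numeric and coded representations (`AT`, `CS`, `DA`, `DT`, `DS`, `FL`,
#' `FD`, `IS`, `SL`, `SS`, `SV`, `TM`, `UL`, `US`, `UV`). Free-text VRs are
#' excluded; the single exception, Manufacturer `(0008,0070)`, is applied by
#' tag rather than by VR.
#'
#' @return Character vector of VR codes.
#' @export
#' @examples
#' dicom_vr_whitelist()
dicom_vr_whitelist <- function() VR_WHITELIST

# Canonical tag form: 8 uppercase hex digits, no punctuation.
canonical_tag <- function(x) {
  x <- toupper(gsub("[^0-9A-Fa-f]", "", x))
  x
}

is_valid_tag <- function(x) {
  grepl("^[0-9A-F]{8}$", x)
}

# Presentation form "(gggg,eeee)".
format_tag <- function(tag) {
  paste0("(", substr(tag, 1, 4), ",", substr(tag, 5, 8), ")")
}

tag_group <- function(tag) strtoi(substr(tag, 1, 4), 16L)
tag_element <- function(tag) strtoi(substr(tag, 5, 8), 16L)

# Private data elements live in odd-numbered groups.
is_private_tag <- function(tag) tag_group(tag) %% 2L == 1L

# Empty-value test: zero length after stripping whitespace and the trailing
# space/NUL padding DICOM uses to even out value lengths.
dicom_trim <- function(x) trimws(x)

is_empty_value <- function(x) {
  is.na(x) | !nzchar(dicom_trim(x))
}
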