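{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Normalized DICOM standard-content interchange files",
  "description": "Contract for the five UTF-8, comma-delimited, headered files the standard-model loaders ingest. Each property below describes one file as an array of row objects.",
  "type": "object",
  "properties": {
    "attributes.csv": {
      "description": "Part 6 data dictionary, one row per attribute.",
      "type": "array",
      "items": {
        "type": "object",
        "required": ["tag", "name", "keyword", "vr", "vm", "retired"],
        "properties": {
          "tag": {"type": "string", "pattern": "^[0-9A-Fa-f]{8}$|^\\([0-9A-Fa-f]{4},[0-9A-Fa-f]{4}\\)$"},
          "name": {"type": "string"},
          "keyword": {"type": "string"},
          "vr": {"type": "string", "enum": ["AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT","OB","OD","OF","OL","OV","OW","PN","SH","SL","SQ","SS","ST","SV","TM","UC","UI","UL","UN","UR","US","UT","UV"]},
          "vm": {"type": "string"},
          "retired": {"type": "string", "enum": ["TRUE", "FALSE", "true", "false", "1", "0", "yes", "no", "t", "f"]}
        }
      }
    },
    "cid_members.csv": {
      "description": "Part 16 context-group member occurrences, one row per (cid, scheme, code); codes used by several CIDs appear once per CID.",
      "type": "array",
      "items": {
        "type": "object",
        "required": ["cid", "scheme", "code", "meaning"],
        "properties": {
          "cid": {"type": "string", "pattern": "^[0-9]+$"},
          "scheme": {"type": "string", "minLength": 1},
          "code": {"type": "string", "minLength": 1},
          "meaning": {"type": "string"}
        }
      }
    },
    "part3_terms.csv": {
      "description": "Part 3 Enumerated Values / Defined Terms, one row per (attribute, value).",
      "type": "array",
      "items": {
        "type": "object",
        "required": ["attribute_tag", "value_string", "meaning", "term_kind", "snomed_code"],
        "properties": {
          "attribute_tag": {"type": "string", "pattern": "^[0-9A-Fa-f]{8}$"},
          "value_string": {"type": "string", "minLength": 1},
          "meaning": {"type": "string"},
          "term_kind": {"type": "string", "enum": ["Enumerated", "Defined"]},
          "snomed_code": {"type": "string"}
        }
      }
    },
    "constraints.csv": {
      "description": "Attribute value constraints: CID rows carry an integer cid, TermList rows leave cid empty and bind the attribute's rows of part3_terms.csv.",
      "type": "array",
      "items": {
        "type": "object",
        "required": ["attribute_tag", "constraint_kind", "cid"],
        "properties": {
          "attribute_tag": {"type": "string", "pattern": "^[0-9A-Fa-f]{8}$"},
          "constraint_kind": {"type": "string", "enum": ["CID", "TermList"]},
          "cid": {"type": "string", "pattern": "^[0-9]*$"}
        }
      }
    },
    "bodypart_map.csv": {
      "description": "Part 16 Body Part Examined cross-map. Rows with a value_string tie a DICOM code string to a SNOMED code (possibly empty when unmapped); rows with an empty value_string are SNOMED-only entries.",
      "type": "array",
      "items": {
        "type": "object",
        "required": ["value_string", "snomed_code"],
        "properties": {
          "value_string": {"type": "string"},
          "snomed_code": {"type": "string"}
        }
      }
    }
  },
  "required": ["attributes.csv", "cid_members.csv", "part3_terms.csv", "constraints.csv", "bodypart_map.csv"]
}
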